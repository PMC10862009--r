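test_that("anchor gap is the plain Euclidean CA-CA distance", {
  ## 3-4-5 triangle: anchors at (0,0,0) and (3,4,0)
  at <- data.frame(
    chain = "A", res_seq = c(1L, 2L, 3L, 4L),
    res_name = "ALA", atom_name = "CA",
    x = c(0, 1, 2, 3), y = c(0, 5, 5, 4), z = 0)
  s <- polymer_structure(at)
  expect_equal(anchor_gap(s, segment_spec("A", 2, 3)), 5.0)
  ## toy scaffold: value equals an independently computed distance
  sc <- build_toy_scaffold()
  ca <- sc$atoms[sc$atoms$atom_name == "CA", ]
  hand <- sqrt(sum((as.numeric(ca[ca$res_seq == 23, c("x", "y", "z")]) -
                      as.numeric(ca[ca$res_seq == 18, c("x", "y", "z")]))^2))
  expect_equal(anchor_gap(sc, toy_scaffold_loop()), hand, tolerance = 1e-12)
  ## loop at the chain terminus has no flanking residue
  expect_error(anchor_gap(sc, segment_spec("A", 1, 4)), "anchor")
})

test_that("helix span follows the 1.5 A per-residue rise", {
  expect_equal(helix_span_estimate(1), 0.0)
  expect_equal(helix_span_estimate(20), 28.5)
  expect_equal(helix_span_estimate(35), 51.0)
  expect_error(helix_span_estimate(0), "n_res")
})

test_that("linker recommendation covers the mismatch plus slack, capped", {
  expect_equal(recommend_linkers(20, 20), 1L)        # slack alone needs one
  expect_equal(recommend_linkers(10, 41), 5L)        # ceil(35/7): a G4S per side
  expect_warning(n <- recommend_linkers(0, 100), "cap")
  expect_equal(n, 10L)
  ## monotone non-decreasing in the mismatch
  mism <- seq(0, 60, by = 2.5)
  recs <- vapply(mism, function(m) {
    suppressWarnings(recommend_linkers(10, 10 + m))
  }, integer(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("chimera assembly obeys the length identity and index-map bijection", {
  sc <- build_toy_scaffold()
  donor <- build_ideal_helix(strrep("A", 20), chain_id = "D")
  des <- build_chimera(sc, toy_scaffold_loop(), donor, segment_spec("D", 1, 20))
  expect_equal(nchar(des$chimera_sequence), 40 - 4 + 5 + 20 + 5)
  map <- des$index_map
  expect_equal(map$chimera_pos, seq_len(nrow(map)))
  dn <- map[map$source == "donor", ]
  expect_equal(dn$source_res, 1:20)            # donor maps in order
  expect_equal(diff(dn$chimera_pos), rep(1L, 19))
  ## identity graft reproduces the scaffold sequence
  des0 <- build_chimera(sc, toy_scaffold_loop(), sc, toy_scaffold_loop(),
                        "", "")
  expect_equal(des0$chimera_sequence, sequence_of(sc, "A"))
})

test_that("chimera length identity holds across randomized designs", {
  set.seed(7)
  for (k in 1:20) {
    n_sc <- sample(12:30, 1)
    loop_start <- sample(4:(n_sc - 7), 1)
    loop_len <- sample(2:4, 1)
    n_dn <- sample(5:25, 1)
    lk_n <- strrep("G", sample(0:6, 1))
    lk_c <- strrep("S", sample(0:6, 1))
    sc <- build_ideal_helix(strrep("A", n_sc))
    dn <- build_ideal_helix(strrep("K", n_dn), chain_id = "D")
    des <- build_chimera(sc, segment_spec("A", loop_start,
                                          loop_start + loop_len - 1),
                         dn, segment_spec("D", 1, n_dn), lk_n, lk_c)
    expect_equal(nchar(des$chimera_sequence),
                 n_sc - loop_len + nchar(lk_n) + n_dn + nchar(lk_c))
    expect_false(anyDuplicated(des$index_map$chimera_pos) > 0)
  }
})

test_that("the initial model keeps scaffold coordinates and avoids clashes", {
  sc <- build_toy_scaffold()
  donor <- build_ideal_helix("AEAAIKEAAAKIEAAEKAAA", chain_id = "D")
  des <- build_chimera(sc, toy_scaffold_loop(), donor, segment_spec("D", 1, 20))
  mod <- build_initial_model(des, sc, donor)
  expect_equal(nrow(residue_table(mod)), 66L)
  ## scaffold part preserved bit-exactly
  map <- des$index_map
  sc_rows <- map[map$source == "scaffold", ]
  for (i in seq_len(nrow(sc_rows))) {
    got <- as.matrix(mod$atoms[mod$atoms$res_seq == sc_rows$chimera_pos[i],
                               c("x", "y", "z")])
    want <- as.matrix(sc$atoms[sc$atoms$res_seq == sc_rows$source_res[i],
                               c("x", "y", "z")])
    expect_identical(unname(got), unname(want))
  }
  ## no inter-segment pair below the 2 A hard-sphere floor
  xyz <- coords(mod)
  seg_of <- map$source[match(mod$atoms$res_seq, map$chimera_pos)]
  d2 <- as.matrix(dist(xyz))^2
  diff_seg <- outer(seg_of, seg_of, "!=")
  adj <- abs(outer(mod$atoms$res_seq, mod$atoms$res_seq, "-")) <= 1
  relevant <- diff_seg & !adj
  expect_gte(sqrt(min(d2[relevant])), 2.0)
})

test_that("an identity graft reproduces the scaffold and an oversized graft fails", {
  sc <- build_toy_scaffold()
  des0 <- build_chimera(sc, toy_scaffold_loop(), sc, toy_scaffold_loop(),
                        "", "")
  mod0 <- build_initial_model(des0, sc, sc)
  expect_equal(coords(mod0), coords(sc))
  donor <- build_ideal_helix(strrep("A", 30), chain_id = "D")
  des_big <- build_chimera(sc, toy_scaffold_loop(), donor,
                           segment_spec("D", 1, 30), "", "")
  expect_error(build_initial_model(des_big, sc, donor, displacement = 1),
               "clash")
})

test_that("alanine truncation removes side chains, keeps backbones, is idempotent", {
  b <- build_helix_bundle()
  s <- b$structure
  trp_atoms <- s$atoms$atom_name[s$atoms$res_seq == 4]
  expect_true(length(trp_atoms) > 5)
  mut <- mutate_to_alanine(s, c(4, 11, 18))
  for (r in c(4, 11, 18)) {
    got <- sort(mut$atoms$atom_name[mut$atoms$res_seq == r])
    expect_equal(got, sort(c("N", "CA", "C", "O", "CB")))
    expect_equal(unique(mut$atoms$res_name[mut$atoms$res_seq == r]), "ALA")
  }
  ## backbone coordinates untouched
  bb <- c("N", "CA", "C", "O")
  for (r in c(4, 11, 18)) {
    a <- mut$atoms[mut$atoms$res_seq == r & mut$atoms$atom_name %in% bb, ]
    b2 <- s$atoms[s$atoms$res_seq == r & s$atoms$atom_name %in% bb, ]
    expect_equal(unname(as.matrix(a[, c("x", "y", "z")])),
                 unname(as.matrix(b2[, c("x", "y", "z")])))
  }
  mut2 <- mutate_to_alanine(mut, c(4, 11, 18))
  expect_identical(mut2$atoms, mut$atoms)
  expect_error(mutate_to_alanine(s, 999), "not found")
})
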