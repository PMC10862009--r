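test_that("the parameter table covers all residues and sums to formal charges", {
  ff <- default_forcefield()
  for (res in names(helixgraft:::AA_SIDECHAIN_ATOMS)) {
    atoms <- c("N", "CA", "C", "O", helixgraft:::AA_SIDECHAIN_ATOMS[[res]])
    if (res != "PRO") atoms <- c(atoms, "H")
    have <- ff$atom_name[ff$res_name == res]
    expect_setequal(have, atoms)
    qsum <- sum(ff$partial_charge[ff$res_name == res])
    expect_equal(qsum, unname(helixgraft:::AA_FORMAL_CHARGE[res]),
                 tolerance = 1e-3)
  }
  expect_true(all(ff$lj_epsilon > 0))
  expect_true(all(ff$lj_rmin_half > 0))
})

test_that("two point charges, the LJ minimum, and the cutoff behave exactly", {
  ## two lysine NZ-like charges 10 A apart, Coulomb only
  at <- data.frame(chain = "A", res_seq = c(1L, 3L), res_name = "XXX",
                   atom_name = "Q1", x = c(0, 10), y = 0, z = 0)
  s <- polymer_structure(at)
  ff <- data.frame(res_name = "XXX", atom_name = "Q1",
                   partial_charge = 1, lj_epsilon = 0, lj_rmin_half = 1)
  e <- pair_energy(s, 1, 3, params = ff)
  expect_equal(unname(e["coulomb"]), 332.0636 / 10, tolerance = 1e-9)
  expect_equal(unname(e["lj"]), 0)
  ## neutral pair at exactly rmin: lj = -eps
  ff2 <- data.frame(res_name = "XXX", atom_name = "Q1",
                    partial_charge = 0, lj_epsilon = 0.25, lj_rmin_half = 2)
  at2 <- at; at2$x <- c(0, 4)
  e2 <- pair_energy(polymer_structure(at2), 1, 3, params = ff2)
  expect_equal(unname(e2["lj"]), -0.25, tolerance = 1e-12)
  ## everything beyond the cutoff vanishes
  at3 <- at; at3$x <- c(0, 12.5)
  e3 <- pair_energy(polymer_structure(at3), 1, 3, params = ff)
  expect_equal(unname(e3), c(0, 0, 0))
})

test_that("pair_energy matches a brute-force double loop on random fixtures", {
  ff <- default_forcefield()
  set.seed(11)
  b <- build_helix_bundle()
  s <- b$structure
  pairs <- rbind(cbind(sample(1:19, 8, replace = TRUE), 0),
                 cbind(sample(1:20, 4), sample(31:50, 4)))
  pairs[1:8, 2] <- pairs[1:8, 1] + 1   # adjacent pairs exercise exclusions
  for (k in seq_len(nrow(pairs))) {
    e <- pair_energy(s, pairs[k, 1], pairs[k, 2], params = ff)
    o <- brute_pair_energy(s, pairs[k, 1], pairs[k, 2], ff)
    expect_equal(unname(e), unname(o), tolerance = 1e-9)
  }
  ## Coulomb term is linear in each charge
  ffq <- ff; ffq$partial_charge <- 2 * ffq$partial_charge
  e1 <- pair_energy(s, 2, 5, params = ff)
  e4 <- pair_energy(s, 2, 5, params = ffq)
  expect_equal(unname(e4["coulomb"]), 4 * unname(e1["coulomb"]),
               tolerance = 1e-9)
  expect_equal(unname(e4["lj"]), unname(e1["lj"]), tolerance = 1e-12)
})

test_that("the energy matrix is symmetric, additive and rigid-invariant", {
  h <- build_ideal_helix("ASLNAQLASLNAQLA")
  set.seed(12)
  frames <- lapply(1:3, function(i) {
    coords(h) + matrix(rnorm(length(coords(h)), sd = 0.15), ncol = 3)
  })
  ens <- ensemble(h, frames)
  M <- energy_matrix(ens, segment_spec("A", 1, 15))
  expect_lt(max(abs(M$total - t(M$total)), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(M$total - (M$coulomb + M$lj)), na.rm = TRUE), 1e-9)
  expect_true(all(is.na(diag(M$total))))
  ## single frame, two residues reduces to pair_energy
  M2 <- energy_matrix(ensemble(h, frames[1]), c(2, 7))
  e <- pair_energy(h, 2, 7, frame = frames[[1]])
  expect_equal(M2$total[1, 2], unname(e["total"]), tolerance = 1e-9)
  ## rigid transform of every frame leaves the matrix unchanged
  tr <- random_rigid()
  ens_r <- ensemble(h, lapply(frames, apply_rigid, tr = tr))
  Mr <- energy_matrix(ens_r, segment_spec("A", 1, 15))
  expect_equal(Mr$total, M$total, tolerance = 1e-6)
})

test_that("an ideal helix shows the adjacent diagonal and the i,i+4 bond band", {
  h <- build_ideal_helix(strrep("A", 20))
  M <- energy_matrix(ensemble(h), segment_spec("A", 1, 20))
  sep <- abs(outer(M$res_seq, M$res_seq, "-"))
  expect_true(all(M$band[sep == 1] == "adjacent"))
  ## hydrogen-bond band cells live at |i-j| = 4 for an ideal helix
  hb <- which(!is.na(M$band) & M$band == "hbond_band", arr.ind = TRUE)
  expect_gt(nrow(hb), 10)
  expect_true(all(abs(M$res_seq[hb[, 1]] - M$res_seq[hb[, 2]]) == 4))
  ## band means: adjacent strongest, then the bond band, then the rest
  m_adj <- mean(M$total[sep == 1])
  is_hb <- !is.na(M$band) & M$band == "hbond_band"
  is_other <- !is.na(M$band) & M$band == "other" & sep > 1
  m_hb <- mean(M$total[is_hb])
  m_other <- mean(M$total[is_other])
  expect_lt(m_adj, m_hb)
  expect_lt(m_hb, m_other)
})

test_that("hydrophobic contacts require proximity and the hydrophobic set", {
  ## two leucines far apart: empty map
  l2 <- build_ideal_helix("LAAAAAAAAAAAAAAAAAAL")
  cm <- hydrophobic_contacts(l2, segment_spec("A", 1, 1),
                             segment_spec("A", 20, 20))
  expect_equal(nrow(cm), 0L)
  ## bundle: planted anchor contacts appear, and only hydrophobic pairs
  b <- build_helix_bundle()
  cm2 <- hydrophobic_contacts(b$structure, b$helixA, b$helixB)
  expect_true(all(cm2$res_a %in% 1:20))
  expect_true(all(cm2$res_b %in% 31:50))
  expect_true(all(b$anchors %in% cm2$res_a))
  nm <- residue_table(b$structure)
  hyd <- helixgraft:::HYDROPHOBIC_RESIDUES
  expect_true(all(nm$res_name[match(cm2$res_a, nm$res_seq)] %in% hyd))
  expect_true(all(nm$res_name[match(cm2$res_b, nm$res_seq)] %in% hyd))
  ## a close LEU-SER pair is excluded by the set rule
  at <- rbind(
    data.frame(chain = "A", res_seq = 1L, res_name = "LEU",
               atom_name = c("N", "CA", "C", "O", "CB"),
               x = c(0, 1.4, 2, 1.5, 1.8), y = 0:4 * 0.1, z = 0),
    data.frame(chain = "A", res_seq = 5L, res_name = "SER",
               atom_name = c("N", "CA", "C", "O", "CB"),
               x = c(0, 1.4, 2, 1.5, 1.8) + 3.8, y = 0:4 * 0.1, z = 0))
  s <- polymer_structure(at)
  expect_equal(nrow(hydrophobic_contacts(s, segment_spec("A", 1, 1),
                                         segment_spec("A", 5, 5))), 0L)
})

test_that("planted aromatic anchors top the cross-helix ranking and their truncation weakens the interface", {
  b <- build_helix_bundle()
  res <- c(1:20, 31:50)
  M <- energy_matrix(ensemble(b$structure), res)
  top <- interhelix_contributors(M, b$helixA, b$helixB, top_k = 3)
  expect_setequal(top$res_seq, b$anchors)
  expect_true(all(top$cross_energy < 0))
  ## alanine truncation of the anchors shrinks |cross-helix energy|
  mut <- mutate_to_alanine(b$structure, b$anchors)
  Mm <- energy_matrix(ensemble(mut), res)
  cross <- function(M) {
    ia <- match(1:20, M$res_seq); ib <- match(31:50, M$res_seq)
    sum(M$total[ia, ib], na.rm = TRUE)
  }
  expect_lt(cross(M), 0)
  expect_lt(abs(cross(Mm)), abs(cross(M)))
})

test_that("contributor ranking handles planted blocks, ties and overlap errors", {
  ## hand-built matrix: one strongly negative cross cell
  M <- list(res_seq = 1:6, res_name = rep("ALA", 6),
            total = matrix(0, 6, 6))
  M$total[2, 5] <- M$total[5, 2] <- -3
  class(M) <- "EnergyMatrix"
  top <- interhelix_contributors(M, segment_spec("A", 1, 3),
                                 segment_spec("A", 4, 6), top_k = 2)
  expect_equal(top$res_seq[1:2], c(2L, 5L))
  ## all-zero cross block: ranked by residue index with zero scores
  M0 <- M; M0$total[] <- 0
  t0 <- interhelix_contributors(M0, segment_spec("A", 1, 3),
                                segment_spec("A", 4, 6), top_k = 6)
  expect_equal(t0$res_seq, 1:6)
  expect_equal(t0$cross_energy, rep(0, 6))
  expect_error(interhelix_contributors(M, segment_spec("A", 1, 4),
                                       segment_spec("A", 4, 6)),
               "disjoint")
})
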