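test_that("a minimal single-residue file parses to one frame of four atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), f)
  ens <- read_pdb(f)
  expect_s3_class(ens, "Ensemble")
  expect_equal(n_frames(ens), 1L)
  expect_equal(nrow(ens$topology$atoms), 4L)
  expect_equal(ens$topology$atoms$res_name, rep("ALA", 4))
})

test_that("MODEL blocks become frames and incongruent blocks are rejected", {
  h <- build_ideal_helix("AEAAIK")
  ens <- ensemble(h, list(coords(h), coords(h) + 1, coords(h) + 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, f)
  back <- read_pdb(f)
  expect_equal(n_frames(back), 3L)
  ## corrupt: drop one atom from the second MODEL
  lines <- readLines(f)
  atom2 <- which(startsWith(lines, "ATOM"))
  drop <- atom2[nrow(h$atoms) + 1]
  writeLines(lines[-drop], f)
  expect_error(read_pdb(f), "topology")
})

test_that("write/read round trip preserves coordinates to 1e-3 and topology", {
  set.seed(42)
  for (seqs in c("AEAAIKEA", "GVVAGLWY")) {
    s <- build_ideal_helix(seqs)
    frames <- list(coords(s),
                   coords(s) + matrix(rnorm(length(coords(s)), sd = 2),
                                      ncol = 3))
    ens <- ensemble(s, frames, frame_spacing_ps = 20, replicate_id = 2L)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(ens, f)
    back <- read_pdb(f, frame_spacing_ps = 20, replicate_id = 2L)
    expect_equal(back$topology$atoms$atom_name, s$atoms$atom_name)
    expect_equal(back$topology$atoms$res_seq, s$atoms$res_seq)
    for (k in 1:2) {
      expect_lt(max(abs(back$frames[[k]] - frames[[k]])), 1e-3)
    }
    ## second round trip is exact (quantization is idempotent)
    f2 <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(back, f2)
    back2 <- read_pdb(f2)
    expect_identical(back2$frames, back$frames)
  }
})

test_that("an independent PDB reader agrees with what write_pdb emits", {
  skip_if_not_installed("bio3d")
  h <- build_ideal_helix("AEAAIKEAAAKI")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ensemble(h), f)
  pb <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(nrow(pb$atom), nrow(h$atoms))
  ours <- read_pdb(f)
  theirs <- matrix(pb$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(theirs - ours$frames[[1]])), 1e-9)
  expect_equal(pb$atom$resno, h$atoms$res_seq)
})

test_that("single-frame writes omit MODEL records, multi-frame writes pair them", {
  h <- build_ideal_helix("AEAA")
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ensemble(h), f1)
  expect_false(any(grepl("^MODEL", readLines(f1))))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ensemble(h, list(coords(h), coords(h))), f2)
  lines <- readLines(f2)
  expect_equal(sum(grepl("^MODEL", lines)), 2L)
  expect_equal(sum(grepl("^ENDMDL", lines)), 2L)
})

test_that("malformed coordinate fields are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.4x8   0.000   0.000  1.00  0.00"), f)
  expect_error(read_pdb(f), "line 2")
})

test_that("altloc conformers collapse to the highest-occupancy one", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00"), f)
  ens <- read_pdb(f)
  n_xyz <- ens$frames[[1]][ens$topology$atoms$atom_name == "N", ]
  expect_equal(unname(n_xyz[1]), 9.0)
  expect_equal(nrow(ens$topology$atoms), 4L)
})

test_that("extract_segment returns inclusive ranges and reports gaps", {
  donor <- build_ideal_helix(strrep("A", 40), start_res = 35L)
  expect_equal(nrow(residue_table(extract_segment(donor,
                                                  segment_spec("A", 35, 69)))),
               35L)
  seg <- extract_segment(donor, segment_spec("A", 35, 54))
  expect_equal(nrow(residue_table(seg)), 20L)
  expect_equal(54 - 35 + 1 - 4, 16)  # interior count after 2-per-end exclusion
  expect_equal(nrow(residue_table(extract_segment(donor,
                                                  segment_spec("A", 40, 40)))),
               1L)
  gappy <- polymer_structure(donor$atoms[donor$atoms$res_seq != 50, ])
  expect_error(extract_segment(gappy, segment_spec("A", 35, 54)), "50")
})

test_that("sequence extraction maps residue names to one-letter codes", {
  loop <- build_backbone("VVAG", phi = -70, psi = 140)
  expect_equal(sequence_of(loop, "A"), "VVAG")
  linker <- build_backbone("GGGGS", phi = -70, psi = 140)
  expect_equal(sequence_of(linker, "A"), "GGGGS")
  expect_equal(sequence_of(loop, "Z"), "")
  odd <- loop
  odd$atoms$res_name[odd$atoms$res_seq == 1] <- "XYZ"
  expect_equal(substr(sequence_of(odd, "A"), 1, 1), "X")
})
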