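## Chimeric antigen construction: loop excision, linker sizing from
## anchor geometry, chimera sequence assembly with index maps, a crude
## clash-checked rigid-placement initial model, and alanine truncation.

HELIX_RISE_PER_RES <- 1.5    # A per residue along an alpha-helix axis
LINKER_REACH_PER_RES <- 3.5  # A per extended linker residue
LINKER_SLACK <- 4.0          # A of required spare reach
LINKER_CAP <- 10L            # residues per side
CLASH_FLOOR <- 2.0           # A heavy-atom hard-sphere floor

#' C-alpha distance between the residues flanking an excisable loop
#'
#' The anchors are residues `loop$start_res - 1` and `loop$end_res + 1`;
#' the grafted segment must bridge this gap.
#'
#' @param scaffold a `PolymerStructure`.
#' @param loop a `SegmentSpec` naming the loop to excise.
#' @return distance in Angstrom.
#' @export
anchor_gap <- function(scaffold, loop) {
  at <- scaffold$atoms
  ca <- function(r) {
    i <- which(at$chain == loop$chain_id & at$res_seq == r &
                 at$atom_name == "CA")
    if (!length(i)) {
      stop("anchor residue ", r, " (chain ", loop$chain_id,
           ") missing or lacks CA")
    }
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  vnorm(ca(loop$end_res + 1L) - ca(loop$start_res - 1L))
}

#' Axial span of an ideal alpha-helix
#'
#' `1.5 * (n_res - 1)` Angstrom, the canonical helical rise.
#'
#' @param n_res number of residues (>= 1).
#' @return span in Angstrom.
#' @export
helix_span_estimate <- function(n_res) {
  if (n_res < 1) stop("n_res must be >= 1")
  HELIX_RISE_PER_RES * (n_res - 1)
}

#' Recommend a per-side flexible linker length
#'
#' Smallest `n >= 0` such that two extended linkers of `n` residues
#' (3.5 A reach each) cover the donor/anchor length mismatch plus 4 A of
#' slack: `2 * n * 3.5 >= |donor_end_to_end - anchor_gap| + 4`.  Capped at
#' 10 residues per side (with a warning).
#'
#' @param anchor_gap_a anchor C-alpha gap, Angstrom.
#' @param donor_end_to_end_a donor terminal C-alpha distance, Angstrom.
#' @return integer residues per side.
#' @export
recommend_linkers <- function(anchor_gap_a, donor_end_to_end_a) {
  stopifnot(anchor_gap_a >= 0, donor_end_to_end_a >= 0)
  need <- abs(donor_end_to_end_a - anchor_gap_a) + LINKER_SLACK
  n <- as.integer(ceiling(need / (2 * LINKER_REACH_PER_RES)))
  if (n > LINKER_CAP) {
    warning("required linker length ", n, " exceeds cap; using ", LINKER_CAP)
    n <- LINKER_CAP
  }
  n
}

#' Geometry report for a prospective graft
#'
#' @param scaffold,loop scaffold structure and loop to excise.
#' @param donor,donor_segment donor structure and segment to graft.
#' @return a `GeometryReport` list: `anchor_gap`, `donor_end_to_end`,
#'   `helix_span_estimate`, `recommended_linker_len`.
#' @export
graft_geometry <- function(scaffold, loop, donor, donor_segment) {
  gap <- anchor_gap(scaffold, loop)
  seg <- extract_segment(donor, donor_segment)
  at <- seg$atoms
  ca <- function(r) {
    i <- which(at$res_seq == r & at$atom_name == "CA" &
                 at$chain == donor_segment$chain_id)
    if (!length(i)) stop("donor terminal residue ", r, " lacks CA")
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  e2e <- vnorm(ca(donor_segment$end_res) - ca(donor_segment$start_res))
  n_res <- donor_segment$end_res - donor_segment$start_res + 1L
  structure(list(anchor_gap = gap, donor_end_to_end = e2e,
                 helix_span_estimate = helix_span_estimate(n_res),
                 recommended_linker_len = recommend_linkers(gap, e2e)),
            class = "GeometryReport")
}

#' @export
print.GeometryReport <- function(x, ...) {
  cat(sprintf(paste0("GeometryReport: anchor gap %.2f A, donor end-to-end",
                     " %.2f A, helix span estimate %.1f A, recommended",
                     " linker %d residue(s) per side\n"),
              x$anchor_gap, x$donor_end_to_end, x$helix_span_estimate,
              x$recommended_linker_len))
  invisible(x)
}

#' Assemble a chimeric graft design
#'
#' The chimera sequence is the scaffold up to the residue before the
#' loop, the N-side linker, the donor segment, the C-side linker, and the
#' scaffold after the loop.  The index map records, for every chimera
#' position (numbered sequentially from 1), its source
#' (scaffold/linker/donor) and the source residue number, so results can
#' be reported in donor coordinates.
#'
#' @param scaffold a `PolymerStructure`.
#' @param loop `SegmentSpec` of the excised scaffold loop.
#' @param donor a `PolymerStructure`.
#' @param donor_segment `SegmentSpec` of the grafted donor region.
#' @param linker_n,linker_c one-letter linker sequences (may be "").
#' @param scaffold_id,donor_id labels carried into the design.
#' @return a `GraftDesign` list with `chimera_sequence` and `index_map`.
#' @export
build_chimera <- function(scaffold, loop, donor, donor_segment,
                          linker_n = "GGGGS", linker_c = "GGGGS",
                          scaffold_id = "scaffold", donor_id = "donor") {
  sc_rt <- residue_table(scaffold, chain = loop$chain_id)
  if (!all(seq.int(loop$start_res, loop$end_res) %in% sc_rt$res_seq)) {
    stop("loop ", format(loop), " not fully present in scaffold")
  }
  donor_seg <- extract_segment(donor, donor_segment)
  dn_rt <- residue_table(donor_seg, chain = donor_segment$chain_id)

  pre <- sc_rt[sc_rt$res_seq < loop$start_res, ]
  post <- sc_rt[sc_rt$res_seq > loop$end_res, ]
  parts <- list(
    data.frame(source = "scaffold", source_res = pre$res_seq,
               letter = aa_three_to_one(pre$res_name)),
    if (nchar(linker_n)) data.frame(source = "linker", source_res = NA_integer_,
                                    letter = strsplit(linker_n, "")[[1]]),
    data.frame(source = "donor", source_res = dn_rt$res_seq,
               letter = aa_three_to_one(dn_rt$res_name)),
    if (nchar(linker_c)) data.frame(source = "linker", source_res = NA_integer_,
                                    letter = strsplit(linker_c, "")[[1]]),
    data.frame(source = "scaffold", source_res = post$res_seq,
               letter = aa_three_to_one(post$res_name))
  )
  map <- do.call(rbind, Filter(Negate(is.null), parts))
  map$chimera_pos <- seq_len(nrow(map))
  rownames(map) <- NULL
  design <- structure(list(
    scaffold_id = scaffold_id, donor_id = donor_id,
    excised_loop = loop, donor_segment = donor_segment,
    linker_n = linker_n, linker_c = linker_c,
    chimera_sequence = paste(map$letter, collapse = ""),
    index_map = map[, c("chimera_pos", "source", "source_res", "letter")]
  ), class = "GraftDesign")
  stopifnot(nchar(design$chimera_sequence) ==
              nrow(sc_rt) - (loop$end_res - loop$start_res + 1L) +
              nchar(linker_n) + nrow(dn_rt) + nchar(linker_c))
  design
}

#' @export
print.GraftDesign <- function(x, ...) {
  cat("GraftDesign:", x$scaffold_id, "loop", format(x$excised_loop),
      "replaced by", x$donor_id, format(x$donor_segment), "with linkers",
      sQuote(x$linker_n), "/", sQuote(x$linker_c), "\n")
  cat("Chimera (", nchar(x$chimera_sequence), " aa): ",
      x$chimera_sequence, "\n", sep = "")
  invisible(x)
}

## Rotation taking unit vector a to unit vector b.
#' @keywords internal
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b); s <- vnorm(v); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## opposite: rotate 180 about any perpendicular
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about_axis(cross3(a, ref), pi))
  }
  rotation_about_axis(v / s, atan2(s, c_))
}

#' Crude rigid-placement initial model of a chimera
#'
#' Keeps scaffold coordinates outside the excised loop bit-exactly.  The
#' donor segment is copied rigid-body: its terminal C-alpha axis is
#' aligned with the anchor axis, its midpoint placed at the anchor
#' midpoint displaced outward along the loop normal, and the pose is
#' scanned in 10-degree steps about the anchor axis until clash-free
#' (ties broken by maximal minimum inter-segment distance).  Linkers are
#' built with ideal extended backbone geometry laid along the
#' anchor-to-donor-terminus direction.  This is an initial model for
#' analysis seeding, not a physical structure: junction peptide bonds are
#' not closed.
#'
#' @param design a `GraftDesign`.
#' @param scaffold,donor the source structures.
#' @param chain_id chain id of the output (default "A").
#' @param displacement outward offset of the donor midpoint from the
#'   anchor midpoint, Angstrom; default scales with linker length.
#' @return a `PolymerStructure` renumbered sequentially from 1, congruent
#'   with the design's index map.
#' @export
build_initial_model <- function(design, scaffold, donor, chain_id = "A",
                                displacement = NULL) {
  stopifnot(inherits(design, "GraftDesign"))
  loop <- design$excised_loop
  at <- scaffold$atoms
  sc_chain <- loop$chain_id
  map <- design$index_map

  ## identity graft: no linkers and the donor segment already sits on the
  ## excised loop's coordinates -> copy the scaffold through unchanged
  identity_graft <- FALSE
  if (nchar(design$linker_n) == 0 && nchar(design$linker_c) == 0 &&
      (design$donor_segment$end_res - design$donor_segment$start_res) ==
      (loop$end_res - loop$start_res)) {
    ds <- tryCatch(extract_segment(donor, design$donor_segment),
                   error = function(e) NULL)
    ls <- tryCatch(extract_segment(scaffold, loop), error = function(e) NULL)
    if (!is.null(ds) && !is.null(ls) &&
        nrow(ds$atoms) == nrow(ls$atoms) &&
        max(abs(coords(ds) - coords(ls))) < 1e-9) {
      identity_graft <- TRUE
    }
  }

  take_residue <- function(src, res, new_pos, new_name = NULL) {
    ix <- which(src$atoms$chain == attr(src, "take_chain") &
                  src$atoms$res_seq == res)
    d <- src$atoms[ix, , drop = FALSE]
    d$res_seq <- new_pos
    d$chain <- chain_id
    if (!is.null(new_name)) d$res_name <- new_name
    d
  }

  ## scaffold portion (coordinates preserved exactly)
  attr(scaffold, "take_chain") <- sc_chain
  pieces <- list()
  for (i in which(map$source == "scaffold")) {
    pieces[[length(pieces) + 1L]] <-
      take_residue(scaffold, map$source_res[i], map$chimera_pos[i])
  }

  if (identity_graft) {
    for (i in which(map$source == "donor")) {
      pieces[[length(pieces) + 1L]] <-
        take_residue(scaffold, map$source_res[i], map$chimera_pos[i])
    }
    allat <- do.call(rbind, pieces)
    allat <- allat[order(allat$res_seq), , drop = FALSE]
    return(polymer_structure(allat, title = "initial chimera model"))
  }

  ## donor rigid body
  dseg <- extract_segment(donor, design$donor_segment)
  attr(dseg, "take_chain") <- design$donor_segment$chain_id
  ca_of <- function(s, chain, r) {
    i <- which(s$atoms$chain == chain & s$atoms$res_seq == r &
                 s$atoms$atom_name == "CA")
    if (!length(i)) stop("residue ", r, " lacks CA")
    as.numeric(s$atoms[i[1], c("x", "y", "z")])
  }
  a1 <- ca_of(scaffold, sc_chain, loop$start_res - 1L)
  a2 <- ca_of(scaffold, sc_chain, loop$end_res + 1L)
  anchor_mid <- (a1 + a2) / 2
  axis <- a2 - a1
  sc_centroid <- colMeans(coords(scaffold))
  out_dir <- anchor_mid - sc_centroid
  out_dir <- out_dir - axis * sum(out_dir * axis) / sum(axis^2)
  if (vnorm(out_dir) < 1e-6) {
    ref <- if (abs(unitv(axis)[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    out_dir <- cross3(axis, ref)
  }
  out_dir <- unitv(out_dir)
  if (is.null(displacement)) {
    ## scale the outward offset with linker reach and donor size so a
    ## long donor helix clears the scaffold body
    displacement <- LINKER_SLACK +
      1.0 * max(nchar(design$linker_n), nchar(design$linker_c)) +
      0.25 * vnorm(d2 <- ca_of(dseg, design$donor_segment$chain_id,
                               design$donor_segment$end_res) -
                     ca_of(dseg, design$donor_segment$chain_id,
                           design$donor_segment$start_res))
  }
  target_mid <- anchor_mid + out_dir * displacement

  d1 <- ca_of(dseg, design$donor_segment$chain_id, design$donor_segment$start_res)
  d2 <- ca_of(dseg, design$donor_segment$chain_id, design$donor_segment$end_res)
  R0 <- rotation_between(d2 - d1, axis)
  dxyz0 <- sweep(coords(dseg) %*% t(R0), 2,
                 target_mid - as.numeric(R0 %*% ((d1 + d2) / 2)), "+")

  scaffold_xyz <- as.matrix(do.call(rbind, pieces)[, c("x", "y", "z")])
  scaffold_pos_per_atom <- do.call(rbind, pieces)$res_seq

  ## chimera positions of mobile atoms (junction-adjacent residues are
  ## covalently linked and exempt from the clash check)
  dn_pos_all <- map$chimera_pos[map$source == "donor"]
  lk_pos_all <- map$chimera_pos[map$source == "linker"]
  ln_pos <- lk_pos_all[seq_len(nchar(design$linker_n))]
  lc_pos <- lk_pos_all[nchar(design$linker_n) + seq_len(nchar(design$linker_c))]
  dseg_res_per_atom <- dseg$atoms$res_seq
  dn_pos_per_atom <- dn_pos_all[match(dseg_res_per_atom,
                                      sort(unique(dseg_res_per_atom)))]

  build_linker <- function(letters_, from, to, offset) {
    if (!length(letters_)) return(NULL)
    ext <- build_backbone(paste(letters_, collapse = ""),
                          phi = 180, psi = 180, with_cb = TRUE)
    exyz <- coords(ext)
    ca_rows <- which(ext$atoms$atom_name == "CA")
    axis_e <- if (length(ca_rows) > 1) {
      exyz[ca_rows[length(ca_rows)], ] - exyz[ca_rows[1], ]
    } else c(1, 0, 0)
    if (vnorm(axis_e) < 1e-9) axis_e <- c(1, 0, 0)
    Rl <- rotation_between(axis_e, to - from)
    exyz <- exyz %*% t(Rl)
    ## centre the linker on the gap midpoint, then push it outward until
    ## it clears both flanking segments
    mid_t <- (from + to) / 2 + out_dir * offset
    mid_e <- colMeans(exyz[ca_rows, , drop = FALSE])
    exyz <- sweep(exyz, 2, mid_t - mid_e, "+")
    list(s = ext, xyz = exyz)
  }

  assemble <- function(theta, off_n, off_c) {
    Rt <- rotation_about_axis(axis, theta)
    dxyz <- sweep(dxyz0, 2, target_mid)
    dxyz <- sweep(dxyz %*% t(Rt), 2, target_mid, "+")
    ca_rows_d <- which(dseg$atoms$atom_name == "CA")
    d_first <- dxyz[ca_rows_d[1], ]
    d_last <- dxyz[ca_rows_d[length(ca_rows_d)], ]
    ln <- build_linker(strsplit(design$linker_n, "")[[1]], a1, d_first, off_n)
    lc <- build_linker(strsplit(design$linker_c, "")[[1]], d_last, a2, off_c)
    list(dxyz = dxyz, ln = ln, lc = lc)
  }

  ## minimum heavy-atom distance among atoms of *different* segments
  ## whose chimera positions differ by more than 1
  pose_min_dist <- function(pose) {
    xyz <- rbind(scaffold_xyz, pose$dxyz)
    pos <- c(scaffold_pos_per_atom, dn_pos_per_atom)
    seg <- c(rep(1L, nrow(scaffold_xyz)), rep(2L, nrow(pose$dxyz)))
    if (!is.null(pose$ln)) {
      xyz <- rbind(xyz, pose$ln$xyz)
      pos <- c(pos, ln_pos[pose$ln$s$atoms$res_seq])
      seg <- c(seg, rep(3L, nrow(pose$ln$xyz)))
    }
    if (!is.null(pose$lc)) {
      xyz <- rbind(xyz, pose$lc$xyz)
      pos <- c(pos, lc_pos[pose$lc$s$atoms$res_seq])
      seg <- c(seg, rep(4L, nrow(pose$lc$xyz)))
    }
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
    mask <- outer(seg, seg, "!=") & abs(outer(pos, pos, "-")) > 1
    if (!any(mask)) return(Inf)
    sqrt(max(0, min(d2[mask])))
  }

  best <- NULL; best_min <- -Inf
  offsets <- seq(0, 8, by = 2)
  found <- FALSE
  for (theta in seq(0, 350, by = 10) * pi / 180) {
    for (off in offsets) {
      pose <- assemble(theta, off, off)
      m <- pose_min_dist(pose)
      if (m > best_min) { best <- pose; best_min <- m }
      if (m >= CLASH_FLOOR) { found <- TRUE; best <- pose; best_min <- m
        break }
    }
    if (found) break
  }
  if (best_min < CLASH_FLOOR) {
    stop(sprintf(paste0("unresolvable clash: minimum inter-segment ",
                        "heavy-atom distance %.2f A below the %.1f A floor ",
                        "after the placement search"), best_min, CLASH_FLOOR))
  }

  ## stitch atoms together under chimera numbering
  dn_pos <- map$chimera_pos[map$source == "donor"]
  dseg_rt <- residue_table(dseg, chain = design$donor_segment$chain_id)
  dseg_moved <- set_coords(dseg, best$dxyz)
  attr(dseg_moved, "take_chain") <- design$donor_segment$chain_id
  for (k in seq_along(dn_pos)) {
    pieces[[length(pieces) + 1L]] <-
      take_residue(dseg_moved, dseg_rt$res_seq[k], dn_pos[k])
  }
  add_linker <- function(lk, side) {
    if (is.null(lk)) return()
    s <- set_coords(lk$s, lk$xyz)
    pos <- map$chimera_pos[map$source == "linker"]
    pos <- if (side == "n") pos[seq_len(nchar(design$linker_n))] else
      pos[nchar(design$linker_n) + seq_len(nchar(design$linker_c))]
    rt <- residue_table(s)
    attr(s, "take_chain") <- s$atoms$chain[1]
    for (k in seq_along(pos)) {
      pieces[[length(pieces) + 1L]] <<-
        take_residue(s, rt$res_seq[k], pos[k])
    }
  }
  add_linker(best$ln, "n")
  add_linker(best$lc, "c")

  allat <- do.call(rbind, pieces)
  allat <- allat[order(allat$res_seq), , drop = FALSE]
  polymer_structure(allat, title = "initial chimera model")
}

#' Truncate residues to alanine
#'
#' Sets the residue name to ALA and removes side-chain atoms beyond CB.
#' Backbone atoms are never altered.  Glycine positions gain no CB; they
#' are renamed with a warning.  Idempotent.
#'
#' @param s a `PolymerStructure`.
#' @param positions residue numbers to mutate.
#' @param chain chain id (default: first chain).
#' @return the mutated structure.
#' @export
mutate_to_alanine <- function(s, positions, chain = NULL) {
  if (is.null(chain)) chain <- s$atoms$chain[1]
  at <- s$atoms
  keepable <- c("N", "H", "CA", "C", "O", "CB", "OXT")
  for (r in positions) {
    ix <- which(at$chain == chain & at$res_seq == r)
    if (!length(ix)) stop("position ", r, " not found in chain ", chain)
    if (at$res_name[ix[1]] == "GLY") {
      warning("position ", r, " is glycine: renamed to ALA but gains no CB")
    }
    at$res_name[ix] <- "ALA"
    drop <- ix[!at$atom_name[ix] %in% keepable]
    if (length(drop)) at <- at[-drop, , drop = FALSE]
  }
  polymer_structure(at, title = s$title)
}
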