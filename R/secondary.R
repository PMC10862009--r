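## Alpha-helix assignment from backbone hydrogen-bond energies
## (Kabsch-Sander electrostatic model, as used by DSSP), and the
## helical-fraction statistic over segments and replicates.

KS_COUPLING <- 27.888   # kcal*A/mol, q1*q2*f for the N-H...O=C dipoles
KS_CUTOFF <- -0.5       # kcal/mol; a hydrogen bond exists below this
KS_EMIN <- -9.9         # clamp floor for near-contact geometries

#' Place amide hydrogens on a frame
#'
#' For each non-proline, non-chain-start residue i with a complete
#' preceding carbonyl, H is placed 1.0 A from N along the C(i-1)->O(i-1)
#' reverse direction: `H = N_i + unit(C_{i-1} - O_{i-1})`.  Prolines and
#' chain starts get no hydrogen.  Residues with missing backbone atoms are
#' flagged un-assignable rather than failing.
#'
#' @param frame n_atoms x 3 coordinate matrix congruent with `topology`.
#' @param topology a `PolymerStructure`.
#' @param chain chain id (default: first chain).
#' @return list with `H` (n_res x 3 matrix, NA rows where no H) and the
#'   backbone index used.
#' @export
place_amide_hydrogens <- function(frame, topology, chain = NULL) {
  if (is.null(chain)) chain <- topology$atoms$chain[1]
  bb <- backbone_index(topology, chain)
  n <- nrow(bb$res)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if (bb$res$res_name[i] == "PRO") next
    ## previous residue must be the sequence neighbour and complete
    if (bb$res$res_seq[i] != bb$res$res_seq[i - 1] + 1L) next
    ni <- bb$N[i]; cp <- bb$C[i - 1]; op <- bb$O[i - 1]
    if (anyNA(c(ni, cp, op))) next
    d <- frame[cp, ] - frame[op, ]
    nd <- vnorm(d)
    if (nd < 1e-9) next
    H[i, ] <- frame[ni, ] + d / nd
  }
  list(H = H, bb = bb)
}

#' Kabsch-Sander hydrogen-bond energy for one donor/acceptor pair
#'
#' `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom, clamped below at -9.9; returns `Inf` if any
#' distance falls under 0.5 A (overlapping atoms), and `NA` when a needed
#' atom is absent (un-assignable pair).
#'
#' @param donor_res,acceptor_res residue indices (within the chain) of the
#'   N-H donor and C=O acceptor.
#' @param frame coordinate matrix congruent with `topology`.
#' @param topology a `PolymerStructure`.
#' @param chain chain id (default: first chain).
#' @param hyd optional precomputed result of [place_amide_hydrogens()].
#' @return energy in kcal/mol.
#' @export
ks_energy <- function(donor_res, acceptor_res, frame, topology,
                      chain = NULL, hyd = NULL) {
  if (is.null(chain)) chain <- topology$atoms$chain[1]
  if (is.null(hyd)) hyd <- place_amide_hydrogens(frame, topology, chain)
  bb <- hyd$bb
  if (abs(donor_res - acceptor_res) < 2) {
    stop("donor and acceptor must be separated by at least 2 residues")
  }
  ni <- bb$N[donor_res]; ci <- bb$C[acceptor_res]; oi <- bb$O[acceptor_res]
  h <- hyd$H[donor_res, ]
  if (anyNA(c(ni, ci, oi)) || anyNA(h)) return(NA_real_)
  N <- frame[ni, ]; C <- frame[ci, ]; O <- frame[oi, ]
  ks_energy_xyz(N, h, C, O)
}

## Pure-coordinate form, also used vectorized by assign_helix.
#' @keywords internal
ks_energy_xyz <- function(N, H, C, O) {
  r_on <- vnorm(O - N); r_ch <- vnorm(C - H)
  r_oh <- vnorm(O - H); r_cn <- vnorm(C - N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(Inf)
  e <- KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  max(e, KS_EMIN)
}

#' Assign alpha-helix (H) vs other (C) per residue for one frame
#'
#' A 4-turn exists at residue i when the Kabsch-Sander energy of the bond
#' from the N-H of residue i+4 to the C=O of residue i is below
#' -0.5 kcal/mol.  Residues i+1..i+4 are labelled H whenever 4-turns exist
#' at both i and i+1; every other residue (including un-assignable ones)
#' is C.
#'
#' @param frame coordinate matrix congruent with `topology`.
#' @param topology a `PolymerStructure`.
#' @param chain chain id (default: first chain).
#' @return character vector of codes ("H"/"C"), one per residue of the
#'   chain, named by residue number.
#' @export
assign_helix <- function(frame, topology, chain = NULL) {
  if (is.null(chain)) chain <- topology$atoms$chain[1]
  hyd <- place_amide_hydrogens(frame, topology, chain)
  bb <- hyd$bb
  n <- nrow(bb$res)
  code <- rep("C", n)
  if (n >= 5) {
    turn <- rep(FALSE, n)
    consecutive <- c(diff(bb$res$res_seq) == 1L, FALSE)
    for (i in seq_len(n - 4)) {
      ## require an unbroken numbering run i..i+4
      if (!all(consecutive[i:(i + 3)])) next
      d <- i + 4L
      ci <- bb$C[i]; oi <- bb$O[i]; nd <- bb$N[d]
      if (anyNA(c(ci, oi, nd)) || anyNA(hyd$H[d, ])) next
      e <- ks_energy_xyz(frame[nd, ], hyd$H[d, ], frame[ci, ], frame[oi, ])
      turn[i] <- is.finite(e) && e < KS_CUTOFF
    }
    for (i in seq_len(n - 5)) {
      if (turn[i] && turn[i + 1]) code[(i + 1):(i + 4)] <- "H"
    }
  }
  stats::setNames(code, bb$res$res_seq)
}

#' Helical fraction of a segment over replicate ensembles
#'
#' For each replicate, the fraction is the occupancy of the H state over
#' all (frame, residue) pairs among the interior segment residues --
#' i.e. after excluding `exclude_terminal` residues from each end of the
#' segment.  The report carries the mean and sample standard deviation
#' (n-1) across replicates, plus the per-residue-majority reading (share
#' of interior residues helical in at least half the frames).
#'
#' @param ensembles an `Ensemble` or list of them (replicates).
#' @param segment a `SegmentSpec`.
#' @param exclude_terminal residues dropped from each segment end
#'   (default 2).
#' @param stride analyze every `stride`-th frame (default 1).
#' @return a `HelicityReport` list: `segment`, `exclude_terminal`,
#'   `interior_res`, `per_replicate_fraction`, `mean`, `std`,
#'   `per_residue_occupancy`, `per_residue_majority_share`.
#' @export
helical_fraction <- function(ensembles, segment, exclude_terminal = 2,
                             stride = 1) {
  if (inherits(ensembles, "Ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1, inherits(segment, "SegmentSpec"))
  lo <- segment$start_res + exclude_terminal
  hi <- segment$end_res - exclude_terminal
  if (hi < lo) stop("no interior residues left after terminal exclusion")
  interior <- seq.int(lo, hi)

  occ_sum <- stats::setNames(numeric(length(interior)), interior)
  occ_n <- 0L
  fractions <- vapply(ensembles, function(ens) {
    topo <- ens$topology
    rt <- residue_table(topo, chain = segment$chain_id)
    if (!all(interior %in% rt$res_seq)) {
      stop("segment ", format(segment), " not resolvable in topology")
    }
    pick <- seq(1, length(ens$frames), by = stride)
    h_count <- 0L
    for (f in pick) {
      code <- assign_helix(ens$frames[[f]], topo, segment$chain_id)
      in_seg <- code[as.character(interior)]
      h_count <- h_count + sum(in_seg == "H")
      occ_sum <<- occ_sum + (in_seg == "H")
    }
    occ_n <<- occ_n + length(pick)
    h_count / (length(pick) * length(interior))
  }, numeric(1))

  per_res <- occ_sum / occ_n
  structure(list(
    segment = segment,
    exclude_terminal = exclude_terminal,
    interior_res = interior,
    per_replicate_fraction = fractions,
    mean = mean(fractions),
    std = if (length(fractions) > 1) stats::sd(fractions) else 0,
    per_residue_occupancy = per_res,
    per_residue_majority_share = mean(per_res >= 0.5)
  ), class = "HelicityReport")
}

#' @export
print.HelicityReport <- function(x, ...) {
  cat(sprintf("Helical fraction of %s (excluding %d per terminus): %.1f%% (+/- %.1f%%) over %d replicate(s)\n",
              format(x$segment), x$exclude_terminal, 100 * x$mean,
              100 * x$std, length(x$per_replicate_fraction)))
  invisible(x)
}
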