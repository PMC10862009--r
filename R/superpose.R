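## Least-squares rigid superposition (Kabsch, via SVD with proper-rotation
## sign correction) and segment C-alpha RMSD time series.

#' Optimal rigid superposition of paired point sets
#'
#' Finds the proper rotation R and translation t minimizing
#' `sum |R p_i + t - q_i|^2` over paired rows of P and Q, and the
#' resulting RMSD.  A reflection in the SVD solution is corrected by
#' flipping the sign of the smallest singular direction, so the returned
#' rotation always has determinant +1.
#'
#' @param P,Q N x 3 matrices of paired coordinates (N >= 3, not
#'   collinear).
#' @return a `SuperpositionResult` list: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3) {
    stop("P and Q must be paired N x 3 matrices")
  }
  n <- nrow(P)
  if (n < 3) stop("superposition needs at least 3 paired points")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  ## collinearity check: rank of the centred cloud
  sp <- svd(P0)$d
  if (sp[2] < 1e-8 * max(sp[1], 1)) {
    stop("degenerate (collinear) point set: superposition is ill-conditioned")
  }
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- qc - as.numeric(R %*% pc)
  Pfit <- P %*% t(R)
  Pfit <- sweep(Pfit, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((Pfit - Q)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

## C-alpha coordinates of the interior of a segment, as an n x 3 matrix.
#' @keywords internal
segment_ca_rows <- function(topology, segment, exclude_terminal) {
  lo <- segment$start_res + exclude_terminal
  hi <- segment$end_res - exclude_terminal
  if (hi < lo) stop("no interior residues left after terminal exclusion")
  at <- topology$atoms
  rows <- vapply(seq.int(lo, hi), function(r) {
    i <- which(at$chain == segment$chain_id & at$res_seq == r &
                 at$atom_name == "CA")
    if (!length(i)) {
      stop("missing CA for residue ", r, " of chain ", segment$chain_id)
    }
    i[1]
  }, integer(1))
  rows
}

#' Segment C-alpha RMSD time series with replicate statistics
#'
#' For every frame of every replicate: superpose the frame's fit-region
#' C-alpha atoms onto the reference, then measure RMSD over the interior
#' segment C-alpha atoms (the segment minus `exclude_terminal` residues
#' per end).  By default the fit region is the interior segment itself, so
#' the series measures internal conformational change of the grafted
#' region rather than rigid-body drift.
#'
#' @param ensembles an `Ensemble` or list of replicates sharing a
#'   topology.
#' @param reference a `PolymerStructure` supplying reference coordinates
#'   (e.g. the initial model), congruent with the ensemble topology in the
#'   fit and segment regions.
#' @param segment a `SegmentSpec` for the measured region.
#' @param exclude_terminal residues dropped from each segment end
#'   (default 2).
#' @param fit_on optional `SegmentSpec` for the superposition region
#'   (default: the measured interior segment).
#' @return an `RMSDReport` list: per-replicate data.frames
#'   (`time_ps`, `rmsd`), per-replicate mean/std, overall mean/std, and
#'   the number of C-alpha atoms used.
#' @export
rmsd_series <- function(ensembles, reference, segment, exclude_terminal = 2,
                        fit_on = NULL) {
  if (inherits(ensembles, "Ensemble")) ensembles <- list(ensembles)
  stopifnot(inherits(reference, "PolymerStructure"),
            inherits(segment, "SegmentSpec"))
  ref_xyz <- coords(reference)

  series <- lapply(ensembles, function(ens) {
    topo <- ens$topology
    seg_rows <- segment_ca_rows(topo, segment, exclude_terminal)
    fit_rows <- if (is.null(fit_on)) seg_rows else
      segment_ca_rows(topo, fit_on, 0)
    ref_seg <- segment_ca_rows(reference, segment, exclude_terminal)
    ref_fit <- if (is.null(fit_on)) ref_seg else
      segment_ca_rows(reference, fit_on, 0)
    r <- vapply(ens$frames, function(fr) {
      sup <- kabsch(fr[fit_rows, , drop = FALSE],
                    ref_xyz[ref_fit, , drop = FALSE])
      moved <- fr[seg_rows, , drop = FALSE] %*% t(sup$rotation)
      moved <- sweep(moved, 2, sup$translation, "+")
      sqrt(mean(rowSums((moved - ref_xyz[ref_seg, , drop = FALSE])^2)))
    }, numeric(1))
    data.frame(time_ps = (seq_along(r) - 1) * ens$frame_spacing_ps, rmsd = r)
  })

  per_mean <- vapply(series, function(d) mean(d$rmsd), numeric(1))
  per_std <- vapply(series, function(d) stats::sd(d$rmsd), numeric(1))
  n_atoms <- length(segment_ca_rows(ensembles[[1]]$topology, segment,
                                    exclude_terminal))
  structure(list(
    segment = segment,
    fit_selection = if (is.null(fit_on)) "segment-interior" else format(fit_on),
    exclude_terminal = exclude_terminal,
    n_ca = n_atoms,
    series = series,
    per_replicate_mean = per_mean,
    per_replicate_std = per_std,
    mean = mean(per_mean),
    std = if (length(per_mean) > 1) stats::sd(per_mean) else 0
  ), class = "RMSDReport")
}

#' @export
print.RMSDReport <- function(x, ...) {
  cat(sprintf("RMSD of %d CA atoms in %s (fit: %s): %.2f (+/- %.2f) A over %d replicate(s)\n",
              x$n_ca, format(x$segment), x$fit_selection, x$mean, x$std,
              length(x$series)))
  invisible(x)
}
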