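## Peptide-level hydrogen-deuterium exchange: uptake table loading,
## bound-minus-apo differencing, and epitope calling with graft-region
## annotation.

#' Load a peptide-level HDX uptake table
#'
#' Expects a CSV with columns `start`, `end` (inclusive residue numbers in
#' construct coordinates), `sequence`, `condition` (`apo` or `bound`),
#' `timepoint_s`, and either `uptake` (deuteration fraction in [0, 1]) or
#' the triple `mass_t`, `mass_0`, `mass_full`, in which case the
#' back-exchange-normalized ratio `(mass_t - mass_0)/(mass_full - mass_0)`
#' is computed.
#'
#' @param path CSV file path.
#' @return data.frame of class `hdx_table` (long format, one row per
#'   peptide x timepoint x condition) with columns `start`, `end`,
#'   `sequence`, `condition`, `timepoint_s`, `uptake`.
#' @export
load_uptake <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "sequence", "condition", "timepoint_s")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("uptake table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"uptake" %in% names(d)) {
    if (!all(c("mass_t", "mass_0", "mass_full") %in% names(d))) {
      stop("uptake table needs either 'uptake' or mass_t/mass_0/mass_full")
    }
    denom <- d$mass_full - d$mass_0
    if (any(denom <= 0)) stop("mass_full must exceed mass_0")
    d$uptake <- (d$mass_t - d$mass_0) / denom
  }
  if (any(d$uptake < -1e-9 | d$uptake > 1 + 1e-9)) {
    bad <- which(d$uptake < -1e-9 | d$uptake > 1 + 1e-9)[1]
    stop("uptake outside [0, 1] at row ", bad, " (", d$uptake[bad], ")")
  }
  d$uptake <- pmin(pmax(d$uptake, 0), 1)
  ## exchangeable amides: backbone NH minus prolines minus the N-terminal
  ## residue of the peptide
  n_pro <- vapply(strsplit(toupper(d$sequence), ""),
                  function(s) sum(s == "P"), integer(1))
  d$n_exchangeable <- nchar(d$sequence) - n_pro - 1L
  if (any(d$n_exchangeable < 1)) {
    stop("peptide with no exchangeable amides at row ",
         which(d$n_exchangeable < 1)[1])
  }
  class(d) <- c("hdx_table", "data.frame")
  d
}

## Split an hdx table into per-peptide keys.
#' @keywords internal
hdx_key <- function(d) paste(d$start, d$end, sep = "-")

#' Differential uptake between bound and apo conditions
#'
#' Matches peptides (by residue range) and timepoints across the two
#' conditions and computes `delta(t) = bound(t) - apo(t)` per peptide,
#' with the per-peptide summary being the mean over timepoints.  Peptides
#' present in only one condition are reported separately, not silently
#' dropped.
#'
#' @param apo,bound `hdx_table`s (or data.frames with the same columns),
#'   each restricted to one condition.
#' @return an `HDXDifferenceReport` list: `peptides` (data.frame `start`,
#'   `end`, `sequence`, `summary_delta`, `n_timepoints`), `deltas` (long
#'   data.frame per timepoint), `unmatched` (character vector of ranges).
#' @export
hdx_difference <- function(apo, bound) {
  if ("condition" %in% names(apo)) apo <- apo[apo$condition == "apo" |
                                               length(unique(apo$condition)) == 1, ]
  if ("condition" %in% names(bound)) bound <- bound[bound$condition == "bound" |
                                                     length(unique(bound$condition)) == 1, ]
  ka <- unique(hdx_key(apo)); kb <- unique(hdx_key(bound))
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no peptides shared between conditions")
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))

  deltas <- list(); summaries <- list()
  for (key in shared) {
    a <- apo[hdx_key(apo) == key, ]
    b <- bound[hdx_key(bound) == key, ]
    tp <- intersect(a$timepoint_s, b$timepoint_s)
    if (!length(tp)) next
    a <- a[match(tp, a$timepoint_s), ]
    b <- b[match(tp, b$timepoint_s), ]
    dl <- data.frame(start = a$start[1], end = a$end[1],
                     sequence = a$sequence[1], timepoint_s = tp,
                     delta = b$uptake - a$uptake)
    deltas[[key]] <- dl
    summaries[[key]] <- data.frame(start = a$start[1], end = a$end[1],
                                   sequence = a$sequence[1],
                                   summary_delta = mean(dl$delta),
                                   n_timepoints = length(tp))
  }
  structure(list(peptides = do.call(rbind, c(summaries,
                                             make.row.names = FALSE)),
                 deltas = do.call(rbind, c(deltas, make.row.names = FALSE)),
                 unmatched = unmatched),
            class = "HDXDifferenceReport")
}

#' @export
print.HDXDifferenceReport <- function(x, ...) {
  cat("HDX difference report:", nrow(x$peptides), "matched peptide(s),",
      length(x$unmatched), "unmatched\n")
  print(x$peptides)
  invisible(x)
}

#' Call protected peptides (candidate epitope) from a difference report
#'
#' Flags peptides whose uptake difference is at or below `threshold` at a
#' minimum number of timepoints.  When a `GraftDesign` is supplied, each
#' flagged peptide is annotated by where its residues fall in the chimera:
#' `grafted`, `scaffold`, `linker`, or `mixed`.
#'
#' @param report an `HDXDifferenceReport`.
#' @param threshold uptake-difference cutoff (default -0.05; protection is
#'   negative).
#' @param min_timepoints minimum number of timepoints at or below the
#'   threshold (default 2).
#' @param design optional `GraftDesign` for region annotation.
#' @return data.frame of all peptides with `flagged` logical,
#'   `n_below_threshold`, `summary_delta`, and (with a design) `region`.
#' @export
call_epitope <- function(report, threshold = -0.05, min_timepoints = 2,
                         design = NULL) {
  stopifnot(inherits(report, "HDXDifferenceReport"))
  pep <- report$peptides
  key <- paste(pep$start, pep$end, sep = "-")
  n_below <- vapply(key, function(k) {
    dl <- report$deltas[paste(report$deltas$start, report$deltas$end,
                              sep = "-") == k, ]
    sum(dl$delta <= threshold)
  }, integer(1))
  pep$n_below_threshold <- unname(n_below)
  pep$flagged <- pep$n_below_threshold >= min_timepoints
  if (!is.null(design)) {
    stopifnot(inherits(design, "GraftDesign"))
    pep$region <- vapply(seq_len(nrow(pep)), function(i) {
      pos <- seq.int(pep$start[i], pep$end[i])
      pos <- pos[pos >= 1 & pos <= nrow(design$index_map)]
      if (!length(pos)) return(NA_character_)
      src <- unique(design$index_map$source[pos])
      if (length(src) > 1) "mixed"
      else switch(src, donor = "grafted", scaffold = "scaffold",
                  linker = "linker", src)
    }, character(1))
  }
  pep[order(pep$start, pep$end), ]
}
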