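## Core containers: PolymerStructure (one conformer) and Ensemble
## (replicate frames over a shared topology).  Atoms live in a flat
## data.frame so per-frame coordinate arrays can be swapped in cheaply.

#' Construct a PolymerStructure
#'
#' A `PolymerStructure` holds ordered residues with named heavy atoms and
#' coordinates in Angstrom, as a flat atom table.  Residue identity is
#' (chain, res_seq) in author numbering; atom order within a residue is
#' preserved from construction.
#'
#' @param atoms data.frame with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `occupancy`, `b_factor`.
#' @param title optional free-text title.
#' @return an object of class `PolymerStructure`.
#' @export
polymer_structure <- function(atoms, title = "") {
  required <- c("chain", "res_seq", "res_name", "atom_name",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(atoms)) stop("atom table is empty")
  if (is.null(atoms$element)) atoms$element <- element_of_atom(atoms$atom_name)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  if (is.null(atoms$b_factor)) atoms$b_factor <- 0.0
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  dup <- duplicated(atoms[, c("chain", "res_seq", "atom_name")])
  if (any(dup)) {
    stop("duplicate atom name within a residue: ",
         paste(unique(paste0(atoms$chain[dup], atoms$res_seq[dup], ":",
                             atoms$atom_name[dup])), collapse = ", "))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "PolymerStructure")
}

#' @export
print.PolymerStructure <- function(x, ...) {
  rt <- residue_table(x)
  cat("PolymerStructure:", nrow(rt), "residues,",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param s a `PolymerStructure`.
#' @param chain optional chain id filter.
#' @return data.frame with one row per residue (`chain`, `res_seq`,
#'   `res_name`) in atom-table order, plus `has_backbone` (N, CA, C, O all
#'   present).
#' @export
residue_table <- function(s, chain = NULL) {
  at <- s$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  key <- paste(at$chain, at$res_seq, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = at$chain[first], res_seq = at$res_seq[first],
                   res_name = at$res_name[first], stringsAsFactors = FALSE)
  bb <- c("N", "CA", "C", "O")
  present <- vapply(split(at$atom_name, factor(key, levels = key[first])),
                    function(a) all(bb %in% a), logical(1))
  rt$has_backbone <- unname(present)
  rownames(rt) <- NULL
  rt
}

#' Coordinates of a structure as an n_atoms x 3 matrix
#' @param s a `PolymerStructure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s a `PolymerStructure`.
#' @param xyz n_atoms x 3 matrix congruent with the atom table.
#' @return the updated structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Define an inclusive residue segment
#'
#' Both ends are inclusive and use author numbering, matching the
#' convention "amino acids 35 to 54".
#'
#' @param chain_id chain identifier.
#' @param start_res,end_res first and last residue numbers (inclusive).
#' @return a `SegmentSpec`.
#' @export
segment_spec <- function(chain_id, start_res, end_res) {
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  if (is.na(start_res) || is.na(end_res) || start_res > end_res) {
    stop("segment requires start_res <= end_res")
  }
  structure(list(chain_id = as.character(chain_id),
                 start_res = start_res, end_res = end_res),
            class = "SegmentSpec")
}

#' @export
format.SegmentSpec <- function(x, ...) {
  sprintf("%s:%d-%d", x$chain_id, x$start_res, x$end_res)
}

#' @export
print.SegmentSpec <- function(x, ...) {
  cat("SegmentSpec", format(x), "\n"); invisible(x)
}

#' Parse "A:35-69" into a SegmentSpec
#' @param text segment in `chain:start-end` form.
#' @return a `SegmentSpec`.
#' @export
parse_segment <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)$", text))[[1]]
  if (length(m) != 4) stop("cannot parse segment '", text, "'")
  segment_spec(m[2], as.integer(m[3]), as.integer(m[4]))
}

#' Extract an inclusive residue range as a new structure
#'
#' Residue numbering is preserved; the residue count always equals
#' `end_res - start_res + 1` unless a gap error is raised.
#'
#' @param s a `PolymerStructure`.
#' @param spec a `SegmentSpec`.
#' @return a `PolymerStructure` restricted to the segment.
#' @export
extract_segment <- function(s, spec) {
  stopifnot(inherits(spec, "SegmentSpec"))
  at <- s$atoms
  keep <- at$chain == spec$chain_id &
    at$res_seq >= spec$start_res & at$res_seq <= spec$end_res
  sub <- at[keep, , drop = FALSE]
  want <- seq.int(spec$start_res, spec$end_res)
  absent <- setdiff(want, unique(sub$res_seq))
  if (length(absent)) {
    stop("gap in segment ", format(spec), ": missing residue(s) ",
         paste(absent, collapse = ", "))
  }
  polymer_structure(sub, title = s$title)
}

#' One-letter sequence of a chain
#'
#' @param s a `PolymerStructure`.
#' @param chain chain identifier.
#' @return one-letter string in residue order; unknown residues are "X";
#'   an empty chain yields "".
#' @export
sequence_of <- function(s, chain) {
  if (!chain %in% s$atoms$chain) return("")
  rt <- residue_table(s, chain = chain)
  paste(aa_three_to_one(rt$res_name), collapse = "")
}

#' Construct an Ensemble
#'
#' An `Ensemble` is a set of frames sharing one topology: each frame is an
#' n_atoms x 3 coordinate matrix congruent with the topology atom order.
#'
#' @param topology a `PolymerStructure` defining atom order.
#' @param frames list of n_atoms x 3 matrices (defaults to the topology's
#'   own coordinates as a single frame).
#' @param frame_spacing_ps time between frames in picoseconds (> 0).
#' @param replicate_id integer replicate label.
#' @return an object of class `Ensemble`.
#' @export
ensemble <- function(topology, frames = NULL, frame_spacing_ps = 10,
                     replicate_id = 1L) {
  stopifnot(inherits(topology, "PolymerStructure"))
  if (is.null(frames)) frames <- list(coords(topology))
  n_atoms <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_atoms &&
                 ncol(f) == 3, logical(1))
  if (!all(ok)) stop("every frame must be an n_atoms x 3 matrix matching the topology")
  if (!is.numeric(frame_spacing_ps) || frame_spacing_ps <= 0) {
    stop("frame_spacing_ps must be > 0")
  }
  structure(list(topology = topology, frames = frames,
                 frame_spacing_ps = frame_spacing_ps,
                 replicate_id = as.integer(replicate_id)),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble: replicate", x$replicate_id, "with", length(x$frames),
      "frame(s) every", x$frame_spacing_ps, "ps;",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Structure snapshot of one frame
#' @param ens an `Ensemble`.
#' @param i frame index.
#' @return the topology with frame `i` coordinates.
#' @export
frame_structure <- function(ens, i) {
  set_coords(ens$topology, ens$frames[[i]])
}

## Row indices of one named atom per residue of a chain, NA when absent.
#' @keywords internal
atom_row_index <- function(s, chain, atom_name) {
  at <- s$atoms
  rt <- residue_table(s, chain = chain)
  sel <- at$chain == chain & at$atom_name == atom_name
  idx <- match(paste(chain, rt$res_seq), paste(at$chain, at$res_seq)[sel])
  which(sel)[idx]
}

## Indices (into the atom table) of backbone atoms per residue of a chain.
#' @keywords internal
backbone_index <- function(s, chain) {
  list(res = residue_table(s, chain = chain),
       N = atom_row_index(s, chain, "N"),
       CA = atom_row_index(s, chain, "CA"),
       C = atom_row_index(s, chain, "C"),
       O = atom_row_index(s, chain, "O"))
}

#' Serialize an ensemble to a long-format coordinate CSV
#'
#' Columns: frame, chain, res_seq, res_name, atom_name, x, y, z.
#'
#' @param ens an `Ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ens, path) {
  at <- ens$topology$atoms
  rows <- lapply(seq_along(ens$frames), function(i) {
    data.frame(frame = i, chain = at$chain, res_seq = at$res_seq,
               res_name = at$res_name, atom_name = at$atom_name,
               x = ens$frames[[i]][, 1], y = ens$frames[[i]][, 2],
               z = ens$frames[[i]][, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
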