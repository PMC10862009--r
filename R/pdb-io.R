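## Fixed-width PDB I/O for single- and multi-MODEL coordinate files.
## HETATM and waters are skipped; altlocs resolved to the
## highest-occupancy conformer (ties by altloc letter order).

#' Read a PDB file into an Ensemble
#'
#' MODEL/ENDMDL blocks become frames; a file without MODEL records yields a
#' single-frame ensemble.  The topology preserves author residue numbering
#' and insertion order.  HETATM records and waters are skipped; hydrogens
#' present in the input are retained.
#'
#' @param path path to a PDB file.
#' @param frame_spacing_ps frame spacing to attach, picoseconds.
#' @param replicate_id replicate label to attach.
#' @return an `Ensemble`.
#' @export
read_pdb <- function(path, frame_spacing_ps = 10, replicate_id = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  title <- trimws(paste(substr(lines[rec == "TITLE "], 11, 80), collapse = " "))

  model_starts <- which(startsWith(rec, "MODEL"))
  model_ends <- which(startsWith(rec, "ENDMDL"))
  if (length(model_starts) != length(model_ends)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  blocks <- if (length(model_starts) == 0) {
    list(seq_along(lines))
  } else {
    mapply(function(a, b) seq.int(a + 1L, b - 1L), model_starts, model_ends,
           SIMPLIFY = FALSE)
  }

  parse_block <- function(idx) {
    sel <- idx[startsWith(rec[idx], "ATOM")]
    if (!length(sel)) return(NULL)
    ln <- lines[sel]
    num <- function(from, to, what) {
      txt <- trimws(substr(ln, from, to))
      v <- suppressWarnings(as.numeric(txt))
      bad <- which(is.na(v) & txt != "")
      if (length(bad)) {
        stop("malformed ", what, " field at line ", sel[bad[1]],
             " of ", path, ": '", txt[bad[1]], "'")
      }
      v
    }
    d <- data.frame(
      atom_name = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      res_name = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      res_seq = as.integer(num(23, 26, "residue number")),
      x = num(31, 38, "x coordinate"),
      y = num(39, 46, "y coordinate"),
      z = num(47, 54, "z coordinate"),
      occupancy = num(55, 60, "occupancy"),
      b_factor = num(61, 66, "B-factor"),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE
    )
    if (any(is.na(d$x) | is.na(d$y) | is.na(d$z))) {
      stop("empty coordinate field at line ",
           sel[which(is.na(d$x) | is.na(d$y) | is.na(d$z))[1]], " of ", path)
    }
    d$occupancy[is.na(d$occupancy)] <- 1.0
    d$b_factor[is.na(d$b_factor)] <- 0.0
    d <- d[!d$res_name %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
    ## altloc policy: highest occupancy wins, tie by altloc letter order
    if (any(d$altloc != " ")) {
      key <- paste(d$chain, d$res_seq, d$atom_name, sep = "\r")
      ord <- order(key, -d$occupancy, d$altloc)
      d <- d[ord, , drop = FALSE]
      d <- d[!duplicated(paste(d$chain, d$res_seq, d$atom_name, sep = "\r")), ,
             drop = FALSE]
      d <- d[order(match(paste(d$chain, d$res_seq, sep = "\r"),
                         unique(paste(d$chain, d$res_seq, sep = "\r")))), ,
             drop = FALSE]
    }
    d$element[d$element == ""] <- element_of_atom(d$atom_name[d$element == ""])
    d$altloc <- NULL
    d
  }

  parsed <- Filter(Negate(is.null), lapply(blocks, parse_block))
  if (!length(parsed)) stop("no ATOM records found in ", path)

  topo_key <- function(d) paste(d$chain, d$res_seq, d$atom_name, sep = "\r")
  ref <- parsed[[1]]
  ref_key <- topo_key(ref)
  for (k in seq_along(parsed)[-1]) {
    if (!identical(topo_key(parsed[[k]]), ref_key)) {
      stop("MODEL block ", k, " of ", path,
           " has a different topology from MODEL 1")
    }
  }
  topology <- polymer_structure(ref, title = title)
  frames <- lapply(parsed, function(d) as.matrix(d[, c("x", "y", "z")]))
  ensemble(topology, frames, frame_spacing_ps = frame_spacing_ps,
           replicate_id = replicate_id)
}

#' Write an Ensemble (or structure) as a PDB file
#'
#' Single-frame ensembles are written as a plain coordinate file without
#' MODEL records; multi-frame ensembles get one MODEL/ENDMDL pair per
#' frame.  Coordinates are written to three decimals in fixed-width
#' columns.
#'
#' @param ens an `Ensemble` or `PolymerStructure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ens, path) {
  if (inherits(ens, "PolymerStructure")) ens <- ensemble(ens)
  stopifnot(inherits(ens, "Ensemble"))
  if (!length(ens$frames)) stop("ensemble has no frames")
  at <- ens$topology$atoms

  pad_name <- function(nm) {
    ## column 13 is blank for short element names per PDB convention
    ifelse(nchar(nm) >= 4, sprintf("%-4s", nm), sprintf(" %-3s", nm))
  }
  atom_lines <- function(xyz) {
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(at)) %% 100000L, pad_name(at$atom_name), at$res_name,
            at$chain, at$res_seq, xyz[, 1], xyz[, 2], xyz[, 3],
            at$occupancy, at$b_factor, at$element)
  }

  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(ens$topology$title)) {
    writeLines(sprintf("TITLE     %s", ens$topology$title), con)
  }
  if (length(ens$frames) == 1L) {
    writeLines(atom_lines(ens$frames[[1]]), con)
  } else {
    for (i in seq_along(ens$frames)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(atom_lines(ens$frames[[i]]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
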