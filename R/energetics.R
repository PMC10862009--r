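## Residue-pair nonbonded energy decomposition (Coulomb + Lennard-Jones)
## over frames, band classification of the resulting matrix, hydrophobic
## contact detection and inter-helix contributor ranking.

COULOMB_CONST <- 332.0636  # kcal*A/(mol*e^2), vacuum dielectric

## Bonded exclusions across the peptide bond (atom pairs within three
## bonds of each other), applied to |i-j| = 1 pairs; first column is the
## N-terminal-side residue.  Nonbonded terms are meaningless at covalent
## distances, so the 1-4 neighbourhood is excluded as well.
PEPTIDE_EXCLUSIONS <- matrix(c(
  "C", "N",
  "C", "H",
  "C", "CA",
  "C", "C",
  "C", "CB",
  "CA", "N",
  "CA", "H",
  "CA", "CA",
  "O", "N",
  "O", "H",
  "O", "CA",
  "N", "N",
  "CB", "N"
), ncol = 2, byrow = TRUE)

## Append placed amide hydrogens (one per eligible residue) to an atom
## table + coordinate frame, unless hydrogens are already present.
#' @keywords internal
augment_with_amide_h <- function(s, frame, chain) {
  at <- s$atoms
  if (any(at$atom_name == "H" & at$chain == chain)) {
    return(list(atoms = at, frame = frame))
  }
  hyd <- place_amide_hydrogens(frame, s, chain)
  bb <- hyd$bb
  keep <- which(!is.na(hyd$H[, 1]))
  if (!length(keep)) return(list(atoms = at, frame = frame))
  h_at <- data.frame(chain = chain, res_seq = bb$res$res_seq[keep],
                     res_name = bb$res$res_name[keep], atom_name = "H",
                     element = "H", x = hyd$H[keep, 1], y = hyd$H[keep, 2],
                     z = hyd$H[keep, 3], occupancy = 1, b_factor = 0,
                     stringsAsFactors = FALSE)
  list(atoms = rbind(at, h_at), frame = rbind(frame, hyd$H[keep, ,
                                                           drop = FALSE]))
}

#' Simplified nonbonded force-field parameter table
#'
#' An embedded schematic all-atom table for the 20 amino acids covering
#' every standard heavy atom plus the amide hydrogen: partial charges (e)
#' that sum to each residue's formal charge, and Lennard-Jones
#' `epsilon` (kcal/mol) / `rmin/2` (Angstrom) assigned per element class.
#' This table is a documented simplification -- band-pattern reproduction,
#' not force-field bit-compatibility, is its contract.
#'
#' @return data.frame with columns `res_name`, `atom_name`,
#'   `partial_charge`, `lj_epsilon`, `lj_rmin_half`.
#' @export
default_forcefield <- function() {
  lj <- function(el) {
    switch(el,
           C = c(0.080, 2.060),
           N = c(0.200, 1.850),
           O = c(0.120, 1.700),
           S = c(0.450, 2.000),
           H = c(0.046, 0.2245),
           stop("no LJ class for element ", el))
  }
  ## backbone charges; PRO has no amide H so its N absorbs the H charge
  backbone <- function(res3) {
    if (res3 == "PRO") {
      data.frame(atom_name = c("N", "CA", "C", "O"),
                 partial_charge = c(-0.05, 0.10, 0.50, -0.55))
    } else {
      data.frame(atom_name = c("N", "H", "CA", "C", "O"),
                 partial_charge = c(-0.30, 0.25, 0.10, 0.50, -0.55))
    }
  }
  side_charges <- list(
    ARG = c(NE = -0.10, CZ = 0.60, NH1 = 0.25, NH2 = 0.25),
    ASN = c(CG = 0.55, OD1 = -0.55),
    ASP = c(CG = 0.30, OD1 = -0.65, OD2 = -0.65),
    CYS = c(CB = 0.20, SG = -0.20),
    GLN = c(CD = 0.55, OE1 = -0.55),
    GLU = c(CD = 0.30, OE1 = -0.65, OE2 = -0.65),
    HIS = c(ND1 = -0.35, CE1 = 0.35),
    LYS = c(CE = 0.25, NZ = 0.75),
    MET = c(CG = 0.10, SD = -0.20, CE = 0.10),
    SER = c(CB = 0.40, OG = -0.40),
    THR = c(CB = 0.40, OG1 = -0.40),
    TRP = c(CD1 = 0.25, NE1 = -0.25),
    TYR = c(CZ = 0.40, OH = -0.40)
  )
  rows <- lapply(names(AA_SIDECHAIN_ATOMS), function(res3) {
    bb <- backbone(res3)
    side <- AA_SIDECHAIN_ATOMS[[res3]]
    q <- stats::setNames(rep(0, length(side)), side)
    sc <- side_charges[[res3]]
    if (!is.null(sc)) q[names(sc)] <- sc
    d <- rbind(bb, data.frame(atom_name = side, partial_charge = unname(q)))
    d$res_name <- res3
    d
  })
  tab <- do.call(rbind, rows)
  el <- element_of_atom(tab$atom_name)
  ljm <- t(vapply(el, lj, numeric(2)))
  tab$lj_epsilon <- ljm[, 1]
  tab$lj_rmin_half <- ljm[, 2]
  rownames(tab) <- NULL
  tab[, c("res_name", "atom_name", "partial_charge",
          "lj_epsilon", "lj_rmin_half")]
}

## Parameter rows for the atoms of one residue, in atom order; errors on
## any uncovered atom.
#' @keywords internal
params_for_atoms <- function(res_name, atom_names, params) {
  sel <- params[params$res_name == res_name, , drop = FALSE]
  idx <- match(atom_names, sel$atom_name)
  if (anyNA(idx)) {
    stop("no force-field parameters for atom(s) ",
         paste(atom_names[is.na(idx)], collapse = ", "),
         " of residue ", res_name)
  }
  sel[idx, , drop = FALSE]
}

#' Nonbonded interaction energy between two residues in one frame
#'
#' Sums, over atom pairs within the cutoff,
#' `332.0636 q_a q_b / r` (Coulomb, vacuum dielectric) and
#' `eps_ab ((rmin_ab/r)^12 - 2 (rmin_ab/r)^6)` (Lennard-Jones) with
#' Lorentz-Berthelot-style combining (`eps_ab = sqrt(eps_a eps_b)`,
#' `rmin_ab = rmin_half_a + rmin_half_b`).  For sequence-adjacent residues
#' the atom pairs within three bonds across the peptide bond (the
#' 1-2/1-3/1-4 neighbourhood) are excluded.  Plain truncation at the
#' cutoff; no switching function.  Amide hydrogens are placed on the fly
#' (see [place_amide_hydrogens()]) when the structure carries none.
#'
#' @param s a `PolymerStructure` (atom table supplies names/residues).
#' @param res_i,res_j residue numbers (author numbering).
#' @param frame optional coordinate matrix (default: the structure's own).
#' @param params force-field table (default [default_forcefield()]).
#' @param cutoff pair-distance cutoff in Angstrom (default 12, the
#'   analysis convention).
#' @param chain chain id (default: first chain).
#' @return named numeric vector `c(coulomb =, lj =, total =)` in kcal/mol.
#' @export
pair_energy <- function(s, res_i, res_j, frame = NULL,
                        params = default_forcefield(), cutoff = 12,
                        chain = NULL) {
  if (is.null(chain)) chain <- s$atoms$chain[1]
  if (abs(res_i - res_j) < 1) stop("residues must differ")
  if (is.null(frame)) frame <- coords(s)
  aug <- augment_with_amide_h(s, frame, chain)
  at <- aug$atoms; frame <- aug$frame
  ai <- which(at$chain == chain & at$res_seq == res_i)
  aj <- which(at$chain == chain & at$res_seq == res_j)
  if (!length(ai) || !length(aj)) stop("residue not found in chain ", chain)
  pe_atoms(at$res_name[ai[1]], at$atom_name[ai], frame[ai, , drop = FALSE],
           at$res_name[aj[1]], at$atom_name[aj], frame[aj, , drop = FALSE],
           res_j - res_i, params, cutoff)
}

## Vector core shared by pair_energy and energy_matrix.
#' @keywords internal
pe_atoms <- function(resn_i, names_i, xyz_i, resn_j, names_j, xyz_j,
                     seq_sep, params, cutoff) {
  pi_ <- params_for_atoms(resn_i, names_i, params)
  pj <- params_for_atoms(resn_j, names_j, params)
  ## pairwise distances
  d2 <- outer(rowSums(xyz_i^2), rowSums(xyz_j^2), "+") -
    2 * xyz_i %*% t(xyz_j)
  r <- sqrt(pmax(d2, 0))
  keep <- r <= cutoff & r > 0
  if (abs(seq_sep) == 1) {
    ## orient exclusions: first atom from the N-terminal-side residue
    first <- if (seq_sep > 0) names_i else names_j
    second <- if (seq_sep > 0) names_j else names_i
    for (k in seq_len(nrow(PEPTIDE_EXCLUSIONS))) {
      rows <- which(first == PEPTIDE_EXCLUSIONS[k, 1])
      cols <- which(second == PEPTIDE_EXCLUSIONS[k, 2])
      if (length(rows) && length(cols)) {
        if (seq_sep > 0) keep[rows, cols] <- FALSE else keep[cols, rows] <- FALSE
      }
    }
  }
  if (!any(keep)) {
    return(c(coulomb = 0, lj = 0, total = 0))
  }
  qq <- outer(pi_$partial_charge, pj$partial_charge)
  eps <- sqrt(outer(pi_$lj_epsilon, pj$lj_epsilon))
  rmin <- outer(pi_$lj_rmin_half, pj$lj_rmin_half, "+")
  rk <- r[keep]
  coul <- sum(COULOMB_CONST * qq[keep] / rk)
  ratio6 <- (rmin[keep] / rk)^6
  lj <- sum(eps[keep] * (ratio6^2 - 2 * ratio6))
  c(coulomb = coul, lj = lj, total = coul + lj)
}

#' Frame-averaged residue-pair energy matrix with band classification
#'
#' Computes the symmetric residue-pair total/Coulomb/LJ energy matrices
#' averaged over frames, then classifies each off-diagonal cell:
#' `adjacent` for |i-j| = 1 (covalently connected neighbours),
#' `hbond_band` for pairs with |i-j| in 3..5 carrying a Kabsch-Sander
#' hydrogen bond in at least `hbond_occupancy` of frames (the helical
#' backbone band), `core` for hydrophobic pairs at or below
#' `core_threshold`, and `other` otherwise.
#'
#' @param ens an `Ensemble`.
#' @param residues a `SegmentSpec` or integer vector of residue numbers.
#' @param params force-field table (default [default_forcefield()]).
#' @param cutoff pair cutoff, Angstrom (default 12).
#' @param stride analyze every `stride`-th frame.
#' @param core_threshold frame-averaged total energy at or below which a
#'   hydrophobic pair is classed `core` (default -1 kcal/mol).
#' @param hbond_occupancy fraction of frames a Kabsch-Sander bond must be
#'   present to class a pair `hbond_band` (default 0.5).
#' @param chain chain id (default: first chain).
#' @return an `EnergyMatrix` list: `res_seq`, `total`, `coulomb`, `lj`
#'   (symmetric matrices, NA diagonal), `band` (character matrix).
#' @export
energy_matrix <- function(ens, residues, params = default_forcefield(),
                          cutoff = 12, stride = 1, core_threshold = -1.0,
                          hbond_occupancy = 0.5, chain = NULL) {
  stopifnot(inherits(ens, "Ensemble"))
  topo <- ens$topology
  if (is.null(chain)) {
    chain <- if (inherits(residues, "SegmentSpec")) residues$chain_id
    else topo$atoms$chain[1]
  }
  res_seq <- if (inherits(residues, "SegmentSpec")) {
    seq.int(residues$start_res, residues$end_res)
  } else as.integer(residues)
  n <- length(res_seq)
  rt <- residue_table(topo, chain = chain)
  if (!all(res_seq %in% rt$res_seq)) {
    stop("residues not resolvable: ",
         paste(setdiff(res_seq, rt$res_seq), collapse = ", "))
  }
  at <- topo$atoms
  atom_rows <- lapply(res_seq, function(r) {
    which(at$chain == chain & at$res_seq == r)
  })
  res_names <- vapply(atom_rows, function(ix) at$res_name[ix[1]], character(1))
  atom_names <- lapply(atom_rows, function(ix) at$atom_name[ix])

  pick <- seq(1, length(ens$frames), by = stride)
  tot <- coul <- lj <- matrix(0, n, n)
  hb_count <- matrix(0, n, n)
  ## residue index within the full chain for KS energies
  chain_pos <- match(res_seq, rt$res_seq)
  has_h <- any(at$atom_name == "H" & at$chain == chain)

  for (f in pick) {
    fr <- ens$frames[[f]]
    hyd <- place_amide_hydrogens(fr, topo, chain)
    ## include the placed amide hydrogens in the nonbonded sums unless
    ## the structure already carries its own
    arows <- atom_rows; anames <- atom_names; fr_aug <- fr
    if (!has_h) {
      keep <- which(!is.na(hyd$H[, 1]))
      if (length(keep)) {
        fr_aug <- rbind(fr, hyd$H[keep, , drop = FALSE])
        h_res <- hyd$bb$res$res_seq[keep]
        for (a in seq_len(n)) {
          hit <- which(h_res == res_seq[a])
          if (length(hit)) {
            arows[[a]] <- c(arows[[a]], nrow(fr) + hit)
            anames[[a]] <- c(anames[[a]], "H")
          }
        }
      }
    }
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        e <- pe_atoms(res_names[a], anames[[a]],
                      fr_aug[arows[[a]], , drop = FALSE],
                      res_names[b], anames[[b]],
                      fr_aug[arows[[b]], , drop = FALSE],
                      res_seq[b] - res_seq[a], params, cutoff)
        tot[a, b] <- tot[a, b] + e["total"]
        coul[a, b] <- coul[a, b] + e["coulomb"]
        lj[a, b] <- lj[a, b] + e["lj"]
        sep <- abs(res_seq[b] - res_seq[a])
        if (sep >= 2) {
          pa <- chain_pos[a]; pb <- chain_pos[b]
          e1 <- tryCatch(ks_energy(pb, pa, fr, topo, chain, hyd),
                         error = function(e) NA_real_)
          e2 <- tryCatch(ks_energy(pa, pb, fr, topo, chain, hyd),
                         error = function(e) NA_real_)
          bonded <- (is.finite(e1) && e1 < KS_CUTOFF) ||
            (is.finite(e2) && e2 < KS_CUTOFF)
          if (bonded) hb_count[a, b] <- hb_count[a, b] + 1
        }
      }
    }
  }
  nf <- length(pick)
  sym <- function(m) { m <- m / nf; m <- m + t(m); diag(m) <- NA_real_; m }
  tot <- sym(tot); coul <- sym(coul); lj <- sym(lj)
  hb_frac <- (hb_count + t(hb_count)) / nf

  sep <- abs(outer(res_seq, res_seq, "-"))
  hydro <- res_names %in% HYDROPHOBIC_RESIDUES
  both_hydro <- outer(hydro, hydro, "&")
  band <- matrix("other", n, n)
  band[both_hydro & !is.na(tot) & tot <= core_threshold] <- "core"
  band[sep %in% 3:5 & hb_frac >= hbond_occupancy] <- "hbond_band"
  band[sep == 1] <- "adjacent"
  diag(band) <- NA_character_

  structure(list(res_seq = res_seq, res_name = res_names, chain = chain,
                 total = tot, coulomb = coul, lj = lj, band = band,
                 hbond_fraction = hb_frac, n_frames_used = nf),
            class = "EnergyMatrix")
}

#' @export
print.EnergyMatrix <- function(x, ...) {
  cat("EnergyMatrix:", length(x$res_seq), "residues over",
      x$n_frames_used, "frame(s); band counts:\n")
  print(table(x$band[upper.tri(x$band)]))
  invisible(x)
}

#' Energy matrix as a long-format data.frame
#' @param M an `EnergyMatrix`.
#' @return data.frame with columns `res_i`, `res_j`, `coulomb`, `lj`,
#'   `total`, `band` (unique unordered pairs).
#' @export
energy_matrix_long <- function(M) {
  n <- length(M$res_seq)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(res_i = M$res_seq[ut[, 1]], res_j = M$res_seq[ut[, 2]],
             coulomb = M$coulomb[ut], lj = M$lj[ut], total = M$total[ut],
             band = M$band[ut])
}

#' Hydrophobic side-chain contacts between two residue groups
#'
#' Reports unordered residue pairs (one from each group) whose minimum
#' side-chain heavy-atom distance is at most `dmax` and where both
#' residues belong to the hydrophobic set (A, V, L, I, M, F, W, Y, P).
#' Glycine contributes its CA as the side-chain proxy.
#'
#' @param s a `PolymerStructure` (or frame via `frame`).
#' @param groupA,groupB `SegmentSpec`s.
#' @param dmax contact distance threshold, Angstrom (default 4.5).
#' @param frame optional coordinate matrix.
#' @return data.frame `res_a`, `res_b`, `min_dist` (possibly empty).
#' @export
hydrophobic_contacts <- function(s, groupA, groupB, dmax = 4.5,
                                 frame = NULL) {
  if (is.null(frame)) frame <- coords(s)
  at <- s$atoms
  side_rows <- function(seg) {
    res <- seq.int(seg$start_res, seg$end_res)
    lapply(res, function(r) {
      ix <- which(at$chain == seg$chain_id & at$res_seq == r)
      if (!length(ix)) return(NULL)
      side <- ix[!at$atom_name[ix] %in% c("N", "CA", "C", "O", "H", "OXT")]
      if (!length(side)) side <- ix[at$atom_name[ix] == "CA"]
      list(res = r, name = at$res_name[ix[1]], rows = side)
    })
  }
  A <- Filter(Negate(is.null), side_rows(groupA))
  B <- Filter(Negate(is.null), side_rows(groupB))
  out <- list()
  for (a in A) {
    if (!a$name %in% HYDROPHOBIC_RESIDUES) next
    for (b in B) {
      if (!b$name %in% HYDROPHOBIC_RESIDUES) next
      if (a$res == b$res && groupA$chain_id == groupB$chain_id) next
      xa <- frame[a$rows, , drop = FALSE]
      xb <- frame[b$rows, , drop = FALSE]
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      dmin <- sqrt(max(0, min(d2)))
      if (dmin <= dmax) {
        out[[length(out) + 1L]] <- data.frame(res_a = a$res, res_b = b$res,
                                              min_dist = dmin)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      min_dist = numeric(0)))
  }
  do.call(rbind, out)
}

#' Rank residues by cross-helix interaction energy
#'
#' For each residue of either helix, sums its frame-averaged pair energies
#' with all residues of the other helix and ranks most-negative first
#' (ties broken by residue number).
#'
#' @param M an `EnergyMatrix` covering both helices.
#' @param helixA,helixB disjoint `SegmentSpec`s.
#' @param top_k how many residues to return (default 5).
#' @return data.frame `res_seq`, `res_name`, `helix`, `cross_energy`,
#'   sorted by energy.
#' @export
interhelix_contributors <- function(M, helixA, helixB, top_k = 5) {
  ra <- seq.int(helixA$start_res, helixA$end_res)
  rb <- seq.int(helixB$start_res, helixB$end_res)
  if (length(intersect(ra, rb))) stop("helices must be disjoint")
  ia <- match(ra, M$res_seq); ib <- match(rb, M$res_seq)
  if (anyNA(ia) || anyNA(ib)) stop("helix residues not covered by the matrix")
  cross <- M$total[ia, ib, drop = FALSE]
  cross[is.na(cross)] <- 0
  score_a <- rowSums(cross)
  score_b <- colSums(cross)
  d <- data.frame(
    res_seq = c(ra, rb),
    res_name = c(M$res_name[ia], M$res_name[ib]),
    helix = c(rep("A", length(ra)), rep("B", length(rb))),
    cross_energy = c(score_a, score_b))
  d <- d[order(d$cross_energy, d$res_seq), ]
  rownames(d) <- NULL
  utils::head(d, top_k)
}
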