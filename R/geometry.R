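## Internal-coordinate chain building (NeRF) and small vector helpers.
## Ideal backbone geometry: N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A;
## angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 degrees;
## trans peptide (omega 180).

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' @keywords internal
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Place atom D given A-B-C, bond |CD|, angle B-C-D (deg), dihedral
## A-B-C-D (deg).  Standard natural-extension reference frame step.
#' @keywords internal
place_atom <- function(a, b, c_, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unitv(c_ - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c_ + bc * d2[1] + m * d2[2] + n * d2[3]
}

## Rotation matrix about unit axis u by angle (radians), Rodrigues form.
#' @keywords internal
rotation_about_axis <- function(u, theta) {
  u <- unitv(u)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Build a peptide backbone from dihedral angles
#'
#' Places N, CA, C, O (and CB for non-glycine) for each residue using
#' ideal bond lengths and angles with trans peptide bonds.  With
#' `phi = -57`, `psi = -47` throughout, this produces a canonical
#' alpha-helix (rise about 1.5 A per residue, 3.6 residues per turn,
#' C-alpha radius about 2.3 A); with `phi = psi = 180` a fully extended
#' chain.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi backbone dihedrals in degrees, recycled to the sequence
#'   length.  `phi[1]` and the last `psi` only affect O/CB placement.
#' @param chain_id chain identifier for the result.
#' @param start_res author number of the first residue.
#' @param with_cb place CB atoms (ideal tetrahedral geometry).
#' @return a `PolymerStructure` with backbone (+CB) atoms.
#' @export
build_backbone <- function(sequence, phi, psi, chain_id = "A",
                           start_res = 1L, with_cb = TRUE) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seq1)
  if (n < 1) stop("sequence must have at least one residue")
  res3 <- aa_one_to_three(seq1)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  ## seed frame for residue 1
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, -1, 0), N[1, ], CA[1, ], 1.525, 111.2, phi[1])
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)        # omega
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
  }
  ## carbonyl O anti to the next amide N (dihedral psi - 180)
  O <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] - 180)
  }
  CB <- matrix(NA_real_, n, 3)
  if (with_cb) {
    for (i in seq_len(n)) {
      if (res3[i] != "GLY") {
        CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 1.530, 110.5,
                              122.55)  # tetrahedral branch off the backbone
      }
    }
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (with_cb && res3[i] != "GLY") {
      nm <- c(nm, "CB"); xyz <- rbind(xyz, CB[i, ])
    }
    rows[[i]] <- data.frame(chain = chain_id,
                            res_seq = start_res + i - 1L,
                            res_name = res3[i], atom_name = nm,
                            element = element_of_atom(nm),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            occupancy = 1.0, b_factor = 0.0,
                            stringsAsFactors = FALSE)
  }
  polymer_structure(do.call(rbind, rows))
}

#' Apply a rigid transform to a structure
#' @param s a `PolymerStructure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector added after rotation.
#' @return the transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(s, xyz)
}

## Schematic full side chains: atoms beyond CB are laid out along the
## CA->CB direction at 1.5 A per bond-graph depth, with branch atoms
## fanned perpendicular to that direction.  Chemically schematic on
## purpose -- gives side chains realistic reach and heavy-atom counts for
## contact and energy analyses without a rotamer library.
#' @keywords internal
add_schematic_sidechains <- function(s) {
  at <- s$atoms
  rt <- residue_table(s)
  extra <- list()
  for (i in seq_len(nrow(rt))) {
    res3 <- rt$res_name[i]
    depth <- AA_SIDECHAIN_DEPTH[[res3]]
    if (is.null(depth) || !length(depth)) next
    sel <- at$chain == rt$chain[i] & at$res_seq == rt$res_seq[i]
    ca <- as.numeric(at[sel & at$atom_name == "CA", c("x", "y", "z")])
    cb <- as.numeric(at[sel & at$atom_name == "CB", c("x", "y", "z")])
    if (!length(cb)) next
    todo <- setdiff(names(depth), at$atom_name[sel])
    if (!length(todo)) next
    d <- unitv(cb - ca)
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- unitv(cross3(d, ref))
    pos <- matrix(0, length(todo), 3)
    for (dep in unique(depth[todo])) {
      grp <- which(depth[todo] == dep)
      off <- (seq_along(grp) - (length(grp) + 1) / 2) * 1.4
      for (j in seq_along(grp)) {
        pos[grp[j], ] <- cb + d * (1.5 * dep) + p * off[j]
      }
    }
    extra[[length(extra) + 1L]] <- data.frame(
      chain = rt$chain[i], res_seq = rt$res_seq[i], res_name = res3,
      atom_name = todo, element = element_of_atom(todo),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occupancy = 1.0, b_factor = 0.0, stringsAsFactors = FALSE)
  }
  if (!length(extra)) return(s)
  allat <- rbind(at, do.call(rbind, extra))
  ## keep residue blocks contiguous in atom order
  allat <- allat[order(match(paste(allat$chain, allat$res_seq, sep = "\r"),
                             unique(paste(at$chain, at$res_seq,
                                          sep = "\r")))), , drop = FALSE]
  polymer_structure(allat, title = s$title)
}

## Unit vector of a helix's axis from its CA trace (principal component,
## oriented N- to C-terminal).
#' @keywords internal
helix_axis <- function(s, chain = NULL) {
  if (is.null(chain)) chain <- s$atoms$chain[1]
  ca <- coords(s)[s$atoms$atom_name == "CA" & s$atoms$chain == chain, ,
                  drop = FALSE]
  ca0 <- sweep(ca, 2, colMeans(ca))
  ax <- svd(ca0)$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  ax
}
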