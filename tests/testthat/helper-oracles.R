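## Independent oracles used across the suite.  These deliberately avoid
## the package's own vectorized code paths: plain scalar loops only.

## Brute-force nonbonded energy between two residues: double loop over
## atom pairs with the same physics (Coulomb 332.0636 q q / r, LJ
## eps[(rmin/r)^12 - 2(rmin/r)^6], Lorentz-Berthelot combining, 12 A
## truncation, 1-2/1-3/1-4 peptide-bond exclusions, amide hydrogens
## placed by the documented rule when the structure has none).
brute_pair_energy <- function(s, ri, rj, params, cutoff = 12) {
  at <- s$atoms
  if (!any(at$atom_name == "H")) {
    res_ids <- unique(at$res_seq)
    for (k in seq_along(res_ids)[-1]) {
      r <- res_ids[k]
      if (res_ids[k] - res_ids[k - 1] != 1) next
      sel <- at[at$res_seq == r, ]
      if (sel$res_name[1] == "PRO") next
      N <- as.numeric(sel[sel$atom_name == "N", c("x", "y", "z")])
      prev <- at[at$res_seq == res_ids[k - 1], ]
      C <- as.numeric(prev[prev$atom_name == "C", c("x", "y", "z")])
      O <- as.numeric(prev[prev$atom_name == "O", c("x", "y", "z")])
      if (!length(N) || !length(C) || !length(O)) next
      d <- C - O
      H <- N + d / sqrt(sum(d^2))
      at <- rbind(at, data.frame(chain = sel$chain[1], res_seq = r,
                                 res_name = sel$res_name[1],
                                 atom_name = "H", element = "H",
                                 x = H[1], y = H[2], z = H[3],
                                 occupancy = 1, b_factor = 0))
    }
  }
  ai <- which(at$res_seq == ri)
  aj <- which(at$res_seq == rj)
  excl <- list(c("C", "N"), c("C", "H"), c("C", "CA"), c("C", "C"),
               c("C", "CB"), c("CA", "N"), c("CA", "H"), c("CA", "CA"),
               c("O", "N"), c("O", "H"), c("O", "CA"), c("N", "N"),
               c("CB", "N"))
  adjacent <- abs(rj - ri) == 1
  first_i <- ri < rj
  coul <- 0; lj <- 0
  for (a in ai) {
    pa <- params[params$res_name == at$res_name[a] &
                   params$atom_name == at$atom_name[a], ]
    for (b in aj) {
      if (adjacent) {
        pair <- if (first_i) c(at$atom_name[a], at$atom_name[b])
        else c(at$atom_name[b], at$atom_name[a])
        skip <- FALSE
        for (e in excl) if (identical(pair, e)) skip <- TRUE
        if (skip) next
      }
      pb <- params[params$res_name == at$res_name[b] &
                     params$atom_name == at$atom_name[b], ]
      r <- sqrt(sum((c(at$x[a], at$y[a], at$z[a]) -
                       c(at$x[b], at$y[b], at$z[b]))^2))
      if (r > cutoff || r == 0) next
      coul <- coul + 332.0636 * pa$partial_charge * pb$partial_charge / r
      rmin <- pa$lj_rmin_half + pb$lj_rmin_half
      eps <- sqrt(pa$lj_epsilon * pb$lj_epsilon)
      lj <- lj + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  c(coulomb = coul, lj = lj, total = coul + lj)
}

## Exhaustive Zimm-Bragg equilibrium helicity for small n: enumerate all
## 2^n binary configurations, keep those whose helical runs are >= 4 and
## whose interior coil gaps are >= 2, and average the helix count under
## the weight s^h sigma^runs.
enum_zb_helicity <- function(n, s, sigma, min_run = 4, min_gap = 2) {
  Z <- 0; H <- 0
  for (m in 0:(2^n - 1)) {
    st <- as.integer(intToBits(m))[1:n]
    r <- rle(st)
    if (any(r$lengths[r$values == 1] < min_run)) next
    coil <- which(r$values == 0)
    inter <- coil[coil > 1 & coil < length(r$values)]
    if (any(r$lengths[inter] < min_gap)) next
    w <- s^sum(st) * sigma^sum(r$values == 1)
    Z <- Z + w; H <- H + w * sum(st)
  }
  H / (Z * n)
}

## Random rigid transform (proper rotation + translation).
random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = stats::rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, tr) {
  sweep(xyz %*% t(tr$R), 2, tr$t, "+")
}

## A short mixed-secondary-structure fixture: residues 1-10 helical,
## 11-20 extended, built from dihedrals.
mixed_helix_coil <- function() {
  build_backbone(strrep("A", 20),
                 phi = c(rep(-57, 10), rep(-150, 10)),
                 psi = c(rep(-47, 10), rep(150, 10)))
}
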