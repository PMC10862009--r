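## Seed-deterministic generators: ideal/extended backbones, a toy
## graftable two-helix scaffold, a helix bundle with planted aromatic
## anchors, Zimm-Bragg-style fraying trajectories with latent ground
## truth, and HDX uptake tables with planted protection.

HELIX_PHI <- -57
HELIX_PSI <- -47
## Coil dihedrals are drawn uniformly from a broad extended
## (beta/polyproline-like) region, well away from helical values, so coil
## stretches can never satisfy the alpha-helix hydrogen-bond geometry.
COIL_PHI_RANGE <- c(-160, -95)
COIL_PSI_RANGE <- c(100, 170)
MIN_HELIX_RUN <- 4L  # one full turn: the smallest nucleus the assignment
                     # rule can represent
MIN_COIL_GAP <- 2L   # interior coil gaps of 1 sit on the edge of the
                     # hydrogen-bond geometry; the latent model keeps
                     # broken stretches at least this long

#' Build an ideal alpha-helix
#'
#' Canonical helix from ideal internal coordinates (phi -57, psi -47):
#' rise about 1.5 A per residue, 100 degrees per residue twist, C-alpha
#' radius about 2.3 A.  Backbone N/CA/C/O plus CB (except glycine).
#'
#' @param sequence one-letter sequence.
#' @param chain_id,start_res output numbering.
#' @return a `PolymerStructure`.
#' @export
build_ideal_helix <- function(sequence, chain_id = "A", start_res = 1L) {
  build_backbone(sequence, phi = HELIX_PHI, psi = HELIX_PSI,
                 chain_id = chain_id, start_res = start_res)
}

#' Build a fully extended chain (phi = psi = 180)
#' @inheritParams build_ideal_helix
#' @return a `PolymerStructure`.
#' @export
build_extended_chain <- function(sequence, chain_id = "A", start_res = 1L) {
  build_backbone(sequence, phi = 180, psi = 180,
                 chain_id = chain_id, start_res = start_res)
}

## Toy scaffold layout: two 18-residue helices joined by a 4-residue
## excisable VVAG loop (residues 19-22), 40 residues total.
TOY_SCAFFOLD_SEQ <- paste0("AEELIKAAEELIKAAEEL",  # helix 1: 1-18
                           "VVAG",                # loop:    19-22
                           "IKAAEELIKAAEELIKAA")  # helix 2: 23-40
TOY_SCAFFOLD_LOOP <- c(19L, 22L)

#' Build the deterministic toy graftable scaffold
#'
#' A 40-residue helix-loop-helix chain whose 4-residue VVAG loop
#' (residues 19-22) is the excisable graft site, mimicking a scaffold
#' displaying loop.  The loop and flanking turn use fixed non-helical
#' dihedrals, so regeneration is bit-identical.  The anchor gap (C-alpha
#' 18 to C-alpha 23) is a fixed constant of the construction, available
#' from [anchor_gap()].
#'
#' @return a `PolymerStructure` (chain "A", residues 1-40).
#' @export
build_toy_scaffold <- function() {
  n <- nchar(TOY_SCAFFOLD_SEQ)
  phi <- rep(HELIX_PHI, n)
  psi <- rep(HELIX_PSI, n)
  ## loop region 19-22 plus the hinge residue 18 break the helix and
  ## turn the chain back on itself into a clash-free hairpin
  loop_phi <- c(-53.6, -95.7, -147.7, -108.4, -117.3)
  loop_psi <- c(145.0, -43.1, -17.7, 119.1, 46.1)
  phi[18:22] <- loop_phi
  psi[18:22] <- loop_psi
  build_backbone(TOY_SCAFFOLD_SEQ, phi = phi, psi = psi, chain_id = "A")
}

#' Segment spec of the toy scaffold's excisable loop
#' @return a `SegmentSpec` (chain A, residues 19-22, sequence VVAG).
#' @export
toy_scaffold_loop <- function() {
  segment_spec("A", TOY_SCAFFOLD_LOOP[1], TOY_SCAFFOLD_LOOP[2])
}

#' Antiparallel two-helix bundle with planted aromatic anchor residues
#'
#' Builds two antiparallel ideal helices with full (schematically
#' placed) side chains.  Three phenylalanine anchors in helix A sit on
#' one helical face (heptad-like spacing) and the helix is rotated about
#' its own axis so their rings reach into the inter-helix gap, where
#' they pack against valines of helix B registered to the same axial
#' positions.  The separation is chosen so these planted aromatic
#' contacts sit near van der Waals contact while the two backbones stay
#' outside the nonbonded cutoff of each other -- the anchors are the
#' unambiguous planted ground truth for inter-helix contributor
#' recovery, and truncating them to alanine removes the contacts.
#'
#' @param seq_a one-letter sequence of helix A (anchors included).
#' @param seq_b one-letter sequence of helix B (facing valines at the
#'   axially registered positions).
#' @param anchors_a residue numbers of the planted anchors in helix A
#'   (default 4, 11, 18: the phenylalanines of the default sequence).
#' @param partners_b positions of the facing valines within helix B
#'   (default 3, 10, 17, i.e. residues 33, 40, 47).
#' @param start_b residue number of the first residue of helix B
#'   (helix A starts at 1).
#' @param separation axis-to-axis distance, Angstrom.
#' @return list `structure` (single chain "A", helix B numbered from
#'   `start_b`), `helixA`, `helixB` (`SegmentSpec`s), `anchors`.
#' @export
build_helix_bundle <- function(seq_a = "ASLFNAALSAFNASASAFLA",
                               seq_b = "ALVSNAALSVANASASVALA",
                               anchors_a = c(4L, 11L, 18L),
                               partners_b = c(3L, 10L, 17L),
                               start_b = 31L, separation = 18.2) {
  orient <- function(s, face_res, face_dir) {
    ## axis to +z
    ax <- helix_axis(s)
    s <- transform_structure(s, rotation_between(ax, c(0, 0, 1)))
    ca_all <- coords(s)[s$atoms$atom_name == "CA", , drop = FALSE]
    s <- transform_structure(s, translation = -colMeans(ca_all))
    ## rotate about z so the face residue's CA->CB direction points
    ## along face_dir in the xy-plane
    at <- s$atoms
    pick <- function(nm) {
      as.numeric(at[at$res_seq == face_res & at$atom_name == nm,
                    c("x", "y", "z")])
    }
    v <- pick("CB") - pick("CA")
    v[3] <- 0
    th <- atan2(face_dir[2], face_dir[1]) - atan2(v[2], v[1])
    transform_structure(s, rotation_about_axis(c(0, 0, 1), th))
  }
  ha <- add_schematic_sidechains(build_ideal_helix(seq_a, start_res = 1L))
  hb <- add_schematic_sidechains(build_ideal_helix(seq_b,
                                                   start_res = start_b))
  mid_anchor <- anchors_a[ceiling(length(anchors_a) / 2)]
  mid_partner <- start_b + partners_b[ceiling(length(partners_b) / 2)] - 1L
  ha <- orient(ha, mid_anchor, c(1, 0))          # anchors face the gap
  hb <- orient(hb, mid_partner, c(-1, 0))        # valines face helix A
  ## antiparallel: flip helix B end over end (the x-axis flip keeps the
  ## valine face toward A while opposing the backbone dipoles)
  hb <- transform_structure(hb, rotation_about_axis(c(1, 0, 0), pi))
  ha <- transform_structure(ha, translation = c(-separation / 2, 0, 0))
  hb <- transform_structure(hb, translation = c(separation / 2, 0, 0))
  s <- polymer_structure(rbind(ha$atoms, hb$atoms), title = "helix bundle")
  ## aim each anchor ring into the gap: re-place its side-chain atoms
  ## along the line from its CA to the nearest helix-B heavy atom, with
  ## the ring tip left just outside van der Waals contact
  at <- s$atoms
  b_rows <- which(at$res_seq >= start_b)
  bxyz <- as.matrix(at[b_rows, c("x", "y", "z")])
  for (r in anchors_a) {
    ca_i <- which(at$res_seq == r & at$atom_name == "CA")
    ca <- as.numeric(at[ca_i, c("x", "y", "z")])
    dd <- sqrt(colSums((t(bxyz) - ca)^2))
    dvec <- unitv(bxyz[which.min(dd), ] - ca)
    depth <- AA_SIDECHAIN_DEPTH[[at$res_name[ca_i]]]
    max_depth <- max(depth)
    spacing <- min(2.0, max(1.0, (min(dd) - 4.2 - 1.53) / max_depth))
    perp <- unitv(cross3(dvec, c(0, 0, 1)))
    side_i <- which(at$res_seq == r &
                      !at$atom_name %in% c("N", "CA", "C", "O"))
    for (k in side_i) {
      nm <- at$atom_name[k]
      if (nm == "CB") {
        at[k, c("x", "y", "z")] <- ca + 1.53 * dvec
      } else {
        dep <- depth[[nm]]
        grp <- names(depth)[depth == dep]
        off <- (match(nm, grp) - (length(grp) + 1) / 2) * 1.4
        at[k, c("x", "y", "z")] <- ca + (1.53 + spacing * dep) * dvec +
          off * perp
      }
    }
  }
  s <- polymer_structure(at, title = "helix bundle")
  list(structure = s,
       helixA = segment_spec("A", 1L, nchar(seq_a)),
       helixB = segment_spec("A", start_b, start_b + nchar(seq_b) - 1L),
       anchors = as.integer(anchors_a))
}

## ---- Zimm-Bragg-style latent helix-coil model -------------------------

## Exact equilibrium helicity of the run-length-constrained Zimm-Bragg
## measure: configuration weight s^(#H) * sigma^(#helical runs), over
## binary sequences whose every helical run has length >= min_run.
## Dynamic programme over (state, run length), carrying (Z, sum w * #H).

#' Exact Zimm-Bragg equilibrium helicity
#'
#' Mean fraction of helical residues under the nucleation-propagation
#' measure `s^h * sigma^runs` restricted to configurations whose helical
#' runs all span at least `min_run` residues (one full turn) and whose
#' interior coil gaps span at least two.  Computed exactly from the
#' forward-backward marginals; serves as the simulator's own
#' ground-truth equilibrium.
#'
#' @param n_res chain length.
#' @param s propagation weight (> 0).
#' @param sigma nucleation weight in (0, 1].
#' @param min_run minimum helical run length (default 4).
#' @return mean helicity in [0, 1].
#' @export
zb_equilibrium_helicity <- function(n_res, s, sigma, min_run = MIN_HELIX_RUN) {
  mean(zb_residue_helicity(n_res, s, sigma, min_run))
}

#' Per-residue equilibrium helix probabilities
#'
#' Forward-backward marginals of the run-length-constrained Zimm-Bragg
#' measure: the probability that each residue is helical at equilibrium.
#' Helical runs span at least `min_run` residues and interior coil gaps
#' at least two; configuration weight is `s^(#H) * sigma^(#runs)`.
#'
#' @inheritParams zb_equilibrium_helicity
#' @return numeric vector of length `n_res`.
#' @export
zb_residue_helicity <- function(n_res, s, sigma, min_run = MIN_HELIX_RUN) {
  stopifnot(n_res >= 1, s > 0, sigma > 0, min_run >= 2)
  ## states: 1 = initial coil (no run yet); 1+r (r in 1..min_run) = in a
  ## run of current length r, capped; then post-run coil of length 1,
  ## and post-run coil of length >= 2 (only there may a new run start)
  cap <- 1L + min_run
  cp1 <- cap + 1L; cp2 <- cap + 2L
  ns <- cp2
  Tm <- matrix(0, ns, ns)
  Tm[1, 1] <- 1                       # initial coil continues
  Tm[1, 2] <- sigma * s               # nucleate from initial coil
  for (r in 1:(min_run - 1)) Tm[1 + r, 2 + r] <- s  # grow a run
  Tm[cap, cap] <- s                   # extend a completed run
  Tm[cap, cp1] <- 1                   # run ends
  Tm[cp1, cp2] <- 1                   # gap grows to 2
  Tm[cp2, cp2] <- 1
  Tm[cp2, 2] <- sigma * s             # nucleate after a full gap
  start <- numeric(ns); start[1] <- 1; start[2] <- sigma * s
  final <- numeric(ns); final[c(1, cap, cp1, cp2)] <- 1
  helix_states <- 2:cap
  Fw <- matrix(0, n_res, ns); Bw <- matrix(0, n_res, ns)
  Fw[1, ] <- start
  if (n_res >= 2) {
    for (i in 2:n_res) {
      v <- as.numeric(Fw[i - 1, ] %*% Tm)
      Fw[i, ] <- v / max(v)
    }
  }
  Bw[n_res, ] <- final
  if (n_res >= 2) {
    for (i in (n_res - 1):1) {
      v <- as.numeric(Tm %*% Bw[i + 1, ])
      Bw[i, ] <- v / max(v)
    }
  }
  vapply(seq_len(n_res), function(i) {
    w <- Fw[i, ] * Bw[i, ]
    sum(w[helix_states]) / sum(w)
  }, numeric(1))
}

#' Calibrate the propagation weight to a target helicity
#'
#' Bisection on log(s) so that [zb_equilibrium_helicity()] matches the
#' target.
#'
#' @param n_res chain length.
#' @param target_helicity target mean helicity, strictly inside (0, 1).
#' @param sigma nucleation weight.
#' @param min_run minimum helical run length.
#' @param tol bisection tolerance on the helicity.
#' @param interior optional residue positions over which the target mean
#'   is enforced (default: the whole chain).
#' @return propagation weight `s`.
#' @export
calibrate_propagation <- function(n_res, target_helicity, sigma,
                                  min_run = MIN_HELIX_RUN, tol = 1e-6,
                                  interior = NULL) {
  if (!(target_helicity > 0 && target_helicity < 1)) {
    stop("target helicity must be strictly inside (0, 1)")
  }
  if (is.null(interior)) interior <- seq_len(n_res)
  f <- function(ls) {
    mean(zb_residue_helicity(n_res, exp(ls), sigma, min_run)[interior]) -
      target_helicity
  }
  lo <- -8; hi <- 12
  if (f(lo) > 0 || f(hi) < 0) stop("target helicity unreachable for this chain")
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  s <- exp((lo + hi) / 2)
  if (abs(f(log(s))) > max(tol, 1e-4)) stop("calibration did not converge")
  s
}

## Valid configuration: every maximal helical run >= min_run and every
## interior coil gap >= MIN_COIL_GAP.
#' @keywords internal
runs_valid <- function(state, min_run = MIN_HELIX_RUN) {
  r <- rle(state)
  if (!all(r$lengths[r$values == 1L] >= min_run)) return(FALSE)
  coil <- which(r$values == 0L)
  interior <- coil[coil > 1 & coil < length(r$values)]
  all(r$lengths[interior] >= MIN_COIL_GAP)
}

## log unnormalized weight of a latent configuration
#' @keywords internal
zb_log_weight <- function(state, log_s, log_sigma) {
  r <- rle(state)
  n_h <- sum(state)
  n_runs <- sum(r$values == 1L)
  n_h * log_s + n_runs * log_sigma
}

#' Fraying-trajectory simulator configuration
#'
#' @param sequence one-letter sequence of the simulated peptide (default
#'   a 20-residue EAK-style helical model peptide).
#' @param n_frames frames recorded per replicate (default 2000).
#' @param n_replicates replicate trajectories (default 3, the analysis
#'   convention).
#' @param target_helicity equilibrium mean helicity aimed for (0, 1).
#' @param nucleation_weight Zimm-Bragg sigma in (0, 1] (default 0.01).
#' @param coordinate_noise_sigma isotropic Gaussian coordinate jitter,
#'   Angstrom (default 0.1).
#' @param frame_spacing_ps nominal frame spacing (default 10 ps).
#' @param sweeps_per_frame Metropolis sweeps between recorded frames.
#' @param burn_in_sweeps sweeps discarded before recording.
#' @param seed integer seed; replicates use `seed + replicate - 1`.
#' @return a `FrayConfig` list.
#' @export
fray_config <- function(sequence = "AEAAIKEAAAKIEAAEKAAA",
                        n_frames = 2000, n_replicates = 3,
                        target_helicity = 0.7, nucleation_weight = 0.01,
                        coordinate_noise_sigma = 0.1,
                        frame_spacing_ps = 10, sweeps_per_frame = 5,
                        burn_in_sweeps = 200, seed = 1L) {
  stopifnot(n_frames >= 1, n_replicates >= 1,
            nucleation_weight > 0, nucleation_weight <= 1,
            coordinate_noise_sigma >= 0)
  structure(list(sequence = toupper(sequence), n_res = nchar(sequence),
                 n_frames = as.integer(n_frames),
                 n_replicates = as.integer(n_replicates),
                 target_helicity = target_helicity,
                 nucleation_weight = nucleation_weight,
                 coordinate_noise_sigma = coordinate_noise_sigma,
                 frame_spacing_ps = frame_spacing_ps,
                 sweeps_per_frame = as.integer(sweeps_per_frame),
                 burn_in_sweeps = as.integer(burn_in_sweeps),
                 seed = as.integer(seed)),
            class = "FrayConfig")
}

## One Metropolis pass over the latent chain: single flips plus
## nucleation/denucleation block flips of min_run residues, rejecting
## moves that violate the run-length constraint.
#' @keywords internal
zb_sweep <- function(state, log_s, log_sigma, min_run = MIN_HELIX_RUN) {
  n <- length(state)
  lw <- zb_log_weight(state, log_s, log_sigma)
  for (k in seq_len(n)) {
    if (stats::runif(1) < 0.5) {
      i <- sample.int(n, 1)
      cand <- state; cand[i] <- 1L - cand[i]
    } else {
      i <- sample.int(n - min_run + 1L, 1)
      cand <- state
      cand[i:(i + min_run - 1L)] <- 1L - cand[i:(i + min_run - 1L)]
    }
    if (!runs_valid(cand, min_run)) next
    lw_c <- zb_log_weight(cand, log_s, log_sigma)
    if (log(stats::runif(1)) < lw_c - lw) {
      state <- cand; lw <- lw_c
    }
  }
  state
}

## Realize coordinates for one latent configuration: helical residues get
## ideal helix dihedrals; the residue immediately before each run gets a
## helical psi (so the run's first hydrogen bond can form and the
## assignment recovers the latent labels exactly); coil residues draw
## fresh extended-region dihedrals.
#' @keywords internal
realize_frame <- function(state, sequence, noise_sigma) {
  n <- length(state)
  phi <- stats::runif(n, COIL_PHI_RANGE[1], COIL_PHI_RANGE[2])
  psi <- stats::runif(n, COIL_PSI_RANGE[1], COIL_PSI_RANGE[2])
  phi[state == 1L] <- HELIX_PHI
  psi[state == 1L] <- HELIX_PSI
  starts <- which(diff(c(0L, state)) == 1L)
  pre <- starts[starts > 1L] - 1L
  psi[pre] <- HELIX_PSI
  s <- build_backbone(sequence, phi = phi, psi = psi)
  xyz <- coords(s)
  if (noise_sigma > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                        ncol = 3)
  }
  xyz
}

#' Simulate replicate helix-fraying trajectories with known ground truth
#'
#' Latent per-residue helix/coil states evolve by Metropolis dynamics
#' under a Zimm-Bragg-style weight (propagation `s` calibrated by
#' bisection so the exact equilibrium helicity matches
#' `target_helicity`; nucleation penalty `sigma`; helical runs
#' constrained to at least one full turn).  Coordinates realize helical
#' stretches with ideal helix geometry and coil stretches with fresh
#' extended-region dihedrals, plus isotropic Gaussian jitter.  Replicates
#' differ only by seed offset.
#'
#' @param cfg a `FrayConfig`.
#' @return list: `ensembles` (list of `Ensemble`s), `ground_truth` (list
#'   of n_frames x n_res 0/1 matrices), `propagation_weight` (calibrated
#'   `s`), `equilibrium_helicity` (exact model value).
#' @export
simulate_fray <- function(cfg) {
  stopifnot(inherits(cfg, "FrayConfig"))
  ## the two terminal residues are pinned coil (frayed ends): the helix
  ## assignment rule cannot represent a run touching a chain end, so
  ## pinning keeps the coordinate realization exactly faithful to the
  ## latent states.  The propagation weight is calibrated so the
  ## equilibrium helicity over the *measured* interior (two residues
  ## excluded per end) matches the target.
  if (cfg$n_res < 8) stop("fray simulation needs at least 8 residues")
  m <- cfg$n_res - 2L
  inner_interior <- 2:(m - 1)   # chain residues 3..n-2
  s_w <- calibrate_propagation(m, cfg$target_helicity,
                               cfg$nucleation_weight,
                               interior = inner_interior)
  log_s <- log(s_w); log_sigma <- log(cfg$nucleation_weight)
  topo <- build_ideal_helix(cfg$sequence)

  ensembles <- vector("list", cfg$n_replicates)
  truth <- vector("list", cfg$n_replicates)
  for (rep_i in seq_len(cfg$n_replicates)) {
    set.seed(cfg$seed + rep_i - 1L)
    ## start all-helix (valid) and burn in
    state <- rep(1L, m)
    for (k in seq_len(cfg$burn_in_sweeps)) {
      state <- zb_sweep(state, log_s, log_sigma)
    }
    frames <- vector("list", cfg$n_frames)
    gt <- matrix(0L, cfg$n_frames, cfg$n_res)
    for (f in seq_len(cfg$n_frames)) {
      for (k in seq_len(cfg$sweeps_per_frame)) {
        state <- zb_sweep(state, log_s, log_sigma)
      }
      full <- c(0L, state, 0L)
      gt[f, ] <- full
      frames[[f]] <- realize_frame(full, cfg$sequence,
                                   cfg$coordinate_noise_sigma)
    }
    ensembles[[rep_i]] <- ensemble(topo, frames,
                                   frame_spacing_ps = cfg$frame_spacing_ps,
                                   replicate_id = rep_i)
    truth[[rep_i]] <- gt
  }
  list(ensembles = ensembles, ground_truth = truth,
       propagation_weight = s_w,
       equilibrium_helicity = mean(zb_residue_helicity(
         m, s_w, cfg$nucleation_weight)[inner_interior]))
}

#' Latent-state helicity over the interior of a segment
#'
#' Companion ground-truth summary for [helical_fraction()]: the fraction
#' of latent helix states over (frame, residue) pairs among interior
#' residues (position range after excluding `exclude_terminal` per end).
#'
#' @param ground_truth list of frame x residue 0/1 matrices (one per
#'   replicate).
#' @param exclude_terminal residues dropped per end (default 2).
#' @return per-replicate latent fractions.
#' @export
latent_helicity <- function(ground_truth, exclude_terminal = 2) {
  vapply(ground_truth, function(gt) {
    n <- ncol(gt)
    interior <- (1 + exclude_terminal):(n - exclude_terminal)
    mean(gt[, interior])
  }, numeric(1))
}

## ---- HDX simulator ----------------------------------------------------

#' HDX uptake simulator configuration
#'
#' @param n_res construct length (default 60).
#' @param epitope_residues residues protected on binding (default 26:45,
#'   aligned with the default peptide tiling so every peptide is either
#'   clearly protected or clearly untouched).
#' @param protection_fold factor multiplying epitope protection factors in
#'   the bound state (default 10).
#' @param peptide_length,peptide_stride tiling of the construct into
#'   overlapping peptides.
#' @param k_int intrinsic amide exchange rates, 1/s; recycled to n_res
#'   (default 1).
#' @param pf_apo apo-state protection factors; recycled (default 50).
#' @param timepoints_s labeling times, seconds.
#' @param noise_sd Gaussian noise on uptake fractions (default 0.01).
#' @param seed integer seed.
#' @return an `HDXSimConfig` list.
#' @export
hdx_sim_config <- function(n_res = 60, epitope_residues = 26:45,
                           protection_fold = 10, peptide_length = 10,
                           peptide_stride = 5, k_int = 1, pf_apo = 50,
                           timepoints_s = c(30, 300, 3000, 30000),
                           noise_sd = 0.01, seed = 1L) {
  stopifnot(protection_fold >= 1, all(k_int > 0), all(pf_apo >= 1))
  structure(list(n_res = as.integer(n_res),
                 epitope_residues = as.integer(epitope_residues),
                 protection_fold = protection_fold,
                 peptide_length = as.integer(peptide_length),
                 peptide_stride = as.integer(peptide_stride),
                 k_int = rep_len(k_int, n_res),
                 pf_apo = rep_len(pf_apo, n_res),
                 timepoints_s = timepoints_s, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "HDXSimConfig")
}

#' Simulate a peptide-level HDX uptake table with a planted epitope
#'
#' Per-residue uptake follows first-order exchange
#' `u(t) = 1 - exp(-k_int t / PF)`; peptide uptake is the mean over
#' exchangeable amides (all residues after the peptide's first).  The
#' bound condition multiplies the protection factor of epitope residues
#' by `protection_fold`.  Gaussian noise is added and clipped to [0, 1].
#'
#' @param cfg an `HDXSimConfig`.
#' @param path optional CSV output path.
#' @return list: `table` (apo+bound long data.frame as read by
#'   [load_uptake()]), `peptides` (tiling with `overlaps_epitope` truth),
#'   `epitope_residues`.  The CSV, when requested, round-trips through
#'   [load_uptake()] unchanged.
#' @export
simulate_hdx <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "HDXSimConfig"))
  set.seed(cfg$seed)
  starts <- seq(1L, cfg$n_res - cfg$peptide_length + 1L,
                by = cfg$peptide_stride)
  peptides <- data.frame(start = starts,
                         end = pmin(starts + cfg$peptide_length - 1L,
                                    cfg$n_res))
  peptides$sequence <- vapply(seq_len(nrow(peptides)), function(i) {
    paste(rep("A", peptides$end[i] - peptides$start[i] + 1L), collapse = "")
  }, character(1))
  ## a peptide carries the planted protection signal when at least two
  ## of its exchangeable amides (all residues after the first) fall in
  ## the epitope; single-amide overlaps dilute below detectability
  peptides$overlaps_epitope <- vapply(seq_len(nrow(peptides)), function(i) {
    length(intersect(seq.int(peptides$start[i] + 1L, peptides$end[i]),
                     cfg$epitope_residues)) >= 2
  }, logical(1))

  pf_bound <- cfg$pf_apo
  pf_bound[cfg$epitope_residues] <- pf_bound[cfg$epitope_residues] *
    cfg$protection_fold

  rows <- list()
  for (cond in c("apo", "bound")) {
    pf <- if (cond == "apo") cfg$pf_apo else pf_bound
    for (i in seq_len(nrow(peptides))) {
      amides <- (peptides$start[i] + 1L):peptides$end[i]
      for (t in cfg$timepoints_s) {
        u <- mean(1 - exp(-cfg$k_int[amides] * t / pf[amides]))
        if (cfg$noise_sd > 0) u <- u + stats::rnorm(1, 0, cfg$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          start = peptides$start[i], end = peptides$end[i],
          sequence = peptides$sequence[i], condition = cond,
          timepoint_s = t, uptake = min(max(u, 0), 1))
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  n_pro <- vapply(strsplit(toupper(tab$sequence), ""),
                  function(s) sum(s == "P"), integer(1))
  tab$n_exchangeable <- nchar(tab$sequence) - n_pro - 1L
  class(tab) <- c("hdx_table", "data.frame")
  list(table = tab, peptides = peptides,
       epitope_residues = cfg$epitope_residues)
}
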