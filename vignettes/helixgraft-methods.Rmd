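---
title: "helixgraft: models, conventions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixgraft: models, conventions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixgraft)
```

# The problem

Short helical epitopes excised from membrane proteins rarely keep their
fold when displayed on a small scaffold, because the packing partners
that stabilized the helix in the parent protein are missing.  The
design loop this package supports is: graft the segment into a scaffold
loop with flexible linkers, model the chimera, simulate or import
conformational ensembles, and ask two quantitative questions — *does
the grafted region stay helical?* and *which residues supply the
stabilizing interactions?* — plus a third, experimental one: *does a
binder raised against the chimera actually engage the grafted region?*
(answered from differential HDX uptake).

This vignette records the models behind each stage, the numerical
conventions, and the design decisions taken where more than one
reasonable choice existed.

# Structures and ensembles

Structures are flat atom tables (`PolymerStructure`) with author
residue numbering preserved everywhere; all residue ranges
(`segment_spec`) are inclusive on both ends, matching the "residues
35–54" convention of the field.  Conformational ensembles (`Ensemble`)
are lists of coordinate frames congruent with one topology, with a
nominal frame spacing in picoseconds (default 10 ps) and a replicate
id.  PDB is the only required format: MODEL/ENDMDL blocks map to
frames, HETATM records and waters are skipped, altloc conformers
collapse to the highest occupancy (ties by altloc letter), and a
single-frame ensemble is written without MODEL records.  Hydrogens in
the input are kept but never required — every analysis that needs an
amide hydrogen places it itself (below).

A stride parameter on the trajectory analyses (default 1, i.e. every
frame) covers the case where only a subsample of snapshots should be
analysed; nothing in the statistics depends on frame order.

# Helix assignment

Backbone hydrogen bonds are scored with the Kabsch–Sander electrostatic
model used by DSSP:

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \mathrm{kcal/mol},$$

with distances in Å, a bond when $E < -0.5$ kcal/mol, a clamp at
$-9.9$ and an overlap sentinel when any distance falls under 0.5 Å.
Amide hydrogens are placed 1.0 Å from N along the preceding carbonyl
C→O direction; prolines and chain starts get none.  A 4-turn exists at
residue $i$ when the N–H of residue $i{+}4$ bonds the C=O of residue
$i$; residues $i{+}1..i{+}4$ are alpha-helical (H) when 4-turns exist
at both $i$ and $i{+}1$; everything else, including un-assignable
residues, is C.  Only the two-state H/C distinction is assigned: every
statistic of interest here is "fraction in alpha-helical conformation",
and counting 3₁₀/π as helical would only shift the fractions upward by
a few percent on fraying ensembles (the assignment rule never produces
those classes on the synthetic data, where coil stretches are built
from extended-region dihedrals).

The helical fraction of a segment is, per replicate, the occupancy of H
over all (frame, residue) pairs among the *interior* residues — the
segment minus two residues per end by default, since terminal residues
cannot satisfy the turn rule and fray first physically.  The report
carries the replicate mean and the sample standard deviation (n−1
denominator, 3 replicates by convention).  A second reading of
"percent of residues helical" — the share of interior residues that
are helical in at least half the frames — is reported alongside as
`per_residue_majority_share`; the pooled-occupancy reading is the
default because it is what a time-averaged secondary-structure summary
measures.  (The per-residue-then-average mean is algebraically
identical to the pooled mean for complete ensembles, so the majority
share is the only genuinely different statistic.)

# Superposition and RMSD

`kabsch()` is the standard SVD solution of the least-squares rigid
superposition problem with the determinant sign correction, so a
reflection is never returned; inputs with fewer than 3 points or a
collinear geometry raise a conditioning error.  `rmsd_series()`
superposes each frame on the reference over a fit region and then
measures RMSD over the interior segment C-alpha atoms.  The default fit
region is the measured interior segment itself: self-fitting measures
internal conformational change of the grafted region, which is the
helix-stability question, rather than rigid-body motion of the segment
relative to the scaffold.  A `fit_on` argument overrides this (e.g. fit
on the scaffold to include wobble of the graft as a whole).  Time axes
are frame index × frame spacing.

# Residue-pair energetics

Pairwise nonbonded energies are the sum over atom pairs within a 12 Å
cutoff of a Coulomb term ($332.0636\,q_aq_b/r$, vacuum dielectric) and
a 12-6 Lennard-Jones term with Lorentz–Berthelot-style combining.
Plain truncation is used — no switching function and no long-range
correction — because pair selection by a 12 Å cutoff is the analysis
convention, and reproducing a particular force field's absolute
energies is explicitly not the goal.

The parameter table is an embedded, documented simplification: all
standard heavy atoms plus the amide hydrogen, partial charges that sum
to each residue's formal charge, and one Lennard-Jones class per
element.  Its contract is the qualitative band structure of the energy
matrix, not force-field compatibility.  Two conventions matter and were
fixed after inspection of the matrix on an ideal helix:

* **Amide hydrogens are included.**  Without the H(+)…O(−) term the
  i→i+4 band loses its attractive component and turns repulsive; the
  energetics therefore place amide hydrogens on the fly (same rule as
  the helix assignment) whenever a structure carries none.
* **Peptide-bond exclusions span the 1-2/1-3/1-4 neighbourhood.**
  Excluding only 1-2/1-3 leaves covalent 1-4 pairs
  (O\_i–CA\_{i+1}, CB\_i–N\_{i+1}, C\_i–C\_{i+1}) at sub-r\_min
  distances, which makes the covalent-adjacent diagonal strongly
  *repulsive* — an artifact of evaluating nonbonded forms at bonded
  geometry.  With the full three-bond exclusion the adjacent diagonal
  is the most negative band and the i→i+4 hydrogen-bond band the
  second, matching the expected qualitative structure.

Matrix cells are classified `adjacent` (|i−j| = 1), `hbond_band`
(|i−j| ∈ 3..5 with a Kabsch–Sander bond in ≥ 50% of frames), `core`
(both residues in the hydrophobic set {A,V,L,I,M,F,W,Y,P} with
frame-averaged total ≤ −1 kcal/mol), or `other`.  Matrices are
frame-averaged by default with a stride option; a single-frame mode is
just a one-frame ensemble.  Inter-helix contributors are ranked by each
residue's summed cross-helix energy, ties by residue number.  Alanine
truncation (`mutate_to_alanine`) renames the residue, deletes
side-chain atoms beyond CB and never touches the backbone, so the
wild-type-minus-mutant cross-helix energy isolates the side chains'
contribution.

# Graft design and the initial model

Linker length is recommended by a reach rule: the smallest $n \ge 0$
with $2n \times 3.5\,\mathrm{Å} \ge |d_{donor} - d_{anchor}| + 4\,
\mathrm{Å}$, capped at 10 per side.  The constants are canonical
geometry (3.5 Å reach per extended residue, 1.5 Å helical rise per
residue for the span estimate) plus 4 Å of slack so a perfectly matched
donor still gets one flexible residue per side.

The initial 3D model is deliberately crude — it seeds analyses and
sanity-checks the geometry, nothing more.  Scaffold coordinates outside
the loop are kept bit-exactly.  The donor is placed rigid-body with its
terminal C-alpha axis along the anchor axis, displaced outward along
the loop normal by a distance that scales with linker length and donor
span, and rotated about the anchor axis in 10° steps; linkers are built
with ideal extended backbone geometry, laid along the anchor-to-donor
gap and pushed outward in 2 Å steps when they would collide with the
segments they bridge (an ideal extended chain is longer than the
straight-line gap it spans, so centring it without the outward search
would bury its ends in the donor terminus).  The first pose in which no
two atoms of *different* segments closer than 2.0 Å exist — residues
adjacent in the chimera sequence are covalently linked and exempt — is
accepted; otherwise the search fails with the achieved minimum
distance.  Junction peptide bonds are not closed and no relaxation is
performed; loop closure and repacking are out of scope by design.

# HDX differencing and epitope calls

Uptake tables are peptide-level deuteration fractions over timepoints,
one row per peptide × timepoint × condition; a maximally labelled
control, when present as `mass_t`/`mass_0`/`mass_full` columns, is
back-exchange-normalized as $(m_t - m_0)/(m_{full} - m_0)$.
Exchangeable amides are all residues after a peptide's first, minus
prolines.  The difference report is bound minus apo per matched peptide
and timepoint; unmatched peptides are listed, not dropped.  A peptide
is called protected when its difference is at or below −0.05 at two or
more timepoints.  Both thresholds are tunable defaults, chosen so that,
at a 10-fold protection-factor change over roughly half a peptide's
amides, the protected curves separate cleanly from noise at the 0.01
uptake-sd level; raw differences are always reported next to the
calls.  No replicate significance test is applied by default (a Welch
test across replicates would need replicate columns that the minimal
table does not require).  With a graft design supplied, each called
peptide is annotated `grafted`, `scaffold`, `linker` or `mixed` through
the chimera index map, which is what turns a protection call into an
epitope statement about the grafted region.

# The synthetic generators

The generators exist to give every analysis operator a ground truth;
they emulate the *statistical* features the operators measure, not
molecular physics.

**Backbones** are built from internal coordinates (ideal bond lengths
and angles, trans peptides); `phi = -57, psi = -47` gives the canonical
alpha-helix (3.8 Å C-alpha virtual bonds, ~1.5 Å rise/residue),
`phi = psi = 180` the extended chain.  Side chains beyond CB, where
needed, are placed schematically — atoms at 1.5 Å per bond-graph depth
along the CA→CB direction with branch atoms fanned sideways.  This
gives side chains realistic reach and atom counts for contact and
energy analyses without a rotamer library; it does not give realistic
ring geometry, and no analysis here depends on one.

**The toy scaffold** is a fixed 40-residue helix-loop-helix hairpin
with an excisable VVAG loop at residues 19–22 and an anchor gap of
8.84 Å; the loop dihedrals were chosen once so the hairpin is clash
free (minimum non-neighbour heavy-atom distance 3.1 Å) and roughly
antiparallel, and are frozen as constants, so regeneration is
bit-identical.

**The planted-anchor bundle** is two antiparallel ideal helices at
18.2 Å axis separation: three phenylalanine anchors on one face of
helix A, registered valines on helix B, with each anchor's schematic
ring re-aimed at the nearest helix-B atom and left just outside van der
Waals contact.  At that separation the two backbones sit entirely
outside each other's 12 Å cutoff, so the cross-helix energy is carried
by the planted contacts alone — which is what makes the bundle an
unambiguous ground truth for contributor ranking and for the
alanine-truncation contrast.  Phenylalanine (uncharged side chain) was
chosen over tryptophan/tyrosine so the planted signal is pure
Lennard-Jones packing; with hard 12 Å truncation, partial charges on
anchor tips would add cutoff-boundary Coulomb noise of the same order
as the packing signal.

**Fraying trajectories** are a kinematic stand-in for replicate MD.
Latent per-residue helix/coil states evolve by Metropolis dynamics
(single flips plus one-turn block flips) under a Zimm–Bragg-style
weight $s^{h}\sigma^{runs}$, with two constraints that make the
coordinate realization exactly faithful to the assignment rule:
helical runs span at least 4 residues (one turn — the smallest nucleus
an i→i+4 bond pattern can represent) and interior coil gaps at least 2
(a single coil residue between runs sits on the edge of the
hydrogen-bond geometry).  The two chain termini are pinned coil
(frayed ends), because no run touching a terminus is representable by
the turn rule.  Coordinates realize helical residues with ideal helix
dihedrals, set a helical psi on the residue immediately before each run
(the 4-turn at $i$ depends on $\psi_i$ and the $\phi/\psi$ of
$i{+}1..i{+}3$ only), draw coil dihedrals uniformly from an extended
region ($\phi \in [-160,-95]$, $\psi \in [100,170]$) fresh each frame,
and add isotropic Gaussian jitter (default 0.1 Å, small enough that
the ±3 kcal/mol margin of helical hydrogen bonds is never crossed).
At zero jitter, `assign_helix` recovers the latent labels exactly —
this is tested frame by frame.

The equilibrium of the constrained measure is computed exactly by a
forward–backward recursion over (state, run-length) — verified against
exhaustive $2^n$ enumeration in the tests — and the propagation weight
$s$ is calibrated by bisection so the equilibrium helicity *over the
measured interior* (two residues excluded per end, matching the
analysis default) equals the target.  Defaults mirror the analysis
conventions: 3 replicates, 10 ps frame spacing, a 20-residue
EAK-style helical model peptide, nucleation weight σ = 0.01 (helix
nucleation is rare relative to propagation, giving realistic
contiguous fraying rather than salt-and-pepper states), 5 Metropolis
sweeps between frames and 200 burn-in sweeps (relaxation from the
all-helix start is complete well within the burn-in at these sizes).

What passing these tests shows — and does not show.  Recovery of a
0.70 or 0.86 target within ±0.05 demonstrates that the assignment and
averaging operators are unbiased on ensembles whose marginal statistics
(two-state fraying with cooperative runs) resemble real helical
peptides.  It does not validate force-field physics, kinetics, or
non-helical secondary structure, and real MD ensembles add correlated
backbone distortions that the jitter model does not emulate.

**HDX curves** follow first-order exchange $u(t) = 1 -
e^{-k_{int}t/PF}$ per amide, averaged over each peptide's exchangeable
amides, with the bound state multiplying epitope protection factors by
a fold change (default 10×).  Defaults: 60-residue construct, 10-mer
peptides with 5-residue stride, epitope at residues 26–45 (aligned
with the tiling so every peptide either carries at least two protected
amides or none — a peptide overlapping a planted epitope by a single
amide is diluted below any sensible calling threshold and would make
"truth" ill-defined), $k_{int} = 1\,s^{-1}$, apo protection factor 50,
timepoints 30 s to 8.3 h, uptake noise sd 0.01.

# Problem sizes and determinism

All stochastic stages consume explicit integer seeds; replicates use
`seed + replicate - 1`, and the pipeline report embeds a hash of its
full content, so end-to-end determinism is a testable property rather
than a hope.  The shipped analyses run at desk scale: helicity
recovery uses 3 replicates × 700 frames per target (the ±0.05 recovery
band is already reached at a tenth of that), the equilibrium
cross-check uses a 16-residue chain where the transfer matrix is exact,
and the demonstration pipeline uses 3 × 400 frames.  Statistics from
sub-microsecond trajectories of real systems are outside what the
synthetic conditions can or should reproduce; the headline helical
fractions from such trajectories are exercisable through the same
functions when real multi-MODEL PDB trajectories are supplied.

# Known limitations

* The initial-model builder is a rigid placer with schematic linkers;
  it makes no claim of physical realism and no attempt at loop closure.
* The energy decomposition uses a schematic parameter table, vacuum
  dielectric and hard truncation; only band patterns and rankings, not
  absolute energies, are meaningful.
* Helix assignment is strict alpha (H/C); 3₁₀ and π helices are folded
  into C.
* The HDX module starts from peptide-level uptake tables; spectral
  processing and peptide identification are upstream of its scope.
* Single-character chain identifiers only (PDB fixed-width columns).
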