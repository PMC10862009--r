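# helixgraft

Design and *in silico* evaluation of scaffold-grafted helical antigens.

A short helical epitope cut out of a membrane protein usually unfolds
when it is displayed on a small scaffold: the residues that packed
against it in the parent protein are gone.  `helixgraft` implements the
computational side of that design problem as a reusable, tested R
pipeline:

* **Graft construction** — excise a scaffold loop, size flexible
  G4S-style linkers from the anchor geometry, assemble the chimera
  sequence with a complete index map (chimera position → scaffold /
  linker / donor origin), and build a crude clash-checked rigid-placement
  initial model.
* **Helical conformation** — per-frame, per-residue alpha-helix
  assignment from Kabsch–Sander backbone hydrogen-bond energies
  (`E = q1·q2·f (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`, bond if
  `E < −0.5` kcal/mol, helix from consecutive i→i+4 turns), summarized
  as the helical fraction of a segment over replicate trajectories with
  a 2-residue terminal exclusion.
* **Conformational drift** — optimal least-squares (Kabsch/SVD)
  superposition with proper-rotation correction and segment C-alpha
  RMSD time series with replicate statistics.
* **Stabilizing interactions** — residue-pair nonbonded energy matrices
  (Coulomb `332.0636·q_a·q_b/r` plus Lennard-Jones
  `ε[(r_min/r)¹² − 2(r_min/r)⁶]`, 12 Å cutoff), band classification
  (covalent-adjacent diagonal, i→i+4 hydrogen-bond band, hydrophobic
  core), hydrophobic contact maps, and ranking of inter-helix
  contributors — plus triple-alanine truncation mutants to probe them.
* **Epitope mapping** — differential hydrogen–deuterium-exchange (HDX)
  uptake analysis: per-peptide bound-minus-apo uptake curves, protected
  peptide calls, and annotation of calls against the graft index map.
* **Synthetic ground truth** — seed-deterministic generators for ideal
  helices, a toy two-helix scaffold with an excisable VVAG loop, a
  planted-anchor helix bundle, Zimm–Bragg helix–coil fraying
  trajectories with exact latent-state ground truth and a
  transfer-matrix equilibrium, and HDX uptake tables with planted
  protection — so every stage of the pipeline is testable without any
  external structure files.

All structures move through plain multi-MODEL PDB files and data
frames; no binary formats are required.

## Worked example

The built-in demonstration grafts a 20-residue helical donor peptide
into the toy scaffold's VVAG loop, simulates three replicate fraying
trajectories of the donor at a target helicity of 0.85, and analyses
helicity, RMSD and the inter-helix energetics of a planted-anchor
bundle:

```r
library(helixgraft)
cfg <- default_run_config(seed = 1)
cfg$simulate$n_frames <- 200
report <- run_design_evaluate(cfg)
print(report)
```

```
== helixgraft run report ==
Chimera: 66 aa (AEELIKAAEELIKAAEELGGGGSAEAAIKEAAAKIEAAEKAAAGGGGSIKAAEELIKAAEELIKAA)
Anchor gap 8.84 A; recommended linker 4 per side
Helicity: 0.838 (+/- 0.008), target 0.85, latent 0.837
Segment RMSD: 1.33 (+/- 0.08) A over 16 CA
Top inter-helix contributors:
  res_seq res_name helix cross_energy
1      18      PHE     A   -0.5299646
2       4      PHE     A   -0.3604544
3      11      PHE     A   -0.3550150
4      33      VAL     B   -0.3112976
5      47      VAL     B   -0.2990437
Report hash: b977bbd0a3c6197ac89db92fd76620af
```

Reading the output: the chimera is the scaffold with its 4-residue loop
replaced by `GGGGS + donor + GGGGS` (40 − 4 + 5 + 20 + 5 = 66 residues).
The anchor C-alpha gap of 8.84 Å against the donor's ~29 Å end-to-end
span yields a recommended linker of 4 residues per side.  The measured
helical fraction of the simulated replicates (0.838) matches both the
latent-state ground truth (0.837) and the configured target within the
Monte-Carlo error of 200-frame replicates; the segment RMSD is reported
over the 16 interior C-alpha atoms (20 minus two per terminus).  The
three planted phenylalanine anchors (residues 4, 11, 18) head the
cross-helix energy ranking, exactly as planted.  The report hash is
identical across repeat runs with the same seed.

A thin command-line wrapper around the same functions is installed at
`inst/cli/helixgraft.R`:

```sh
Rscript inst/cli/helixgraft.R simulate fray --seed 1 --out out/
Rscript inst/cli/helixgraft.R ss --pdb out/fray_rep1.pdb --segment A:1-20
```

## Documentation

The methods vignette (`vignettes/helixgraft-methods.Rmd`) describes the
models, the numerical conventions, what the synthetic generators do and
do not emulate, and the design decisions behind the defaults.
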