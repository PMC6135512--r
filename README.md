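# dimerdyn

Trajectory analysis of cofactor-bound protein homodimers in R.

`dimerdyn` implements the post-processing pipeline used to study how
interface point substitutions destabilize pyridoxal 5'-phosphate (PLP)
binding in dimeric aspartate aminotransferase (human GOT1): a homodimer of
two 413-residue chains with one PLP in each of its two interface active
sites. Given topologies and trajectories for a reference system and a set
of variants, it computes:

- **Geometry** — Kabsch superposition; cofactor RMSD series and
  distributions; per-residue RMSF with monomer averaging; ring-stacking
  separation/angle (e.g. the tryptophan indole against the PLP pyrimidine
  ring); catalytic pocket distances; "door"-loop opening detection from
  bound/unbound RMSF gains.
- **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 3.5 Å,
  D–H–A ≥ 135° by default, heavy-atom-only fallback), exact per-bond
  occupancies, and variant-vs-reference network comparison with key-bond
  (occupancy = 1) flagging.
- **Essential dynamics** — pooled PCA of the Cartesian covariance over
  the inner Cα atoms of both chains plus the cofactor C6 carbons
  (N = 730 centers for the full-size dimer; 3N × 3N covariance), and the
  scalar PC1 displacement per frame with the reference mean set to zero —
  the dimer-interface misalignment statistic. Displacement–energy
  ellipse summaries (mean ± SD on both axes) are emitted per system.
- **Energetics** — implicit-solvent MM-GB/SA (OBC2 generalized Born,
  α = 1.0, β = 0.8, γ = 4.85, offset 0.09 Å; LCPO surface area; no
  nonbonded cutoff) decomposed as

  ```
  EM = EM1 + EM2                        monomer energies
  EE = E(dimer) − EM1 − EM2             dimerization energy
  EL = Σ_s E(dimer+lig_s) − E(dimer) − E(lig_s)   cofactor binding
  ET = EM + EE + EL                     total (exact identity, per frame)
  ```

  with per-residue decompositions of EE and EL that sum to the totals
  exactly, optionally reported relative to the reference system.

Because the microsecond MD data behind the published analysis are not
deposited, the package includes a first-class synthetic-trajectory
generator (`build_toy_dimer()`, `generate_trajectory()`) that plants a
known interface counter-rotation mode, a loop-opening event, two-state
Markov hydrogen bonds and calibrated cofactor mobility, so every stage is
validated against exact ground truth.

## Worked example

```r
library(dimerdyn)

cfg <- make_demo("demo_ws", seed = 1)   # writes toy PDB/TSV/XYZ + config
run_demo_config(cfg)                    # full pipeline, ~5 min on 1 CPU

read.csv("demo_ws/out/displacement_summary.csv")
#>   system          mean        sd
#>       WT  0.000000e+00 0.7026897
#>    E266K -1.095231e+00 0.7353727
#>    R267H  2.385348e+00 0.7958471
#>    P300L -1.107145e+00 0.7886253

read.csv("demo_ws/out/plp_rmsd_summary.csv")
#>   system      mean        sd
#>       WT 0.9915749 0.5370722
#>    E266K 1.1132280 0.6709957
#>    R267H 1.5293880 0.9723432
#>    P300L 1.4131143 0.9015060
```

The displacement summary shows the planted interface-misalignment
pattern recovered by the pooled PCA: the reference is zeroed, one variant
(R267H) is displaced positively along PC1 and the other two negatively.
The cofactor RMSD means reproduce the published ordering (wild type most
stable, R267H/P300L most mobile). Other outputs in `demo_ws/out/` include
per-system occupancy tables and the network comparison (the planted
always-formed bonds appear at occupancy 1.0 and the variants' weakened
phosphate bonds at ~0.6), the loop-opening verdict
(`loop_opening.json`, detected at the 10 Å RMSF-gain threshold), the
EM/EE/EL/ET table, per-residue EE/EL profiles relative to the reference,
and a manifest with input/output MD5 hashes. Rerunning the same config
reproduces every output byte for byte.

A thin CLI with `validate` / `demo` / `run` / `report` verbs is installed
at `inst/cli/dimerdyn.R`.

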