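---
title: "Methods: trajectory analysis of a cofactor-bound homodimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of a cofactor-bound homodimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model system

`dimerdyn` analyses molecular-dynamics trajectories of two-fold symmetric
enzymes that bind a cofactor at the dimer interface. The motivating system
is human cytosolic aspartate aminotransferase (hGOT1), a homodimer of two
413-residue chains with one pyridoxal 5'-phosphate (PLP) molecule in each
of the two interface active sites. Disease-linked point substitutions at
the interface (E266K, R267H, P300L) are compared against the wild type
through four families of observables:

1. **Geometry** — Kabsch superposition, cofactor RMSD distributions,
   per-residue RMSF (monomers averaged), ring-stacking distance/angle of
   the tryptophan indole against the cofactor pyrimidine ring, catalytic
   pocket distances, and the opening of the small-domain "door" loop
   (positions 15-32 in hGOT1 numbering).
2. **Hydrogen bonds** — geometric detection, exact per-bond occupancy over
   the trajectory, and network comparison of variants against the
   reference system.
3. **Essential dynamics** — pooled PCA over all systems of the Cartesian
   covariance of the inner Calpha atoms (residues 40-403 of both chains)
   plus the cofactor C6 carbons (N = 730 centers for the full-size dimer),
   and the scalar PC1 displacement with the reference system's mean set to
   zero. PC1 is the dimer-interface misalignment coordinate.
4. **Energetics** — implicit-solvent MM-GB/SA post-processing: monomer
   energies (EM = EM1 + EM2), dimerization energy
   (EE = E(dimer) - EM1 - EM2), per-site cofactor binding energy
   (EL_s = E(dimer + ligand_s) - E(dimer) - E(ligand_s), summed over both
   sites), and the total ET = EM + EE + EL, which holds per frame to
   machine rounding by construction. A per-residue decomposition assigns
   EE and EL exactly to residues.

Raw microsecond trajectories for this system are not publicly deposited,
so the package ships a synthetic-trajectory generator that plants known
structure; every analysis stage is validated against that ground truth.

# Frame schedule

Production runs are 1000 ns sampled at 1 frame/ns; all windowed analyses
(energies, occupancies, PCA pooling, displacement series) default to the
last 800 ns at 1 frame/ns, giving 800 frames per system and 3200 pooled
PCA frames for four systems. `schedule_frames()` implements the window.

# Geometry

* **Superposition** uses the SVD form of the Kabsch algorithm with the
  determinant sign correction, so the returned rotation is always proper.
  Degenerate (collinear) fit sets are rejected.
* **Cofactor RMSD** (protocol choice; the original analysis does not state
  one): each frame is fitted on the large-domain-core Calpha atoms of both
  monomers (config `core_resno`, scaled hGOT1 80-300), then the
  heavy-atom RMSD of each cofactor against its reference pose is measured
  without re-fitting. The two sites are reported separately; summary
  statistics use their concatenation. "Distribution width" is reported as
  the SD of the RMSD series, the only moment-level reading consistent with
  a mean being quoted alongside; histograms use 0.05 A bins, fine enough
  to resolve ~0.2 A widths.
* **RMSF** superposes all frames on their iteratively refined mean
  structure (fit -> mean -> fit until the mean moves < 1e-6 A, at most 100
  rounds), then averages per-atom RMSF within residues and, on request,
  across the two monomers. Calpha-only fitting over the whole chain is the
  package's choice; the original figure does not state its fit set.
* **Ring stacking** fits a least-squares plane to each ring; the angle is
  `acos(|n_A . n_B|)` (0-90 degrees) and the separation is the centroid
  offset projected on the sign-aligned mean normal.
* **Loop opening** is called on paired bound/unbound RMSF profiles: the
  verdict requires every loop residue to gain at least the threshold
  (default 10 A, the published RMSF gain) of RMSF.

# Hydrogen bonds

The original work does not state its geometric criteria; the package
defaults to the most common MD convention, donor-acceptor <= 3.5 A with a
D-H-A angle >= 135 degrees, both configurable. Topologies without
hydrogens (such as the toy model) use the distance criterion alone; in
that mode mirrored donor/acceptor orientations are collapsed to one bond
per heavy-atom pair. A bond's identity is its heavy-atom pair, so
occupancy is at most 1 regardless of how many hydrogens a donor carries,
and occupancies are exact ratios of formed-frame counts. The
cofactor-coupled network of the published figures is reproduced by the
`"ligand"` candidate restriction (exactly one partner in a cofactor
site). Network comparison aligns bonds by (chain, residue number, atom
name) so bonds at substituted residues still match; bonds whose atoms
exist in no other system are listed as unmatched rather than dropped.

# Essential dynamics

Frames of all non-auxiliary systems are pooled on the schedule, restricted
to the selection, and superposed on the iteratively refined pooled mean —
superposition before covariance is necessary for a meaningful Cartesian
covariance even where a protocol does not spell it out, and the model
records it in its provenance. The 3N x 3N covariance (1/(n-1)
normalization, no mass weighting — the selection counts plain Calpha atoms
and the C6 carbon equally) is eigendecomposed; eigenvalues are reported in
A^2. Because an eigenvector's sign is arbitrary, each component is
oriented so its largest-|loading| coordinate is positive, making the
"positive displacement" direction reproducible across runs. Projection
superposes each frame on the model mean over the selection and takes the
inner product of the centered 3N coordinate vector with the component;
displacement series are zeroed by subtracting the reference system's mean
from every system. Displacement-energy summaries are axis-aligned
ellipses: componentwise mean and SD, no covariance tilt.

# Energetics

All terms are evaluated without cutoff or periodicity.

* **Coulomb** uses 332.0637 kcal A / (mol e^2); 1-2 and 1-3 pairs are
  excluded and 1-4 pairs scaled by 1/1.2 (Coulomb) and 1/2.0 (LJ), the
  AMBER convention, configurable in `energy_constants()`.
* **Generalized Born** follows the OBC2 recipe (`igb = 5` defaults):
  HCT pairwise descreening integrals summed into Psi, tanh rescaling with
  alpha = 1.0, beta = 0.8, gamma = 4.85, dielectric offset 0.09 A,
  element-based screening factors, interior/exterior dielectrics 1 and
  78.5. The energy includes self terms and all pairs (no exclusions),
  with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / 4 R_i R_j))`. An isolated
  ion reproduces the Born formula exactly; at large separation the energy
  approaches the sum of Born self terms plus the screened point-charge
  interaction `-k (1/eps_in - 1/eps_out) q_i q_j / r` — note that this
  pair term decays only as 1/r and is part of the correct closed form.
* **Nonpolar solvation** is LCPO surface area (`gbsa = 1` defaults) with a
  1.4 A probe and surface tension 0.005 kcal/(mol A^2), atom radii taken
  as the LJ rmin/2 values.
* **Decomposition** uses the single-trajectory approximation standard in
  MM-GB/SA practice: monomer and ligand conformations are extracted from
  complex frames. Born radii and surface areas are recomputed in every
  evaluation context (dimer, monomer alone, ligand alone), so EE and EL
  contain the GB desolvation cross terms — this is what "interaction
  energy" means under GB post-processing. EM includes each monomer's own
  solvation self-energy. Entropy terms are not computed. Summary errors
  are reported both as per-frame SDs and 5-block block-averaged standard
  errors, since published tables rarely say which convention their
  uncertainties follow.
* **Per-residue decomposition** is exact rather than approximate: cross
  Coulomb/LJ and GB pair terms are split half-and-half between the two
  residues, GB self/intra-pair desolvation (complex-context minus
  separated-context radii) and per-atom surface-area changes are assigned
  to their own residue. The per-residue contributions therefore sum to
  the total EE (or EL) for every frame to 1e-6 kcal/mol, a property the
  test suite asserts. Variant profiles can be reported relative to the
  reference system's profile.

# The synthetic-data generator

`build_toy_dimer()` constructs a mirror-symmetric pair of chains
(Calpha + one sidechain dummy per residue) at x = +/- 7 A along a common
axis, a 12-atom PLP-like ligand per interface site (six-membered coplanar
ring containing C6 and N1, hydroxyl, bridge carbon, phosphate-like tail;
net charge -2 e — the protonation state of the real cofactor's phosphate
is not documented, so the toy makes it explicit), three serine-like donor
residues per monomer whose OG atoms sit 2.9 A from ligand-1 acceptors,
and a tryptophan-like ring stacked 3.8 A from the ligand-2 ring plane.
All toy parameters (charges, LJ, GB radii, LCPO coefficients) are
assigned per element from standard-magnitude values; bond parameters are
harmonic with the reference geometry as equilibrium.

`generate_trajectory()` plants, in order:

* an **interface mode**: a tapered counter-rotation of the two core
  domains (scaled residues 80-300) about the interface axis, stored as a
  unit 3N vector. Monomer B's field is scaled by 0.85 and the rotation
  angle tapered along the chain so the mode has a unique largest
  coordinate; this pins the package's PC sign convention to the planted
  direction, making the recovered sign pattern stable. Per-frame
  amplitudes are `N(mean[label], sd)` with defaults WT = 0,
  E266K = P300L = -2 A, R267H = +4 A (sd 1 A), mirroring the published
  positive-R267H / negative-E266K,P300L displacement pattern with the
  wild type at zero. The rigid-body-projected restriction of the mode to
  the PCA selection, and the fraction `eta` of amplitude visible to it,
  are stored so recovery can be scored exactly.
* a **door-loop opening**: the loop parameter is the target RMSF gain; a
  displacement of twice that value is applied to the loop after the onset
  frame (default half-way), so the two-state time split yields an RMSF
  equal to the target exactly. The default planted gain of 12 A clears
  the 10 A detection threshold.
* **cofactor mobility**: a per-frame rigid slide of each ligand along the
  pocket axis, `N(0, amp[label]^2)`. The axial direction is chosen
  because it is clash-free by construction for any amplitude (an
  isotropic displacement can drive the ligand into its stacking partner).
  Default amplitudes (1.05, 1.24, 1.71, 1.60 A) were calibrated once,
  from the closed form `E sqrt(z^2 + 3 sigma^2)`, so the mean fitted
  cofactor RMSD reproduces the published per-system averages (0.99,
  1.13, 1.48, 1.40 A) under the default jitter.
* **hydrogen-bond dynamics**: each planted donor follows a two-state
  Markov chain (formed 2.9 A / broken 5.5 A along the interface normal)
  with per-frame rates k_on, k_off, stationary occupancy
  k_on/(k_on+k_off). Donor atoms are posed relative to their acceptor's
  current (displaced, jittered) position and carry no independent jitter:
  this keeps the planted occupancy an exact chain statistic instead of
  being blurred by jitter-induced cutoff crossings.
* **thermal jitter**: iid Gaussian noise (default sigma = 0.25 A per
  coordinate) on all other atoms, applied after the deterministic modes
  (linear modes + additive noise, the model PCA assumes).

All randomness derives from one integer seed combined with the system
label; identical spec + seed + label is bitwise reproducible.

**What the toy does not emulate:** a real fold (the chains are extended,
not globular), physically balanced force-field parameters, correlated
backbone dynamics beyond the single planted mode, water, or binding
energetics on the published scale (the published EM/EE/EL/ET magnitudes
reflect a solvated 825-residue complex and cannot be reproduced by a toy;
the package instead verifies the accounting identity on the published
table itself and all structural identities on the toy). Passing tests
therefore demonstrate correctness of the computational machinery and
recoverability of planted signals, not force-field realism.

# The demonstration workspace

`make_demo()` writes a complete workspace: toy topologies (PDB), parameter
sidecars (TSV, which also carry the bond graph), four 1000-frame synthetic
systems (WT reference and the three variants with planted negative /
positive / negative displacements, weakened phosphate hydrogen bonds with
stationary occupancy 0.6, and raised cofactor mobility) plus one auxiliary
substrate-free system with the loop opening planted, and a `config.yaml`.
The demo uses 24 residues per monomer — large enough for every selection
(door loop, donors, core, stacking residue) to exist at scaled positions,
small enough that the full pipeline (including ~800-frame MM-GB/SA
decompositions of five energy contexts per frame for four systems) runs
in about five minutes on one CPU. `run_pipeline()` is deterministic given
the same inputs: rerunning reproduces every CSV/JSON byte for byte, and
the manifest records input and output MD5 hashes.

# Numerical choices and edge cases

* Mean-structure refinement tolerance 1e-6 A (1e-8 for PCA pooling, where
  projection-variance identities are asserted at 1e-6 relative); at most
  100 iterations.
* Eigenvector sign: largest-|loading| coordinate positive; ties broken by
  the first index (the planted mode is constructed to avoid ties).
* Overlapping atoms (r < 1e-6 A) are an error in the nonbonded kernels,
  not a silent Inf.
* Alternate locations and insertion codes in PDB input are rejected;
  silent handling would hide fixture bugs.
* Residue intervals are closed and use author (1-based PDB) numbering
  throughout: "residues 40 to 403" includes both ends, which is what
  makes the hGOT1 selection count 2 x 364 + 2 = 730.
* Degenerate inputs (collinear fit sets, rings with < 3 atoms, empty
  measure sets, schedules outside the trajectory) raise errors naming the
  offending input.

# Known limitations

* Pure-R energy kernels: O(n^2) per frame per context; practical up to a
  few thousand atoms per context at hundreds of frames.
* The heavy-atom hydrogen-bond mode cannot apply the angle criterion;
  explicit-hydrogen topologies are supported but the toy does not build
  them.
* LCPO per-atom areas are not clamped at zero; for the sparse toy
  geometries used here negative areas do not occur.
* No entropy estimates, no Poisson-Boltzmann cross-check, no explicit
  solvent.
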