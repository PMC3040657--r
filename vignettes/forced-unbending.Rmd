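---
title: "Forced unbending of a bent multidomain molecule: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forced unbending: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pullMD` studies force-induced unbending of a bent, two-chain multidomain
adhesion receptor — the integrin-ectodomain class of molecule, whose bent
resting conformation is held by a headpiece/tailpiece interface and whose
activation involves extension at two "knee" hinges. The package provides

* a coarse-grained (pseudo-atomic) builder for a bent two-chain molecule
  with that architecture, plus an overdamped Langevin engine implementing
  the three pulling protocols of steered-MD studies: free dynamics,
  constant-velocity pulling with a moving virtual spring
  (`F = k (v t - x)` on the pulled centre of mass), and constant-force
  pulling;
* the trajectory analyses such studies rely on: Shrake–Rupley solvent
  accessible surface area and the buried-area interface metric, geometric
  hydrogen-bond detection, Hingefind-style inter-domain hinge angles with
  linear cooperativity fits, extension / COM-distance / RMSD series, and
  force-peak detection;
* two-state escape kinetics: waiting-time extraction from distance traces,
  exponential escape simulation, and Bell-model fitting
  `t = t0 exp(-F dx / kB T)`.

All-atom force fields, solvent, electrostatics and the thermostat/barostat
machinery of atomistic MD are out of scope: the coarse model is a synthetic
stand-in whose role is to exercise the protocols and analyses at desk
scale, with its own force and time units.

# Units

Lengths are in Å, forces in pN, times in ns, energies in pN·Å.
Conversions: 1 kcal·mol⁻¹·Å⁻¹ = 69.479 pN, and kB·T = 41.4195 pN·Å at
300 K (kB = 0.0138065 pN·nm/K). Protocol spring constants may be given in
kcal·mol⁻¹·Å⁻² (the unit the SMD literature quotes); the default
constraint tether is 10 kcal·mol⁻¹·Å⁻² = 694.79 pN/Å.

# The coarse-grained model

`buildBentModel()` places twelve 12-bead domains (144 beads): chain A (the
α-subunit analog) carries the β-propeller, thigh, calf-1 and calf-2;
chain B (the β-subunit analog) carries βA, hybrid, PSI, EGF1–EGF4 and βTD.
Each bead is one residue; residue numbers are spread through the shipped
`defaultDomainMap()` ranges (β-propeller 1–438, thigh 439–600, …,
βTD 606–690), so the same selection machinery works on the synthetic model
and on user-supplied structures.

The bent geometry is built from a few deliberate mechanical elements:

* **An elongated hybrid rod.** The hybrid domain spans ~30 Å below the βA
  head. Its lower face carries four donor/hydrogen bead pairs facing four
  βTD acceptor beads (the polar interface, rest length 3 Å) and two
  hydrophobic beads facing an EGF4 pair (the nonpolar cluster, rest length
  4 Å). Both interfaces are *breakable contacts*: truncated harmonic wells
  that exert force only inside a break radius and re-engage whenever the
  pair re-enters it. Their rupture produces the dominant force peak, and
  their well depths (75–110 pN·Å each, ~2–3 kB·T) set the thermally
  activated escape times under constant force.
* **One rigid upper body.** The head dimer (βA + β-propeller) and both
  upper legs (thigh; hybrid–PSI–EGF1) are tied into a single rigid-ish
  body by weak all-pair springs, reflecting the packing of the headpiece
  and upper legs in the bent molecule. This leaves the two knees as the
  only soft articulations, which is what makes their opening concurrent.
* **Pin-bead knee axles.** Each knee (thigh/calf-1 and EGF1/EGF2) is a
  physical hinge: two coincident bead pairs, shared between the flanking
  domains and tied by zero-length bonds, sitting on an axle perpendicular
  to the leg plane. Bending about the axle is free; all other relative
  motion (torsion, shear) is suppressed. Without such axles the rod-shaped
  bodies spin freely about their long axes and Kabsch-based hinge angles
  read torsion instead of bending.
* **Parallel legs with matched contours.** The α leg runs beside the β leg
  at a 5 Å lateral offset, its knee on the same axle direction at the same
  height, its lower arm along the same return direction. Inter-leg packing
  springs (calf-1↔EGF3, calf-2↔EGF4) then stay at rest length under
  concurrent knee opening but resist differential opening — the mechanical
  origin of knee cooperativity, mirroring the leg–leg association of the
  real molecule.
* **Two-tier knee wells with bent equilibria.** Each knee carries a stiff
  narrow well (1500 pN·Å/rad² within 10°) that keeps thermal bending
  wobble near ±10°, plus a soft wide well (300 pN·Å/rad², truncated at
  70°/60° for the α/β knee) that pulls partially opened knees back toward
  the bent state. Beyond the truncation the knee is torque-free, so a
  fully opened knee feels no restoring drive.
* **Extension-stabilizing locks.** A bead on each upper arm and one on the
  corresponding lower arm are placed — by rotating about the knee axle — so
  that they meet only once the knee has opened by a set angle (95°/100°).
  On the α side this pair is the thigh-aspartate / α-genu-ion analog
  (metric `genu_ion_D457`): ~12 Å apart when bent, it collapses to ~3 Å
  upon extension and the resulting contact stabilizes the extended state,
  the same role the newly formed metal coordination plays in the molecule
  this model emulates.

Bistability therefore emerges from the combination: the bent state is held
by the interface contacts and the knee wells; the extended state is held
by torque-free knees plus the locks; partially extended states relax back.

## What the generator emulates, and what it does not

The synthetic system reproduces the *shapes* of the phenomena: a dominant
rupture force peak coinciding with the collapse of the hybrid/βTD +
hybrid/EGF4 buried areas; hydrogen-bond counts dropping from several to
zero across the peak; concurrent, linearly coupled knee opening before the
molecule is over-stretched; constant-force waiting times that shorten
roughly exponentially with force; rebending of partially extended
structures with re-formation of the hydrophobic cluster; and metastability
of fully extended structures. It does **not** reproduce absolute scales:
the molecule is geometrically smaller (bent head-tail distance 45 Å
against ~16 nm of full extension in the real system), its force grid
(97–195 pN) is adopted as a label for comparability rather than derived
from a molecular force field, and its nanosecond axis is set by the chosen
friction, not by water viscosity. Passing tests on this system validate
the protocols and analysis pipeline, not quantitative statements about any
real receptor.

# Dynamics

The engine integrates overdamped Langevin (Euler–Maruyama) dynamics,
`dx = (F/γ) dt + sqrt(2 kB T dt / γ) ξ`, per bead, in compiled code using
R's RNG so that a seed replays bit-identically. Defaults: γ = 0.5
pN·ns/Å (chosen so that post-rupture unfolding relaxes on the nanosecond
scale; at much higher friction the rotational drag of the upper body, with
lever arms of tens of Å, makes unbending drift-limited rather than
barrier-limited), dt = 2.5×10⁻⁴ ns, T = 300 K, one frame saved every
0.1 ns. Two guards protect the integration: at start, dt must satisfy the
overdamped Euler bound `dt < 2γ/k_max` with `k_max` the largest per-bead
sum of incident spring constants; at run time any per-step displacement
above 5 Å aborts with a diagnostic. Hinge forces floor the sine of the
bending angle at 0.05 and the torsional dihedral restraints saturate at
1 rad deviation — both keep near-degenerate geometries from producing
force spikes. Dihedral gradients are validated against numerical
differentiation in the test suite.

The pulling force acts on the pull-group COM, distributed equally over the
pulled beads (uniform weighting throughout: coarse beads carry no
meaningful masses). The pulling direction is fixed at t = 0 as the unit
vector from the constraint COM to the pull COM — the direction force
adopts after the initial rigid-body rotation in pulling simulations — with
a tracking mode available for comparison.

# Analysis conventions

* **SASA.** Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points, probe 1.4 Å), so all areas are bit-stable. Radii
  come from a fixed table (C 1.70, N 1.55, O 1.52, S 1.80, pseudo-bead
  1.8 Å); published analyses rarely state their radius set, so absolute
  areas are compared only on the package's own scale. Buried area of A
  against B is SASA(A alone) − SASA(A with B); a per-domain restriction
  sums only that domain's atoms and works from either side of the split.
* **Hydrogen bonds.** Donor–acceptor < 3.5 Å and donor–hydrogen–acceptor
  angle > 120°, both strict, union of the two donor→acceptor directions;
  bifurcated geometries count once per (donor, acceptor) pair.
* **Hinge angles.** Relative-rotation formulation: superpose the frame on
  the reference by domain A, then the rotation angle of the Kabsch fit of
  domain B, `acos((tr R − 1)/2)`, reported as change from the reference
  (an additive offset turns the series into absolute angles when the
  starting geometry is known); the rotation axis is also returned. Per
  frame alignment is used for RMSD series as well (the standard Cα-RMSD
  convention).
* **Cooperativity.** Ordinary least squares of one hinge-angle series on
  the other. Because the hinge bodies wobble thermally (~±10°) around the
  driven opening, the series may be time-averaged (centred moving average,
  `smoothFrames`; 1.5–3 ns is appropriate at the default frame spacing)
  before fitting. The shipped pre-straightening window keeps frames before
  the x hinge reaches 95% of its plateau; the acceptance analysis delimits
  the window on the extension coordinate (5 Å above baseline up to 85% of
  the final extension), which is more robust run-to-run.
* **Waiting times.** Baseline = mean over an initial window (default 1 ns
  for constant-force runs started from the bent state); the waiting time
  is the first time the extension exceeds baseline + δ (default 20 Å,
  roughly a third of the bent-to-extended change, so onset is called
  during the rapid transition) and stays above for ≥ 1 ns. The published
  traces mark onsets by eye; this rule is the package's explicit stand-in.
* **Bell fits.** OLS of ln t on F: `dx = −slope·kB·T`,
  `t0 = exp(intercept)`, standard errors from the regression covariance
  (delta method for t0). Recovery experiments fit ln(mean waiting time)
  per force: the mean of n exponential samples estimates τ(F) without
  bias, whereas a single drawn ln t underestimates ln τ by the
  Euler–Mascheroni constant (≈0.577) and would bias t0 low by ~44% — a
  dedicated test demonstrates both facts.
* **Force peaks.** Centred moving average in the extension domain
  (default 2 Å), local maxima ranked by topographic prominence; the major
  peak is rank 1.

# Problem sizes

The shipped experiment suite runs at desk scale: 60 ns constant-velocity
pulls at 1 Å/ns with a 0.5 kcal·mol⁻¹·Å⁻² spring; five constant forces
(97, 122, 146, 170, 195) with five seeds each, 60 ns per run; six free
25-ns restarts from a partially extended and six from a fully extended
snapshot; and 200 replicate Bell-recovery fits of 100 samples per force.
The full behavioural suite completes in a few minutes on one CPU.

# Known limitations

* No excluded volume: beads of different domains can interpenetrate.
  Interfaces are shaped by explicit contacts, not packing.
* The knee axles and the rigid upper body remove degrees of freedom a real
  molecule has; they are what makes hinge-angle analysis clean at this
  resolution, and the trade-off is that leg splaying and head rocking are
  not explored.
* Waiting-time distributions of the coarse system are narrower than
  exponential (the escape path has a deterministic unfolding component),
  so the ln-linear force dependence holds for medians while the scatter
  between seeds is smaller than a true two-state system would show. The
  statistical escape generator (`simulateEscape`) is exactly exponential
  and is the component used for parameter-recovery experiments.
* Real PDB input gets a minimal chemical heuristic (N donors, O acceptors,
  H attached to the nearest donor within 1.2 Å, fixed radii); sidecar
  annotation tables override it and are the supported route for
  non-standard systems.

# Reproducibility

Every stochastic stage takes an explicit integer seed; the engine consumes
R's RNG stream so `set.seed`-style replay is exact. `cmdSimulate()` writes
a log with the seed and a hash of the configuration next to each run; the
determinism test re-derives a run bit-identically from config + seed.
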