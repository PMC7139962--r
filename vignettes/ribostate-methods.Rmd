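---
title: "Methods: implicit-solvent binding energetics and state analysis of riboswitch aptamers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: implicit-solvent binding energetics and state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostate)
```

`ribostate` analyses snapshot ensembles of RNA aptamer–ligand complexes:
an end-point MM-GB/SA free energy engine with per-nucleotide decomposition
and normal-mode entropy, trajectory geometry, and open/middle/closed
conformational-state statistics. This vignette is the package's account of
the underlying models, the defaults and why they were chosen, what the
synthetic generators do and do not emulate, and the numerical decisions a
maintainer would want written down.

## The free energy model

For a complex snapshot the binding free energy is decomposed as

$$\Delta G_{bind} = \Delta H_{gas} + \Delta G_{solv} - T\Delta S,\qquad
\Delta H_{gas} = \Delta E_{int} + \Delta E_{vdW} + \Delta E_{ele},\qquad
\Delta G_{solv} = \Delta G_{pol} + \Delta G_{nonpol}.$$

Each $\Delta$ term is complex − receptor − ligand. Under the default
**single-trajectory convention** the species coordinates are taken from the
same complex frame, so every intramolecular term cancels exactly:
$\Delta E_{int} = 0$ by construction and $\Delta E_{ele}$, $\Delta E_{vdW}$
reduce to inter-group pair sums, which is how they are computed (the
equality with the explicit difference route is asserted in the tests). An
optional **three-trajectory mode** accepts species-own geometries and then
evaluates every term, including the bonded internal energy, as a genuine
difference. Published component tables for this system report
$\Delta E_{int}\approx 1.4$ kcal/mol, which cannot arise from a pure
single-trajectory protocol; since the reference state used there is not
documented, both modes are provided and neither is claimed to be the
original authors' choice.

No nonbonded cutoff is used anywhere: the inputs are post-processed solute
snapshots of at most a few thousand atoms, where exact sums are cheaper
than cutoff artifacts.

### Polar solvation: one GB model for everything

The polar term is a generalized Born model with OBC-II effective radii:
pairwise HCT descreening integrals $I_i$, $\Psi = I_i\tilde\rho_i$,
$R_i^{-1} = \tilde\rho_i^{-1} - \tanh(\alpha\Psi - \beta\Psi^2 +
\gamma\Psi^3)/\rho_i$ with $\alpha=1$, $\beta=0.8$, $\gamma=4.85$ and a
dielectric offset of 0.09 Å ($\tilde\rho_i = \rho_i - 0.09$), then

$$G_{pol} = -\frac{k}{2}\Big(\frac{1}{\varepsilon_{in}} -
\frac{1}{\varepsilon_{out}}\Big)\sum_{ij}\frac{q_iq_j}{f_{GB}},\qquad
f_{GB} = \sqrt{r^2 + R_iR_j e^{-r^2/4R_iR_j}},$$

self terms included, $\varepsilon_{in}=1$, $\varepsilon_{out}=80$,
$k = 332.0637$ kcal·Å/(mol·e²). An isolated atom reduces exactly to the
Born ion formula, which the tests exploit as a closed-form oracle.

Studies of this system classically use a numerical Poisson–Boltzmann
solver for the totals and GB only for the per-residue decomposition. This
package deliberately uses the **same GB model for both**, so that residue
contributions sum to the whole-system totals exactly (machine precision
for the MM columns, 1e−6 for the solvation columns) and every number is
desk-checkable. A PB solver is out of scope; where the two models differ,
totals here are GB totals.

### Nonpolar solvation

$G_{nonpol} = \gamma\,\mathrm{SASA} + \beta$ with $\gamma = 0.00542$
kcal/(mol·Å²) and $\beta = 0.92$ kcal/mol, the conventional parameters of
this pipeline family. SASA is Shrake–Rupley sphere-point counting with a
deterministic Fibonacci-spiral point set (960 points per atom, probe 1.4 Å,
atomic radii from the Lennard-Jones `rmin/2` unless given explicitly). Two
consequences of the point-count estimator are worth recording:

* it is rotation-invariant only to quadrature resolution (a fraction of an
  Å², ~0.003 kcal/mol through $\gamma$), so invariance tests hold it to a
  looser band than the analytic terms;
* it is piecewise constant in the coordinates, so the nonpolar term
  carries **zero force and zero curvature almost everywhere**. It is
  therefore excluded from the default minimization/Hessian term set — with
  an a.e.-zero gradient it cannot move a stationary point or a normal
  mode, and its discontinuous energy jumps only mislead line searches.

### Per-residue decomposition

Pairwise terms (Coulomb, LJ, GB cross terms) are split half to each
partner's residue; GB self terms and per-atom SASA differences go to their
own residue; the constant $\beta$ enters the total exactly once and is
reported on a pseudo-residue row labelled `offset`. Column sums reproduce
the corresponding whole-system Δ values by construction, which the test
suite asserts on random bead complexes.

### Replica aggregation

Frames are averaged within each replica; the reported mean is the mean of
replica means and the standard error is $\sigma = \mathrm{sd}(\text{replica
means})/\sqrt N$ — the convention of the reference tables (N = 10 there).
Derived rows ($\Delta H$, $\Delta G_{ele+pol}$, $\Delta G_{vdW+nonpol}$,
$\Delta G_{bind}$) are formed per replica before aggregation so their
standard errors are internally consistent.

## Normal-mode entropy

$-T\Delta S$ uses harmonic vibrational entropies of minimized geometries:
L-BFGS minimization on analytic gradients (including the full Born-radius
chain rule of the GB term) to an RMS-gradient tolerance of 1e−6
kcal/(mol·Å) by default; Hessian by central finite differences of the
analytic gradient (step 1e−4 Å — differencing gradients, not energies,
for conditioning), symmetrized; mass-weighted eigenvalues converted to
wavenumbers. Modes with $|\nu| < 1$ cm⁻¹ are treated as rigid-body
(6 expected for a nonlinear species, 5 for a linear one — the diatomic
test pins this); eigenvalues below −(threshold)² count as imaginary, and
snapshots with imaginary modes in any species are dropped with a warning.
Entropy analyses default to every 10th analysis snapshot because
minimization dominates cost.

The entropy is **vibrational only**: gas-phase translational/rotational
terms and symmetry numbers are intentionally not included, since ligand
ranking rests on entropy *differences*. A consequence worth stating: on
weakly bound toy dimers the association converts six rigid-body freedoms
of the free species into soft complex vibrations, so the vibration-only
$T\Delta S$ can be *positive* there. The published negative $T\Delta S$
values for the real complexes include the lost translational/rotational
entropy; the package's per-snapshot log makes the accounting explicit
rather than hiding a compensating term.

## Trajectory geometry

* **Superposition** is Kabsch via SVD with the determinant sign
  correction; degenerate sets (fewer than three points or collinear, i.e.
  a vanishing second singular value) fall back to a translation-only fit
  and are flagged. The independent cross-check in the tests is
  `bio3d::fit.xyz`.
* **RMSF** superposes frames onto their mean structure (one refinement
  pass), not frame 1 — the standard fluctuation definition. The rigid-body
  fit absorbs a fraction $6/3N$ of the variance; recovery tests therefore
  use 60-atom scaffolds where that deflation (~1.7%) sits well inside the
  5% recovery band. Crystallographic B-factors convert via
  $\mathrm{RMSF} = \sqrt{3B/8\pi^2}$.
* **Hydrogen bonds**: a donor–hydrogen–acceptor triple satisfies a frame
  when donor–acceptor distance ≤ 3.5 Å and D–H–A angle ≥ 135°. These
  cutoffs are a common trajectory-analysis convention (the source tables
  for this system do not state theirs); both are config-overridable and
  echoed in output headers.
* **Distances** are Euclidean separations of group mass centers. The
  shipped defaults follow the reference construction: the pocket distance
  between the mass centers of U51+A52 and of C74+C75, and the junction
  distance D1; the exact atom sets for the remaining pocket distances
  (D4–D7) are figure-defined in the source material and are therefore
  config-only, with no default asserted as the original one.

## Conformational states

Strictly greater than the open threshold → open; strictly less than the
closed threshold → closed; everything else, boundaries included, → middle.
The strict inequalities mirror the wording that defines the states
("greater than"/"less than"), making the boundary-value tie rule explicit.
Thresholds are either configured (20.59 / 22.98 Å for the
guanine-aptamer reference system: the trailing-window mean D1 of the
bound and apo simulations respectively) or derived by
`deriveThresholds()` with a trailing window defaulting to the last half of
each series.

Across-ligand statistics (distance vs state-percentage correlations) are
computed on per-ligand summary values, matching the reference table's
construction, not on pooled frames. Two recorded caveats: that table
contains an identical duplicated row for the ADE complex in both aptamer
columns, which is taken at face value in all arithmetic; and recomputing
its correlation coefficients from the *rounded* printed entries yields
≈0.65/−0.55 for the mutant aptamer where 0.66/−0.56 are printed — the
package reports full precision and treats the discrepancy as rounding
sensitivity of a five-point correlation.

The experimental affinities convert via $\Delta G = RT\ln K_d$
($R = 0.0019872$ kcal/(mol·K), 1 M reference state), so sub-molar
dissociation constants give negative binding free energies, consistent
with the tabulated experimental values. (Source footnotes of this pipeline
family often print the formula as $-RT\ln K_d$; that sign is only
consistent with an association constant.)

## Synthetic data: what it emulates and what it does not

The generators define the package's study conditions and plant the ground
truth every statistical test recovers:

* `makeToySystem()` — bead molecules with uniform charges (shifted to an
  exact net charge), LJ/GB parameters in physically plausible ranges
  (rmin/2 1.4–2.0 Å, ε 0.05–0.2 kcal/mol, GB radii 1.3–1.9 Å), packed at
  ≥2.8 Å separation, last beads forming the ligand residue. Energy oracles
  run on ≤20-atom instances.
* `makeTwoStateSeries()` — a first-order Markov chain on {open, closed}
  with Gaussian emission. Defaults place the state means at the reference
  D1 values (22.98 / 20.59 Å) with stay probabilities 0.98 and an emission
  sd of 0.6 Å — chosen once so that the two distance modes overlap
  slightly, as the real distance histograms do; the distributional form is
  a modeling choice, the source material shows only bimodal histograms.
* `makeEnergyFrames()` — i.i.d. Gaussian per-frame component draws per
  replica, the fixture for the $\sigma = \mathrm{sd}/\sqrt N$ aggregation
  rule and its $1/\sqrt N$ scaling (checked at N = 4, 16, 64).
* `makeFluctuatingTrajectory()` — isotropic Gaussian jitter with a
  prescribed per-atom sd about a rigid scaffold, optionally composed with
  random global rigid motions to exercise superposition.

Each generator draws from a deterministic substream derived from its name
and the run seed, so adding a generator never perturbs the others and
every output is bit-reproducible for a fixed seed.

What passing these tests shows: the estimators recover planted truth under
their own assumptions (Markovian two-state switching, isotropic Gaussian
fluctuations, independent Gaussian energy noise). What they do not show:
anything about force-field quality, RNA geometry, sampling convergence of
real trajectories, or the validity of the harmonic/implicit-solvent
approximations themselves. Quantities that depend on the original
multi-microsecond trajectories (absolute energy means, apo state
percentages, RMSD tables) are outside what desk-scale recomputation can
reproduce; the package instead recomputes everything derivable from the
published tables and validates the machinery on synthetic ground truth.

## Problem sizes and runtimes

The shipped tests use bead systems of 4–20 atoms for energy oracles
(100 random instances), 60-atom scaffolds × 2000 frames for fluctuation
recovery, 10⁴–10⁵-frame Markov chains for state statistics, and 4-atom
complexes for the full minimize→Hessian→entropy path — sizes chosen so the
whole suite completes in well under a minute while still exercising every
code path at meaningful statistical power.

## Known limitations

* GB (OBC-II) polar solvation throughout; no Poisson–Boltzmann option.
* Bonded terms are harmonic bonds only (no angles/dihedrals): sufficient
  for the analysis and its toys, not for general-purpose minimization of
  real force fields.
* Vibrational-only entropy (see above); no quasi-harmonic or
  interaction-entropy alternatives.
* PDB dialect: ATOM/HETATM, altloc ''/A only, no mmCIF, no solvent boxes —
  inputs are implicit-solvent solute snapshots by design.
* The Shrake–Rupley estimator's quadrature noise bounds how tightly
  surface-dependent quantities can be compared across rigid motions.
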