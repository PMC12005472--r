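---
title: "Detecting ligand-linked protonation changes: models and methods"
author: "protlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ligand-linked protonation changes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlink)
```

# Scientific background

Binding of a charged ligand perturbs the electrostatic environment of nearby
titratable residues. If a perturbed residue's pKa crosses the working pH,
the binding event is accompanied by net proton uptake or release, with three
observable consequences that this package models jointly:

* **Calorimetric**: the apparent binding enthalpy depends on the buffer,
  because the proton transferred to or from the protein is supplied by
  buffer deprotonation, whose enthalpy is buffer-specific.
* **Electrostatic**: continuum models of the complex and of the free protein
  predict shifted titration curves for the affected sites.
* **Dynamic**: constant-pH molecular dynamics shows the titration coordinate
  of the affected residue spending more frames in the protonated state in
  the complex.

# Module-by-module model description

## ITC proton linkage

Integrated injection heats follow the single-site (Wiseman) isotherm. With
total injected volume $V$, cell volume $V_0$, syringe concentration $L_s$
and binding-site concentration $N \cdot P_0$, the displaced-volume dilution
is modeled continuously:

$$P_\text{tot} = N P_0 e^{-V/V_0}, \qquad
  L_\text{tot} = L_s\,(1 - e^{-V/V_0}),$$

and the complex concentration $C$ is the positive root of
$C^2 - C\,(P_\text{tot}+L_\text{tot}+K_d) + P_\text{tot}L_\text{tot} = 0$.
The heat of injection $i$ is $\Delta H$ times the change of complex held in
the cell plus a trapezoidal term for complex displaced into the overflow
during the injection, normalized per mole of injectant. `fitOneSite`
performs Levenberg–Marquardt least squares over $(N, \log K_d, \Delta H)$;
`genItcInjections` uses the identical forward model, which is a deliberate
design decision: the noise-free round-trip is then an exact oracle, and the
fit is provably invariant to splitting injections (both are asserted in the
tests). A c-value ($N P_0 / K_d$) above $10^4$ triggers an explicit
unidentifiability warning.

Across buffers, `linkageRegression` fits ordinary least squares to

$$\Delta H_\text{observed} = \Delta H_\text{corrected}
  + \Delta n_{H^+} \cdot \Delta H_\text{ionization},$$

with proton uptake by the complex counted positive. Unweighted OLS is the
default because per-buffer uncertainties are usually not available; a
weighted mode accepts standard errors. `correctedProfile` completes the
profile with $\Delta G = \overline{RT \ln K_d}$ over buffers and
$-T\Delta S = \Delta G - \Delta H_\text{corrected}$.

## Continuum electrostatics

`solveLPBE` solves the linearized Poisson–Boltzmann equation on a regular
grid with a 7-point stencil:

* two dielectric regions — the van-der-Waals union of atom spheres at
  $\varepsilon_\text{in}$ (default 15), solvent at $\varepsilon_\text{out}$
  (default 80); no solvent-excluded surface and no Stern layer, the simplest
  testable choice;
* face dielectrics by harmonic averaging weighted by the fraction of each
  grid edge inside the sphere union (4 samples per edge);
* Debye screening $\kappa^2$ from the ionic strength (default 0.05 M),
  applied only at solvent nodes;
* trilinear spreading of point charges, Debye–Hückel monopole boundary
  values, successive over-relaxation ($\omega = 1.9$) to a residual below
  $10^{-6}$ of the source norm, and grid focusing that halves the box per
  level with boundary values interpolated from the parent solution.

Accuracy is established against three closed forms in the test suite: the
Coulomb potential in a uniform dielectric (within 2% for $r \in [4, 10]$ Å),
the Born self-energy of a charge centered in a 2 Å sphere (within 5%, with
grid-halving convergence below 3%), and the screened-Coulomb interaction of
point-like sites (within 5%).

`siteEnergies` decomposes the cost of ionizing a site into a desolvation
penalty — the charging free energy of the site's ionized-minus-neutral
charge difference in the full molecular environment minus the same quantity
for the isolated model compound, both computed **on identical grids** so the
infinite grid self-energy cancels exactly — and a background term, the
interaction of that charge difference with all static charges.
`intrinsicPKa` converts to

$$\text{p}K_a^\text{intr} = \text{p}K_a^\text{ref} +
  \frac{s\,(\Delta\Delta G_\text{desolv} + \Delta G_\text{back})}{\ln 10\,RT},$$

with $s = +1$ for acids, $-1$ for bases, and reference pKas Asp 4.0,
Glu 4.5, His 6.5, Tyr 9.8, Lys 10.4, Arg 12.5 and 4.32 for the ligand
carboxylate. Cysteines are never titrated. `interactionMatrix` computes the
symmetric coupling matrix $W$ from one solve per site (or analytically in
the screened-Coulomb fallback backend, which doubles as the test oracle).

## Titration engine

With $x_i = 1$ meaning *ionized* (deprotonated acid or protonated base), a
microstate's energy is

$$E(\mathbf{x}) = \sum_i x_i\, s_i \ln 10\, RT\,
  (\text{p}K_{a,i}^\text{intr} - \text{pH})
  + \sum_{i<j} x_i x_j W_{ij}.$$

The single-ionized convention lets acids and bases share one Hamiltonian;
per-site protonated fractions are recovered through $s_i$. With this sign
choice a lone acid reproduces the Henderson–Hasselbalch curve
$\theta = 1/(1+10^{\text{pH}-\text{p}K_a})$ exactly, which the tests assert
to machine precision.

`enumerateTitration` Boltzmann-averages over all $2^n$ states ($n \le 22$);
`mcTitration` runs Metropolis sampling with single-site flips plus
correlated pair flips for pairs coupled by more than 2.5 pK units (the
catalytic-dyad regime), discards 10% burn-in, and reports batch-means
standard errors from at least 20 batches. Total bound protons are
non-increasing in pH (a thermodynamic identity,
$d\langle n \rangle/d\text{pH} = -\ln 10 \cdot \mathrm{Var}(n) \le 0$),
asserted as a property test.

`coupledPairApparentPKas` treats two coupled acids as a diprotic acid: from
the 4-state partition function, the apparent pKas are the pH values where
the expected number of bound protons crosses 1.5 and 0.5. Two limits anchor
the implementation: identical independent sites split by the statistical
factor $\pm\log_{10} 2$, and strong coupling approaches a splitting of
$|\text{p}K_2 - \text{p}K_1| + w/(\ln 10\, RT)$.

`titrateComplexAndFree` runs the full chain for the complex and the
ligand-deleted system on an identical grid geometry (fixed by the complex's
bounding box) so that grid placement cannot masquerade as a binding-induced
shift.

## Titration analysis

`cphmdFractions` classifies lambda frames with thresholds 0.2/0.8 —
intermediate frames are excluded, a documented, configurable choice —
computes per-replica deprotonation fractions after burn-in removal, and
reports replica means with standard errors of the mean. `fitHH` fits the
Henderson–Hasselbalch equation by nonlinear least squares with the Hill
coefficient fixed at 1 (a free-Hill mode exists as a diagnostic).
`residueDeltaNH` evaluates per-residue proton uptake
$\theta(\text{p}K_a^\text{complex}, \text{pH}) -
\theta(\text{p}K_a^\text{free}, \text{pH})$, with optional half-up rounding
to two decimals for table-style reporting. `totalDeltaNH` reports both the
independent-site sum and the coupled-model total (difference in total bound
protons); the two agree only for uncoupled systems, so both are always
reported rather than asserted equal.

## Structure analysis

`kabschSuperpose` implements the SVD-based least-squares rigid superposition
with the determinant correction that excludes reflections. All-atom RMSD
between two crystal structures pairs atoms by (chain, residue number, atom
name), skipping and counting unpaired atoms; alternate locations resolve to
the highest occupancy, ties alphabetical. `rmsfPerResidue` superposes all
snapshots on their ensemble mean, iterated twice, before computing
fluctuations. `boxStats` uses linear-interpolation quartiles and the
1.5 · IQR whisker rule.

# Synthetic generators and their realism

Every pipeline input has a generator with known ground truth:

* `genToySites` builds exact line/ring/pair geometries of one-atom sites
  with physically consistent charge sets (each protonation state sums to its
  formal charge).
* `genItcInjections` produces Wiseman heats with i.i.d. Gaussian noise on
  the integrated molar heats — noise on integrated heats, not on power
  traces, because the analysis chain operates on integrated heats; a power
  mode synthesizes smooth response pulses purely to exercise
  `integrateThermogram`.
* `genLambdaTrajectories` simulates, per site/pH/replica, a two-state Markov
  chain whose stationary deprotonation probability is the
  Henderson–Hasselbalch value and whose switching obeys detailed balance at
  the requested mean rate (default 0.05 transitions per frame). The default
  protocol is 17 pH replicas from 2.5 to 10.5 in steps of 0.5, in
  triplicate. Emission is binary with optional sub-threshold jitter confined
  to $[0, 0.2] \cup [0.8, 1]$, exercising the classification thresholds
  without changing assignments.
* `genDisplacedStructure` applies exact rigid motions plus isotropic
  Gaussian jitter for superposition fixtures.

# Numerical choices

* Constants: $R = 8.3144626\times10^{-3}$ kJ/mol/K, Coulomb constant
  $1389.35$ kJ·Å·mol⁻¹·e⁻²; $\ln 10\, RT = 5.708$ kJ/mol at 298.15 K.
* The SOR solver checks its residual every 10 sweeps against a tolerance
  scaled by the source magnitude, and fails loudly (with residual history)
  rather than returning an unconverged field.
* The Monte Carlo core uses R's own RNG stream, so `set.seed`-style
  reproducibility extends through the compiled code; identical seeds give
  bit-identical curves.
* Half-up decimal rounding is implemented explicitly for table-style output
  because R's `round` rounds half to even.

# Limitations

* The dielectric boundary is the van-der-Waals union; no solvent-excluded
  surface, ion-exclusion layer, or nonlinear PB. Absolute pKas from real
  protein structures therefore depend on radius/charge inputs and are not
  benchmarked — the validated claims are the analytic oracles, internal
  consistency, and the *direction* of binding-induced shifts.
* Charge assignment is out of scope: charges come from the PQR input or the
  toy generator.
* The lambda generator makes no attempt to model MD forces; it reproduces
  only the statistical structure (stationary fractions, switching, replica
  scatter) that the post-processing consumes.
* Ensembles are lists of structures or directories of PDBs; trajectory
  formats (XTC/DCD) are not read.
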