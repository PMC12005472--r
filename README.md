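# protlink

Detecting and localizing proton-transfer events that accompany
protein–ligand binding.

When a ligand binds, the electrostatic environment of nearby titratable
residues changes; an aspartate whose pKa rises above the working pH will pick
up a proton from the buffer as part of the binding event. `protlink`
implements the complete computational chain used to detect and localize such
events, built around the classic case of an aspartic protease binding an
anionic peptide inhibitor:

1. **ITC proton linkage** (`linkageRegression`, `fitOneSite`,
   `integrateThermogram`, `correctedProfile`). Measuring the same binding
   reaction in buffers of different ionization enthalpy separates the
   intrinsic binding enthalpy from the heat of buffer deprotonation:
   ΔH_observed = ΔH_corrected + ΔnH⁺ · ΔH_ionization. The slope of observed
   enthalpy against buffer ionization enthalpy is the net number of protons
   taken up per binding event.
2. **Continuum-electrostatics titration** (`solveLPBE`, `siteEnergies`,
   `intrinsicPKa`, `interactionMatrix`, `enumerateTitration`, `mcTitration`,
   `coupledPairApparentPKas`, `titrateComplexAndFree`). A finite-difference
   linearized Poisson–Boltzmann solver yields per-site desolvation and
   background energies, intrinsic pKas and the site–site coupling matrix;
   protonation microstates are then averaged exactly (≤ 22 sites) or by
   Metropolis Monte Carlo, for the complex and the ligand-deleted protein on
   identical grids. Strongly coupled catalytic-dyad pairs get the closed-form
   diprotic-acid treatment.
3. **Constant-pH MD post-processing** (`cphmdFractions`, `cphmdPKas`,
   `fitHH`, `residueDeltaNH`, `totalDeltaNH`). Lambda (titration-coordinate)
   trajectories per pH replica are classified into
   protonated/deprotonated/intermediate frames, averaged over replicas, and
   fitted to the Henderson–Hasselbalch equation; pKa pairs for the free and
   complexed forms convert into per-residue proton uptake ΔnH⁺ at any pH.
4. **Structural comparison** (`readStructure`, `kabschSuperpose`,
   `structureRMSD`, `rmsdSeries`, `rmsfPerResidue`, `boxStats`,
   `distanceTable`). Kabsch superposition with (chain, residue, atom-name)
   pairing, per-residue Cα RMSF about the iterated ensemble mean, box-plot
   statistics with the 1.5·IQR whisker rule.

A synthetic-data module (`genToySites`, `genItcInjections`,
`genBufferSeries`, `genLambdaTrajectories`, `genDisplacedStructure`)
generates every input with known ground truth, so the entire chain is
testable offline; each generator has a round-trip test against its
downstream estimator.

## Worked example

```r
library(protlink)

## 1. ITC proton linkage across four buffers ---------------------------
pts <- genBufferSeries(slope = 1.67, intercept = -53.3,
                       dHIonization = c(3.60, 12.23, 20.04, 47.45),
                       noiseSD = 1, seed = 7,
                       bufferNames = c("phosphate", "ADA", "HEPES", "TRIS"))
pts
#>      buffer dHIonization dHObserved
#> 1 phosphate         3.60  -45.00075
#> 2       ADA        12.23  -34.07267
#> 3     HEPES        20.04  -20.52749
#> 4      TRIS        47.45   25.52921

fit <- linkageRegression(pts)
fit
#> Proton-linkage fit over 4 buffers
#>   dnH+        = +1.633 +/- 0.052 protons
#>   dH_corrected = -52.54 +/- 1.38 kJ/mol   (r^2 = 0.9980)

correctedProfile(Kd = 1e-6, dHcorrected = fit@dHcorrected)
#> Thermodynamic profile at 298.15 K (kJ/mol)
#>   dG = -34.25   dH = -52.54   -TdS = +18.29

## 2. Electrostatic titration of a toy acid + anionic ligand -----------
sysC <- genToySites(toySystemSpec(2, "pair", distance = 4,
                                  siteTypes = c("Asp", "LigCOOH")))
res <- titrateComplexAndFree(sysC, NULL, gridSpec(spacing = 0.8),
                             electroParams(), pHGrid = seq(1, 10, 0.25))
round(pKaHalf(res$complex$curve), 3)   # Asp pKa shifts up in the complex
#>     Asp1 LigCOOH2
#>    4.207    4.815
round(pKaHalf(res$free$curve), 3)
#> Asp1
#>    4

totalDeltaNH(res$complex$curve, res$free$curve, pH = 7)
#> Protonation change on complexation at pH 7.00
#>   Asp1       +0.004
#>   total (independent sites) +0.004
#>   total (coupled model)     +0.013

## 3. Constant-pH-MD lambda trajectories -------------------------------
trajs <- genLambdaTrajectories(lambdaSimSpec(truePKa = 7.6, seed = 42))
cphmdPKas(trajs)[[1]]
#> Henderson-Hasselbalch fit: pKa = 7.610 +/- 0.008  (rms residual 0.0065 over 17 points)
```

The tabulated per-residue proton uptake between two fitted pKas is one call:

```r
residueDeltaNH(pKaFree = 5.5, pKaComplex = 7.0, pH = 7.0, digits = 2)
#> [1] 0.47
```

## Model notes

- The FD-LPBE solver uses a 7-point stencil with harmonically mixed face
  dielectrics, trilinear charge spreading, Debye–Hückel boundary values and
  grid focusing; it is validated against the analytic Coulomb, Born and
  screened-Coulomb oracles in the test suite. Desolvation energies are always
  differences of energies computed on identical grids, so grid self-energy
  cancels.
- Default parameters: internal dielectric 15, solvent 80, ionic strength
  0.05 M, 298.15 K; reference pKas Asp 4.0, Glu 4.5, His 6.5, Tyr 9.8,
  Lys 10.4, Arg 12.5, ligand carboxylate 4.32. Cys is never titrated.
- The Monte Carlo titration uses single-site flips plus pair flips for site
  pairs coupled by more than 2.5 pK units, 10% burn-in, and batch-means
  standard errors. It is tested for agreement with exact enumeration within
  3 SE.

See the vignette (`vignettes/proton-linkage.Rmd`) for the full model
description, parameter choices and limitations.

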