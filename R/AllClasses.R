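#' @import methods
NULL

# ---- synthetic-data specifications -----------------------------------------

#' Specification of a toy titratable-site system
#'
#' Describes a small synthetic system of titratable sites (Asp/Glu/His/Lys/
#' Tyr/Arg side chains or a ligand carboxylate) laid out on a simple geometry,
#' plus optional fixed background charges. Used by [genToySites()] to build a
#' [TitratableSiteSystem-class] with known ground truth.
#'
#' @slot nSites Number of titratable sites (>= 1).
#' @slot geometry One of `"line"`, `"ring"`, `"pair"`.
#' @slot distance Inter-site distance in Angstrom (> 1).
#' @slot siteTypes Character vector of residue classes, recycled to `nSites`.
#' @slot referencePKas Per-site model-compound pKa; `NA` entries take the
#'   built-in reference value for the residue class.
#' @slot backgroundCharges data.frame with columns `x`, `y`, `z`, `q`
#'   (positions in Angstrom, charges in e); may have zero rows.
#' @slot seed Integer seed.
#' @export
setClass("ToySystemSpec", representation(
  nSites = "integer", geometry = "character", distance = "numeric",
  siteTypes = "character", referencePKas = "numeric",
  backgroundCharges = "data.frame", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (!object@geometry %in% c("line", "ring", "pair"))
    msg <- c(msg, "geometry must be one of 'line', 'ring', 'pair'")
  if (object@geometry == "pair" && object@nSites != 2L)
    msg <- c(msg, "'pair' geometry requires exactly 2 sites")
  if (!is.finite(object@distance) || object@distance <= 1.0)
    msg <- c(msg, "inter-site distance must exceed 1.0 Angstrom")
  if (length(object@siteTypes) != object@nSites)
    msg <- c(msg, "siteTypes must have one entry per site")
  if (!all(object@siteTypes %in% names(.REF_PKA)))
    msg <- c(msg, paste("unknown residue class; allowed:",
                        paste(names(.REF_PKA), collapse = ", ")))
  if (length(object@referencePKas) != object@nSites)
    msg <- c(msg, "referencePKas must have one entry per site")
  bg <- object@backgroundCharges
  if (nrow(bg) > 0 && !all(c("x", "y", "z", "q") %in% names(bg)))
    msg <- c(msg, "backgroundCharges needs columns x, y, z, q")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic 1:1 ITC titration
#'
#' Ground-truth parameters for [genItcInjections()]: a Wiseman-type single-site
#' binding isotherm with Gaussian noise on the integrated heats. Defaults
#' mirror a standard automated-calorimeter setup (50 uM protein in a 0.2 mL
#' cell titrated with 500 uM ligand).
#'
#' @slot Kd Dissociation constant, mol/L.
#' @slot dH Binding enthalpy, kJ/mol.
#' @slot N Stoichiometry (0 < N <= 2).
#' @slot cellConc,syringeConc Concentrations, mol/L.
#' @slot cellVolume Cell volume, mL.
#' @slot injectionVolumes Injection volumes, uL.
#' @slot noiseSD Gaussian noise on molar heats, kJ/mol.
#' @slot seed Integer seed.
#' @export
setClass("ItcSimSpec", representation(
  Kd = "numeric", dH = "numeric", N = "numeric",
  cellConc = "numeric", syringeConc = "numeric", cellVolume = "numeric",
  injectionVolumes = "numeric", noiseSD = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@Kd <= 0) msg <- c(msg, "Kd must be > 0")
  if (object@N <= 0 || object@N > 2) msg <- c(msg, "N must be in (0, 2]")
  if (object@cellConc <= 0 || object@syringeConc <= 0)
    msg <- c(msg, "concentrations must be > 0")
  if (object@cellVolume <= 0) msg <- c(msg, "cell volume must be > 0")
  if (length(object@injectionVolumes) < 1 || any(object@injectionVolumes <= 0))
    msg <- c(msg, "injection volumes must be positive")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of synthetic constant-pH lambda trajectories
#'
#' Ground truth for [genLambdaTrajectories()]: per site, a two-state Markov
#' chain over {protonated, deprotonated} whose stationary deprotonation
#' probability follows the Henderson-Hasselbalch curve at each pH replica.
#' Defaults emulate a 17-replica grid from pH 2.5 to 10.5 in steps of 0.5,
#' run in triplicate.
#'
#' @slot truePKa Per-site ground-truth pKa.
#' @slot pHGrid Strictly increasing pH values (one replica each).
#' @slot nFrames Frames per trajectory (after 0-based frame 1).
#' @slot burnInFrames Frames flagged for discarding downstream.
#' @slot switchRate Mean transitions per frame at the curve midpoint
#'   (0 < rate <= 0.5).
#' @slot nReplicas Independent replicas per pH.
#' @slot jitter Amplitude of sub-threshold emission jitter in [0, 0.2];
#'   0 emits pure {0,1} lambda values.
#' @slot seed Integer seed.
#' @export
setClass("LambdaSimSpec", representation(
  truePKa = "numeric", pHGrid = "numeric", nFrames = "integer",
  burnInFrames = "integer", switchRate = "numeric", nReplicas = "integer",
  jitter = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (length(object@truePKa) < 1) msg <- c(msg, "need at least one site pKa")
  if (is.unsorted(object@pHGrid, strictly = TRUE))
    msg <- c(msg, "pHGrid must be strictly increasing")
  if (object@nFrames <= object@burnInFrames || object@burnInFrames < 0L)
    msg <- c(msg, "need nFrames > burnInFrames >= 0")
  if (object@switchRate <= 0 || object@switchRate > 0.5)
    msg <- c(msg, "switchRate must be in (0, 0.5]")
  if (object@nReplicas < 1L) msg <- c(msg, "nReplicas must be >= 1")
  if (object@jitter < 0 || object@jitter > 0.2)
    msg <- c(msg, "jitter must be in [0, 0.2]")
  if (length(msg)) msg else TRUE
})

# ---- core containers --------------------------------------------------------

#' A system of titratable sites for continuum electrostatics
#'
#' Atom-level description of a molecule (or toy construct) whose titratable
#' sites are to be titrated: atom positions, radii (defining the dielectric
#' boundary as the van-der-Waals union), static background charges, and per
#' site the residue class, reference pKa and the charge sets of the
#' protonated and deprotonated forms.
#'
#' @slot atoms data.frame with columns `x`, `y`, `z` (Angstrom), `radius`
#'   (Angstrom, > 0), `charge` (static background charge, e), `ligand`
#'   (logical).
#' @slot sites List; each element a list with fields `id` (character),
#'   `class` (residue class), `pkaRef` (numeric), `atomIdx` (integer indices
#'   into `atoms`), `qProt`, `qDeprot` (numeric charge sets over `atomIdx`),
#'   `acid` (logical; TRUE when the deprotonated form is the ionized one),
#'   `ligand` (logical).
#' @seealso [genToySites()], [siteEnergies()], [interactionMatrix()]
#' @export
setClass("TitratableSiteSystem", representation(
  atoms = "data.frame", sites = "list"
), validity = function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("x", "y", "z", "radius", "charge")
  if (!all(need %in% names(a)))
    msg <- c(msg, "atoms needs columns x, y, z, radius, charge")
  else {
    if (!all(is.finite(as.matrix(a[, need])))) msg <- c(msg, "non-finite atom fields")
    if (any(a$radius <= 0)) msg <- c(msg, "atom radii must be > 0")
  }
  for (s in object@sites) {
    if (identical(s$class, "Cys"))
      msg <- c(msg, "Cys is never titrated (kept neutral and protonated)")
    if (length(s$qProt) != length(s$atomIdx) ||
        length(s$qDeprot) != length(s$atomIdx))
      msg <- c(msg, sprintf("site %s: charge sets must match atomIdx length", s$id))
    dq <- sum(s$qDeprot) - sum(s$qProt)
    want <- if (isTRUE(s$acid)) -1 else -1  # deprotonation removes +1 in both
    if (abs(dq - want) > 1e-9)
      msg <- c(msg, sprintf("site %s: deprotonated-minus-protonated charge must sum to -1 e", s$id))
  }
  if (length(msg)) msg else TRUE
})

#' Titration curves of a multi-site system
#'
#' Per-site protonated fractions on a pH grid plus the total number of bound
#' titratable protons, as produced by [enumerateTitration()] or
#' [mcTitration()].
#'
#' @slot pH Numeric pH grid.
#' @slot theta Matrix (pH x sites) of protonated fractions in [0, 1].
#' @slot nBound Numeric; total bound titratable protons per pH
#'   (`rowSums(theta)`).
#' @slot mcSE Matrix of Monte-Carlo standard errors on `theta` (all zero for
#'   exact enumeration).
#' @slot siteIds Character site identifiers (column names of `theta`).
#' @export
setClass("TitrationCurve", representation(
  pH = "numeric", theta = "matrix", nBound = "numeric", mcSE = "matrix",
  siteIds = "character"
), validity = function(object) {
  msg <- character()
  if (nrow(object@theta) != length(object@pH))
    msg <- c(msg, "theta must have one row per pH")
  if (any(object@theta < -1e-9 | object@theta > 1 + 1e-9))
    msg <- c(msg, "protonated fractions must lie in [0, 1]")
  if (max(abs(object@nBound - rowSums(object@theta))) > 1e-6)
    msg <- c(msg, "nBound must equal the row sums of theta")
  if (length(msg)) msg else TRUE
})

#' A series of ITC injections
#'
#' Per-injection volumes and integrated molar heats for a single titration,
#' plus the cell/syringe setup needed to fit a 1:1 binding model.
#'
#' @slot cellConc Cell (protein) concentration, mol/L.
#' @slot syringeConc Syringe (ligand) concentration, mol/L.
#' @slot cellVolume Cell volume, mL.
#' @slot temperature Temperature, K.
#' @slot injections data.frame with columns `volume` (uL) and `heat`
#'   (kJ per mol of injectant).
#' @export
setClass("InjectionSeries", representation(
  cellConc = "numeric", syringeConc = "numeric", cellVolume = "numeric",
  temperature = "numeric", injections = "data.frame"
), validity = function(object) {
  msg <- character()
  if (object@cellConc <= 0 || object@syringeConc <= 0 || object@cellVolume <= 0)
    msg <- c(msg, "concentrations and cell volume must be > 0")
  inj <- object@injections
  if (!all(c("volume", "heat") %in% names(inj)))
    msg <- c(msg, "injections needs columns volume, heat")
  else if (any(inj$volume <= 0)) msg <- c(msg, "injection volumes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-site, per-pH-replica lambda trajectories
#'
#' Titration-coordinate series from constant-pH MD (or its synthetic
#' emulation): for each site and independent replica, a frames-by-pH matrix
#' of lambda values in [0, 1], where lambda near 0 is protonated and near 1
#' deprotonated.
#'
#' @slot sites Character site names.
#' @slot pH Numeric pH grid (one replica ladder).
#' @slot burnIn Integer; leading frames to discard in analysis.
#' @slot lambda List over sites; each element a list over replicas of
#'   matrices (frames x pH).
#' @export
setClass("LambdaTrajectorySet", representation(
  sites = "character", pH = "numeric", burnIn = "integer", lambda = "list"
), validity = function(object) {
  msg <- character()
  if (length(object@lambda) != length(object@sites))
    msg <- c(msg, "lambda must have one element per site")
  for (ls in object@lambda) {
    if (length(ls) < 1) { msg <- c(msg, "need >= 1 replica"); next }
    for (m in ls) {
      if (ncol(m) != length(object@pH))
        msg <- c(msg, "each trajectory matrix needs one column per pH")
      if (any(m < -1e-9 | m > 1 + 1e-9)) msg <- c(msg, "lambda values must be in [0, 1]")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' A macromolecular structure as an atom table
#'
#' @slot atoms data.frame with columns `chain`, `resno` (as in the source
#'   file), `resid` (residue name), `atom` (atom name), `element`, `x`, `y`,
#'   `z`, `occupancy`, `altloc`.
#' @slot source Character; provenance label (file path or id).
#' @export
setClass("Structure", representation(
  atoms = "data.frame", source = "character"
), validity = function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "atom", "element",
            "x", "y", "z", "occupancy", "altloc")
  if (!all(need %in% names(a)))
    return(paste("atoms needs columns", paste(need, collapse = ", ")))
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite coordinates")
  key <- paste(a$chain, a$resno, a$atom, a$altloc)
  if (anyDuplicated(key)) return("duplicate (chain, resno, atom, altloc)")
  TRUE
})

# ---- fit-result containers --------------------------------------------------

#' Proton-linkage regression fit
#'
#' Ordinary (or weighted) least-squares fit of observed binding enthalpy on
#' buffer ionization enthalpy. The slope is the number of protons taken up
#' by the protein-ligand system per binding event (positive = uptake); the
#' intercept is the buffer-corrected binding enthalpy.
#'
#' @slot dnH Slope, protons per binding event.
#' @slot dHcorrected Intercept, kJ/mol.
#' @slot slopeSE,interceptSE Standard errors.
#' @slot r2 Coefficient of determination.
#' @slot n Number of buffers.
#' @export
setClass("LinkageFit", representation(
  dnH = "numeric", dHcorrected = "numeric", slopeSE = "numeric",
  interceptSE = "numeric", r2 = "numeric", n = "integer"
), validity = function(object) {
  if (object@slopeSE < 0 || object@interceptSE < 0)
    "standard errors must be >= 0" else TRUE
})

#' Buffer-corrected thermodynamic profile
#'
#' @slot dG Gibbs free energy of binding, kJ/mol.
#' @slot dH Buffer-corrected enthalpy, kJ/mol.
#' @slot minusTdS Entropic contribution -T*dS = dG - dH, kJ/mol.
#' @slot temperature K.
#' @export
setClass("ThermoProfile", representation(
  dG = "numeric", dH = "numeric", minusTdS = "numeric", temperature = "numeric"
), validity = function(object) {
  if (abs(object@dG - (object@dH + object@minusTdS)) > 1e-9)
    "dG must equal dH + minusTdS" else TRUE
})

#' Henderson-Hasselbalch fit
#'
#' @slot pKa Fitted midpoint.
#' @slot hill Hill coefficient (1 when fixed).
#' @slot hillFixed Logical; TRUE for the pure Henderson-Hasselbalch fit.
#' @slot sePKa Standard error of the midpoint.
#' @slot residualRMS Root-mean-square residual in fraction units.
#' @slot data data.frame of `pH`, `fraction` (deprotonated), `fitted`.
#' @export
setClass("HHFit", representation(
  pKa = "numeric", hill = "numeric", hillFixed = "logical",
  sePKa = "numeric", residualRMS = "numeric", data = "data.frame"
), validity = function(object) {
  if (object@sePKa < 0) "sePKa must be >= 0" else TRUE
})

#' One-site (Wiseman) binding fit
#'
#' @slot N Stoichiometry.
#' @slot Kd Dissociation constant, mol/L.
#' @slot dH Binding enthalpy, kJ/mol.
#' @slot se Named numeric standard errors for N, Kd, dH.
#' @slot cValue Wiseman c = N * cellConc / Kd.
#' @slot fitted Fitted molar heats, kJ/mol.
#' @export
setClass("OneSiteFit", representation(
  N = "numeric", Kd = "numeric", dH = "numeric", se = "numeric",
  cValue = "numeric", fitted = "numeric"
))

#' Protonation change upon complexation
#'
#' Per-site and total proton uptake at a stated pH, from paired free/complex
#' titration curves. `totalIndependent` sums the per-site values;
#' `totalCoupled` differences the total bound protons of the coupled model.
#'
#' @slot perSite Named numeric, each in [-1, 1].
#' @slot totalIndependent Sum of per-site values.
#' @slot totalCoupled n_bound(complex) - n_bound(free) at `pH`.
#' @slot pH Evaluation pH.
#' @export
setClass("DeltaNH", representation(
  perSite = "numeric", totalIndependent = "numeric",
  totalCoupled = "numeric", pH = "numeric"
), validity = function(object) {
  if (any(object@perSite < -1 - 1e-9 | object@perSite > 1 + 1e-9))
    "per-site proton changes must lie in [-1, 1]" else TRUE
})
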