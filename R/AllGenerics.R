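# Accessor generics and show methods.

#' @rdname TitrationCurve-class
#' @param object,x An object.
#' @export
setGeneric("pHGrid", function(x) standardGeneric("pHGrid"))

#' @rdname TitrationCurve-class
#' @export
setGeneric("thetaProt", function(x) standardGeneric("thetaProt"))

#' @rdname TitrationCurve-class
#' @export
setGeneric("nBound", function(x) standardGeneric("nBound"))

#' @rdname TitrationCurve-class
#' @export
setGeneric("mcSE", function(x) standardGeneric("mcSE"))

#' @rdname TitratableSiteSystem-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname TitratableSiteSystem-class
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname InjectionSeries-class
#' @export
setGeneric("injections", function(x) standardGeneric("injections"))

#' @rdname TitrationCurve-class
#' @param x A `TitrationCurve`.
#' @export
setMethod("pHGrid", "TitrationCurve", function(x) x@pH)

#' @rdname TitrationCurve-class
#' @export
setMethod("thetaProt", "TitrationCurve", function(x) {
  m <- x@theta
  colnames(m) <- x@siteIds
  m
})

#' @rdname TitrationCurve-class
#' @export
setMethod("nBound", "TitrationCurve", function(x) x@nBound)

#' @rdname TitrationCurve-class
#' @export
setMethod("mcSE", "TitrationCurve", function(x) x@mcSE)

#' @rdname LambdaTrajectorySet-class
#' @export
setMethod("pHGrid", "LambdaTrajectorySet", function(x) x@pH)

#' @rdname TitratableSiteSystem-class
#' @export
setMethod("atoms", "TitratableSiteSystem", function(x) x@atoms)

#' @rdname Structure-class
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname TitratableSiteSystem-class
#' @export
setMethod("sites", "TitratableSiteSystem", function(x) x@sites)

#' @rdname LambdaTrajectorySet-class
#' @export
setMethod("sites", "LambdaTrajectorySet", function(x) x@sites)

#' @rdname InjectionSeries-class
#' @export
setMethod("injections", "InjectionSeries", function(x) x@injections)

setMethod("show", "TitratableSiteSystem", function(object) {
  cat(sprintf("TitratableSiteSystem: %d atoms, %d titratable site(s)\n",
              nrow(object@atoms), length(object@sites)))
  for (s in object@sites)
    cat(sprintf("  %s [%s]  pKa_ref %.2f  %s\n", s$id, s$class, s$pkaRef,
                if (s$acid) "acid" else "base"))
})

setMethod("show", "TitrationCurve", function(object) {
  cat(sprintf("TitrationCurve: %d sites on %d pH points [%.2f, %.2f]\n",
              ncol(object@theta), length(object@pH),
              min(object@pH), max(object@pH)))
  if (any(object@mcSE > 0))
    cat(sprintf("  Monte-Carlo sampled; median SE %.4f\n",
                stats::median(object@mcSE)))
  else cat("  exact enumeration\n")
})

setMethod("show", "InjectionSeries", function(object) {
  cat(sprintf(paste0("InjectionSeries: %d injections, cell %.1f uM / ",
                     "syringe %.1f uM, V0 %.3g mL, T %.2f K\n"),
              nrow(object@injections), 1e6 * object@cellConc,
              1e6 * object@syringeConc, object@cellVolume, object@temperature))
})

setMethod("show", "LambdaTrajectorySet", function(object) {
  nrep <- length(object@lambda[[1]])
  nfr <- nrow(object@lambda[[1]][[1]])
  cat(sprintf(paste0("LambdaTrajectorySet: %d site(s) x %d pH replicas x ",
                     "%d replicate run(s), %d frames (burn-in %d)\n"),
              length(object@sites), length(object@pH), nrep, nfr,
              object@burnIn))
})

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure [%s]: %d atoms, %d residues, chains: %s\n",
              object@source, nrow(a),
              length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = " ")))
})

setMethod("show", "LinkageFit", function(object) {
  cat(sprintf("Proton-linkage fit over %d buffers\n", object@n))
  cat(sprintf("  dnH+        = %+.3f +/- %.3f protons\n",
              object@dnH, object@slopeSE))
  cat(sprintf("  dH_corrected = %+.2f +/- %.2f kJ/mol   (r^2 = %.4f)\n",
              object@dHcorrected, object@interceptSE, object@r2))
})

setMethod("show", "ThermoProfile", function(object) {
  cat(sprintf("Thermodynamic profile at %.2f K (kJ/mol)\n", object@temperature))
  cat(sprintf("  dG = %+.2f   dH = %+.2f   -TdS = %+.2f\n",
              object@dG, object@dH, object@minusTdS))
})

setMethod("show", "HHFit", function(object) {
  cat(sprintf("Henderson-Hasselbalch fit: pKa = %.3f +/- %.3f", object@pKa,
              object@sePKa))
  if (!object@hillFixed) cat(sprintf(", Hill = %.3f", object@hill))
  cat(sprintf("  (rms residual %.4f over %d points)\n",
              object@residualRMS, nrow(object@data)))
})

setMethod("show", "OneSiteFit", function(object) {
  cat("One-site binding fit\n")
  cat(sprintf("  N  = %.4f +/- %.2g\n", object@N, object@se[["N"]]))
  cat(sprintf("  Kd = %.4g +/- %.2g M   (c = %.3g)\n", object@Kd,
              object@se[["Kd"]], object@cValue))
  cat(sprintf("  dH = %.4g +/- %.2g kJ/mol\n", object@dH, object@se[["dH"]]))
})

setMethod("show", "DeltaNH", function(object) {
  cat(sprintf("Protonation change on complexation at pH %.2f\n", object@pH))
  for (nm in names(object@perSite))
    cat(sprintf("  %-10s %+0.3f\n", nm, object@perSite[[nm]]))
  cat(sprintf("  total (independent sites) %+0.3f\n", object@totalIndependent))
  cat(sprintf("  total (coupled model)     %+0.3f\n", object@totalCoupled))
})
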