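# ITC analysis: thermogram integration, 1:1 binding fits, proton-linkage
# regression across buffers, and the buffer-corrected thermodynamic profile.

#' Construct an injection series
#'
#' @param volumes Injection volumes, uL.
#' @param heats Integrated heats, kJ per mol of injectant.
#' @param cellConc,syringeConc Concentrations, M.
#' @param cellVolume Cell volume, mL.
#' @param temperature K.
#' @return An [InjectionSeries-class].
#' @export
injectionSeries <- function(volumes, heats, cellConc, syringeConc,
                            cellVolume, temperature = 298.15) {
  new("InjectionSeries", cellConc = cellConc, syringeConc = syringeConc,
      cellVolume = cellVolume, temperature = temperature,
      injections = data.frame(volume = volumes, heat = heats))
}

#' Integrate a raw thermogram into per-injection heats
#'
#' Splits a power trace into inter-injection windows, estimates a linear
#' baseline per window from the medians of the leading and trailing
#' `baselineWindow` seconds, and integrates the baseline-subtracted power by
#' the trapezoidal rule.
#'
#' @param trace data.frame with columns `time` (s) and `power` (uW).
#' @param injectionTimes Strictly increasing injection times within the trace.
#' @param baselineWindow Seconds of data at each window edge used for the
#'   baseline medians.
#' @return Numeric vector of per-injection heats, uJ.
#' @export
integrateThermogram <- function(trace, injectionTimes, baselineWindow = 10) {
  stopifnot(all(c("time", "power") %in% names(trace)))
  tt <- trace$time
  if (is.unsorted(injectionTimes, strictly = TRUE))
    stop("injection times must be strictly increasing (overlapping windows)")
  if (min(injectionTimes) < min(tt) || max(injectionTimes) > max(tt))
    stop("injection times must lie inside the trace")
  ends <- c(injectionTimes[-1], max(tt))
  vapply(seq_along(injectionTimes), function(i) {
    t0 <- injectionTimes[i]; t1 <- ends[i]
    # pre-peak baseline: samples just before the injection; post-peak: the
    # relaxed tail of this window
    pre <- trace$power[tt >= t0 - baselineWindow & tt <= t0]
    post <- trace$power[tt >= t1 - baselineWindow & tt <= t1]
    b0 <- stats::median(pre)
    b1 <- stats::median(post)
    sel <- tt >= t0 & tt <= t1
    t_w <- tt[sel]; p_w <- trace$power[sel]
    base <- b0 + (b1 - b0) * (t_w - t0) / max(t1 - t0, .Machine$double.eps)
    y <- p_w - base
    sum(diff(t_w) * (y[-1] + y[-length(y)]) / 2)
  }, numeric(1))
}

#' Fit the 1:1 (Wiseman) binding model to an injection series
#'
#' Least-squares fit of stoichiometry, dissociation constant and binding
#' enthalpy to per-injection molar heats. The forward model takes the bound
#' fraction from the positive root of the 1:1 mass-balance quadratic at each
#' injection, with continuous volume-displacement dilution of both species
#' and a trapezoidal correction for complex displaced from the cell.
#'
#' @param series An [InjectionSeries-class].
#' @param skipFirst Exclude the first injection from the fit (common ITC
#'   practice); default `FALSE`.
#' @param start Optional named list of starting values (`N`, `Kd`, `dH`).
#' @return A [OneSiteFit-class]. If the Wiseman c-value N*cellConc/Kd exceeds
#'   1e4 a warning is raised: Kd is then unidentifiable and only an upper
#'   bound is reported.
#' @export
fitOneSite <- function(series, skipFirst = FALSE, start = NULL) {
  stopifnot(is(series, "InjectionSeries"))
  inj <- series@injections
  if (nrow(inj) < 5) stop("need at least 5 injections to fit")
  w <- rep(1, nrow(inj))
  if (skipFirst) w[1] <- 0
  v <- inj$volume; y <- inj$heat

  if (abs(max(y) - min(y)) < 1e-12) {
    # Flat heats: dH = 0 exactly; N, Kd unidentifiable.
    return(new("OneSiteFit", N = 1, Kd = series@cellConc, dH = 0,
               se = c(N = NA_real_, Kd = NA_real_, dH = NA_real_),
               cValue = NA_real_, fitted = rep(0, length(y))))
  }
  if (is.null(start)) {
    # ratio at the steepest heat change approximates N
    ratio <- cumsum(series@syringeConc * v) /
      (series@cellConc * series@cellVolume * 1e3)
    mid <- which.max(abs(diff(y)))
    start <- list(N = max(min(ratio[mid], 2), 0.1),
                  Kd = series@cellConc / 10, dH = y[1])
  }
  model <- function(N, lKd, dH)
    .wiseman_heats(v, exp(lKd), dH, N, series@cellConc, series@syringeConc,
                   series@cellVolume)
  df <- data.frame(y = y, w = w)
  fit <- minpack.lm::nlsLM(
    y ~ model(N, lKd, dH), data = df, weights = w,
    start = list(N = start$N, lKd = log(start$Kd), dH = start$dH),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(N = NA, lKd = NA, dH = NA))
  Kd <- exp(cf[["lKd"]])
  cval <- cf[["N"]] * series@cellConc / Kd
  if (is.finite(cval) && cval > 1e4)
    warning(sprintf(paste0("c-value %.3g > 1e4: Kd is unidentifiable; ",
                           "report only the bound Kd < %.3g M"), cval, Kd))
  new("OneSiteFit", N = cf[["N"]], Kd = Kd, dH = cf[["dH"]],
      se = c(N = unname(se[["N"]]), Kd = Kd * unname(se[["lKd"]]),
             dH = unname(se[["dH"]])),
      cValue = cval, fitted = model(cf[["N"]], cf[["lKd"]], cf[["dH"]]))
}

#' Proton-linkage regression across buffers
#'
#' Regresses the observed binding enthalpy on the buffer ionization enthalpy:
#' dH_observed = dH_corrected + dnH * dH_ionization. The slope is the net
#' proton uptake by the protein-ligand complex per binding event (positive =
#' uptake) and the intercept the buffer-corrected binding enthalpy.
#' Unweighted by default; supplying `se` runs weighted least squares with
#' weights 1/se^2.
#'
#' @param points data.frame with columns `dHIonization` and `dHObserved`
#'   (kJ/mol), e.g. from [genBufferSeries()] or [readBufferSeries()].
#' @param se Optional per-buffer standard errors of `dHObserved`.
#' @return A [LinkageFit-class].
#' @examples
#' pts <- genBufferSeries(1.67, -53.3, c(3.60, 12.23, 20.04, 47.45))
#' linkageRegression(pts)
#' @export
linkageRegression <- function(points, se = NULL) {
  stopifnot(all(c("dHIonization", "dHObserved") %in% names(points)))
  x <- points$dHIonization; y <- points$dHObserved
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("singular design: need >= 2 points with distinct ionization enthalpies")
  wts <- if (is.null(se)) NULL else 1 / se^2
  fit <- stats::lm(y ~ x, weights = wts)
  sm <- summary(fit)
  co <- sm$coefficients
  slopeSE <- if (nrow(points) > 2) co["x", "Std. Error"] else 0
  intSE <- if (nrow(points) > 2) co["(Intercept)", "Std. Error"] else 0
  new("LinkageFit", dnH = unname(stats::coef(fit)[["x"]]),
      dHcorrected = unname(stats::coef(fit)[["(Intercept)"]]),
      slopeSE = slopeSE, interceptSE = intSE,
      r2 = sm$r.squared, n = length(x))
}

#' Buffer-corrected thermodynamic profile
#'
#' Combines per-buffer dissociation constants with the buffer-corrected
#' enthalpy from the linkage regression: dG_b = R T ln(Kd_b) per buffer
#' (negative for sub-molar Kd), dG is their mean, and the entropic
#' contribution is the numerical difference -TdS = dG - dH_corrected.
#'
#' @param Kd Per-buffer dissociation constants, M.
#' @param dHcorrected Buffer-corrected enthalpy, kJ/mol.
#' @param temperature K.
#' @return A [ThermoProfile-class].
#' @examples
#' correctedProfile(1e-6, -53.3)  # dG = -34.25 kJ/mol at 298.15 K
#' @export
correctedProfile <- function(Kd, dHcorrected, temperature = 298.15) {
  if (any(Kd <= 0)) stop("Kd must be > 0")
  dG <- mean(.RGAS * temperature * log(Kd))
  new("ThermoProfile", dG = dG, dH = dHcorrected,
      minusTdS = dG - dHcorrected, temperature = temperature)
}
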