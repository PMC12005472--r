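# Henderson-Hasselbalch analysis: closed-form fractions, nonlinear midpoint
# fitting, per-residue and total protonation changes on binding, and
# constant-pH-MD lambda-trajectory post-processing.

#' Henderson-Hasselbalch protonated fraction
#'
#' theta = 1 / (1 + 10^(pH - pKa)); the deprotonated fraction is 1 - theta.
#'
#' @param pKa Site pKa.
#' @param pH pH value(s).
#' @return Protonated fraction(s) in [0, 1].
#' @examples
#' hhFraction(7, 7)    # 0.5
#' hhFraction(5.5, 7)  # 0.0307
#' @export
hhFraction <- function(pKa, pH) {
  1 / (1 + 10^(pH - pKa))
}

#' Fit the Henderson-Hasselbalch equation to deprotonated fractions
#'
#' Nonlinear least squares of 1 - theta(pKa) = 1 / (1 + 10^(hill * (pKa -
#' pH))) to observed deprotonated fractions. The Hill coefficient is fixed at
#' 1 by default (the pure Henderson-Hasselbalch curve); `freeHill = TRUE`
#' releases it as a diagnostic. Weighted when per-point errors are supplied.
#'
#' @param pH pH values (>= 3 points; a warning is raised when they do not
#'   bracket the midpoint).
#' @param deprotonated Deprotonated fractions in [0, 1].
#' @param errors Optional per-point standard errors (weights 1/se^2).
#' @param freeHill Release the Hill coefficient.
#' @return An [HHFit-class].
#' @examples
#' pH <- seq(2.5, 10.5, 0.5)
#' fitHH(pH, 1 - hhFraction(7.6, pH))  # recovers 7.6
#' @export
fitHH <- function(pH, deprotonated, errors = NULL, freeHill = FALSE) {
  stopifnot(length(pH) == length(deprotonated))
  if (any(deprotonated < -1e-9 | deprotonated > 1 + 1e-9))
    stop("fractions must lie in [0, 1]")
  eps <- 1e-12
  if (all(deprotonated <= eps) || all(deprotonated >= 1 - eps))
    stop("unidentifiable fit: all fractions are 0 or all are 1")
  if (length(pH) < 3 || min(deprotonated) > 0.5 || max(deprotonated) < 0.5)
    warning("points do not bracket the midpoint; fit may be ill-posed")
  w <- if (is.null(errors)) rep(1, length(pH)) else 1 / pmax(errors, 1e-6)^2
  # start at the interpolated half-deprotonation point
  ord <- order(pH)
  p0 <- tryCatch(stats::approx(deprotonated[ord], pH[ord], xout = 0.5,
                               ties = mean)$y, error = function(e) NA)
  if (!is.finite(p0)) p0 <- stats::median(pH)
  df <- data.frame(pH = pH, d = deprotonated)
  if (freeHill) {
    fit <- minpack.lm::nlsLM(
      d ~ 1 / (1 + 10^(h * (pKa - pH))), data = df, weights = w,
      start = list(pKa = p0, h = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
  } else {
    fit <- minpack.lm::nlsLM(
      d ~ 1 / (1 + 10^(pKa - pH)), data = df, weights = w,
      start = list(pKa = p0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["pKa", "Std. Error"],
                 error = function(e) NA_real_)
  fitted <- stats::predict(fit)
  new("HHFit", pKa = unname(cf[["pKa"]]),
      hill = if (freeHill) unname(cf[["h"]]) else 1,
      hillFixed = !freeHill,
      sePKa = if (is.finite(se)) se else 0,
      residualRMS = sqrt(mean((deprotonated - fitted)^2)),
      data = data.frame(pH = pH, fraction = deprotonated, fitted = fitted))
}

#' Per-residue protonation change on complexation
#'
#' dnH = theta_prot(pKa_complex, pH) - theta_prot(pKa_free, pH): the extra
#' protons bound by the site in the complex relative to the free protein at
#' the stated pH (positive = proton uptake on binding). Computed from the
#' single-site Henderson-Hasselbalch curves of the two pKas.
#'
#' @param pKaFree,pKaComplex Site pKas in the free and complexed forms.
#' @param pH Evaluation pH.
#' @param digits When non-NULL, round half-up to this many decimals
#'   (table-style reporting).
#' @return Protonation change in [-1, 1].
#' @examples
#' residueDeltaNH(5.5, 7.0, 7.0, digits = 2)  # 0.47
#' @export
residueDeltaNH <- function(pKaFree, pKaComplex, pH, digits = NULL) {
  out <- hhFraction(pKaComplex, pH) - hhFraction(pKaFree, pH)
  if (!is.null(digits)) out <- .round_half_up(out, digits)
  out
}

#' Total protonation change from paired titration curves
#'
#' Differences the complex and free titration curves at a pH: per-site values
#' from the protonated-fraction difference (linear interpolation on the
#' grid), their sum as the independent-site total, and the coupled-model
#' total from the difference in total bound protons. The two totals agree
#' exactly only for uncoupled systems; both are reported.
#'
#' @param curveComplex,curveFree Aligned [TitrationCurve-class] objects
#'   (same sites for the shared site ids; ligand-only sites in the complex
#'   are included in the coupled total but not matched per-site).
#' @param pH Evaluation pH (inside both grids).
#' @return A [DeltaNH-class].
#' @export
totalDeltaNH <- function(curveComplex, curveFree, pH) {
  stopifnot(is(curveComplex, "TitrationCurve"), is(curveFree, "TitrationCurve"))
  if (pH < max(min(curveComplex@pH), min(curveFree@pH)) ||
      pH > min(max(curveComplex@pH), max(curveFree@pH)))
    stop("pH outside the curve grids")
  interp <- function(curve, j)
    stats::approx(curve@pH, curve@theta[, j], xout = pH)$y
  shared <- intersect(curveFree@siteIds, curveComplex@siteIds)
  per <- vapply(shared, function(id) {
    interp(curveComplex, match(id, curveComplex@siteIds)) -
      interp(curveFree, match(id, curveFree@siteIds))
  }, numeric(1))
  nbC <- stats::approx(curveComplex@pH, curveComplex@nBound, xout = pH)$y
  nbF <- stats::approx(curveFree@pH, curveFree@nBound, xout = pH)$y
  new("DeltaNH", perSite = per, totalIndependent = sum(per),
      totalCoupled = nbC - nbF, pH = pH)
}

#' Deprotonated fractions from lambda trajectories
#'
#' Classifies each post-burn-in frame by its titration coordinate: lambda
#' above `hi` counts deprotonated, below `lo` protonated, intermediate frames
#' are excluded. Per (site, pH) the fraction deprotonated/(deprotonated +
#' protonated) is computed per replica; the point estimate is the mean over
#' replicas and the error its standard error of the mean.
#'
#' @param trajs A [LambdaTrajectorySet-class].
#' @param lo,hi Classification thresholds (defaults 0.2 / 0.8).
#' @param burnIn Frames to discard from the start of every trajectory;
#'   default the set's own `burnIn` slot.
#' @return data.frame with columns `site`, `pH`, `fraction`, `sem`,
#'   `nReplicas`.
#' @export
cphmdFractions <- function(trajs, lo = 0.2, hi = 0.8, burnIn = NULL) {
  stopifnot(is(trajs, "LambdaTrajectorySet"))
  if (is.null(burnIn)) burnIn <- trajs@burnIn
  out <- list()
  for (i in seq_along(trajs@sites)) {
    reps <- trajs@lambda[[i]]
    nfr <- nrow(reps[[1]])
    if (burnIn >= nfr) stop("burn-in removes every frame")
    fr <- matrix(NA_real_, length(reps), length(trajs@pH))
    for (r in seq_along(reps)) {
      m <- reps[[r]][(burnIn + 1):nfr, , drop = FALSE]
      nd <- colSums(m > hi)
      np <- colSums(m < lo)
      if (any(nd + np == 0))
        stop(sprintf(
          "site %s, replica %d: all frames intermediate at some pH",
          trajs@sites[i], r))
      fr[r, ] <- nd / (nd + np)
    }
    mu <- colMeans(fr)
    sem <- if (nrow(fr) > 1) apply(fr, 2, stats::sd) / sqrt(nrow(fr))
           else rep(0, ncol(fr))
    out[[i]] <- data.frame(site = trajs@sites[i], pH = trajs@pH,
                           fraction = mu, sem = sem, nReplicas = nrow(fr))
  }
  do.call(rbind, out)
}

#' Fit per-site pKas to constant-pH-MD deprotonation fractions
#'
#' Convenience wrapper: [cphmdFractions()] followed by [fitHH()] per site.
#'
#' @inheritParams cphmdFractions
#' @param weighted Weight the fit by the replica SEMs.
#' @param freeHill Release the Hill coefficient.
#' @return Named list of [HHFit-class] objects, one per site.
#' @export
cphmdPKas <- function(trajs, lo = 0.2, hi = 0.8, burnIn = NULL,
                      weighted = FALSE, freeHill = FALSE) {
  fr <- cphmdFractions(trajs, lo, hi, burnIn)
  fits <- lapply(split(fr, fr$site), function(d) {
    fitHH(d$pH, d$fraction,
          errors = if (weighted) pmax(d$sem, 1e-3) else NULL,
          freeHill = freeHill)
  })
  fits[trajs@sites]
}
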