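# Synthetic-data generators: every input the analysis chain consumes can be
# produced here with known ground truth.

# Model-compound reference pKas of titratable residue classes (ligand
# carboxylate default mirrors a C-terminal statine carboxy group).
.REF_PKA <- c(Asp = 4.0, Glu = 4.5, His = 6.5, Tyr = 9.8, Lys = 10.4,
              Arg = 12.5, LigCOOH = 4.32)
.IS_ACID <- c(Asp = TRUE, Glu = TRUE, His = FALSE, Tyr = TRUE, Lys = FALSE,
              Arg = FALSE, LigCOOH = TRUE)

#' Construct a toy-system specification
#'
#' @param nSites Number of titratable sites.
#' @param geometry `"line"`, `"ring"` or `"pair"`.
#' @param distance Inter-site distance, Angstrom.
#' @param siteTypes Residue classes (`"Asp"`, `"Glu"`, `"His"`, `"Lys"`,
#'   `"Tyr"`, `"Arg"`, `"LigCOOH"`); recycled to `nSites`.
#' @param referencePKas Per-site model pKas; `NA` uses the class default
#'   (Asp 4.0, Glu 4.5, His 6.5, Tyr 9.8, Lys 10.4, Arg 12.5).
#' @param backgroundCharges data.frame of `x`, `y`, `z`, `q` fixed charges.
#' @param seed Integer seed.
#' @return A [ToySystemSpec-class].
#' @export
toySystemSpec <- function(nSites, geometry = c("line", "ring", "pair"),
                          distance = 5.0, siteTypes = "Asp",
                          referencePKas = NA_real_,
                          backgroundCharges = data.frame(
                            x = numeric(), y = numeric(), z = numeric(),
                            q = numeric()),
                          seed = 1L) {
  geometry <- match.arg(geometry)
  nSites <- as.integer(nSites)
  siteTypes <- rep_len(siteTypes, nSites)
  referencePKas <- rep_len(as.numeric(referencePKas), nSites)
  idx <- is.na(referencePKas)
  referencePKas[idx] <- .REF_PKA[siteTypes[idx]]
  new("ToySystemSpec", nSites = nSites, geometry = geometry,
      distance = distance, siteTypes = siteTypes,
      referencePKas = referencePKas, backgroundCharges = backgroundCharges,
      seed = as.integer(seed))
}

#' Generate a toy titratable-site system
#'
#' Builds a [TitratableSiteSystem-class] with one atom per site placed on the
#' requested geometry. Acidic sites carry charge 0 when protonated and -1 e
#' when deprotonated; basic sites +1 e when protonated and 0 when
#' deprotonated, so each charge set sums to the formal charge of the
#' corresponding microstate. Background charges become additional fixed atoms.
#' Deterministic for a fixed spec (the seed is carried for downstream use;
#' geometry is exact by construction).
#'
#' @param spec A [ToySystemSpec-class].
#' @param siteRadius Atom radius for site atoms, Angstrom.
#' @param bgRadius Atom radius for background-charge atoms, Angstrom.
#' @return A [TitratableSiteSystem-class].
#' @examples
#' sys <- genToySites(toySystemSpec(2, "pair", distance = 3, siteTypes = "Asp"))
#' sites(sys)[[1]]$pkaRef  # 4.0
#' @export
genToySites <- function(spec, siteRadius = 2.0, bgRadius = 1.5) {
  stopifnot(is(spec, "ToySystemSpec"))
  validObject(spec)
  n <- spec@nSites
  d <- spec@distance
  pos <- switch(spec@geometry,
    pair = ,
    line = cbind(x = (seq_len(n) - 1) * d, y = 0, z = 0),
    ring = {
      if (n == 1) cbind(x = 0, y = 0, z = 0) else {
        # circumradius such that adjacent sites are d apart
        r <- d / (2 * sin(pi / n))
        ang <- 2 * pi * (seq_len(n) - 1) / n
        cbind(x = r * cos(ang), y = r * sin(ang), z = 0)
      }
    })
  at <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   radius = siteRadius, charge = 0,
                   ligand = spec@siteTypes == "LigCOOH")
  bg <- spec@backgroundCharges
  if (nrow(bg) > 0)
    at <- rbind(at, data.frame(x = bg$x, y = bg$y, z = bg$z,
                               radius = bgRadius, charge = bg$q,
                               ligand = FALSE))
  st <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- spec@siteTypes[i]
    acid <- .IS_ACID[[cls]]
    st[[i]] <- list(id = sprintf("%s%d", cls, i), class = cls,
                    pkaRef = spec@referencePKas[i], atomIdx = i,
                    qProt = if (acid) 0 else 1,
                    qDeprot = if (acid) -1 else 0,
                    acid = acid, ligand = identical(cls, "LigCOOH"))
  }
  new("TitratableSiteSystem", atoms = at, sites = st)
}

#' Construct an ITC simulation specification
#'
#' Defaults follow a standard automated-calorimeter titration: 50 uM protein
#' in a 0.2 mL cell, 500 uM ligand in the syringe, 19 injections of 2 uL.
#'
#' @param Kd Dissociation constant, M.
#' @param dH Binding enthalpy, kJ/mol.
#' @param N Stoichiometry.
#' @param cellConc,syringeConc Concentrations, M.
#' @param cellVolume Cell volume, mL.
#' @param injectionVolumes Injection volumes, uL.
#' @param noiseSD Gaussian noise SD on molar heats, kJ/mol.
#' @param seed Integer seed.
#' @return An [ItcSimSpec-class].
#' @export
itcSimSpec <- function(Kd = 1e-6, dH = -50, N = 1, cellConc = 50e-6,
                       syringeConc = 500e-6, cellVolume = 0.2,
                       injectionVolumes = rep(2, 19), noiseSD = 0,
                       seed = 1L) {
  new("ItcSimSpec", Kd = Kd, dH = dH, N = N, cellConc = cellConc,
      syringeConc = syringeConc, cellVolume = cellVolume,
      injectionVolumes = injectionVolumes, noiseSD = noiseSD,
      seed = as.integer(seed))
}

# Forward model for a 1:1 titration. Cumulative injected volume V dilutes the
# cell continuously (overflow cell): [P]_tot = P0 exp(-V/V0), [L]_tot =
# Ls (1 - exp(-V/V0)). Complex concentration from the positive root of the
# 1:1 mass balance; per-injection heat differences the complex held in the
# cell plus a trapezoidal term for complex displaced during the injection.
# Returns kJ per mol of injectant.
.wiseman_heats <- function(volumes_uL, Kd, dH, N, cellConc, syringeConc,
                           cellVolume_mL) {
  v0 <- cellVolume_mL * 1e3                      # uL
  vcum <- cumsum(volumes_uL)
  dil <- exp(-c(0, vcum) / v0)
  P <- N * cellConc * dil                        # binding-site concentration
  L <- syringeConc * (1 - dil)
  b <- P + L + Kd
  C <- (b - sqrt(pmax(b * b - 4 * P * L, 0))) / 2  # complex, mol/L
  k <- length(volumes_uL)
  dC_cell <- v0 * (C[-1] - C[-(k + 1)])          # uL * mol/L
  displaced <- volumes_uL * (C[-1] + C[-(k + 1)]) / 2
  dH * (dC_cell + displaced) / (syringeConc * volumes_uL)
}

#' Generate synthetic ITC injection heats
#'
#' Simulates the integrated heats of a 1:1 (Wiseman) titration, accounting
#' for dilution of both species by the injected volume, and adds i.i.d.
#' Gaussian noise on the molar heats. With `mode = "power"` additionally
#' returns a synthetic power trace (exponential response pulses on a flat
#' baseline) suitable for [integrateThermogram()].
#'
#' @param spec An [ItcSimSpec-class].
#' @param mode `"heats"` (default) or `"power"`.
#' @param tau Instrument response time constant for power mode, s.
#' @param spacing Injection spacing for power mode, s.
#' @param dt Sampling interval for power mode, s.
#' @return For `"heats"`, an [InjectionSeries-class]. For `"power"`, a list
#'   with the series, a `trace` data.frame (`time` s, `power` uW) and
#'   `injectionTimes` (s).
#' @export
genItcInjections <- function(spec, mode = c("heats", "power"), tau = 8,
                             spacing = 150, dt = 0.5) {
  stopifnot(is(spec, "ItcSimSpec"))
  validObject(spec)
  mode <- match.arg(mode)
  set.seed(spec@seed)
  q <- .wiseman_heats(spec@injectionVolumes, spec@Kd, spec@dH, spec@N,
                      spec@cellConc, spec@syringeConc, spec@cellVolume)
  q <- q + stats::rnorm(length(q), 0, spec@noiseSD)
  series <- new("InjectionSeries", cellConc = spec@cellConc,
                syringeConc = spec@syringeConc, cellVolume = spec@cellVolume,
                temperature = 298.15,
                injections = data.frame(volume = spec@injectionVolumes,
                                        heat = q))
  if (mode == "heats") return(series)
  # Power mode: each injection's heat becomes an exponential pulse (uJ -> uW).
  nInj <- length(q)
  tEnd <- spacing * (nInj + 1)
  tm <- seq(0, tEnd, by = dt)
  inj_t <- spacing * seq_len(nInj)
  # molar heat (kJ/mol) -> absolute heat (uJ): kJ * 1e9 = uJ
  molInj <- spec@syringeConc * spec@injectionVolumes * 1e-6  # mol (uL -> L)
  qAbs <- q * molInj * 1e9                                   # uJ
  # smooth instrument response: p(t) = q * (t - t0)/tau^2 * exp(-(t - t0)/tau),
  # unit integral, zero at onset (keeps trapezoidal re-integration accurate)
  pw <- numeric(length(tm))
  for (i in seq_len(nInj)) {
    after <- tm > inj_t[i]
    dtq <- tm[after] - inj_t[i]
    pw[after] <- pw[after] + qAbs[i] * dtq / tau^2 * exp(-dtq / tau)
  }
  list(series = series, trace = data.frame(time = tm, power = pw),
       injectionTimes = inj_t)
}

#' Generate per-buffer observed enthalpies on a proton-linkage line
#'
#' Constructs one observed binding enthalpy per buffer from the linear
#' proton-linkage model dH_obs = dH_corrected + dnH * dH_ionization, plus
#' Gaussian noise: the synthetic counterpart of measuring the same binding
#' reaction in buffers of different ionization enthalpy.
#'
#' @param slope Generating proton uptake dnH (protons per binding event).
#' @param intercept Generating buffer-corrected enthalpy, kJ/mol.
#' @param dHIonization Buffer ionization enthalpies, kJ/mol (>= 2 distinct).
#' @param noiseSD Gaussian noise SD, kJ/mol.
#' @param seed Integer seed.
#' @param bufferNames Optional labels.
#' @return data.frame with columns `buffer`, `dHIonization`, `dHObserved`.
#' @examples
#' genBufferSeries(1.67, -53.3, c(3.60, 12.23, 20.04, 47.45), noiseSD = 0)
#' @export
genBufferSeries <- function(slope, intercept, dHIonization, noiseSD = 0,
                            seed = 1L, bufferNames = NULL) {
  if (length(dHIonization) < 2 || length(unique(dHIonization)) < 2)
    stop("need at least 2 buffers with distinct ionization enthalpies")
  set.seed(as.integer(seed))
  obs <- intercept + slope * dHIonization +
    stats::rnorm(length(dHIonization), 0, noiseSD)
  if (is.null(bufferNames))
    bufferNames <- sprintf("buffer%d", seq_along(dHIonization))
  data.frame(buffer = bufferNames, dHIonization = dHIonization,
             dHObserved = obs)
}

#' Construct a lambda-trajectory simulation specification
#'
#' Defaults emulate a constant-pH MD protocol of 17 pH replicas spanning
#' pH 2.5 to 10.5 in steps of 0.5, run in triplicate.
#'
#' @param truePKa Per-site ground-truth pKa (named or not).
#' @param pHGrid Strictly increasing pH replicas.
#' @param nFrames Frames per trajectory.
#' @param burnInFrames Leading frames flagged for discarding downstream.
#' @param switchRate Mean transitions per frame at the midpoint (0, 0.5].
#' @param nReplicas Independent replicas.
#' @param jitter Emission jitter amplitude in [0, 0.2]; 0 for pure {0,1}.
#' @param seed Integer seed.
#' @return A [LambdaSimSpec-class].
#' @export
lambdaSimSpec <- function(truePKa, pHGrid = seq(2.5, 10.5, by = 0.5),
                          nFrames = 10000L, burnInFrames = 0L,
                          switchRate = 0.05, nReplicas = 3L, jitter = 0,
                          seed = 1L) {
  new("LambdaSimSpec", truePKa = truePKa, pHGrid = pHGrid,
      nFrames = as.integer(nFrames), burnInFrames = as.integer(burnInFrames),
      switchRate = switchRate, nReplicas = as.integer(nReplicas),
      jitter = jitter, seed = as.integer(seed))
}

# One two-state chain: states 0 (protonated) / 1 (deprotonated), stationary
# P(deprot) = pi1, detailed-balance transition probabilities p01 = s*pi1,
# p10 = s*pi0 with s = 2*switchRate (mean transitions/frame = switchRate at
# the midpoint). The chain starts in its stationary distribution.
.lambda_chain <- function(n, pi1, s) {
  p01 <- s * pi1
  p10 <- s * (1 - pi1)
  x <- integer(n)
  x[1] <- as.integer(stats::runif(1) < pi1)
  u <- stats::runif(n - 1)
  for (t in 2:n) {
    x[t] <- if (x[t - 1] == 0L) {
      if (u[t - 1] < p01) 1L else 0L
    } else {
      if (u[t - 1] < p10) 0L else 1L
    }
  }
  x
}

#' Generate synthetic lambda trajectories
#'
#' For each site, pH replica and replicate run, simulates a two-state Markov
#' chain on {protonated, deprotonated} whose stationary deprotonated
#' probability is the Henderson-Hasselbalch value 1/(1 + 10^(pKa - pH)),
#' with detailed-balance switching at the requested mean rate. States are
#' emitted as lambda = 0/1, optionally with sub-threshold jitter confined to
#' [0, 0.2] and [0.8, 1] so downstream classification thresholds are
#' exercised without changing the assignments.
#'
#' @param spec A [LambdaSimSpec-class].
#' @return A [LambdaTrajectorySet-class].
#' @examples
#' trj <- genLambdaTrajectories(lambdaSimSpec(7.6, nFrames = 2000))
#' @export
genLambdaTrajectories <- function(spec) {
  stopifnot(is(spec, "LambdaSimSpec"))
  validObject(spec)
  set.seed(spec@seed)
  s <- 2 * spec@switchRate
  siteNames <- names(spec@truePKa)
  if (is.null(siteNames))
    siteNames <- sprintf("site%d", seq_along(spec@truePKa))
  lam <- vector("list", length(spec@truePKa))
  for (i in seq_along(spec@truePKa)) {
    pi1 <- 1 / (1 + 10^(spec@truePKa[i] - spec@pHGrid))
    reps <- vector("list", spec@nReplicas)
    for (r in seq_len(spec@nReplicas)) {
      m <- matrix(0, spec@nFrames, length(spec@pHGrid))
      for (k in seq_along(spec@pHGrid)) {
        x <- .lambda_chain(spec@nFrames, pi1[k], s)
        if (spec@jitter > 0) {
          j <- stats::runif(spec@nFrames, 0, spec@jitter)
          m[, k] <- abs(x - j)
        } else m[, k] <- x
      }
      reps[[r]] <- m
    }
    lam[[i]] <- reps
  }
  names(lam) <- siteNames
  new("LambdaTrajectorySet", sites = siteNames, pH = spec@pHGrid,
      burnIn = spec@burnInFrames, lambda = lam)
}

#' Apply a rigid motion plus Gaussian jitter to coordinates
#'
#' Rotates coordinates by ZYX Euler angles about their centroid, translates,
#' and adds isotropic Gaussian noise; the standard fixture for testing
#' superposition-based comparisons (rigid motions must leave the Kabsch RMSD
#' at zero).
#'
#' @param coords Numeric matrix (n x 3), Angstrom.
#' @param rotation Euler angles (z, y, x) in radians.
#' @param translation Length-3 translation vector, Angstrom.
#' @param noiseSD Isotropic Gaussian jitter SD, Angstrom.
#' @param seed Integer seed.
#' @return Numeric matrix (n x 3).
#' @export
genDisplacedStructure <- function(coords, rotation = c(0, 0, 0),
                                  translation = c(0, 0, 0), noiseSD = 0,
                                  seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  R <- .euler_rotation(rotation)
  ctr <- colMeans(coords)
  out <- sweep(coords, 2, ctr) %*% t(R)
  out <- sweep(out, 2, ctr + translation, `+`)
  if (noiseSD > 0) {
    set.seed(as.integer(seed))
    out <- out + matrix(stats::rnorm(length(out), 0, noiseSD), ncol = 3)
  }
  dimnames(out) <- dimnames(coords)
  out
}

.euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
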