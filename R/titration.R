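# Protonation-state titration: microstate Hamiltonian, exact enumeration,
# Metropolis Monte Carlo with paired moves for strongly coupled sites, the
# closed coupled-pair (diprotic acid) treatment, and the complex-vs-free
# titration chain.

# ionization sign vector: +1 acid (ionized = deprotonated), -1 base
.site_signs <- function(acid) ifelse(acid, 1, -1)

#' Microstate energy of a protonation configuration
#'
#' E(x) = sum_i x_i s_i ln(10) R T (pKa_intr,i - pH)
#'      + sum_(i<j) x_i x_j W[i, j],
#' where x_i = 1 denotes the ionized form of site i (deprotonated acid or
#' protonated base) and s_i = +1 for acids, -1 for bases. The all-neutral
#' state is the energy reference; at pH above an acid's pKa its ionized state
#' has negative energy.
#'
#' @param x Binary vector over sites (1 = ionized).
#' @param pH pH value.
#' @param pKaIntr Per-site intrinsic pKas.
#' @param W Interaction matrix, kJ/mol (zero diagonal, symmetric); `NULL`
#'   for independent sites.
#' @param acid Logical per site; default all acids.
#' @param temperature K.
#' @return Energy in kJ/mol.
#' @export
microstateEnergy <- function(x, pH, pKaIntr, W = NULL,
                             acid = rep(TRUE, length(pKaIntr)),
                             temperature = 298.15) {
  n <- length(pKaIntr)
  if (length(x) != n || length(acid) != n)
    stop("dimension mismatch between x, pKaIntr and acid")
  if (is.null(W)) W <- matrix(0, n, n)
  if (!all(dim(W) == n)) stop("dimension mismatch: W")
  s <- .site_signs(acid)
  sum(x * s * ln10RT(temperature) * (pKaIntr - pH)) +
    sum(W[upper.tri(W)] * (outer(x, x)[upper.tri(W)]))
}

# all 2^n microstates as an n-column 0/1 matrix
.microstates <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

.curve_from_mean_x <- function(meanX, seX, pH, acid, ids) {
  theta <- meanX
  theta[, acid] <- 1 - theta[, acid, drop = FALSE]  # acids: protonated = 1-x
  theta <- pmin(pmax(theta, 0), 1)
  new("TitrationCurve", pH = pH, theta = theta, nBound = rowSums(theta),
      mcSE = seX, siteIds = ids)
}

#' Exact titration by microstate enumeration
#'
#' Boltzmann-averages the ionization vector over all 2^n microstates at each
#' pH. Serves as the exact reference for [mcTitration()]; limited to 22
#' sites.
#'
#' @param pKaIntr Per-site intrinsic pKas (names become site ids).
#' @param W Interaction matrix, kJ/mol, or `NULL`.
#' @param pHGrid pH grid (default 0 to 14 in steps of 0.2).
#' @param acid Logical per site.
#' @param temperature K.
#' @return A [TitrationCurve-class] with zero Monte-Carlo SEs.
#' @examples
#' crv <- enumerateTitration(4.0, pHGrid = seq(2, 6, 0.5))
#' thetaProt(crv)[, 1]  # Henderson-Hasselbalch exactly
#' @export
enumerateTitration <- function(pKaIntr, W = NULL,
                               pHGrid = seq(0, 14, by = 0.2),
                               acid = rep(TRUE, length(pKaIntr)),
                               temperature = 298.15) {
  n <- length(pKaIntr)
  if (n > 22)
    stop("exact enumeration is limited to 22 sites; use mcTitration()")
  if (is.null(W)) W <- matrix(0, n, n)
  stopifnot(all(dim(W) == n))
  ids <- names(pKaIntr)
  if (is.null(ids)) ids <- sprintf("site%d", seq_len(n))
  s <- .site_signs(acid)
  X <- .microstates(n)
  RT <- .RGAS * temperature
  l10 <- ln10RT(temperature)
  Wterm <- rowSums((X %*% W) * X) / 2
  a <- as.vector(X %*% (s * l10 * pKaIntr))  # pH-independent part
  b <- as.vector(X %*% (s * l10))            # coefficient of -pH
  meanX <- matrix(0, length(pHGrid), n)
  for (p in seq_along(pHGrid)) {
    E <- a - pHGrid[p] * b + Wterm
    w <- exp(-(E - min(E)) / RT)
    meanX[p, ] <- colSums(X * w) / sum(w)
  }
  .curve_from_mean_x(meanX, matrix(0, length(pHGrid), n), pHGrid, acid, ids)
}

#' Monte Carlo titration
#'
#' Metropolis sampling over protonation microstates with single-site flips
#' plus paired flips for site pairs coupled by more than `pairThreshold` pK
#' units (the diprotic-acid regime); the first 10 percent of steps are
#' discarded as burn-in and standard errors come from batch means (>= 20
#' batches). Reproducible under `set.seed()` via the `seed` argument.
#'
#' @inheritParams enumerateTitration
#' @param steps Monte Carlo steps per pH point (default 1e7, >= 1e4).
#' @param seed Integer seed.
#' @param pairThreshold Coupling threshold for double moves, pK units.
#' @param burnIn Fraction of steps discarded.
#' @param nBatches Batches for the batch-means standard error.
#' @return A [TitrationCurve-class] with per-point Monte-Carlo SEs.
#' @export
mcTitration <- function(pKaIntr, W = NULL, pHGrid = seq(0, 14, by = 0.2),
                        acid = rep(TRUE, length(pKaIntr)), steps = 1e7,
                        seed = 1L, temperature = 298.15,
                        pairThreshold = 2.5, burnIn = 0.1, nBatches = 20L) {
  if (steps < 1e4) stop("steps must be >= 1e4")
  n <- length(pKaIntr)
  if (is.null(W)) W <- matrix(0, n, n)
  stopifnot(all(dim(W) == n))
  ids <- names(pKaIntr)
  if (is.null(ids)) ids <- sprintf("site%d", seq_len(n))
  s <- .site_signs(acid)
  l10 <- ln10RT(temperature)
  thr <- pairThreshold * l10
  pairs <- which(abs(W) > thr & upper.tri(W), arr.ind = TRUE)
  pairs <- matrix(as.integer(pairs - 1L), ncol = 2)  # 0-based for C++
  set.seed(as.integer(seed))
  meanX <- seX <- matrix(0, length(pHGrid), n)
  for (p in seq_along(pHGrid)) {
    dG <- s * l10 * (pKaIntr - pHGrid[p])
    res <- .mc_titrate_cpp(dG, W, pairs, steps, burnIn,
                           as.integer(nBatches), .RGAS * temperature)
    meanX[p, ] <- res$mean_x
    seX[p, ] <- res$se_x
  }
  .curve_from_mean_x(meanX, seX, pHGrid, acid, ids)
}

#' Apparent pKas of an electrostatically coupled acid pair
#'
#' Treats two coupled acidic sites as one diprotic acid (the catalytic-dyad
#' situation) and extracts the two macroscopic pKas from the four-microstate
#' partition function: the low pKa is the pH at which the singly deprotonated
#' population equals the fully protonated one, the high pKa where the doubly
#' deprotonated population equals the singly deprotonated one; both located
#' by bisection to 1e-6 pH. For two identical independent sites (w = 0) this
#' reproduces the statistical-factor splitting of +/- log10(2); for strong
#' coupling the splitting approaches |pK2 - pK1| + w / (ln(10) R T).
#'
#' @param pK1,pK2 Intrinsic pKas of the two (acidic) sites.
#' @param w Interaction energy between the ionized forms, kJ/mol (>= 0 for
#'   like-charged acids; a strongly negative w, attraction between like
#'   charges, is flagged as invalid).
#' @param temperature K.
#' @return Named numeric: `pKaAppLow`, `pKaAppHigh`.
#' @examples
#' coupledPairApparentPKas(4, 4, 0)  # c(3.699, 4.301)
#' @export
coupledPairApparentPKas <- function(pK1, pK2, w, temperature = 298.15) {
  l10 <- ln10RT(temperature)
  RT <- .RGAS * temperature
  # Boltzmann weights of the 4 microstates relative to the fully protonated
  # state: p00 = 1, p10, p01 (one site ionized), p11 (both, paying w)
  logw <- function(pH) {
    g10 <- -l10 * (pK1 - pH) / RT
    g01 <- -l10 * (pK2 - pH) / RT
    c(p00 = 0, p10 = g10, p01 = g01, p11 = g10 + g01 - w / RT)
  }
  f_low <- function(pH) { # log(singly) - log(p00), crossing 0
    lw <- logw(pH)
    max(lw["p10"], lw["p01"]) + log1p(exp(-abs(lw["p10"] - lw["p01"]))) -
      lw["p00"]
  }
  f_high <- function(pH) {
    lw <- logw(pH)
    lw["p11"] -
      (max(lw["p10"], lw["p01"]) + log1p(exp(-abs(lw["p10"] - lw["p01"]))))
  }
  lo <- min(pK1, pK2) - abs(w) / l10 - 20
  hi <- max(pK1, pK2) + abs(w) / l10 + 20
  pk_low <- stats::uniroot(f_low, c(lo, hi), tol = 1e-7)$root
  pk_high <- stats::uniroot(f_high, c(lo, hi), tol = 1e-7)$root
  if (pk_high < pk_low)
    stop("invalid input: w is so negative (attraction between like charges)",
         " that the apparent pKas cross")
  c(pKaAppLow = pk_low, pKaAppHigh = pk_high)
}

# pH at which a site's protonated fraction crosses 0.5 (linear interpolation
# on the grid); NA when the curve never crosses
.pka_half <- function(pH, theta) {
  above <- theta >= 0.5
  if (all(above) || all(!above)) return(NA_real_)
  k <- which(diff(above) != 0)[1]
  t1 <- theta[k]; t2 <- theta[k + 1]
  pH[k] + (0.5 - t1) * (pH[k + 1] - pH[k]) / (t2 - t1)
}

#' Half-protonation points of a titration curve
#'
#' @param curve A [TitrationCurve-class].
#' @return Named numeric: pH at which each site's protonated fraction crosses
#'   0.5 (`NA` if it never does on the grid).
#' @export
pKaHalf <- function(curve) {
  stopifnot(is(curve, "TitrationCurve"))
  out <- vapply(seq_along(curve@siteIds),
                function(j) .pka_half(curve@pH, curve@theta[, j]), numeric(1))
  names(out) <- curve@siteIds
  out
}

# full electrostatics + titration chain for one system
.titrate_system <- function(system, grid, params, pHGrid, mode, backend,
                            steps, seed, geometry = NULL) {
  ns <- length(system@sites)
  acid <- vapply(system@sites, `[[`, TRUE, "acid")
  ids <- vapply(system@sites, `[[`, "", "id")
  pka <- numeric(ns)
  if (backend == "fd" && is.null(geometry)) {
    allpos <- as.matrix(system@atoms[, c("x", "y", "z")])
    geometry <- .grid_geometry(grid, allpos, allpos,
                               center = colMeans(allpos))
  }
  for (i in seq_len(ns)) {
    en <- if (backend == "fd")
      .site_energies_geom(system, system@sites[[i]], grid, params, geometry)
    else siteEnergies(system, system@sites[[i]], grid, params, backend)
    pka[i] <- intrinsicPKa(system@sites[[i]], en, params)
  }
  names(pka) <- ids
  W <- if (ns >= 2) interactionMatrix(system, grid, params, backend)
       else matrix(0, ns, ns)
  curve <- if (mode == "enumerate")
    enumerateTitration(pka, W, pHGrid, acid, params@temperature)
  else mcTitration(pka, W, pHGrid, acid, steps = steps, seed = seed,
                   temperature = params@temperature)
  list(curve = curve, pKaIntr = pka, W = W)
}

# like siteEnergies(backend = "fd") but on a caller-fixed grid geometry so
# complex and free solves difference on identical grids
.site_energies_geom <- function(system, site, grid, params, geometry) {
  dq <- .site_delta_charges(system, site)
  bg_idx <- setdiff(seq_len(nrow(system@atoms)), site$atomIdx)
  bg <- system@atoms[bg_idx, c("x", "y", "z", "charge")]
  names(bg)[4] <- "q"
  bg <- bg[bg$q != 0, , drop = FALSE]
  f_prot <- solveLPBE(system, dq, grid, params, geometry = geometry)
  model <- system@atoms[site$atomIdx, , drop = FALSE]
  f_model <- solveLPBE(model, dq, grid, params, geometry = geometry)
  at_site <- as.matrix(dq[, c("x", "y", "z")])
  desolv <- 0.5 * (sum(dq$q * potentialAt(f_prot, at_site)) -
                   sum(dq$q * potentialAt(f_model, at_site)))
  backg <- if (nrow(bg)) sum(bg$q * potentialAt(f_prot, bg[, 1:3])) else 0
  list(desolvation = desolv, background = backg)
}

#' Titrate a complex and its ligand-free form on identical grids
#'
#' Runs the full electrostatics-plus-titration chain (site energies,
#' intrinsic pKas, interaction matrix, titration curve) on the complex and on
#' the free system with identical grid placement, so that curve differences
#' isolate the ligand's effect. By default the free system is derived from
#' the complex by deleting its ligand atoms and sites.
#'
#' @param systemComplex A [TitratableSiteSystem-class] whose ligand atoms are
#'   flagged in `atoms(system)$ligand` / site `$ligand`.
#' @param systemFree Optional explicit free system (must share site ordering
#'   for the retained sites); default: complex minus ligand.
#' @param grid,params Grid and electrostatics parameters.
#' @param pHGrid pH grid.
#' @param mode `"enumerate"` or `"mc"`.
#' @param backend `"fd"` or `"coulomb"`.
#' @param steps,seed Monte Carlo controls for `mode = "mc"`.
#' @return List with elements `complex` and `free` (each: `curve`, `pKaIntr`,
#'   `W`).
#' @export
titrateComplexAndFree <- function(systemComplex, systemFree = NULL,
                                  grid = gridSpec(), params = electroParams(),
                                  pHGrid = seq(0, 14, by = 0.2),
                                  mode = c("enumerate", "mc"),
                                  backend = c("fd", "coulomb"),
                                  steps = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (is.null(systemFree)) systemFree <- removeLigand(systemComplex)
  idsC <- vapply(systemComplex@sites, `[[`, "", "id")
  idsF <- vapply(systemFree@sites, `[[`, "", "id")
  if (!identical(idsF, idsC[idsC %in% idsF]))
    stop("site-ordering mismatch between complex and free systems")
  geometry <- NULL
  if (backend == "fd") {
    allpos <- as.matrix(systemComplex@atoms[, c("x", "y", "z")])
    geometry <- .grid_geometry(grid, allpos, allpos,
                               center = colMeans(allpos))
  }
  list(complex = .titrate_system(systemComplex, grid, params, pHGrid, mode,
                                 backend, steps, seed, geometry),
       free = .titrate_system(systemFree, grid, params, pHGrid, mode,
                              backend, steps, seed + 1L, geometry))
}

#' Delete the ligand from a titratable-site system
#'
#' Drops atoms flagged `ligand` and any site flagged `ligand`, reindexing the
#' remaining sites' atom references.
#'
#' @param system A [TitratableSiteSystem-class].
#' @return A [TitratableSiteSystem-class].
#' @export
removeLigand <- function(system) {
  keep <- !system@atoms$ligand
  map <- cumsum(keep)
  st <- Filter(function(s) !isTRUE(s$ligand), system@sites)
  st <- lapply(st, function(s) {
    if (any(!keep[s$atomIdx]))
      stop("site ", s$id, " references ligand atoms")
    s$atomIdx <- map[s$atomIdx]
    s
  })
  new("TitratableSiteSystem", atoms = system@atoms[keep, , drop = FALSE],
      sites = st)
}
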