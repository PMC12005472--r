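# Continuum electrostatics: grid/parameter containers, the FD-LPBE solver
# front end with focusing, per-site energy decomposition, intrinsic pKas and
# the site-site interaction matrix. An analytic screened-Coulomb backend is
# available both as a fast fallback and as the oracle in uniform dielectrics.

#' Finite-difference grid specification
#'
#' @slot spacing Finest grid spacing, Angstrom.
#' @slot extent Cubic box edge length at the coarsest level, Angstrom
#'   (`NA` = automatic: system bounding box plus a 5 Angstrom margin).
#' @slot focusLevels Number of focusing levels (1 = single grid); each level
#'   halves the box edge about the focus center and interpolates its boundary
#'   potential from the parent level.
#' @slot boundary `"dh"` (Debye-Hueckel potential of the source charges) or
#'   `"zero"` at the coarsest boundary.
#' @export
setClass("GridSpec", representation(
  spacing = "numeric", extent = "numeric", focusLevels = "integer",
  boundary = "character"
), validity = function(object) {
  msg <- character()
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (object@focusLevels < 1L) msg <- c(msg, "focusLevels must be >= 1")
  if (!object@boundary %in% c("dh", "zero"))
    msg <- c(msg, "boundary must be 'dh' or 'zero'")
  if (length(msg)) msg else TRUE
})

#' @rdname GridSpec-class
#' @param spacing,extent,focusLevels,boundary See slots.
#' @return A `GridSpec`.
#' @export
gridSpec <- function(spacing = 0.5, extent = NA_real_, focusLevels = 2L,
                     boundary = c("dh", "zero")) {
  new("GridSpec", spacing = spacing, extent = as.numeric(extent),
      focusLevels = as.integer(focusLevels), boundary = match.arg(boundary))
}

#' Continuum-electrostatics parameters
#'
#' Defaults follow the protocol used for aspartic-protease pKa work: internal
#' dielectric 15, solvent dielectric 80, ionic strength 0.05 M, 298.15 K.
#'
#' @slot epsInternal Dielectric constant of the molecular region.
#' @slot epsSolvent Solvent dielectric constant.
#' @slot ionicStrength mol/L (1:1 electrolyte).
#' @slot temperature K.
#' @export
setClass("ElectroParams", representation(
  epsInternal = "numeric", epsSolvent = "numeric", ionicStrength = "numeric",
  temperature = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@epsInternal < 1 || object@epsSolvent < 1)
    msg <- c(msg, "dielectric constants must be >= 1")
  if (object@ionicStrength < 0) msg <- c(msg, "ionic strength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ElectroParams-class
#' @param epsInternal,epsSolvent,ionicStrength,temperature See slots.
#' @return An `ElectroParams`.
#' @export
electroParams <- function(epsInternal = 15, epsSolvent = 80,
                          ionicStrength = 0.05, temperature = 298.15) {
  new("ElectroParams", epsInternal = epsInternal, epsSolvent = epsSolvent,
      ionicStrength = ionicStrength, temperature = temperature)
}

# Grid geometry shared between solves that must cancel grid artifacts:
# list of levels, each with origin, dims, spacing. Cubic boxes; each focus
# level halves the edge about `center` while staying inside its parent.
.grid_geometry <- function(grid, atoms_xyz, charges_xyz, center = NULL) {
  pts <- rbind(atoms_xyz, charges_xyz)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (is.na(grid@extent)) {
    edge <- max(hi - lo) + 10  # 5 A margin each side at the coarsest level
  } else {
    edge <- grid@extent
    if (edge < max(hi - lo) + 10)
      stop("grid extent must enclose the system plus a 5 Angstrom margin")
  }
  box_c <- (lo + hi) / 2
  if (is.null(center)) center <- colMeans(charges_xyz)
  L <- grid@focusLevels
  levels <- vector("list", L)
  for (l in seq_len(L)) {
    sp <- grid@spacing * 2^(L - l)
    e_l <- edge / 2^(l - 1)
    c_l <- if (l == 1) box_c else center
    if (l > 1) {
      # keep the focused box inside its parent
      par <- levels[[l - 1]]
      pl <- par$origin; ph <- par$origin + (par$dims - 1) * par$spacing
      c_l <- pmin(pmax(c_l, pl + e_l / 2), ph - e_l / 2)
    }
    nn <- ceiling(e_l / sp) + 1
    levels[[l]] <- list(origin = c_l - (nn - 1) * sp / 2,
                        dims = as.integer(rep(nn, 3)), spacing = sp)
  }
  levels
}

# trilinear interpolation of a gridded field at points (n x 3)
.interp_grid <- function(phi, origin, spacing, pts) {
  d <- dim(phi)
  g <- sweep(pts, 2, origin) / spacing
  i0 <- pmin(pmax(floor(g[, 1]), 0), d[1] - 2)
  j0 <- pmin(pmax(floor(g[, 2]), 0), d[2] - 2)
  k0 <- pmin(pmax(floor(g[, 3]), 0), d[3] - 2)
  fx <- g[, 1] - i0; fy <- g[, 2] - j0; fz <- g[, 3] - k0
  out <- numeric(nrow(pts))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
      (if (dk) fz else 1 - fz)
    out <- out + w * phi[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  out
}

#' Solved electrostatic potential field
#'
#' Multilevel (focused) finite-difference solution; query with
#' [potentialAt()].
#'
#' @slot levels List of levels (`phi` array, `origin`, `spacing`, `dims`),
#'   coarsest first.
#' @slot params The [ElectroParams-class] used.
#' @export
setClass("LPBEField", representation(levels = "list", params = "ElectroParams"))

setMethod("show", "LPBEField", function(object) {
  cat(sprintf("LPBEField: %d level(s)\n", length(object@levels)))
  for (l in object@levels)
    cat(sprintf("  %dx%dx%d at h = %.3g A\n", l$dims[1], l$dims[2], l$dims[3],
                l$spacing))
})

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Seven-point finite-difference solution with two dielectric regions (the
#' van-der-Waals union of the system's atom spheres at `epsInternal`, solvent
#' at `epsSolvent`), Debye screening from the ionic strength outside the
#' molecular region, trilinear charge spreading and successive
#' over-relaxation to a maximum residual below `tol` of the source norm.
#' Focusing levels refine the solution around `center` with boundary values
#' interpolated from the parent level.
#'
#' @param system A [TitratableSiteSystem-class] providing the dielectric
#'   boundary (its atoms' positions and radii).
#' @param charges Matrix or data.frame with columns `x`, `y`, `z`, `q`: the
#'   source charges (need not coincide with system atoms).
#' @param grid A [GridSpec-class].
#' @param params An [ElectroParams-class].
#' @param center Focus center (default: centroid of the source charges).
#' @param tol Convergence tolerance relative to the source norm.
#' @param maxit Maximum SOR sweeps per level.
#' @param omega Over-relaxation factor.
#' @param geometry Optional precomputed geometry (internal; guarantees
#'   identical grids across solves whose energies are differenced).
#' @return An [LPBEField-class].
#' @export
solveLPBE <- function(system, charges, grid = gridSpec(),
                      params = electroParams(), center = NULL, tol = 1e-6,
                      maxit = 20000L, omega = 1.9, geometry = NULL) {
  at <- if (is(system, "TitratableSiteSystem")) system@atoms else system
  atoms_m <- as.matrix(at[, c("x", "y", "z", "radius")])
  ch <- as.matrix(as.data.frame(charges)[, c("x", "y", "z", "q")])
  if (is.null(geometry))
    geometry <- .grid_geometry(grid, atoms_m[, 1:3, drop = FALSE],
                               ch[, 1:3, drop = FALSE], center)
  kap2 <- .kappa2(params@ionicStrength, params@epsSolvent,
                  params@temperature)
  bmode <- if (grid@boundary == "dh") 1L else 0L
  levels <- vector("list", length(geometry))
  for (l in seq_along(geometry)) {
    gm <- geometry[[l]]
    bphi <- numeric(0)
    if (l > 1) {
      # boundary values interpolated from the parent solution
      prev <- levels[[l - 1]]
      nn <- gm$dims
      ii <- as.matrix(expand.grid(i = 0:(nn[1] - 1), j = 0:(nn[2] - 1),
                                  k = 0:(nn[3] - 1)))
      pts <- sweep(ii * gm$spacing, 2, gm$origin, `+`)
      bphi <- .interp_grid(prev$phi, prev$origin, prev$spacing, pts)
    }
    sol <- .lpbe_solve_cpp(atoms_m, ch, gm$origin, gm$dims, gm$spacing,
                           params@epsInternal, params@epsSolvent, kap2,
                           bmode, bphi, omega, tol, as.integer(maxit))
    levels[[l]] <- list(phi = sol$phi, origin = gm$origin,
                        spacing = gm$spacing, dims = gm$dims)
  }
  new("LPBEField", levels = levels, params = params)
}

#' Evaluate a solved potential at points
#'
#' Uses the finest focusing level that contains each point (with a one-cell
#' margin), falling back to coarser levels outside the focus region.
#'
#' @param field An [LPBEField-class].
#' @param pts Matrix (n x 3) or data.frame with `x`, `y`, `z`.
#' @return Potential values, kJ/mol/e.
#' @export
potentialAt <- function(field, pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y", "z")])
  pts <- matrix(as.numeric(pts), ncol = 3)
  out <- rep(NA_real_, nrow(pts))
  for (l in rev(seq_along(field@levels))) {
    lv <- field@levels[[l]]
    lo <- lv$origin + lv$spacing
    hi <- lv$origin + (lv$dims - 1 - 1) * lv$spacing
    ok <- is.na(out) &
      pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    if (any(ok))
      out[ok] <- .interp_grid(lv$phi, lv$origin, lv$spacing,
                              pts[ok, , drop = FALSE])
  }
  if (anyNA(out)) stop("point(s) outside the coarsest grid")
  out
}

# ionized-minus-neutral charge difference of a site, as an x/y/z/q table
.site_delta_charges <- function(system, site) {
  pos <- system@atoms[site$atomIdx, c("x", "y", "z"), drop = FALSE]
  dq <- if (site$acid) site$qDeprot - site$qProt else site$qProt - site$qDeprot
  data.frame(pos, q = dq)
}

.get_site <- function(system, site) {
  if (is.list(site)) return(site)
  ids <- vapply(system@sites, `[[`, "", "id")
  hit <- if (is.character(site)) match(site, ids) else as.integer(site)
  if (is.na(hit) || hit < 1 || hit > length(system@sites))
    stop("unknown site: ", site)
  system@sites[[hit]]
}

#' Desolvation and background energies of a titratable site
#'
#' Decomposes the electrostatic work of ionizing a site into (i) the
#' desolvation penalty: the difference in charging free energy of the site's
#' ionized-minus-neutral charge difference between the full molecular
#' dielectric environment and an isolated model compound (the site's atoms
#' alone in solvent), both on identical grids so that grid self-energy
#' cancels; and (ii) the background term: the interaction of that charge
#' difference with all static charges outside the site.
#'
#' @param system A [TitratableSiteSystem-class].
#' @param site Site id, index, or site list.
#' @param grid A [GridSpec-class].
#' @param params An [ElectroParams-class].
#' @param backend `"fd"` (finite difference) or `"coulomb"` (analytic
#'   screened Coulomb in a uniform `epsSolvent` dielectric; desolvation is
#'   zero by construction there).
#' @return List with `desolvation` and `background`, kJ/mol.
#' @export
siteEnergies <- function(system, site, grid = gridSpec(),
                         params = electroParams(),
                         backend = c("fd", "coulomb")) {
  backend <- match.arg(backend)
  site <- .get_site(system, site)
  dq <- .site_delta_charges(system, site)
  bg_idx <- setdiff(seq_len(nrow(system@atoms)), site$atomIdx)
  bg <- system@atoms[bg_idx, c("x", "y", "z", "charge")]
  names(bg)[4] <- "q"
  bg <- bg[bg$q != 0, , drop = FALSE]
  if (backend == "coulomb") {
    kap <- sqrt(.kappa2(params@ionicStrength, params@epsSolvent,
                        params@temperature))
    return(list(desolvation = 0,
                background = .screened_coulomb_cross(dq, bg, params, kap)))
  }
  geom <- .grid_geometry(grid, as.matrix(system@atoms[, c("x", "y", "z")]),
                         as.matrix(dq[, c("x", "y", "z")]),
                         center = colMeans(dq[, c("x", "y", "z")]))
  f_prot <- solveLPBE(system, dq, grid, params, geometry = geom)
  model <- system@atoms[site$atomIdx, , drop = FALSE]
  f_model <- solveLPBE(model, dq, grid, params, geometry = geom)
  at_site <- as.matrix(dq[, c("x", "y", "z")])
  desolv <- 0.5 * (sum(dq$q * potentialAt(f_prot, at_site)) -
                   sum(dq$q * potentialAt(f_model, at_site)))
  backg <- if (nrow(bg)) sum(bg$q * potentialAt(f_prot, bg[, 1:3])) else 0
  list(desolvation = desolv, background = backg)
}

.screened_coulomb_cross <- function(a, b, params, kappa) {
  if (!nrow(a) || !nrow(b)) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    r <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2 + (b$z - a$z[i])^2)
    tot <- tot + sum(.KCOUL * a$q[i] * b$q * exp(-kappa * r) /
                       (params@epsSolvent * r))
  }
  tot
}

#' Intrinsic pKa from the energy decomposition
#'
#' pKa_intr = pKa_ref + s * (desolvation + background) / (ln(10) R T), with
#' s = +1 for acids (a positive energy cost of ionization raises the pKa)
#' and s = -1 for bases.
#'
#' @param site A site list (see [TitratableSiteSystem-class]) or a residue
#'   class name; for a class name the built-in reference pKa is used.
#' @param energies List with `desolvation` and `background` (kJ/mol), as
#'   returned by [siteEnergies()].
#' @param params An [ElectroParams-class] (temperature).
#' @return Intrinsic pKa.
#' @examples
#' intrinsicPKa("Asp", list(desolvation = 0, background = 0))      # 4.0
#' intrinsicPKa("Asp", list(desolvation = 5.708, background = 0))  # 5.0
#' @export
intrinsicPKa <- function(site, energies, params = electroParams()) {
  if (is.character(site)) {
    if (!site %in% names(.REF_PKA)) stop("unknown residue class: ", site)
    site <- list(pkaRef = .REF_PKA[[site]], acid = .IS_ACID[[site]])
  }
  s <- if (site$acid) 1 else -1
  site$pkaRef + s * (energies$desolvation + energies$background) /
    ln10RT(params@temperature)
}

#' Site-site interaction matrix
#'
#' W[i, j] is the interaction energy between the ionized-minus-neutral charge
#' differences of sites i and j: the potential generated by site j's charge
#' difference, evaluated on site i's. Symmetrized by averaging the two
#' orderings; zero diagonal.
#'
#' @param system A [TitratableSiteSystem-class] with >= 2 sites.
#' @param grid A [GridSpec-class].
#' @param params An [ElectroParams-class].
#' @param backend `"fd"` or `"coulomb"` (analytic screened Coulomb in a
#'   uniform `epsSolvent` dielectric; also the fast fallback).
#' @return Symmetric numeric matrix (kJ/mol) with site ids as dimnames.
#' @export
interactionMatrix <- function(system, grid = gridSpec(),
                              params = electroParams(),
                              backend = c("fd", "coulomb")) {
  backend <- match.arg(backend)
  ns <- length(system@sites)
  if (ns < 2) stop("need at least 2 sites")
  ids <- vapply(system@sites, `[[`, "", "id")
  W <- matrix(0, ns, ns, dimnames = list(ids, ids))
  dqs <- lapply(system@sites, function(s) .site_delta_charges(system, s))
  if (backend == "coulomb") {
    kap <- sqrt(.kappa2(params@ionicStrength, params@epsSolvent,
                        params@temperature))
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
      W[i, j] <- W[j, i] <- .screened_coulomb_cross(dqs[[i]], dqs[[j]],
                                                    params, kap)
    return(W)
  }
  allpos <- as.matrix(system@atoms[, c("x", "y", "z")])
  geom <- .grid_geometry(grid, allpos, allpos, center = colMeans(allpos))
  for (i in seq_len(ns)) {
    f_i <- solveLPBE(system, dqs[[i]], grid, params, geometry = geom)
    for (j in seq_len(ns)) {
      if (i == j) next
      W[j, i] <- sum(dqs[[j]]$q *
                       potentialAt(f_i, dqs[[j]][, c("x", "y", "z")]))
    }
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}
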