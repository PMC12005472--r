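# FD-LPBE solver against analytic oracles: Coulomb, Born, screened-Coulomb
# interactions, intrinsic-pKa arithmetic.

test_that("uniform-dielectric potential matches Coulomb within 2%", {
  sys <- new("TitratableSiteSystem",
             atoms = data.frame(x = 0, y = 0, z = 0, radius = 1e-6,
                                charge = 1, ligand = FALSE),
             sites = list())
  prm <- electroParams(epsInternal = 80, epsSolvent = 80, ionicStrength = 0)
  grd <- gridSpec(spacing = 0.5, extent = 32, focusLevels = 2)
  fld <- solveLPBE(sys, charges = data.frame(x = 0, y = 0, z = 0, q = 1),
                   grid = grd, params = prm)
  r <- seq(4, 10, 1)
  phi <- potentialAt(fld, cbind(r, 0, 0))
  exact <- 1389.35 / (80 * r)
  expect_lt(max(abs(phi - exact) / exact), 0.02)
})

test_that("zero charges give an identically zero potential", {
  sys <- new("TitratableSiteSystem",
             atoms = data.frame(x = 0, y = 0, z = 0, radius = 2,
                                charge = 0, ligand = FALSE),
             sites = list())
  fld <- solveLPBE(sys, charges = data.frame(x = 0, y = 0, z = 0, q = 0),
                   grid = gridSpec(spacing = 1, extent = 20),
                   params = electroParams())
  expect_equal(max(abs(fld@levels[[length(fld@levels)]]$phi)), 0)
})

test_that("superposition holds for the linearized solver", {
  at <- data.frame(x = c(-2, 2), y = 0, z = 0, radius = 1e-6,
                   charge = c(1, 1), ligand = FALSE)
  sys <- new("TitratableSiteSystem", atoms = at, sites = list())
  prm <- electroParams(epsInternal = 80, epsSolvent = 80, ionicStrength = 0.05)
  grd <- gridSpec(spacing = 0.5, extent = 24, focusLevels = 1)
  geo <- protlink:::.grid_geometry(grd, as.matrix(at[, 1:3]),
                                   as.matrix(at[, 1:3]), c(0, 0, 0))
  chg <- function(q) data.frame(x = at$x, y = at$y, z = at$z, q = q)
  f12 <- solveLPBE(sys, chg(c(1, 1)), grd, prm, geometry = geo)
  f1 <- solveLPBE(sys, chg(c(1, 0)), grd, prm, geometry = geo)
  f2 <- solveLPBE(sys, chg(c(0, 1)), grd, prm, geometry = geo)
  pts <- cbind(c(0, 1, 4), c(3, -2, 2), 0)
  expect_equal(potentialAt(f12, pts),
               potentialAt(f1, pts) + potentialAt(f2, pts),
               tolerance = 1e-4)
})

test_that("Born self-energy is within 5% of the analytic value, converging", {
  sys <- new("TitratableSiteSystem",
             atoms = data.frame(x = 0, y = 0, z = 0, radius = 2,
                                charge = 1, ligand = FALSE),
             sites = list())
  exact <- 0.5 * 1389.35 / 2 * (1 / 80 - 1 / 4)  # -82.49 kJ/mol
  born <- function(h) {
    grd <- gridSpec(spacing = h, extent = 24, focusLevels = 2)
    geo <- protlink:::.grid_geometry(grd, matrix(0, 1, 3), matrix(0, 1, 3),
                                     c(0, 0, 0))
    prmIn <- electroParams(epsInternal = 4, epsSolvent = 80,
                           ionicStrength = 0)
    prmRef <- electroParams(epsInternal = 4, epsSolvent = 4,
                            ionicStrength = 0)
    q1 <- data.frame(x = 0, y = 0, z = 0, q = 1)
    fI <- solveLPBE(sys, q1, grd, prmIn, geometry = geo)
    fR <- solveLPBE(sys, q1, grd, prmRef, geometry = geo)
    0.5 * (potentialAt(fI, matrix(0, 1, 3)) -
             potentialAt(fR, matrix(0, 1, 3)))
  }
  e05 <- born(0.5)
  expect_lt(abs(e05 - exact) / abs(exact), 0.05)
  e025 <- born(0.25)
  expect_lt(abs(e025 - e05) / abs(e05), 0.03)  # grid-halving convergence
})

test_that("isolated model compound has zero desolvation and background", {
  sys <- genToySites(toySystemSpec(1, "line", siteTypes = "Asp"))
  en <- siteEnergies(sys, 1, gridSpec(spacing = 0.6, focusLevels = 2),
                     electroParams(), backend = "fd")
  expect_equal(en$desolvation, 0, tolerance = 1e-6)
  expect_equal(en$background, 0, tolerance = 1e-6)
})

test_that("background energy follows the Coulomb oracle and 1/r scaling", {
  prm <- electroParams(ionicStrength = 0)
  grd <- gridSpec(spacing = 0.6, focusLevels = 2)
  bgAt <- function(d) {
    sys <- genToySites(toySystemSpec(
      1, "line", siteTypes = "Asp",
      backgroundCharges = data.frame(x = d, y = 0, z = 0, q = -1)))
    siteEnergies(sys, 1, grd, prm, backend = "coulomb")$background
  }
  e5 <- bgAt(5)
  expect_gt(e5, 0)
  expect_lt(abs(e5 - 1389.35 / (80 * 5)) / (1389.35 / (80 * 5)), 0.05)
  expect_equal(bgAt(10), e5 / 2, tolerance = 0.05)
})

test_that("intrinsic pKa arithmetic follows the stated convention", {
  asp <- list(id = "Asp1", class = "Asp", pkaRef = 4, acid = TRUE)
  lys <- list(id = "Lys1", class = "Lys", pkaRef = 10.4, acid = FALSE)
  expect_equal(intrinsicPKa(asp, list(desolvation = 0, background = 0),
                            electroParams()), 4)
  expect_equal(intrinsicPKa(asp, list(desolvation = 5.708, background = 0),
                            electroParams()), 5, tolerance = 1e-4)
  expect_equal(intrinsicPKa(lys, list(desolvation = 0, background = 5.708),
                            electroParams()), 9.4, tolerance = 1e-4)
})

test_that("interaction matrix matches the Coulomb oracle and decays", {
  prm <- electroParams(epsInternal = 15, epsSolvent = 15, ionicStrength = 0)
  sys <- genToySites(toySystemSpec(2, "pair", distance = 3),
                     siteRadius = 1e-6)
  grd <- gridSpec(spacing = 0.5, extent = 30, focusLevels = 3)
  W <- interactionMatrix(sys, grd, prm, backend = "fd")
  expect_lt(abs(W[1, 2] - 1389.35 / (15 * 3)) / (1389.35 / (15 * 3)), 0.05)
  expect_equal(unname(diag(W)), c(0, 0))
  expect_lt(abs(W[1, 2] - W[2, 1]), 1e-6)
  # screened decay at 50 A with 0.05 M ions
  sysFar <- genToySites(toySystemSpec(2, "pair", distance = 50))
  Wfar <- interactionMatrix(sysFar, grd, electroParams(),
                            backend = "coulomb")
  expect_lt(abs(Wfar[1, 2]), 0.5)
})
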