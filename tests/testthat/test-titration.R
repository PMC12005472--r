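# Titration engine: microstate energies, exact enumeration, Monte Carlo
# sampling, the coupled diprotic pair, complex-vs-free pipeline.

test_that("microstate energies follow the stated Hamiltonian", {
  expect_equal(microstateEnergy(c(0, 0), 7, c(4, 6), acid = c(TRUE, TRUE)), 0)
  expect_equal(microstateEnergy(1, 5, 5, acid = TRUE), 0)
  expect_equal(microstateEnergy(1, 6, 5, acid = TRUE), -ln10RT(),
               tolerance = 1e-9)
  expect_equal(ln10RT(), 5.708, tolerance = 1e-4)
  expect_error(microstateEnergy(c(1, 0), 7, 4, acid = TRUE), "dimension")
})

test_that("single-site enumeration is exactly Henderson-Hasselbalch", {
  crv <- enumerateTitration(4.5, pHGrid = seq(0, 14, 0.2))
  expect_equal(thetaProt(crv)[, 1], hhFraction(4.5, pHGrid(crv)),
               tolerance = 1e-14)
  expect_equal(unname(mcSE(crv)[1, 1]), 0)
})

test_that("uncoupled identical acids titrate independently", {
  crv <- enumerateTitration(c(4, 4), matrix(0, 2, 2), seq(2, 7, 0.5))
  th <- thetaProt(crv)
  expect_equal(th[, 1], th[, 2], tolerance = 1e-12)
  expect_equal(th[, 1], hhFraction(4, pHGrid(crv)), tolerance = 1e-12)
})

test_that("n_bound is non-increasing in pH for random coupled systems", {
  for (s in 1:5) {
    p <- randomSiteParams(6, seed = s)
    crv <- enumerateTitration(p$pka, p$W, seq(0, 14, 0.1), p$acid)
    expect_true(all(diff(nBound(crv)) <= 1e-10))
  }
})

test_that("enumeration rejects oversized systems", {
  expect_error(enumerateTitration(rep(4, 23), pHGrid = 7), "mcTitration")
})

test_that("MC agrees with enumeration within 3 SE on random systems", {
  for (s in c(3, 17)) {
    p <- randomSiteParams(8, seed = s)
    ph <- seq(2, 12, 1)
    en <- enumerateTitration(p$pka, p$W, ph, p$acid)
    mc <- mcTitration(p$pka, p$W, ph, p$acid, steps = 4e5, seed = s)
    dev <- abs(thetaProt(mc) - thetaProt(en))
    # a small absolute floor covers saturated points where the chain never
    # flips and the batch-means SE collapses to zero
    expect_true(all(dev <= 3 * mcSE(mc) + 0.004))
  }
})

test_that("single-site MC matches Henderson-Hasselbalch and is seeded", {
  mc1 <- mcTitration(5, pHGrid = seq(3, 7, 0.5), steps = 1e5, seed = 9)
  mc2 <- mcTitration(5, pHGrid = seq(3, 7, 0.5), steps = 1e5, seed = 9)
  expect_identical(thetaProt(mc1), thetaProt(mc2))
  dev <- abs(thetaProt(mc1)[, 1] - hhFraction(5, pHGrid(mc1)))
  expect_true(all(dev <= 3 * mcSE(mc1)[, 1] + 0.004))
  expect_error(mcTitration(5, pHGrid = 7, steps = 100), "1e4")
})

test_that("coupled-pair apparent pKas reproduce the statistical splitting", {
  pk <- coupledPairApparentPKas(4, 4, 0)
  expect_equal(unname(pk), c(4 - log10(2), 4 + log10(2)), tolerance = 1e-5)
})

test_that("coupled-pair splitting approaches the strong-coupling asymptote", {
  w <- 5 * ln10RT()  # 5 pK units of coupling
  pk <- coupledPairApparentPKas(3, 5, w)
  expect_lt(abs((pk[2] - pk[1]) - (5 + 2)), 0.05)
})

test_that("decoupled distinct sites keep their intrinsic pKas", {
  pk <- coupledPairApparentPKas(2, 9, 0)
  expect_equal(unname(pk), c(2, 9), tolerance = 0.01)
})

test_that("coupled-pair pKas agree with the n_bound half-points", {
  w <- 2 * ln10RT()
  crv <- enumerateTitration(c(4, 4), matrix(c(0, w, w, 0), 2),
                            seq(0, 10, 0.01))
  pk <- coupledPairApparentPKas(4, 4, w)
  halfPt <- function(target)
    approx(nBound(crv), pHGrid(crv), xout = target)$y
  expect_equal(unname(pk[1]), halfPt(1.5), tolerance = 0.01)
  expect_equal(unname(pk[2]), halfPt(0.5), tolerance = 0.01)
})

test_that("a chargeless ligand atom leaves the titration unchanged", {
  sysF <- genToySites(toySystemSpec(1, "line", siteTypes = "Asp"))
  at <- rbind(atoms(sysF),
              data.frame(x = 4, y = 0, z = 0, radius = 1.5, charge = 0,
                         ligand = TRUE))
  sysC <- new("TitratableSiteSystem", atoms = at, sites = sites(sysF))
  res <- titrateComplexAndFree(sysC, NULL, gridSpec(spacing = 0.8),
                               electroParams(), pHGrid = seq(1, 8, 0.5),
                               backend = "coulomb")
  expect_equal(thetaProt(res$complex$curve), thetaProt(res$free$curve),
               tolerance = 1e-6)
})

test_that("a nearby anionic ligand charge shifts the acid pKa upward", {
  sysC <- genToySites(toySystemSpec(2, "pair", distance = 4,
                                    siteTypes = c("Asp", "LigCOOH")))
  res <- titrateComplexAndFree(sysC, NULL, gridSpec(spacing = 0.8),
                               electroParams(), pHGrid = seq(1, 9, 0.25))
  pkC <- pKaHalf(res$complex$curve)[["Asp1"]]
  pkF <- pKaHalf(res$free$curve)[["Asp1"]]
  expect_gt(pkC, pkF)
})

test_that("a far-away ligand does not shift the curve", {
  sysC <- genToySites(toySystemSpec(2, "pair", distance = 50,
                                    siteTypes = c("Asp", "LigCOOH")))
  res <- titrateComplexAndFree(sysC, NULL, gridSpec(spacing = 1),
                               electroParams(), pHGrid = seq(1, 9, 0.25),
                               backend = "coulomb")
  expect_equal(pKaHalf(res$complex$curve)[["Asp1"]],
               pKaHalf(res$free$curve)[["Asp1"]], tolerance = 0.01)
})
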