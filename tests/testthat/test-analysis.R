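# Henderson-Hasselbalch analysis, protonation-change arithmetic and
# constant-pH-MD post-processing.

test_that("hhFraction matches closed-form values", {
  expect_equal(hhFraction(7, 7), 0.5)
  expect_equal(hhFraction(5.5, 7), 1 / (1 + 10^1.5))
  expect_equal(round(hhFraction(5.5, 7), 4), 0.0307)
  expect_equal(hhFraction(6, 3), 0.999, tolerance = 1e-3)
  # protonated and deprotonated fractions are complementary
  expect_equal(hhFraction(4.2, 1:10) + (1 - hhFraction(4.2, 1:10)),
               rep(1, 10))
})

test_that("fitHH round-trips noise-free fractions to machine precision", {
  pH <- seq(2.5, 10.5, 0.5)
  fit76 <- fitHH(pH, 1 - hhFraction(7.6, pH))
  expect_equal(fit76@pKa, 7.6, tolerance = 1e-6)
  fit36 <- fitHH(pH, 1 - hhFraction(3.6, pH))
  expect_equal(fit36@pKa, 3.6, tolerance = 1e-6)
})

test_that("fitHH tolerates symmetric noise and flags bad input", {
  pH <- seq(2.5, 10.5, 0.5)
  set.seed(21)
  noisy <- pmin(pmax(1 - hhFraction(6, pH) +
                       runif(length(pH), -0.01, 0.01), 0), 1)
  expect_lt(abs(fitHH(pH, noisy)@pKa - 6), 0.05)
  expect_error(fitHH(pH, rep(0, length(pH))), "unidentifiable")
  expect_error(fitHH(pH, rep(1, length(pH))), "unidentifiable")
  expect_warning(fitHH(c(9, 10, 11), 1 - hhFraction(4, c(9, 10, 11))),
                 "midpoint")
})

test_that("per-residue protonation changes reproduce printed-table rounding", {
  expect_equal(residueDeltaNH(5.5, 7.0, 7.0, digits = 2), 0.47)
  expect_equal(residueDeltaNH(5.8, 6.4, 7.0, digits = 2), 0.14)
  expect_equal(residueDeltaNH(4, 4, 7), 0)
  # antisymmetry under swapping the two forms
  expect_equal(residueDeltaNH(5.5, 7.0, 7.0), -residueDeltaNH(7.0, 5.5, 7.0))
})

test_that("total protonation change matches per-site sums when uncoupled", {
  ph <- seq(0, 14, 0.2)
  free <- enumerateTitration(c(A = 4, B = 6), matrix(0, 2, 2), ph,
                             acid = c(TRUE, TRUE))
  cplx <- enumerateTitration(c(A = 5, B = 6.5), matrix(0, 2, 2), ph,
                             acid = c(TRUE, TRUE))
  dn <- totalDeltaNH(cplx, free, 7)
  expect_equal(dn@totalIndependent, dn@totalCoupled, tolerance = 1e-9)
  expect_equal(unname(dn@perSite["A"]),
               residueDeltaNH(4, 5, 7), tolerance = 1e-9)
  # identical curves difference to zero
  zero <- totalDeltaNH(free, free, 7)
  expect_equal(unname(zero@perSite), c(0, 0))
  expect_equal(zero@totalCoupled, 0)
  # fully protonated regime: nothing to transfer
  low <- totalDeltaNH(cplx, free, 0.2)
  expect_lt(abs(low@totalCoupled), 0.002)
  expect_error(totalDeltaNH(cplx, free, 20), "outside")
})

test_that("cphmd fractions classify, exclude and average as stated", {
  # three replicas engineered to fractions 0.4 / 0.5 / 0.6 at one pH
  mk <- function(f) matrix(c(rep(1, f * 10), rep(0, 10 - f * 10)), ncol = 1)
  trajs <- new("LambdaTrajectorySet", sites = "siteA", pH = 7, burnIn = 0L,
               lambda = list(siteA = list(mk(0.4), mk(0.5), mk(0.6))))
  fr <- cphmdFractions(trajs)
  expect_equal(fr$fraction, 0.5)
  expect_equal(fr$sem, 0.1 / sqrt(3), tolerance = 1e-6)
  # all-zero trajectory: fraction 0, sem 0
  z <- new("LambdaTrajectorySet", sites = "s", pH = 5, burnIn = 0L,
           lambda = list(s = list(matrix(0, 10, 1))))
  frz <- cphmdFractions(z)
  expect_equal(frz$fraction, 0)
  expect_equal(frz$sem, 0)
  # intermediate frames are excluded; all-intermediate errors
  half <- new("LambdaTrajectorySet", sites = "s", pH = 5, burnIn = 0L,
              lambda = list(s = list(matrix(0.5, 10, 1))))
  expect_error(cphmdFractions(half), "intermediate")
})

test_that("burn-in removal ignores leading garbage frames", {
  spec <- lambdaSimSpec(6, pHGrid = c(5, 6, 7), nFrames = 2000L,
                        nReplicas = 2L, seed = 8L)
  tr <- genLambdaTrajectories(spec)
  dirty <- tr
  dirty@lambda <- lapply(tr@lambda, function(reps)
    lapply(reps, function(m) rbind(matrix(1, 50, ncol(m)), m)))
  dirty@burnIn <- 50L
  expect_equal(cphmdFractions(dirty)$fraction,
               cphmdFractions(tr, burnIn = 0)$fraction)
  expect_error(cphmdFractions(tr, burnIn = 5000), "burn-in")
})

test_that("lambda round-trip recovers the generating pKa within 0.1", {
  fits <- cphmdPKas(genLambdaTrajectories(lambdaSimSpec(7.6, seed = 42L)))
  expect_lt(abs(fits[[1]]@pKa - 7.6), 0.1)
  fits2 <- cphmdPKas(genLambdaTrajectories(
    lambdaSimSpec(3.6, jitter = 0.15, seed = 43L)))
  expect_lt(abs(fits2[[1]]@pKa - 3.6), 0.1)
})
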