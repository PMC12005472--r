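# Synthetic-data generators: geometry, determinism, and agreement of each
# generator with its downstream estimator.

test_that("toy-site geometry is exact and charge sets are consistent", {
  sys <- genToySites(toySystemSpec(2, "pair", distance = 3,
                                   siteTypes = "Asp"))
  a <- atoms(sys)
  d <- sqrt(sum((a[1, c("x", "y", "z")] - a[2, c("x", "y", "z")])^2))
  expect_equal(d, 3, tolerance = 1e-12)
  s <- sites(sys)[[1]]
  expect_equal(s$pkaRef, 4.0)
  expect_true(s$acid)
  expect_equal(sum(s$qDeprot) - sum(s$qProt), -1)
})

test_that("ring geometry places adjacent sites at the requested distance", {
  sys <- genToySites(toySystemSpec(5, "ring", distance = 4))
  a <- atoms(sys)
  d <- sqrt(sum((a[1, c("x", "y", "z")] - a[2, c("x", "y", "z")])^2))
  expect_equal(d, 4, tolerance = 1e-12)
})

test_that("toy-site generation is deterministic and rejects bad geometry", {
  spec <- toySystemSpec(3, "line", distance = 5, siteTypes = "His")
  expect_identical(genToySites(spec), genToySites(spec))
  expect_error(toySystemSpec(2, "helix"), "arg")
  expect_error(genToySites(toySystemSpec(2, "line", distance = 0.5)))
})

test_that("a single-Asp toy system titrates on the pKa-4 HH curve", {
  sys <- genToySites(toySystemSpec(1, "line", siteTypes = "Asp"))
  prm <- electroParams()
  res <- titrateComplexAndFree(sys, sys, gridSpec(spacing = 0.8),
                               prm, pHGrid = seq(1, 8, 0.5))
  expect_equal(thetaProt(res$free$curve)[, 1],
               hhFraction(4.0, pHGrid(res$free$curve)), tolerance = 1e-9)
})

test_that("zero-enthalpy ITC heats are exactly the injected noise", {
  ser <- genItcInjections(itcSimSpec(dH = 0, noiseSD = 0))
  expect_equal(injections(ser)$heat, rep(0, 19))
  ser2 <- genItcInjections(itcSimSpec(dH = 0, noiseSD = 1, seed = 3))
  set.seed(3)
  expect_equal(injections(ser2)$heat, rnorm(19, 0, 1))
})

test_that("tight binding gives constant heats until N, then zero", {
  ser <- genItcInjections(itcSimSpec(Kd = 1e-15, dH = -50, N = 1))
  h <- injections(ser)$heat
  # molar ratio passes N at injection 11 of 19 x 2 uL (0.2 mL cell)
  expect_equal(h[1:9], rep(-50, 9), tolerance = 1e-4)
  expect_equal(h[12:19], rep(0, 8), tolerance = 1e-3)
})

test_that("noise-free ITC round-trip recovers the generating parameters", {
  fit <- fitOneSite(genItcInjections(itcSimSpec(Kd = 1e-6, dH = -50, N = 1)))
  expect_equal(fit@Kd, 1e-6, tolerance = 1e-4)
  expect_equal(fit@dH, -50, tolerance = 1e-4)
  expect_equal(fit@N, 1, tolerance = 1e-4)
})

test_that("buffer series is constructed on the stated line", {
  pts <- genBufferSeries(1.67, -53.3, bufferDH, noiseSD = 0)
  expect_equal(pts$dHObserved, c(-47.288, -32.8759, -19.8332, 25.9415),
               tolerance = 1e-9)
  flat <- genBufferSeries(0, -10, bufferDH, noiseSD = 0)
  expect_equal(flat$dHObserved, rep(-10, 4))
  expect_error(genBufferSeries(1, 0, c(5, 5)), "distinct")
})

test_that("lambda chains have the stated stationary behaviour", {
  spec <- lambdaSimSpec(7.0, pHGrid = c(7.0, 12.0), nFrames = 20000L,
                        nReplicas = 1L, seed = 11L)
  tr <- genLambdaTrajectories(spec)
  lam <- tr@lambda[[1]][[1]]
  f_mid <- mean(lam[, 1])
  # SE of the mean of a two-state chain with switch prob s = 0.1 at midpoint
  se <- sqrt(0.25 / 20000 * (2 / 0.1 - 1))
  expect_lt(abs(f_mid - 0.5), 3 * se)
  expect_gt(mean(lam[, 2]), 0.999)
})

test_that("lambda generation is deterministic and jitter stays sub-threshold", {
  spec <- lambdaSimSpec(5, nFrames = 500L, jitter = 0.15, seed = 2L)
  tr1 <- genLambdaTrajectories(spec)
  tr2 <- genLambdaTrajectories(spec)
  expect_identical(tr1@lambda, tr2@lambda)
  v <- unlist(tr1@lambda)
  expect_true(all(v <= 0.2 | v >= 0.8))
})

test_that("displaced structures respect rigid motions exactly", {
  set.seed(1)
  co <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(genDisplacedStructure(co), co)
  mob <- genDisplacedStructure(co, rotation = c(0.3, -1, 0.7),
                               translation = c(2, 0, -4))
  expect_lt(kabschSuperpose(co, mob)$rmsd, 1e-9)
  shifted <- genDisplacedStructure(co, translation = c(1, 0, 0))
  expect_equal(rawRMSD(co, shifted), 1, tolerance = 1e-12)
})
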