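# Structure I/O, Kabsch superposition, RMSD/RMSF, box statistics, distances.

test_that("PDB reading preserves coordinates and applies the altloc rule", {
  f <- writeAltlocFixture(tempfile(fileext = ".pdb"))
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 5)
  # highest occupancy (B, 0.6) wins over A (0.4)
  ca1 <- a[a$resno == 1 & a$atom == "CA", ]
  expect_equal(ca1$altloc, "B")
  expect_equal(ca1$x, 11.700)
  expect_equal(a$x[1], 11.104)
  # keep-all mode retains both altlocs
  expect_equal(nrow(atoms(readStructure(f, keepAltlocs = TRUE))), 6)
})

test_that("structure write/read round-trips the atom table", {
  set.seed(14)
  s <- structureFromCoords(matrix(round(rnorm(18) * 5, 3), ncol = 3),
                           resno = 1:6)
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  expect_equal(atoms(readStructure(f)), atoms(s))
})

test_that("Kabsch superposition is exact under rigid motion", {
  set.seed(5)
  co <- matrix(rnorm(60, sd = 7), ncol = 3)
  expect_lt(kabschSuperpose(co, co)$rmsd, 1e-9)
  mob <- genDisplacedStructure(co, rotation = c(1.2, 0.3, -0.8),
                               translation = c(3, -1, 9))
  fit <- kabschSuperpose(co, mob)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # symmetry of the rmsd in its arguments
  set.seed(6)
  noisy <- co + matrix(rnorm(60, sd = 0.3), ncol = 3)
  expect_equal(kabschSuperpose(co, noisy)$rmsd,
               kabschSuperpose(noisy, co)$rmsd, tolerance = 1e-9)
  expect_warning(kabschSuperpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
                 "collinear")
})

test_that("Kabsch matches a dense rotational grid search on a planar set", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  mob <- sq
  mob[3, 1] <- mob[3, 1] + 1  # one corner displaced by 1 A
  rmsdAt <- function(th) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
    a <- sweep(sq, 2, colMeans(sq))
    b <- sweep(mob, 2, colMeans(mob)) %*% t(R)
    sqrt(mean(rowSums((a - b)^2)))
  }
  best <- min(vapply(seq(0, 2 * pi, length.out = 72001), rmsdAt, numeric(1)))
  fit <- suppressWarnings(kabschSuperpose(sq, mob))
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
})

test_that("all-atom RMSD pairs by chain/residue/atom and reports skips", {
  set.seed(7)
  co <- matrix(rnorm(30, sd = 5), ncol = 3)
  ref <- structureFromCoords(co, resno = 1:10)
  # mobile misses residue 10 and has an extra residue 11
  mob <- structureFromCoords(rbind(co[1:9, ], c(50, 50, 50)),
                             resno = c(1:9, 11))
  r <- structureRMSD(ref, mob, selection = "all")
  expect_equal(r$nPaired, 9)
  expect_equal(r$nSkipped, 2)
  expect_lt(r$rmsd, 1e-9)
})

test_that("an ensemble of reference copies has zero RMSD everywhere", {
  set.seed(8)
  ref <- structureFromCoords(matrix(rnorm(30, sd = 5), ncol = 3))
  ens <- list(ref, ref, ref)
  expect_equal(rmsdSeries(ref, ens, "ca"), c(0, 0, 0), tolerance = 1e-9)
})

test_that("noisy-ensemble RMSD matches the Gaussian expectation", {
  set.seed(9)
  co <- matrix(rnorm(600, sd = 10), ncol = 3)  # 200 atoms
  ref <- structureFromCoords(co, resno = 1:200)
  ens <- lapply(1:30, function(i) structureFromCoords(
    genDisplacedStructure(co, noiseSD = 0.5, seed = i), resno = 1:200))
  m <- mean(rmsdSeries(ref, ens, "ca"))
  expect_lt(abs(m - sqrt(3) * 0.5) / (sqrt(3) * 0.5), 0.1)
  # single snapshot equals the kabschSuperpose rmsd
  one <- rmsdSeries(ref, ens[1], "ca")
  expect_equal(one, kabschSuperpose(structureCoords(ref),
                                    structureCoords(ens[[1]]))$rmsd)
})

test_that("RMSF isolates a jittered residue and is order-invariant", {
  set.seed(10)
  co <- matrix(rnorm(300, sd = 8), ncol = 3)  # 100 residues
  ens <- lapply(1:500, function(i) {
    c2 <- co
    c2[1, ] <- c2[1, ] + rnorm(3, 0, 0.5)
    structureFromCoords(c2, resno = 1:100)
  })
  rf <- rmsfPerResidue(ens, "ca")
  expect_lt(abs(rf[1] - 0.866) / 0.866, 0.1)
  expect_lt(max(rf[-1]), 0.05)
  # static ensemble: all zeros
  stat <- lapply(1:3, function(i) structureFromCoords(co, resno = 1:100))
  expect_equal(max(rmsfPerResidue(stat, "ca")), 0, tolerance = 1e-9)
  # permutation invariance (up to the iterative mean's numerical noise)
  expect_equal(rmsfPerResidue(rev(ens), "ca"), rf, tolerance = 1e-5)
})

test_that("RMSF is invariant to rigid motion of every snapshot", {
  set.seed(11)
  co <- matrix(rnorm(60, sd = 6), ncol = 3)
  ens <- lapply(1:5, function(i) structureFromCoords(
    genDisplacedStructure(co, noiseSD = 0.3, seed = i), resno = 1:20))
  moved <- lapply(seq_along(ens), function(i) structureFromCoords(
    genDisplacedStructure(structureCoords(ens[[i]]),
                          rotation = c(0.1 * i, -0.2, 0.05 * i),
                          translation = c(i, -i, 2 * i)),
    resno = 1:20))
  expect_equal(rmsfPerResidue(moved, "ca"), rmsfPerResidue(ens, "ca"),
               tolerance = 1e-6)
})

test_that("box statistics follow the quartile and whisker rules", {
  b <- boxStats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$q25, 2)
  expect_equal(b$q75, 4)
  expect_equal(length(b$outliers), 0)
  expect_equal(b$whiskerLo, 1)  # no point beyond 1.5 IQR: whisker = min
  expect_equal(b$whiskerHi, 5)
  b2 <- boxStats(c(1, 2, 3, 4, 100))
  expect_equal(b2$outliers, 100)
  b3 <- boxStats(rep(7, 5))
  expect_equal(b3$q25, b3$q75)
  expect_equal(length(b3$outliers), 0)
})

test_that("distance tables resolve selectors and round as stated", {
  s <- structureFromCoords(rbind(c(0, 0, 0), c(3, 0, 0), c(1, 2, 2)),
                           resno = 1:3)
  d <- distanceTable(s, list(c("A:1:CA", "A:2:CA"), c("A:1:CA", "A:1:CA"),
                             c("A:1:CA", "A:3:CA")))
  expect_equal(d$distance, c(3.0, 0.0, 3.0))
  expect_error(distanceTable(s, list(c("A:1:CA", "B:9:CA"))))
})
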