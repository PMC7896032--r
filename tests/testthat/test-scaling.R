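# Size-number fits: agreement with a normal-equations oracle, closed-form
# cases, invariances, and recovery of the conserved-area scaling.

test_that("every fit reproduces the normal-equations oracle to 1e-10", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    a <- runif(n, 0.3, 6)
    cells <- makeCells(sample(4:20, n, replace = TRUE), a)
    f1 <- fitReciprocalSqrt(cells)
    o1 <- olsOracle(cells$sqrt_mean_area, 1 / cells$n_pads)
    expect_equal(unname(coef(f1)), c(o1$intercept, o1$slope),
                 tolerance = 1e-10)
    expect_equal(r2(f1), o1$r2, tolerance = 1e-10)
    f2 <- fitPowerLaw(a, cells$n_pads)
    o2 <- olsOracle(log10(a), log10(cells$n_pads))
    expect_equal(exponent(f2), o2$slope, tolerance = 1e-10)
    expect_equal(r2(f2), o2$r2, tolerance = 1e-10)
  }
})

test_that("exact relationships are fitted exactly", {
  n <- c(2, 4, 5, 10, 20)
  cells <- makeCells(n, (1 / (0.2 * n))^2)  # 1/n = 0.2 * sqrt(area)
  f <- fitReciprocalSqrt(cells)
  expect_equal(unname(coef(f)["slope"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(coef(f)["intercept"]), 0, tolerance = 1e-12)
  expect_equal(r2(f), 1, tolerance = 1e-12)
  # constant response: zero slope, zero R2
  flat <- makeCells(rep(5, 10), seq(0.5, 5, length.out = 10))
  f0 <- fitReciprocalSqrt(flat)
  expect_equal(unname(coef(f0)["slope"]), 0)
  expect_equal(r2(f0), 0)
  # zero-variance predictor is an error
  expect_error(fitReciprocalSqrt(makeCells(2:11, rep(1, 10))),
               "zero-variance")
})

test_that("power-law fits: exact exponent, constant case, scale invariance", {
  x <- seq(0.5, 10, 0.5)
  f <- fitPowerLaw(x, 5 * x^-1)
  expect_equal(exponent(f), -1, tolerance = 1e-12)
  expect_equal(r2(f), 1, tolerance = 1e-12)
  fc <- fitPowerLaw(x, rep(3, length(x)))
  expect_equal(exponent(fc), 0)
  set.seed(3)
  y <- 2 * x^-1.4 * exp(rnorm(length(x), 0, 0.1))
  f1 <- fitPowerLaw(x, y)
  f2 <- fitPowerLaw(7 * x, y)
  f3 <- fitPowerLaw(x, 0.01 * y)
  expect_equal(exponent(f1), exponent(f2), tolerance = 1e-12)
  expect_equal(exponent(f1), exponent(f3), tolerance = 1e-12)
  expect_error(fitPowerLaw(c(-1, 0, 1), c(1, 2, 3)), "positive")
})

test_that("conserved total area drives the count-size exponent to -1", {
  p <- populationParams(nCells = 300, totalPadArea = 16, areaCV = 0,
                        countLaw = list(type = "uniform", min = 4, max = 32),
                        seed = 41)
  tr <- simulatePopulation(p, render = FALSE)$truth
  meanArea <- tapply(tr$pads$area_um2, tr$pads$cell_id, mean)
  n <- tr$cells$n_pads
  f <- fitPowerLaw(as.numeric(meanArea), n)
  expect_equal(exponent(f), -1, tolerance = 1e-9)  # exact when areaCV = 0
  # and the reciprocal-sqrt view gives a strong positive linear trend
  cells <- makeCells(n, as.numeric(meanArea))
  fr <- fitReciprocalSqrt(cells)
  expect_gt(unname(coef(fr)["slope"]), 0)
  expect_gt(r2(fr), 0.5)
})

test_that("exponential size-spectrum fit recovers a known rate and exact bins", {
  set.seed(55)
  areas <- stats::rexp(5000, rate = 2)
  f <- fitExponential(areas)
  expect_equal(unname(coef(f)["slope"]), -2, tolerance = 0.2)
  expect_lt(unname(coef(f)["slope"]), 0)
  expect_error(fitExponential(rep(1, 50)), "non-empty bins")
  # counts following an exact exponential at the bin centres fit with R2 = 1
  centers <- seq(0.5, 5.5, 1)
  counts <- c(128, 64, 32, 16, 8, 4)
  areas2 <- rep(centers, counts)
  f2 <- fitExponential(areas2, nBins = 6, areaCap = 6)
  expect_equal(r2(f2), 1, tolerance = 1e-12)
  expect_equal(unname(coef(f2)["slope"]), -log(2), tolerance = 1e-12)
})

test_that("centromere clustering fits expose both linear and exponential views", {
  a <- seq(0.5, 5, 0.5)
  pads <- data.frame(area_um2 = a, centromere_count = 2 * a)
  f <- fitCentromereClustering(pads)
  expect_equal(unname(coef(f$linear)["slope"]), 2, tolerance = 1e-12)
  expect_equal(r2(f$linear), 1, tolerance = 1e-12)
  # single-centromere chromocenters of varying area: flat, degenerate
  ones <- data.frame(area_um2 = seq(0.3, 6, length.out = 12),
                     centromere_count = 1)
  f1 <- fitCentromereClustering(ones)
  expect_equal(unname(coef(f1$linear)["slope"]), 0)
  expect_equal(f1$exponential@details$flag, "degenerate: all counts equal")
  # generator recovery: fitted density within 15 percent of the truth
  tr <- simulatePopulation(populationParams(nCells = 60, seed = 43),
                           render = FALSE)$truth
  fg <- fitCentromereClustering(tr$pads)
  expect_lt(abs(unname(coef(fg$linear)["slope"]) - 1.2) / 1.2, 0.15)
})

test_that("permuting the response destroys an exact fit", {
  set.seed(7)
  x <- runif(100, 1, 10)
  y <- 3 + 2 * x
  f <- olsOracle(x, y)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  perm <- vapply(1:50, function(i) olsOracle(x, sample(y))$r2, numeric(1))
  expect_lt(median(perm), 0.05)
})

test_that("condition comparison detects unravelling of large chromocenters", {
  p <- populationParams(nCells = 40, seed = 61)
  trc <- simulatePopulation(p, render = FALSE)$truth
  ctl <- makeCells(trc$cells$n_pads,
                   as.numeric(tapply(trc$pads$area_um2, trc$pads$cell_id,
                                     mean)))
  # treated: many small chromocenters of nearly fixed size
  set.seed(62)
  trtN <- sample(14:20, 40, replace = TRUE)
  trt <- makeCells(trtN, 0.5 + rnorm(40, 0, 0.02))
  cmp <- compareConditions(ctl, trt)
  expect_lt(cmp$treated$median_mean_area, cmp$control$median_mean_area)
  expect_lt(cmp$test$p, 0.01)
  expect_gt(cmp$r2_drop, 0)
  # identical cohorts: no difference
  same <- compareConditions(ctl, ctl)
  expect_equal(same$test$p, 1)
})
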