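# The generators: seeded determinism, conservation of the total
# chromocenter amount, nesting of foci in chromocenters, and the
# controllable AO / heterogeneity / qPCR signals.

test_that("identical parameters and seed reproduce images and truth exactly", {
  p <- populationParams(nCells = 3, seed = 7, imageSize = 128)
  s1 <- simulatePopulation(p)
  s2 <- simulatePopulation(p)
  expect_identical(s1$truth$cells, s2$truth$cells)
  expect_identical(s1$truth$pads, s2$truth$pads)
  for (i in seq_along(s1$images))
    for (ch in channelNames(s1$images[[i]]))
      expect_identical(channel(s1$images[[i]], ch),
                       channel(s2$images[[i]], ch))
  # truth is independent of whether rasters are rendered
  s3 <- simulatePopulation(p, render = FALSE)
  expect_identical(s1$truth$pads, s3$truth$pads)
})

test_that("total chromocenter area is conserved exactly when areaCV = 0", {
  p <- populationParams(nCells = 25, areaCV = 0, seed = 3)
  tr <- simulatePopulation(p, render = FALSE)$truth
  sums <- as.numeric(tapply(tr$pads$area_um2, tr$pads$cell_id, sum))
  expect_equal(sums, rep(p$totalPadArea, 25), tolerance = 1e-12)
  # with areaCV > 0 the per-cell totals scatter around the conserved amount
  p2 <- populationParams(nCells = 200, areaCV = 0.1, seed = 4)
  tr2 <- simulatePopulation(p2, render = FALSE)$truth
  s2 <- tapply(tr2$pads$area_um2, tr2$pads$cell_id, sum)
  expect_lt(abs(mean(log(s2 / p2$totalPadArea))), 0.03)
  expect_lt(abs(sd(log(s2)) - 0.1), 0.03)
})

test_that("centromere foci nest inside chromocenters and chromocenters inside nuclei", {
  tr <- simulatePopulation(populationParams(nCells = 6, seed = 5),
                           render = FALSE)$truth
  for (i in unique(tr$cells$cell_id)) {
    ci <- tr$cells[tr$cells$cell_id == i, ]
    pd <- tr$pads[tr$pads$cell_id == i, ]
    # chromocenter discs inside the nucleus ellipse
    expect_true(all(((pd$cy - ci$cy) / (ci$ry - pd$r_px))^2 +
                    ((pd$cx - ci$cx) / (ci$rx - pd$r_px))^2 <= 1 + 1e-9))
    fo <- tr$foci[tr$foci$cell_id == i, ]
    d <- sqrt((fo$x - pd$cx[fo$pad_id])^2 + (fo$y - pd$cy[fo$pad_id])^2)
    expect_true(all(d <= pd$r_px[fo$pad_id]))
    expect_true(all(pd$centromere_count >= 1))
  }
})

test_that("count law draws respect their support", {
  p <- populationParams(nCells = 150, seed = 9,
                        countLaw = list(type = "categorical",
                                        values = c(4, 8), probs = c(.5, .5)))
  tr <- simulatePopulation(p, render = FALSE)$truth
  main <- tr$cells$dna_class != "preapoptotic"
  expect_true(all(tr$cells$n_pads[main] %in% c(4, 8)))
})

test_that("AO generator hits its target ratio exactly without noise and on average with it", {
  s0 <- simulateAOPopulation(20, controlRG = 1.3, shiftFactor = 1.2,
                             noiseSd = 0, seed = 2)
  for (img in s0$images) {
    mask <- channel(img, "green") > 0
    m <- rgIndex(img, mask)
    expect_equal(m$rg_raw, 1.3 * 1.2, tolerance = 1e-12)
  }
  expect_equal(s0$truth$cells$true_rg, rep(1.56, 20))
  # identity case: unit shift recovered within 3 standard errors
  s1 <- simulateAOPopulation(300, shiftFactor = 1, noiseSd = 0.15, seed = 8)
  v <- s1$truth$cells$true_rg
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 1), 3 * se + 0.02)
})

test_that("a 20 percent AO shift at n = 300 per group is detected at alpha 0.001", {
  a <- simulateAOPopulation(300, shiftFactor = 1.0, noiseSd = 0.15,
                            seed = 21)$truth$cells$true_rg
  b <- simulateAOPopulation(300, shiftFactor = 1.2, noiseSd = 0.15,
                            seed = 22)$truth$cells$true_rg
  expect_lt(shiftTest(a, b)$p, 0.001)
})

test_that("heterogeneity fields realize their target deviating fraction", {
  mask <- rectMask(40, 40, 5:36, 5:36)
  img0 <- simulateHeterogeneityField(mask, 0, seed = 1)
  ni0 <- NucleusImage(list(green = img0), pxPerUm = 1)
  expect_equal(heterogeneity(ni0, mask), 0)
  img1 <- simulateHeterogeneityField(mask, 1, seed = 1)
  expect_equal(heterogeneity(NucleusImage(list(green = img1), pxPerUm = 1),
                             mask), 1)
  med <- vapply(1:50, function(s) {
    im <- simulateHeterogeneityField(mask, 0.4, seed = s)
    heterogeneity(NucleusImage(list(green = im), pxPerUm = 1), mask)
  }, numeric(1))
  expect_gte(mean(med), 0.38)
  expect_lte(mean(med), 0.42)
})

test_that("qPCR plate generator yields the intended fold change", {
  p0 <- qpcrSimParams(list(HS3_9 = c(ST = 1, HRG60 = 2)), ctNoiseSd = 0,
                      seed = 1)
  tb0 <- simulateQPCRPlate(p0)
  r <- rq(tb0, "HS3_9", "GAPDH", "ST")
  expect_equal(r$rq[r$sample == "HRG60"], 2, tolerance = 1e-12)
  # Monte-Carlo mean of the recovered fold under realistic noise
  rqs <- vapply(1:100, function(s) {
    tb <- simulateQPCRPlate(qpcrSimParams(
      list(G = c(ST = 1, T1 = 1.5)), replicates = 4, ctNoiseSd = 0.2,
      seed = s))
    r <- rq(tb, "G", "GAPDH", "ST")
    r$rq[r$sample == "T1"]
  }, numeric(1))
  expect_gte(mean(rqs), 1.4)
  expect_lte(mean(rqs), 1.6)
})

test_that("infeasible heterogeneity targets and bad parameters error", {
  mask <- rectMask(4, 4, 1:2, 1:2)  # 4 px: fraction 0.4 unreachable
  expect_error(simulateHeterogeneityField(mask, 0.4), "infeasible")
  expect_error(populationParams(totalPadArea = -1))
  expect_error(populationParams(countLaw = list(type = "uniform",
                                                min = 0, max = 3)))
})
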