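# Segmentation and per-cell measurement: nuclei, DNA content and gating,
# chromocenters, centromere counting, heterogeneity, per-cell summary.

test_that("connected-component labelling honours the requested connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # touch only diagonally
  expect_equal(max(labelComponents(m, 8)), 1)
  expect_equal(max(labelComponents(m, 4)), 2)
  m2 <- matrix(FALSE, 6, 6)
  m2[1:2, 1:2] <- TRUE; m2[5:6, 5:6] <- TRUE
  expect_equal(max(labelComponents(m2, 8)), 2)
})

test_that("a blank field yields zero nuclei, not an error", {
  img <- NucleusImage(list(blue = matrix(0, 64, 64)), pxPerUm = 8)
  ns <- segmentNuclei(img)
  expect_equal(nrow(records(ns)), 0)
})

test_that("non-touching synthetic nuclei are recovered with accurate areas", {
  p <- populationParams(nCells = 10, cellsPerField = 10, imageSize = 420,
                        totalPadArea = 8, noiseSd = 0, seed = 13)
  sim <- simulatePopulation(p)
  ns <- segmentNuclei(sim$images[[1]])
  tb <- records(ns)
  expect_equal(nrow(tb), 10)
  truthArea <- pi * sim$truth$cells$rx * sim$truth$cells$ry / p$pxPerUm^2
  # match segmented to true nuclei by position-free area ordering
  expect_equal(sort(tb$area_um2), sort(truthArea), tolerance = 0.05)
})

test_that("an implausibly large object is flagged as under-segmentation", {
  blue <- matrix(0, 300, 300)
  blue[31:270, 31:270] <- 1  # 240x240 px = 900 um^2 at 8 px/um
  img <- NucleusImage(list(blue = blue), pxPerUm = 8)
  ns <- segmentNuclei(img)
  expect_equal(processingLog(ns)$undersegmented, 1L)
  expect_true("undersegmented" %in% records(ns)$flag)
})

test_that("integrated DAPI intensity is a sum over the mask and additive", {
  img <- NucleusImage(list(blue = matrix(3, 20, 20)), pxPerUm = 1)
  whole <- rectMask(20, 20, 6:15, 6:15)
  expect_equal(measureDNAContent(img, whole), 300)
  a <- whole; a[, 11:20] <- FALSE
  b <- whole; b[, 1:10] <- FALSE
  set.seed(1)
  img2 <- NucleusImage(list(blue = matrix(runif(400), 20, 20)), pxPerUm = 1)
  expect_equal(measureDNAContent(img2, whole),
               measureDNAContent(img2, a) + measureDNAContent(img2, b))
})

test_that("a noise-free S-G2 cell integrates twice the DAPI of a 2C cell", {
  p <- populationParams(nCells = 40, noiseSd = 0, areaCV = 0, seed = 17,
                        imageSize = 128)
  sim <- simulatePopulation(p)
  ifi <- vapply(seq_along(sim$images), function(i) {
    ns <- segmentNuclei(sim$images[[i]])
    records(ns)$dapi_ifi[1]
  }, numeric(1))
  cls <- sim$truth$cells$dna_class
  # normalize out nucleus-size variation using the true geometry
  nucArea <- pi * sim$truth$cells$rx * sim$truth$cells$ry
  dens <- ifi / nucArea
  expect_gte(sum(cls == "S-G2"), 2)  # the seed draws several S-G2 cells
  expect_equal(mean(dens[cls == "S-G2"]) / mean(dens[cls == "2C"]), 2,
               tolerance = 0.05)
})

test_that("DNA-content gating recovers the simulated class mixture", {
  # identical IFI: everything is 2C
  g0 <- gateCells(makeIFISet(rep(100, 30)))
  expect_true(all(records(g0)$gate == "2C"))
  # too few records: unassigned with a warning
  expect_warning(g1 <- gateCells(makeIFISet(rep(100, 5))), "too few")
  expect_true(all(records(g1)$gate == "unassigned"))
  # bimodal at x and 2x: taller peak anchors 2C, doubled cells gate S-G2
  g2 <- gateCells(makeIFISet(c(rnorm(150, 100, 3), rnorm(30, 200, 3))))
  tb2 <- records(g2)
  expect_true(all(tb2$gate[tb2$dapi_ifi > 180] == "S-G2"))
  expect_true(all(tb2$gate[tb2$dapi_ifi < 120] == "2C"))
  # full mixture via the image pipeline at n = 200, noise-free
  sim <- simulatePopulation(populationParams(nCells = 200, noiseSd = 0,
                                             seed = 11, imageSize = 128))
  ifi <- unlist(lapply(sim$images,
                       function(im) records(segmentNuclei(im))$dapi_ifi))
  gated <- records(gateCells(makeIFISet(ifi)))$gate
  truth <- sim$truth$cells$dna_class
  for (cl in c("2C", "S-G2", "preapoptotic"))
    expect_lt(abs(mean(gated == cl) - mean(truth == cl)), 0.03)
})

test_that("preapoptotic gating can require chromocenter aggregation", {
  ifi <- c(rep(100, 40), 60, 60)
  padArea <- c(rep(1, 40), 8, 0.5)  # only the first low cell aggregates
  g <- gateCells(makeIFISet(ifi), padArea = padArea)
  tb <- records(g)
  expect_equal(tb$gate[41], "preapoptotic")
  expect_equal(tb$gate[42], "unassigned")
})

test_that("chromocenter segmentation: uniform square, blank plane, exact counts", {
  nucMask <- rectMask(60, 60, 6:55, 6:55)
  red <- matrix(0, 60, 60)
  red[21:30, 21:30] <- 1
  img <- NucleusImage(list(blue = 1 * nucMask, red = red), pxPerUm = 1)
  ns <- makeNucleusSet(list(nucMask))
  ps <- segmentPADs(img, ns, config = list(minPadAreaUm2 = 0.2))
  expect_equal(nrow(records(ps)), 1)
  expect_equal(records(ps)$area_px, 100)
  # blank red plane: zero chromocenters
  img0 <- NucleusImage(list(blue = 1 * nucMask, red = matrix(0, 60, 60)),
                       pxPerUm = 1)
  expect_equal(nrow(records(segmentPADs(img0, ns))), 0)
})

test_that("noise-free non-touching chromocenters are counted exactly with accurate areas", {
  sim <- simulatePopulation(populationParams(nCells = 8, noiseSd = 0,
                                             seed = 7, imageSize = 128))
  for (i in 1:8) {
    img <- sim$images[[i]]
    ns <- segmentNuclei(img)
    ps <- segmentPADs(img, ns)
    tp <- sim$truth$pads[sim$truth$pads$cell_id == i, ]
    expect_equal(nrow(records(ps)), nrow(tp))
    relerr <- abs(sort(records(ps)$area_um2) - sort(tp$area_um2)) /
      sort(tp$area_um2)
    expect_lt(max(relerr), 0.10)
  }
})

test_that("centromere foci are assigned to the chromocenter holding their centroid", {
  nucMask <- rectMask(60, 60, 3:58, 3:58)
  padA <- rectMask(60, 60, 10:19, 10:19)
  padB <- rectMask(60, 60, 35:44, 35:44)
  green <- matrix(0, 60, 60)
  img0 <- NucleusImage(list(green = green), pxPerUm = 1)
  ps <- makePADSet(list(padA, padB))
  out0 <- countCentromeres(img0, ps)
  expect_true(all(records(out0)$centromere_count == 0))
  green[14:15, 14:15] <- 1; green[39:40, 39:40] <- 1
  img1 <- NucleusImage(list(green = green), pxPerUm = 1)
  out1 <- countCentromeres(img1, ps)
  expect_equal(records(out1)$centromere_count, c(1L, 1L))
})

test_that("centromere counts match ground truth when foci are separated", {
  sim <- simulatePopulation(populationParams(nCells = 10, noiseSd = 0,
                                             seed = 19, imageSize = 128,
                                             centromereDensity = 0.8))
  for (i in 1:10) {
    img <- sim$images[[i]]
    ps <- countCentromeres(img, segmentPADs(img, segmentNuclei(img)))
    tp <- sim$truth$pads[sim$truth$pads$cell_id == i, ]
    if (!all(tp$sep_ok)) next
    expect_equal(sum(records(ps)$centromere_count),
                 sum(tp$centromere_count))
    # no more foci assigned than components found
    lg <- processingLog(ps)
    expect_lte(sum(records(ps)$centromere_count), lg$foci_total)
  }
})

test_that("heterogeneity matches its closed forms and is scale invariant", {
  u <- NucleusImage(list(green = matrix(7, 10, 10)), pxPerUm = 1)
  allMask <- matrix(TRUE, 10, 10)
  expect_equal(heterogeneity(u, allMask), 0)
  half <- NucleusImage(list(green = matrix(c(50, 150), 10, 10)), pxPerUm = 1)
  expect_equal(heterogeneity(half, allMask), 1)
  # deviations of exactly the tolerance are NOT counted (strict inequality)
  tie <- NucleusImage(list(green = matrix(c(90, 100, 110, 100), 2, 2)),
                      pxPerUm = 1)
  expect_equal(heterogeneity(tie, matrix(TRUE, 2, 2)), 0)
  set.seed(42)
  v <- matrix(runif(400, 10, 30), 20, 20)
  img <- NucleusImage(list(green = v), pxPerUm = 1)
  img3 <- NucleusImage(list(green = 3.7 * v), pxPerUm = 1)
  mk <- rectMask(20, 20, 3:18, 3:18)
  expect_equal(heterogeneity(img, mk), heterogeneity(img3, mk))
  # monotone non-decreasing as the tolerance shrinks
  expect_gte(heterogeneity(img, mk, tolerance = 0.05),
             heterogeneity(img, mk, tolerance = 0.10))
  expect_gte(heterogeneity(img, mk, tolerance = 0.10),
             heterogeneity(img, mk, tolerance = 0.20))
  # uniformly zero field is defined as homogeneous
  z <- NucleusImage(list(green = matrix(0, 4, 4)), pxPerUm = 1)
  expect_message(h0 <- heterogeneity(z, matrix(TRUE, 4, 4)), "zero mean")
  expect_equal(h0, 0)
})

test_that("per-cell summaries aggregate chromocenters correctly", {
  nuc <- makeNucleusSet(list(rectMask(40, 40, 2:39, 2:39)))
  pads4 <- makePADSet(lapply(seq(0, 30, 10), function(o)
    rectMask(40, 40, 5:14, (3 + o):(3 + o))), pxPerUm = 1)
  # four 10-px strips of 10 px^2 each... use 1 um^2 pads via pxPerUm
  pads4@table$area_um2 <- rep(1, 4)
  cs <- summarizeCells(nuc, pads4)
  expect_equal(cs$n_pads, 4)
  expect_equal(cs$mean_area_um2, 1)
  expect_equal(cs$total_area_um2, 4)
  expect_equal(cs$sqrt_mean_area, 1)
  pad9 <- makePADSet(list(rectMask(40, 40, 10:12, 10:12)))
  pad9@table$area_um2 <- 9
  cs9 <- summarizeCells(nuc, pad9)
  expect_equal(cs9$sqrt_mean_area, 3)
  # a cell without chromocenters is flagged, not an error
  none <- makePADSet(list(rectMask(40, 40, 1, 1)))
  none@table <- none@table[0, ]
  cs0 <- summarizeCells(nuc, none)
  expect_equal(cs0$flag, "no_pads")
  expect_true(is.na(cs0$mean_area_um2))
})

test_that("measured per-cell totals reproduce the conserved amount", {
  p <- populationParams(nCells = 6, areaCV = 0, noiseSd = 0, seed = 23,
                        imageSize = 128)
  sim <- simulatePopulation(p)
  for (i in 1:6) {
    img <- sim$images[[i]]
    ps <- segmentPADs(img, segmentNuclei(img))
    expect_equal(sum(records(ps)$area_um2), p$totalPadArea,
                 tolerance = 0.05)
  }
})
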