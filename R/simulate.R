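## Seeded generators of synthetic microscopy fields and qPCR plates with
## ground truth. The generators emulate the statistical structure the
## downstream cytometry assumes: a conserved per-cell amount of pericentric
## heterochromatin redistributed over a variable number of chromocenters
## (fusion-splitting), centromere foci nested inside chromocenters with count
## proportional to chromocenter area, two-plane acridine-orange images with a
## controllable population R/G shift, and CT tables with known fold changes.

#' Parameters of a simulated cell population
#'
#' @param nCells number of cells to simulate.
#' @param totalPadArea conserved total chromocenter area per cell, um^2. The
#'   default 16 um^2 is the conserved constitutive-heterochromatin amount each
#'   cell redistributes over its chromocenters.
#' @param areaCV cell-to-cell coefficient of variation of the total area
#'   (0 = exact conservation). Applied as a lognormal multiplier.
#' @param countLaw distribution of the per-cell chromocenter count n: either
#'   `list(type = "uniform", min, max)` (uniform over integers) or
#'   `list(type = "categorical", values, probs)`. Default uniform 6..16, the
#'   range most interphase cells display.
#' @param centromereDensity centromeres per um^2 of chromocenter area; the
#'   default 1.2 reproduces the observed clustering scale (chromocenters of
#'   5-6 um^2 holding more than six centromere foci at epifluorescence
#'   resolution, where tightly apposed centromeres merge into one focus).
#' @param concentration symmetric Dirichlet concentration of the
#'   stick-breaking fragment-size law; larger = more even fragments.
#' @param minFragArea smallest fragment area admitted by the stick-breaking
#'   redraw (um^2); keeps every rendered chromocenter above the finest
#'   resolvable unit (0.2 um^2) so it stays detectable.
#' @param classProbs probabilities of the DNA-content classes 2C, S-G2 and
#'   preapoptotic (default 85/10/5 percent).
#' @param imageSize field side length in pixels.
#' @param pxPerUm pixel calibration.
#' @param cellsPerField nuclei rendered per field (laid out on a jittered
#'   grid so nuclei never touch).
#' @param noiseSd Gaussian read-noise SD added to every channel (intensity
#'   units on the 0..1 render scale).
#' @param seed root seed; all randomness derives from it (see Details).
#'
#' @details All randomness is split from the root seed by one documented
#' rule: `set.seed(seed)` is called once, per-cell sub-seeds are drawn with
#' `sample.int(.Machine$integer.max - 1, nCells)`, and each cell's draws
#' (class, count, fragment sizes, geometry, foci) happen in its own stream
#' seeded by its sub-seed, followed by per-field noise streams. Ground truth
#' is therefore identical whether or not rasters are rendered.
#'
#' @return A list of class `populationParams`.
#' @export
populationParams <- function(nCells = 100, totalPadArea = 16, areaCV = 0.1,
                             countLaw = list(type = "uniform", min = 6, max = 16),
                             centromereDensity = 1.2, concentration = 5,
                             minFragArea = 0.25,
                             classProbs = c("2C" = 0.85, "S-G2" = 0.10,
                                            "preapoptotic" = 0.05),
                             imageSize = 160, pxPerUm = 8,
                             cellsPerField = 1, noiseSd = 0.01, seed = 1) {
  stopifnot(nCells >= 1, totalPadArea > 0, areaCV >= 0, pxPerUm > 0,
            centromereDensity > 0, concentration > 0, noiseSd >= 0,
            imageSize >= 32, cellsPerField >= 1, minFragArea >= 0)
  countLaw <- .checkCountLaw(countLaw)
  classProbs <- classProbs / sum(classProbs)
  structure(list(nCells = as.integer(nCells), totalPadArea = totalPadArea,
                 areaCV = areaCV, countLaw = countLaw,
                 centromereDensity = centromereDensity,
                 concentration = concentration, minFragArea = minFragArea,
                 classProbs = classProbs,
                 imageSize = as.integer(imageSize), pxPerUm = pxPerUm,
                 cellsPerField = as.integer(cellsPerField),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "populationParams")
}

.checkCountLaw <- function(law) {
  if (!is.list(law) || is.null(law$type))
    stop("countLaw must be a list with a 'type' field")
  if (law$type == "uniform") {
    stopifnot(law$min >= 1, law$max >= law$min)
    law$min <- as.integer(law$min); law$max <- as.integer(law$max)
  } else if (law$type == "categorical") {
    stopifnot(all(law$values >= 1), length(law$values) == length(law$probs),
              all(law$probs >= 0), sum(law$probs) > 0)
  } else stop("countLaw$type must be 'uniform' or 'categorical'")
  law
}

.drawCount <- function(law) {
  if (law$type == "uniform") {
    if (law$min == law$max) law$min
    else sample(seq.int(law$min, law$max), 1L)
  } else sample(law$values, 1L, prob = law$probs)
}

## symmetric Dirichlet via normalized gammas
.rdirichletSym <- function(n, conc) {
  g <- stats::rgamma(n, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

## Split `total` into n fragments; redraw (bounded) until every fragment
## clears minFrag, else clamp-and-renormalize so the sum is exact anyway.
.stickBreak <- function(total, n, conc, minFrag = 0, maxTries = 200) {
  if (n == 1) return(total)
  for (i in seq_len(maxTries)) {
    f <- .rdirichletSym(n, conc) * total
    if (all(f >= minFrag)) return(f)
  }
  f <- pmax(f, minFrag)
  f / sum(f) * total
}

.splitSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a population of multi-channel nucleus images with ground truth
#'
#' Each cell's conserved chromocenter area is split into n fragments by
#' symmetric-Dirichlet stick-breaking (n drawn from the count law), rendered
#' as disjoint Gaussian-profile discs (nominal mask = half-maximum contour)
#' inside an elliptical nucleus. The DAPI channel is nucleus base intensity
#' plus chromocenter excess, scaled by the DNA-content class (2C = 1,
#' S-G2 = 2, preapoptotic = 0.6; preapoptotic cells aggregate into 2-4
#' large chromocenters). Centromere foci (green) are placed inside each
#' chromocenter, `max(1, round(density * area))` per chromocenter.
#'
#' @param params a [populationParams()] object.
#' @param render if `FALSE`, skip raster rendering and return ground truth
#'   only (identical truth either way; useful for purely statistical work
#'   on the fragmentation law).
#' @return list with elements `images` (list of [NucleusImage-class], or
#'   `NULL` when `render = FALSE`) and `truth` (list of data.frames `cells`,
#'   `pads`, `foci` plus the `params`).
#' @examples
#' sim <- simulatePopulation(populationParams(nCells = 2, seed = 7))
#' sim$truth$cells
#' @export
simulatePopulation <- function(params, render = TRUE) {
  stopifnot(inherits(params, "populationParams"))
  p <- params
  seeds <- .splitSeeds(p$seed, p$nCells + ceiling(p$nCells / p$cellsPerField))
  cellSeeds <- seeds[seq_len(p$nCells)]
  fieldSeeds <- seeds[-seq_len(p$nCells)]

  classScale <- c("2C" = 1, "S-G2" = 2, "preapoptotic" = 0.6)
  W <- p$imageSize
  g <- ceiling(sqrt(p$cellsPerField))
  tile <- W / g
  nFields <- ceiling(p$nCells / p$cellsPerField)

  cells <- vector("list", p$nCells)
  padL <- vector("list", p$nCells)
  fociL <- vector("list", p$nCells)
  geom <- vector("list", p$nCells)

  for (i in seq_len(p$nCells)) {
    set.seed(cellSeeds[i])
    cls <- sample(names(p$classProbs), 1L, prob = p$classProbs)
    n <- if (cls == "preapoptotic") sample(2:4, 1L) else .drawCount(p$countLaw)
    total <- p$totalPadArea *
      if (p$areaCV > 0) exp(rnorm(1, 0, p$areaCV)) else 1
    areas <- .stickBreak(total, n, p$concentration,
                         minFrag = min(p$minFragArea, total / (2 * n)))
    k <- pmax(1L, as.integer(round(p$centromereDensity * areas)))

    fieldIdx <- ceiling(i / p$cellsPerField)
    slot <- (i - 1L) %% p$cellsPerField
    tr <- slot %/% g; tc <- slot %% g
    cx0 <- tc * tile + tile / 2 + runif(1, -0.04, 0.04) * tile
    cy0 <- tr * tile + tile / 2 + runif(1, -0.04, 0.04) * tile
    rx <- 0.30 * tile * runif(1, 0.95, 1.05)
    ry <- rx * runif(1, 0.85, 0.95)

    gm <- NULL
    for (att in 1:20) {  # re-randomize the whole arrangement if wedged
      gm <- tryCatch(.placeBlobs(areas, cx0, cy0, rx, ry, p$pxPerUm),
                     error = function(e) NULL)
      if (!is.null(gm)) break
    }
    if (is.null(gm))
      stop("placement failure: cell ", i, " (n = ", n,
           ") could not be arranged without overlap")
    fc <- .placeFoci(gm, k)

    cells[[i]] <- data.frame(cell_id = i, field_id = fieldIdx,
                             n_pads = n, total_pad_area_um2 = total,
                             dna_class = cls,
                             dapi_scale = unname(classScale[cls]),
                             cx = cx0, cy = cy0, rx = rx, ry = ry)
    padL[[i]] <- data.frame(cell_id = i, pad_id = seq_len(n),
                            area_um2 = areas, centromere_count = k,
                            cx = gm$cx, cy = gm$cy, r_px = gm$r,
                            sep_ok = fc$sep_ok)
    fociL[[i]] <- if (nrow(fc$xy))
      data.frame(cell_id = i, pad_id = fc$xy$pad, x = fc$xy$x, y = fc$xy$y)
    else NULL
    geom[[i]] <- list(cell = cells[[i]], pads = padL[[i]], foci = fc$xy)
  }

  truth <- list(cells = do.call(rbind, cells),
                pads = do.call(rbind, padL),
                foci = do.call(rbind, fociL),
                params = p)

  images <- NULL
  if (render) {
    images <- vector("list", nFields)
    for (f in seq_len(nFields)) {
      idx <- which(truth$cells$field_id == f)
      set.seed(fieldSeeds[f])
      images[[f]] <- .renderField(geom[idx], W, p$pxPerUm, p$noiseSd,
                                  fieldId = sprintf("field%04d", f))
    }
  }
  list(images = images, truth = truth)
}

## Rejection-sampling placement of disjoint discs inside an ellipse.
## Bounded retries; failure is reported, never silently overlapped.
.placeBlobs <- function(areas, cx0, cy0, rx, ry, pxPerUm,
                        gap = 2, maxTries = 200) {
  n <- length(areas)
  ord <- order(areas, decreasing = TRUE)
  r <- sqrt(areas / pi) * pxPerUm
  cx <- cy <- numeric(n)
  for (j in ord) {
    s <- 1 - (r[j] + gap) / min(rx, ry)
    if (s <= 0)
      stop("placement failure: chromocenter of radius ", round(r[j], 1),
           " px does not fit inside the nucleus")
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      repeat {
        u <- runif(1, -1, 1); v <- runif(1, -1, 1)
        if (u * u + v * v <= 1) break
      }
      x <- cx0 + u * rx * s; y <- cy0 + v * ry * s
      placed <- ord[seq_len(which(ord == j) - 1)]
      if (length(placed) == 0 ||
          all(sqrt((cx[placed] - x)^2 + (cy[placed] - y)^2) >
              r[placed] + r[j] + gap)) {
        cx[j] <- x; cy[j] <- y; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("placement failure: could not place chromocenter ", j,
           " without overlap after ", maxTries, " retries")
  }
  list(cx = cx, cy = cy, r = r)
}

## Foci inside discs, pairwise separation >= minSep when feasible.
.placeFoci <- function(gm, k, minSep = 4, maxTries = 200) {
  xs <- ys <- pad <- numeric(0)
  sep_ok <- logical(length(k))
  for (j in seq_along(k)) {
    # keep the whole detected focus footprint inside the chromocenter disc
    rr <- max(0.5, 0.7 * gm$r[j] - 1.5)
    px <- py <- numeric(0)
    ok <- TRUE
    for (m in seq_len(k[j])) {
      done <- FALSE
      for (t in seq_len(maxTries)) {
        a <- runif(1, 0, 2 * pi); d <- sqrt(runif(1)) * rr
        x <- gm$cx[j] + d * cos(a); y <- gm$cy[j] + d * sin(a)
        if (length(px) == 0 || all(sqrt((px - x)^2 + (py - y)^2) >= minSep)) {
          px <- c(px, x); py <- c(py, y); done <- TRUE; break
        }
      }
      if (!done) {  # best effort: place without the separation guarantee
        a <- runif(1, 0, 2 * pi); d <- sqrt(runif(1)) * rr
        px <- c(px, gm$cx[j] + d * cos(a)); py <- c(py, gm$cy[j] + d * sin(a))
        ok <- FALSE
      }
    }
    sep_ok[j] <- ok
    xs <- c(xs, px); ys <- c(ys, py); pad <- c(pad, rep(j, k[j]))
  }
  list(xy = data.frame(pad = pad, x = xs, y = ys), sep_ok = sep_ok)
}

.renderField <- function(cellGeoms, W, pxPerUm, noiseSd, fieldId,
                         dapiBase = 0.35, dapiPadExcess = 0.35,
                         redAmp = 0.8, focusAmp = 0.9, focusSigma = 0.8) {
  rowM <- row(matrix(0, W, W)); colM <- col(matrix(0, W, W))
  blue <- red <- green <- matrix(0, W, W)
  for (cg in cellGeoms) {
    ci <- cg$cell
    nucMask <- ((rowM - ci$cy) / ci$ry)^2 + ((colM - ci$cx) / ci$rx)^2 <= 1
    padMask <- matrix(FALSE, W, W)
    for (j in seq_len(nrow(cg$pads))) {
      pj <- cg$pads[j, ]
      d2 <- (rowM - pj$cy)^2 + (colM - pj$cx)^2
      sig <- pj$r_px / sqrt(2 * log(2))
      # Gaussian profile truncated at its half-maximum contour: soft-edged
      # inside the nominal radius, zero outside, so neighbouring
      # chromocenters never bridge through their tails.
      inside <- d2 <= pj$r_px^2
      red <- red + redAmp * exp(-d2 / (2 * sig^2)) * inside
      padMask <- padMask | inside
    }
    if (!is.null(cg$foci) && nrow(cg$foci)) {
      for (m in seq_len(nrow(cg$foci))) {
        d2 <- (rowM - cg$foci$y[m])^2 + (colM - cg$foci$x[m])^2
        green <- green + focusAmp * exp(-d2 / (2 * focusSigma^2)) *
          (d2 <= (3 * focusSigma)^2)
      }
    }
    blue <- blue + ci$dapi_scale * (dapiBase * nucMask + dapiPadExcess * padMask)
  }
  if (noiseSd > 0) {
    blue <- blue + rnorm(W * W, 0, noiseSd)
    red <- red + rnorm(W * W, 0, noiseSd)
    green <- green + rnorm(W * W, 0, noiseSd)
  }
  NucleusImage(list(blue = pmax(blue, 0), red = pmax(red, 0),
                    green = pmax(green, 0)),
               pxPerUm = pxPerUm, fieldId = fieldId)
}

#' Simulate an acridine-orange two-plane population
#'
#' Per-nucleus red/green integrated-intensity ratios are lognormally
#' distributed around `controlRG * shiftFactor`; `noiseSd` is the SD of
#' log(R/G) across nuclei (0 = every nucleus exactly at the target ratio).
#' One disc-shaped nucleus is rendered per field with uniform green
#' intensity and red = green x ratio; optional pixel read noise is clipped
#' at zero with the clip count reported in the log attribute.
#'
#' @param nCells number of nuclei.
#' @param controlRG baseline R/G of the untreated (starving control) state.
#' @param shiftFactor population shift (1 = no shift).
#' @param noiseSd SD of log(R/G) across nuclei.
#' @param seed root seed.
#' @param imageSize,pxPerUm field geometry.
#' @param pixelNoiseSd optional per-pixel Gaussian noise.
#' @return list(images, truth) where `truth$cells` carries `true_rg` and the
#'   attribute `clipped` on `images` counts zero-clipped pixels.
#' @export
simulateAOPopulation <- function(nCells, controlRG = 1, shiftFactor = 1,
                                 noiseSd = 0.15, seed = 1, imageSize = 96,
                                 pxPerUm = 8, pixelNoiseSd = 0) {
  stopifnot(nCells >= 1, controlRG > 0, shiftFactor > 0, noiseSd >= 0)
  seeds <- .splitSeeds(seed, nCells)
  W <- imageSize
  rowM <- row(matrix(0, W, W)); colM <- col(matrix(0, W, W))
  images <- vector("list", nCells)
  rg <- numeric(nCells)
  clipped <- 0L
  for (i in seq_len(nCells)) {
    set.seed(seeds[i])
    rg[i] <- controlRG * shiftFactor *
      if (noiseSd > 0) exp(rnorm(1, 0, noiseSd)) else 1
    disc <- (rowM - W / 2)^2 + (colM - W / 2)^2 <= (0.35 * W)^2
    green <- 0.5 * disc
    red <- green * rg[i]
    if (pixelNoiseSd > 0) {
      green <- green + rnorm(W * W, 0, pixelNoiseSd)
      red <- red + rnorm(W * W, 0, pixelNoiseSd)
      clipped <- clipped + sum(green < 0) + sum(red < 0)
      green <- pmax(green, 0); red <- pmax(red, 0)
    }
    images[[i]] <- NucleusImage(list(red = red, green = green),
                                pxPerUm = pxPerUm,
                                fieldId = sprintf("ao%04d", i))
  }
  attr(images, "clipped") <- clipped
  list(images = images,
       truth = list(cells = data.frame(cell_id = seq_len(nCells),
                                       true_rg = rg)))
}

#' Simulate a single-channel texture with controlled heterogeneity
#'
#' Builds an image whose measured >10 percent-deviation pixel fraction over
#' `mask` equals `targetFraction` (up to integer rounding): a fraction of
#' mask pixels is displaced symmetrically to `base * (1 +/- deviation)` so
#' the mask mean stays at `base` and exactly the displaced pixels deviate
#' beyond the tolerance.
#'
#' @param mask logical matrix (region of interest).
#' @param targetFraction desired deviating-pixel fraction in [0, 1].
#' @param seed seed choosing which pixels deviate.
#' @param base background intensity.
#' @param deviation relative displacement of deviating pixels (> tolerance
#'   used downstream; default 0.3).
#' @return numeric matrix, zero outside the mask.
#' @export
simulateHeterogeneityField <- function(mask, targetFraction, seed = 1,
                                       base = 0.5, deviation = 0.3) {
  stopifnot(is.matrix(mask), targetFraction >= 0, targetFraction <= 1,
            deviation > 0.1, base > 0)
  N <- sum(mask)
  if (N == 0) stop("empty mask")
  k <- round(targetFraction * N)
  if (abs(k / N - targetFraction) > 0.02)
    stop("infeasible target fraction ", targetFraction,
         " for a mask of ", N, " pixels")
  set.seed(seed)
  img <- matrix(0, nrow(mask), ncol(mask))
  img[mask] <- base
  if (k > 0) {
    idx <- sample(which(mask), k)
    kUp <- ceiling(k / 2)
    img[idx[seq_len(kUp)]] <- base * (1 + deviation)
    if (k > kUp) img[idx[(kUp + 1):k]] <- base * (1 - deviation)
  }
  img
}

#' Parameters of a simulated qPCR plate
#'
#' @param genes named list; one named numeric vector of true fold changes
#'   per gene, indexed by sample label (control sample fold = 1).
#' @param refGenes named numeric vector: reference-gene labels with their
#'   true instability (SD of log2 expression across samples; 0 = perfectly
#'   stable).
#' @param replicates technical replicates per well group.
#' @param ctNoiseSd per-well CT measurement noise, cycles.
#' @param baselineCt,refBaselineCt CT at unit expression for target and
#'   reference genes.
#' @param seed root seed.
#' @return list of class `qpcrSimParams`.
#' @export
qpcrSimParams <- function(genes, refGenes = c(GAPDH = 0, B2M = 0),
                          replicates = 4, ctNoiseSd = 0.2,
                          baselineCt = 26, refBaselineCt = 20, seed = 1) {
  stopifnot(is.list(genes), length(genes) >= 1, replicates >= 1,
            ctNoiseSd >= 0, all(refGenes >= 0), length(refGenes) >= 1)
  samples <- names(genes[[1]])
  if (is.null(samples)) stop("fold-change vectors must be named by sample")
  for (g in genes) stopifnot(identical(names(g), samples), all(g > 0))
  structure(list(genes = genes, refGenes = refGenes, samples = samples,
                 replicates = as.integer(replicates), ctNoiseSd = ctNoiseSd,
                 baselineCt = baselineCt, refBaselineCt = refBaselineCt,
                 seed = as.integer(seed)),
            class = "qpcrSimParams")
}

#' Simulate a qPCR CT table
#'
#' CT = baseline - log2(expression) + noise per well. Target-gene expression
#' follows the specified fold changes; reference-gene log2 expression wobbles
#' across samples with the stated instability SD.
#'
#' @param params a [qpcrSimParams()] object.
#' @return data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @examples
#' p <- qpcrSimParams(list(FOS = c(ST = 1, HRG20 = 4)), ctNoiseSd = 0)
#' simulateQPCRPlate(p)
#' @export
simulateQPCRPlate <- function(params) {
  stopifnot(inherits(params, "qpcrSimParams"))
  p <- params
  set.seed(p$seed)
  rows <- list()
  for (g in names(p$genes)) {
    for (s in p$samples) {
      ct <- p$baselineCt - log2(p$genes[[g]][[s]]) +
        rnorm(p$replicates, 0, p$ctNoiseSd)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = s, gene = g, replicate = seq_len(p$replicates),
                   ct = ct)
    }
  }
  for (r in names(p$refGenes)) {
    for (s in p$samples) {
      wobble <- if (p$refGenes[[r]] > 0) rnorm(1, 0, p$refGenes[[r]]) else 0
      ct <- p$refBaselineCt - wobble + rnorm(p$replicates, 0, p$ctNoiseSd)
      rows[[length(rows) + 1L]] <-
        data.frame(sample = s, gene = r, replicate = seq_len(p$replicates),
                   ct = ct)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
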