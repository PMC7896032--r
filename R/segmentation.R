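## Segmentation of nuclei (DAPI/blue), chromocenters (H3K9me3/red) and
## centromere foci (CENPA/green). The original measurements were made on
## interactively drawn contours; here every contour is derived automatically
## from configurable thresholds so that runs are reproducible.

#' Label connected components of a binary mask
#'
#' 8-connectivity (default) is obtained by labelling with 4-connectivity via
#' \code{EBImage::bwlabel} and then merging labels that touch diagonally
#' (union-find over the label graph).
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), labels
#'   compact and ordered by first pixel in column-major order.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  lab <- EBImage::imageData(EBImage::bwlabel(mask != 0))
  K <- max(lab)
  if (K == 0 || connectivity == 4) return(matrix(as.integer(lab), nrow(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal neighbours
  c2 <- lab[-nr, -1]; d <- lab[-1, -nc]    # up-right diagonal neighbours
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c2), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(K), find, integer(1))
  compact <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  matrix(as.integer(out), nr)
}

#' Default segmentation configuration
#'
#' All thresholds of the quantification pipeline in one place; any subset
#' can be overridden via the `config` argument of the segmentation
#' functions or the YAML run configuration.
#'
#' @return named list of defaults: `blurSigma` (px, DAPI smoothing before
#'   Otsu), `nucleusThreshFrac` (the Otsu cut is multiplied by this factor
#'   so that dim nuclei -- preapoptotic cells with partial DNA loss -- stay
#'   above threshold), `minNucleusArea`/`maxNucleusArea` (um^2; objects below are
#'   dropped, above are flagged as under-segmented), `dropBorder`,
#'   `minPadAreaUm2` (0.2 um^2, the finest resolvable chromocenter unit),
#'   `padThreshFrac`/`fociThreshFrac` (fraction of the background-to-peak
#'   range used as threshold), `minFocusPx`, `modeWindow` (2C gate
#'   half-width), `hetTolerance` (heterogeneity deviation tolerance).
#' @export
segmentationConfig <- function() {
  list(blurSigma = 2, nucleusThreshFrac = 0.6,
       minNucleusArea = 20, maxNucleusArea = 400,
       dropBorder = TRUE, minPadAreaUm2 = 0.2, padThreshFrac = 0.5,
       fociThreshFrac = 0.5, minFocusPx = 1, modeWindow = 0.25,
       hetTolerance = 0.10)
}

.mergeConfig <- function(config) {
  cfg <- segmentationConfig()
  if (!is.null(config)) cfg[names(config)] <- config
  cfg
}

#' Segment nuclei from the DAPI (blue) channel
#'
#' Gaussian smoothing followed by Otsu thresholding and 8-connected
#' labelling. Objects touching the image border or smaller than
#' `minNucleusArea` are dropped (counted in the log); objects larger than
#' `maxNucleusArea` are kept but flagged as under-segmented. The integrated
#' DAPI fluorescence intensity (IFI) of each nucleus is measured over its
#' mask; gates start as `"unassigned"` (see [gateCells()]).
#'
#' @param image a [NucleusImage-class] with a `blue` channel.
#' @param config list overriding [segmentationConfig()] entries.
#' @return a [NucleusSet-class]. An image without signal yields an empty set.
#' @export
segmentNuclei <- function(image, config = NULL) {
  stopifnot(is(image, "NucleusImage"))
  cfg <- .mergeConfig(config)
  blue <- channel(image, "blue")
  emptySet <- function(log) new("NucleusSet",
    labels = matrix(0L, nrow(blue), ncol(blue)),
    table = data.frame(nucleus_id = integer(), area_px = numeric(),
                       area_um2 = numeric(), dapi_ifi = numeric(),
                       gate = character(), flag = character()),
    pxPerUm = pxPerUm(image), log = log)
  rng <- range(blue)
  if (diff(rng) == 0)
    return(emptySet(list(dropped_small = 0L, dropped_border = 0L,
                         undersegmented = 0L, note = "flat blue channel")))
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(blue),
                                          sigma = cfg$blurSigma))
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- cfg$nucleusThreshFrac *
    EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  mask <- smn > thr
  lab <- labelComponents(mask, 8)
  K <- max(lab)
  if (K == 0)
    return(emptySet(list(dropped_small = 0L, dropped_border = 0L,
                         undersegmented = 0L)))
  pxArea <- 1 / pxPerUm(image)^2
  keep <- integer(0); droppedSmall <- 0L; droppedBorder <- 0L; underseg <- 0L
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab[lab > 0], nbins = K)
  flags <- character(0)
  for (k in seq_len(K)) {
    if (cfg$dropBorder && k %in% border) { droppedBorder <- droppedBorder + 1L
    } else if (areas[k] * pxArea < cfg$minNucleusArea) {
      droppedSmall <- droppedSmall + 1L
    } else {
      keep <- c(keep, k)
      if (areas[k] * pxArea > cfg$maxNucleusArea) {
        underseg <- underseg + 1L
        flags <- c(flags, "undersegmented")
      } else flags <- c(flags, "")
    }
  }
  out <- lab
  out[!(lab %in% keep)] <- 0L
  newId <- match(out[out > 0], keep)
  out[out > 0] <- newId
  ifi <- vapply(seq_along(keep),
                function(i) sum(blue[out == i]), numeric(1))
  tb <- data.frame(nucleus_id = seq_along(keep),
                   area_px = areas[keep],
                   area_um2 = areas[keep] * pxArea,
                   dapi_ifi = ifi,
                   gate = rep("unassigned", length(keep)),
                   flag = flags)
  new("NucleusSet", labels = matrix(as.integer(out), nrow(out)), table = tb,
      pxPerUm = pxPerUm(image),
      log = list(dropped_small = droppedSmall,
                 dropped_border = droppedBorder,
                 undersegmented = underseg))
}

#' Integrated fluorescence intensity over a mask
#'
#' Sum of channel intensities over the mask pixels; additive over any
#' partition of the mask.
#'
#' @param image a [NucleusImage-class].
#' @param mask logical matrix (same shape as the image).
#' @param channelName channel to integrate (default `"blue"`, the DAPI IFI
#'   used as DNA-content proxy).
#' @return numeric scalar.
#' @examples
#' img <- NucleusImage(list(blue = matrix(3, 10, 10)), pxPerUm = 1)
#' measureDNAContent(img, matrix(TRUE, 10, 10))  # 300
#' @export
measureDNAContent <- function(image, mask, channelName = "blue") {
  stopifnot(is(image, "NucleusImage"), is.matrix(mask),
            all(dim(mask) == dim(image)))
  sum(channel(image, channelName)[mask != 0])
}

#' Segment chromocenters (PADs) inside nucleus masks
#'
#' Within each nucleus, the red (H3K9me3) plane is thresholded at
#' `background + padThreshFrac * (peak - background)` where background is
#' the median red intensity inside the nucleus; 8-connected components
#' smaller than `minPadAreaUm2` (default 0.2 um^2, the finest resolvable
#' chromocenter unit) are discarded and counted in the log. PAD masks are
#' clipped to their parent nucleus, so nesting and pairwise disjointness
#' hold by construction.
#'
#' @param image a [NucleusImage-class] with a `red` channel.
#' @param nuclei a [NucleusSet-class] from [segmentNuclei()].
#' @param config list overriding [segmentationConfig()] entries.
#' @return a [PADSet-class]; `centromere_count` is `NA` until
#'   [countCentromeres()] fills it.
#' @export
segmentPADs <- function(image, nuclei, config = NULL) {
  stopifnot(is(image, "NucleusImage"), is(nuclei, "NucleusSet"))
  cfg <- .mergeConfig(config)
  red <- channel(image, "red")
  nlab <- labelMatrix(nuclei)
  pxArea <- 1 / pxPerUm(image)^2
  minPx <- cfg$minPadAreaUm2 / pxArea
  out <- matrix(0L, nrow(red), ncol(red))
  rows <- list(); droppedSmall <- 0L; padId <- 0L
  for (nid in records(nuclei)$nucleus_id) {
    inNuc <- nlab == nid
    vals <- red[inNuc]
    bg <- median(vals); pk <- max(vals)
    if (pk <= bg) next
    thr <- bg + cfg$padThreshFrac * (pk - bg)
    mask <- (red > thr) & inNuc
    lab <- labelComponents(mask, 8)
    K <- max(lab)
    if (K == 0) next
    areas <- tabulate(lab[lab > 0], nbins = K)
    for (k in seq_len(K)) {
      if (areas[k] < minPx) { droppedSmall <- droppedSmall + 1L; next }
      padId <- padId + 1L
      out[lab == k] <- padId
      rows[[padId]] <- data.frame(pad_id = padId, nucleus_id = nid,
                                  area_px = areas[k],
                                  area_um2 = areas[k] * pxArea,
                                  centromere_count = NA_integer_)
    }
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pad_id = integer(), nucleus_id = integer(),
               area_px = numeric(), area_um2 = numeric(),
               centromere_count = integer())
  new("PADSet", labels = out, table = tb, pxPerUm = pxPerUm(image),
      log = list(dropped_small = droppedSmall))
}

#' Count centromere foci per chromocenter
#'
#' Green (CENPA) foci are 8-connected components of the thresholded green
#' plane (threshold analogous to the PAD rule, computed over the whole
#' image) of at least `minFocusPx` pixels; each focus is assigned to the
#' PAD whose mask contains its centroid pixel. PADs with no focus get 0.
#'
#' @param image a [NucleusImage-class] with a `green` channel.
#' @param pads a [PADSet-class].
#' @param config list overriding [segmentationConfig()] entries.
#' @return the [PADSet-class] with `centromere_count` filled; the log gains
#'   `foci_total` (components found) and `foci_outside` (centroid in no PAD).
#' @export
countCentromeres <- function(image, pads, config = NULL) {
  stopifnot(is(image, "NucleusImage"), is(pads, "PADSet"))
  cfg <- .mergeConfig(config)
  green <- channel(image, "green")
  tb <- records(pads)
  tb$centromere_count <- 0L
  plab <- labelMatrix(pads)
  bg <- median(green); pk <- max(green)
  log <- processingLog(pads)
  if (pk > bg) {
    thr <- bg + cfg$fociThreshFrac * (pk - bg)
    lab <- labelComponents(green > thr, 8)
    K <- max(lab)
    outside <- 0L
    if (K > 0) for (k in seq_len(K)) {
      px <- which(lab == k, arr.ind = TRUE)
      if (nrow(px) < cfg$minFocusPx) next
      cy <- round(mean(px[, 1])); cx <- round(mean(px[, 2]))
      pid <- plab[cy, cx]
      if (pid > 0) {
        i <- which(tb$pad_id == pid)
        tb$centromere_count[i] <- tb$centromere_count[i] + 1L
      } else outside <- outside + 1L
    }
    log$foci_total <- K
    log$foci_outside <- outside
  } else {
    log$foci_total <- 0L
    log$foci_outside <- 0L
  }
  new("PADSet", labels = plab, table = tb, pxPerUm = pxPerUm(pads), log = log)
}
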