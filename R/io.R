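## File interfaces: multi-page 16-bit TIFF (with a JSON sidecar naming the
## channel order and intensity scale), 8/16-bit PNG, CT tables and ground
## truth as CSV, run configuration as YAML.

#' Write a NucleusImage as multi-page 16-bit TIFF
#'
#' One page per channel, written in the image's channel order (by default
#' blue, red, green). Intensities are divided by `scaleMax` and clipped to
#' [0, 1] for the 16-bit encoding; a JSON sidecar `<path>.json` records the
#' channel order, calibration and scale so the image can be re-read
#' losslessly up to 16-bit quantization.
#'
#' @param image a [NucleusImage-class].
#' @param path output TIFF path.
#' @param scaleMax intensity mapped to the 16-bit maximum.
#' @return the path, invisibly.
#' @export
writeNucleusImage <- function(image, path, scaleMax = 4) {
  stopifnot(is(image, "NucleusImage"), scaleMax > 0)
  pages <- lapply(channelNames(image), function(nm)
    pmin(pmax(channel(image, nm) / scaleMax, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(channels = channelNames(image), px_per_um = pxPerUm(image),
               field_id = fieldId(image), scale_max = scaleMax)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a NucleusImage from TIFF or PNG
#'
#' Multi-page TIFF pages map to channels in order; an RGB PNG maps its
#' planes to the given channel names. If a JSON sidecar written by
#' [writeNucleusImage()] exists it supplies channel names, calibration and
#' intensity scale; explicit arguments override it.
#'
#' @param path TIFF or PNG file.
#' @param channels channel names in page/plane order (default blue, red,
#'   green, truncated to the number of planes found).
#' @param pxPerUm calibration; required if no sidecar is present.
#' @param scaleMax intensity scale to undo (default from sidecar, else 1).
#' @return a [NucleusImage-class].
#' @export
readNucleusImage <- function(path, channels = c("blue", "red", "green"),
                             pxPerUm = NULL, scaleMax = NULL) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (missing(channels)) channels <- meta$channels
    if (is.null(pxPerUm)) pxPerUm <- meta$px_per_um
    if (is.null(scaleMax)) scaleMax <- meta$scale_max
  }
  if (is.null(scaleMax)) scaleMax <- 1
  if (is.null(pxPerUm)) stop("pxPerUm required (no sidecar found)")
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    arr <- png::readPNG(path)
    planes <- if (length(dim(arr)) == 2) list(arr) else
      lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    planes <- if (is.list(pages)) pages else list(pages)
    planes <- lapply(planes, function(p)
      if (length(dim(p)) == 3) p[, , 1] else p)
  }
  k <- min(length(planes), length(channels))
  ch <- lapply(planes[seq_len(k)], function(p) p * scaleMax)
  names(ch) <- channels[seq_len(k)]
  NucleusImage(ch, pxPerUm = pxPerUm,
               fieldId = sub("\\.(tiff?|png)$", "", basename(path),
                             ignore.case = TRUE))
}

#' Write a simulated population to disk
#'
#' Per-field TIFFs (via [writeNucleusImage()]), ground truth as CSV files
#' with a JSON sidecar, and the generator parameters as YAML.
#'
#' @param sim result of [simulatePopulation()] (rendered).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(!is.null(sim$images))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in sim$images)
    writeNucleusImage(img, file.path(dir, paste0(fieldId(img), ".tif")))
  write.csv(sim$truth$cells, file.path(dir, "truth_cells.csv"),
            row.names = FALSE)
  write.csv(sim$truth$pads, file.path(dir, "truth_pads.csv"),
            row.names = FALSE)
  if (!is.null(sim$truth$foci))
    write.csv(sim$truth$foci, file.path(dir, "truth_foci.csv"),
              row.names = FALSE)
  jsonlite::write_json(list(n_fields = length(sim$images),
                            files = vapply(sim$images, fieldId, "")),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  p <- sim$truth$params
  yaml::write_yaml(p[setdiff(names(p), "classProbs")],
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a CT table from CSV
#'
#' Expected header: `sample,gene,replicate,ct` (CT in cycles, positive).
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
readCTTable <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(tb)))
    stop("CT table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(tb$ct)) || any(tb$ct <= 0))
    stop("CT values must be positive numbers")
  tb
}
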