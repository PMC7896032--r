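## End-to-end runners tying generation -> quantification -> fits ->
## statistics -> report. Every runner is deterministic given its
## configuration (which includes the seed), writes documented CSV/JSON
## outputs plus a run log with dropped-object counts, and returns its
## results invisibly.

#' Default run configuration
#'
#' The YAML-serializable configuration consumed by [runPads()], [runAO()]
#' and [runQPCR()]. Cohorts/groups are either simulated (`simulate:` block
#' of [populationParams()] / [simulateAOPopulation()] arguments) or read
#' from a directory of TIFF/PNG fields (`dir:` plus `px_per_um`).
#'
#' @return nested named list with entries `seed`, `outdir`, `segmentation`
#'   (overrides of [segmentationConfig()]), `pads` (cohorts `control` and
#'   optional `treated`), `ao` (`control`, `groups`, `noise_sd`), `qpcr`
#'   (`table` or `simulate`, `targets`, `ref`, `control_sample`).
#' @export
defaultRunConfig <- function() {
  list(seed = 1, outdir = "padcyto_out",
       segmentation = list(),
       pads = list(control = list(simulate = list(nCells = 30))),
       ao = list(control = list(nCells = 100, shiftFactor = 1),
                 groups = list(HRG20 = list(nCells = 100,
                                            shiftFactor = 1.16)),
                 noiseSd = 0.15),
       # gene maps are nested lists (not named vectors) so they survive a
       # YAML round trip with names intact
       qpcr = list(simulate = list(
                     genes = list(HS3_9 = list(ST = 1, HRG20 = 0.8,
                                               HRG60 = 1.5)),
                     ctNoiseSd = 0.2),
                   targets = "HS3_9", ref = "GAPDH",
                   control_sample = "ST"))
}

#' Read a YAML run configuration
#'
#' Missing top-level entries are filled from [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  cfg
}

.logLines <- new.env(parent = emptyenv())

.logReset <- function() assign("lines", character(0), envir = .logLines)
.log <- function(...) {
  msg <- paste0(...)
  assign("lines", c(get("lines", envir = .logLines), msg),
         envir = .logLines)
  invisible(msg)
}
.logWrite <- function(outdir, file = "run.log") {
  writeLines(get("lines", envir = .logLines), file.path(outdir, file))
}

## Load a cohort: simulated (seeded) or a directory of image files.
.loadCohort <- function(spec, seed) {
  if (!is.null(spec$simulate)) {
    args <- spec$simulate
    if (is.null(args$seed)) args$seed <- seed
    params <- do.call(populationParams, args)
    sim <- simulatePopulation(params)
    list(images = sim$images, truth = sim$truth)
  } else if (!is.null(spec$dir)) {
    files <- sort(list.files(spec$dir, pattern = "\\.(tiff?|png)$",
                             full.names = TRUE, ignore.case = TRUE))
    imgs <- list()
    for (f in files) {
      img <- tryCatch(readNucleusImage(f, pxPerUm = spec$px_per_um),
                      error = function(e) {
                        .log("skipped unreadable image ", f, ": ",
                             conditionMessage(e))
                        NULL
                      })
      if (!is.null(img)) imgs[[length(imgs) + 1L]] <- img
    }
    list(images = imgs, truth = NULL)
  } else stop("cohort needs either a 'simulate' block or a 'dir'")
}

## Quantify one cohort of fields: segment, pool-gate, segment PADs, count
## centromeres, heterogeneity, per-cell summary.
.quantifyCohort <- function(images, segConfig) {
  perField <- list()
  for (img in images) {
    nuc <- segmentNuclei(img, segConfig)
    lg <- processingLog(nuc)
    .log(fieldId(img), ": ", nrow(records(nuc)), " nuclei (dropped small=",
         lg$dropped_small, ", border=", lg$dropped_border,
         ", undersegmented=", lg$undersegmented, ")")
    if (nrow(records(nuc)) == 0) next
    pads <- segmentPADs(img, nuc, segConfig)
    pads <- countCentromeres(img, pads, segConfig)
    .log(fieldId(img), ": ", nrow(records(pads)), " PADs (dropped small=",
         processingLog(pads)$dropped_small, ")")
    cs <- summarizeCells(nuc, pads, image = img,
                         tolerance = .mergeConfig(segConfig)$hetTolerance)
    ntb <- records(nuc)
    cs$dapi_ifi <- ntb$dapi_ifi
    cs$field_id <- fieldId(img)
    ptb <- records(pads)
    if (nrow(ptb)) ptb$field_id <- fieldId(img)
    perField[[length(perField) + 1L]] <- list(cells = cs, pads = ptb)
  }
  if (length(perField) == 0) stop("zero segmented cells; aborting")
  cells <- do.call(rbind, lapply(perField, `[[`, "cells"))
  pads <- do.call(rbind, lapply(perField, `[[`, "pads"))
  # pooled DNA-content gating across all fields of the cohort
  pooled <- new("NucleusSet", labels = matrix(0L, 1, 1),
                table = data.frame(nucleus_id = seq_len(nrow(cells)),
                                   area_px = 1, area_um2 = 1,
                                   dapi_ifi = cells$dapi_ifi,
                                   gate = "unassigned"),
                pxPerUm = 1, log = list())
  gated <- tryCatch(gateCells(pooled,
                              modeWindow = .mergeConfig(segConfig)$modeWindow,
                              padArea = cells$mean_area_um2),
                    warning = function(w) { .log("gating: ",
                                                 conditionMessage(w));
                      suppressWarnings(gateCells(pooled)) })
  cells$gate <- records(gated)$gate
  fr <- processingLog(gated)$gate_fractions
  if (!is.null(fr))
    .log("gate fractions: ",
         paste(names(fr), round(fr, 3), sep = "=", collapse = ", "))
  list(cells = cells, pads = pads)
}

.fitSummary <- function(f) {
  if (is.null(f)) return(NULL)
  list(model = f@model, intercept = unname(coef(f)["intercept"]),
       slope = unname(coef(f)["slope"]), exponent = exponent(f),
       r2 = r2(f), n_points = nPoints(f))
}

#' Run the chromocenter size-number pipeline
#'
#' Generation (or loading) -> nucleus segmentation -> pooled DNA-content
#' gating -> chromocenter segmentation -> centromere counting ->
#' heterogeneity -> per-cell summary -> size-number fits; with a treated
#' cohort, the control-versus-treated comparison. Writes `per_cell.csv`,
#' `pads.csv`, `fits.json`, `comparison.json` (when applicable) and
#' `run.log` into the output directory. Deterministic given config + seed.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a path
#'   to a YAML file.
#' @return invisibly, a list with `cells`, `pads`, `fits` and (optionally)
#'   `comparison`.
#' @export
runPads <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  .logReset()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seg <- config$segmentation

  ctl <- .loadCohort(config$pads$control, config$seed)
  qc <- .quantifyCohort(ctl$images, seg)
  qc$cells$cohort <- "control"
  if (nrow(qc$pads)) qc$pads$cohort <- "control"
  cells <- qc$cells; pads <- qc$pads

  cmp <- NULL
  if (!is.null(config$pads$treated)) {
    trt <- .loadCohort(config$pads$treated, config$seed + 1L)
    qt <- .quantifyCohort(trt$images, seg)
    qt$cells$cohort <- "treated"
    if (nrow(qt$pads)) qt$pads$cohort <- "treated"
    cmp <- compareConditions(qc$cells, qt$cells)
    cells <- rbind(cells, qt$cells)
    pads <- rbind(pads, qt$pads)
  }

  use <- qc$cells[qc$cells$gate %in% c("2C", "unassigned") &
                  qc$cells$n_pads >= 1, ]
  fits <- list(
    reciprocal_sqrt = tryCatch(fitReciprocalSqrt(use),
                               error = function(e) { .log("fit: ",
                                 conditionMessage(e)); NULL }),
    power = tryCatch(fitPowerLaw(use$mean_area_um2, use$n_pads),
                     error = function(e) { .log("fit: ",
                       conditionMessage(e)); NULL }),
    exponential = tryCatch(fitExponential(qc$pads$area_um2),
                           error = function(e) { .log("fit: ",
                             conditionMessage(e)); NULL }),
    centromere = tryCatch(fitCentromereClustering(qc$pads),
                          error = function(e) { .log("fit: ",
                            conditionMessage(e)); NULL }))

  write.csv(cells, file.path(config$outdir, "per_cell.csv"),
            row.names = FALSE)
  write.csv(pads, file.path(config$outdir, "pads.csv"), row.names = FALSE)
  fitsJson <- list(
    reciprocal_sqrt = .fitSummary(fits$reciprocal_sqrt),
    power = .fitSummary(fits$power),
    exponential = .fitSummary(fits$exponential),
    centromere_linear = .fitSummary(fits$centromere$linear),
    centromere_exponential = .fitSummary(fits$centromere$exponential))
  jsonlite::write_json(fitsJson, file.path(config$outdir, "fits.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  if (!is.null(cmp))
    jsonlite::write_json(
      list(control_median_mean_area = cmp$control$median_mean_area,
           treated_median_mean_area = cmp$treated$median_mean_area,
           welch_p = cmp$test$p, r2_drop = cmp$r2_drop),
      file.path(config$outdir, "comparison.json"),
      auto_unbox = TRUE, digits = 10, null = "null")
  .logWrite(config$outdir)
  invisible(list(cells = cells, pads = pads, fits = fits,
                 comparison = cmp))
}

#' Run the acridine-orange R/G pipeline
#'
#' For the control and each treated group: simulate (or load) two-plane
#' fields, segment nuclei on the summed planes, measure per-nucleus R/G,
#' normalize all groups to the control mean, Welch-test each group against
#' control (one Benjamini-Hochberg family per run), and write
#' `ao_cells.csv`, `ao_summary.csv`, `ao_tests.csv` and `run.log`.
#'
#' @param config configuration list or YAML path; see [defaultRunConfig()]
#'   (`ao` block: `control` and `groups` are argument lists for
#'   [simulateAOPopulation()], or `dir` specs).
#' @return invisibly: list with `cells`, `summary`, `tests`.
#' @export
runAO <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  .logReset()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ao <- config$ao
  groups <- c(list(control = ao$control), ao$groups)
  vals <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    spec <- groups[[gi]]
    if (!is.null(spec$dir)) {
      coh <- .loadCohort(spec, config$seed + gi)
      imgs <- coh$images
    } else {
      args <- spec
      if (is.null(args$noiseSd)) args$noiseSd <- ao$noiseSd
      if (is.null(args$seed)) args$seed <- config$seed + gi
      imgs <- do.call(simulateAOPopulation, args)$images
    }
    rg <- numeric(0)
    for (img in imgs) {
      red <- channel(img, "red"); green <- channel(img, "green")
      seg <- segmentNuclei(NucleusImage(
        list(blue = red + green, red = red, green = green),
        pxPerUm = pxPerUm(img), fieldId = fieldId(img)),
        config$segmentation)
      if (nrow(records(seg)) == 0) next
      m <- rgIndexSet(img, seg)
      rg <- c(rg, m$rg_raw[m$valid])
      if (any(!m$valid)) .log(fieldId(img), ": ", sum(!m$valid),
                              " invalid R/G measurement(s)")
    }
    .log("group ", gname, ": ", length(rg), " nuclei measured")
    vals[[gname]] <- rg
  }
  if (length(vals$control) == 0) stop("zero segmented control cells")
  norm <- lapply(vals, function(v) v / mean(vals$control))
  cellsTab <- do.call(rbind, lapply(names(norm), function(g)
    data.frame(group = g, rg_raw = vals[[g]], rg_norm = norm[[g]])))
  summaryTab <- do.call(rbind, lapply(names(norm), function(g)
    data.frame(group = g, mean = mean(norm[[g]]), sd = sd(norm[[g]]),
               n = length(norm[[g]]))))
  testRows <- lapply(setdiff(names(norm), "control"), function(g) {
    r <- shiftTest(norm$control, norm[[g]])
    r$comparison <- paste("control vs", g)
    r
  })
  tests <- if (length(testRows)) {
    tt <- do.call(rbind, testRows)
    tt$p_adjusted <- bhAdjust(tt$p)
    tt
  } else NULL
  write.csv(cellsTab, file.path(config$outdir, "ao_cells.csv"),
            row.names = FALSE)
  write.csv(summaryTab, file.path(config$outdir, "ao_summary.csv"),
            row.names = FALSE)
  if (!is.null(tests))
    write.csv(tests, file.path(config$outdir, "ao_tests.csv"),
              row.names = FALSE)
  .logWrite(config$outdir, "ao_run.log")
  invisible(list(cells = cellsTab, summary = summaryTab, tests = tests))
}

#' Run the qPCR relative-quantification pipeline
#'
#' Loads (or simulates) a CT table, computes RQ per target gene against the
#' configured reference scheme and control sample, the geNorm M of the
#' reference candidates (when two or more), and the per-gene
#' maximum-normalized time course. Writes `rq.csv`, `biphasic.csv`,
#' `genorm.csv` and `run.log`.
#'
#' @param config configuration list or YAML path; `qpcr` block fields:
#'   `table` (CSV path) or `simulate` ([qpcrSimParams()] arguments),
#'   `targets`, `ref` (one or two gene names), `control_sample`.
#' @return invisibly: list with `rq`, `biphasic`, `genorm`.
#' @export
runQPCR <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  .logReset()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  q <- config$qpcr
  if (!is.null(q$table)) {
    tb <- readCTTable(q$table)
  } else {
    args <- q$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    if (!is.null(args$genes))
      args$genes <- lapply(args$genes, function(g) unlist(g))
    if (!is.null(args$refGenes)) args$refGenes <- unlist(args$refGenes)
    tb <- simulateQPCRPlate(do.call(qpcrSimParams, args))
  }
  ref <- unlist(q$ref)
  rqTab <- do.call(rbind, lapply(unlist(q$targets), function(g)
    rq(tb, g, ref, q$control_sample)))
  .log("RQ computed for ", length(unique(rqTab$gene)), " gene(s), ",
       length(unique(rqTab$sample)), " sample(s); reference scheme: ",
       if (length(ref) == 2) "two-gene geometric mean" else "single-gene")
  biph <- tryCatch(normalizeBiphasicReport(rqTab),
                   error = function(e) { .log("biphasic: ",
                     conditionMessage(e)); NULL })
  gen <- if (length(ref) >= 2) {
    m <- genormM(tb, ref)
    data.frame(gene = names(m), M = unname(m))
  } else NULL
  write.csv(rqTab, file.path(config$outdir, "rq.csv"), row.names = FALSE)
  if (!is.null(biph))
    write.csv(biph, file.path(config$outdir, "biphasic.csv"),
              row.names = FALSE)
  if (!is.null(gen))
    write.csv(gen, file.path(config$outdir, "genorm.csv"),
              row.names = FALSE)
  .logWrite(config$outdir, "qpcr_run.log")
  invisible(list(rq = rqTab, biphasic = biph, genorm = gen))
}
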