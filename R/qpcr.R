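## qPCR relative quantification: delta-CT against one reference gene or the
## geometric mean of two, delta-delta-CT and RQ = 2^-ddCT against a control
## sample, the geNorm reference-stability measure M, and per-gene
## normalization of time courses to their maximum. Amplification efficiency
## is fixed at 2 (the 2^-ddCT model); CT replicates are averaged
## arithmetically before any difference is taken.

.meanCt <- function(table, gene) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(table)))
  sub <- table[table$gene == gene, ]
  if (nrow(sub) == 0) stop("gene '", gene, "' absent from the CT table")
  out <- aggregate(ct ~ sample, data = sub, FUN = mean)
  setNames(out$ct, out$sample)
}

#' Delta-CT of a target gene against one or two reference genes
#'
#' Replicates are averaged first; dCT = mean CT(target) - mean CT(ref).
#' With two reference genes the reference CT is the arithmetic mean of the
#' pair's CTs, which on the quantity scale is geometric-mean normalization.
#'
#' @param table CT table: columns `sample`, `gene`, `replicate`, `ct`.
#' @param target target gene name.
#' @param ref one or two reference gene names.
#' @return named numeric vector of dCT per sample.
#' @examples
#' tb <- data.frame(sample = "ST", gene = c("HS3_9", "GAPDH"),
#'                  replicate = 1, ct = c(25, 20))
#' deltaCt(tb, "HS3_9", "GAPDH")  # 5
#' @export
deltaCt <- function(table, target, ref) {
  stopifnot(length(ref) %in% c(1, 2))
  tg <- .meanCt(table, target)
  refCt <- .meanCt(table, ref[1])
  if (length(ref) == 2) {
    r2ct <- .meanCt(table, ref[2])
    common <- intersect(names(refCt), names(r2ct))
    refCt <- (refCt[common] + r2ct[common]) / 2
  }
  miss <- setdiff(names(tg), names(refCt))
  if (length(miss))
    stop("reference missing in sample(s): ", paste(miss, collapse = ", "))
  tg - refCt[names(tg)]
}

#' Relative quantification (delta-delta-CT)
#'
#' ddCT = dCT - dCT(control sample); RQ = 2^-ddCT, so the control sample's
#' RQ is exactly 1 and log2(RQ) = -ddCT to machine precision. Computed
#' within one plate (one CT table); no cross-plate pooling.
#'
#' @param table CT table (columns `sample`, `gene`, `replicate`, `ct`).
#' @param target target gene name.
#' @param ref one or two reference gene names (see [deltaCt()]).
#' @param controlSample label of the calibrator sample.
#' @return data.frame per sample: `sample`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `rq`, plus the reference scheme as an attribute.
#' @export
rq <- function(table, target, ref, controlSample) {
  d <- deltaCt(table, target, ref)
  if (!controlSample %in% names(d))
    stop("control sample '", controlSample, "' absent")
  dd <- d - d[[controlSample]]
  out <- data.frame(sample = names(d), gene = target,
                    delta_ct = unname(d), delta_delta_ct = unname(dd),
                    rq = unname(2^(-dd)))
  attr(out, "ref_scheme") <- if (length(ref) == 2)
    "two-gene geometric mean" else "single-gene"
  rownames(out) <- NULL
  out
}

#' geNorm expression-stability measure M
#'
#' For candidate reference gene j, M(j) is the mean over the other
#' candidates k of the standard deviation across samples of
#' log2(Q_j / Q_k), with Q = 2^-CT the relative quantity. Perfectly
#' covarying references (constant CT difference across samples) give
#' M = 0; M is invariant under adding a constant to all CTs of one sample
#' (the plate offset cancels in the ratio).
#'
#' @param table CT table (replicates averaged internally).
#' @param candidates two or more candidate reference gene names.
#' @return named numeric vector M per candidate (lower = more stable).
#' @export
genormM <- function(table, candidates) {
  stopifnot(length(candidates) >= 2)
  ct <- lapply(candidates, function(g) .meanCt(table, g))
  names(ct) <- candidates
  samples <- Reduce(intersect, lapply(ct, names))
  if (length(samples) < 2)
    stop("need at least 2 samples shared by all candidates")
  vapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(vapply(others, function(k) {
      # log2(Q_j/Q_k) = CT_k - CT_j
      sd(ct[[k]][samples] - ct[[j]][samples])
    }, numeric(1)))
  }, numeric(1))
}

#' Normalize a time course to each gene's maximal mean expression
#'
#' For visualizing biphasic kinetics on one axis: per gene, the mean RQ per
#' time point is divided by that gene's maximal mean RQ, so every gene
#' peaks at 1.
#'
#' @param rqResults data.frame with columns `gene`, `sample` and `rq`
#'   (multiple rows per (gene, sample) are averaged).
#' @return data.frame: `gene`, `sample`, `mean_rq`, `norm` (max per gene
#'   = 1).
#' @export
normalizeBiphasicReport <- function(rqResults) {
  stopifnot(all(c("gene", "sample", "rq") %in% names(rqResults)))
  agg <- aggregate(rq ~ gene + sample, data = rqResults, FUN = mean)
  names(agg)[names(agg) == "rq"] <- "mean_rq"
  out <- do.call(rbind, lapply(split(agg, agg$gene), function(g) {
    if (nrow(g) < 2) stop("need >= 2 time points per gene")
    g$norm <- g$mean_rq / max(g$mean_rq)
    g
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$sample), ]
}
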