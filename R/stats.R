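## Group-comparison statistics: two-tailed Welch tests computable directly
## from published summary statistics (mean, SD, n), Benjamini-Hochberg
## adjustment, and assembly of the normalized per-experiment results table.

#' Two-tailed Welch t-test from summary statistics
#'
#' t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b), with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value from the
#' t distribution. Works from published group summaries, no raw data
#' needed. Degenerate inputs: both SDs zero with equal means gives p = 1;
#' both zero with different means is reported as p below machine epsilon
#' with a flag.
#'
#' @param meanA,sdA,nA summary of group A (n >= 2, sd >= 0).
#' @param meanB,sdB,nB summary of group B.
#' @param labelA,labelB optional group labels for the comparison string.
#' @return data.frame: `comparison`, `statistic`, `df`, `p`, `flag`.
#' @examples
#' welchTFromSummary(1, 0.15, 400, 1.16, 0.16, 400)$p  # far below 0.001
#' @export
welchTFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                              labelA = "A", labelB = "B") {
  stopifnot(nA >= 2, nB >= 2, sdA >= 0, sdB >= 0)
  lab <- paste(labelA, "vs", labelB)
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB)
      return(data.frame(comparison = lab, statistic = 0, df = NA_real_,
                        p = 1, flag = ""))
    return(data.frame(comparison = lab, statistic = Inf, df = NA_real_,
                      p = .Machine$double.xmin, flag = "zero_variance"))
  }
  va <- sdA^2 / nA; vb <- sdB^2 / nB
  t <- (meanA - meanB) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  data.frame(comparison = lab, statistic = t, df = df,
             p = 2 * pt(-abs(t), df), flag = "")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Assemble a normalized per-experiment results table
#'
#' Mirrors the layout of a treated-versus-control ratio table: group means
#' and SDs are normalized to the control-group mean (control fold = 1),
#' each requested pairwise comparison is tested with the Welch test from
#' summaries, and the p-values of the experiment form one
#' Benjamini-Hochberg family.
#'
#' @param groups data.frame: `label`, `mean`, `sd`, `n` (n >= 2 each).
#' @param comparisons list of length-2 character vectors of group labels;
#'   empty list gives a table without p columns.
#' @param control label of the control group.
#' @return list: `groups` (normalized means/SDs and fold versus control),
#'   `comparisons` (statistic, raw and adjusted p per pair; NULL when no
#'   comparisons were requested).
#' @export
buildExperimentTable <- function(groups, comparisons = list(),
                                 control) {
  stopifnot(all(c("label", "mean", "sd", "n") %in% names(groups)),
            all(groups$n >= 2), all(groups$sd >= 0))
  if (!control %in% groups$label)
    stop("control group '", control, "' missing")
  m0 <- groups$mean[groups$label == control]
  if (m0 == 0) stop("control mean is zero; cannot normalize")
  gt <- data.frame(label = groups$label,
                   norm_mean = groups$mean / m0,
                   norm_sd = groups$sd / abs(m0),
                   n = groups$n,
                   fold = groups$mean / m0)
  if (length(comparisons) == 0)
    return(list(groups = gt, comparisons = NULL))
  rows <- lapply(comparisons, function(cp) {
    stopifnot(length(cp) == 2, all(cp %in% groups$label))
    a <- gt[gt$label == cp[1], ]; b <- gt[gt$label == cp[2], ]
    welchTFromSummary(a$norm_mean, a$norm_sd, a$n,
                      b$norm_mean, b$norm_sd, b$n,
                      labelA = cp[1], labelB = cp[2])
  })
  ct <- do.call(rbind, rows)
  ct$p_adjusted <- bhAdjust(ct$p)
  list(groups = gt, comparisons = ct)
}
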