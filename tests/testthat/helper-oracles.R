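# Independent oracles and small fixture builders used across the suite.

# Ordinary least squares straight from the normal equations.
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# Benjamini-Hochberg step-up written directly from its definition:
# sort ascending, q_i = min_{j >= i} (p_j * m / j), cap at 1, restore order.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-tailed Welch p-value via numerical integration of the t density.
welchPOracle <- function(tstat, df) {
  2 * stats::integrate(function(u) stats::dt(u, df), abs(tstat), Inf,
                       rel.tol = 1e-12)$value
}

# A NucleusSet wrapping explicit masks (list of logical matrices).
makeNucleusSet <- function(masks, pxPerUm = 1, ifi = NULL) {
  stopifnot(length(masks) >= 1)
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  areas <- vapply(masks, sum, numeric(1))
  if (is.null(ifi)) ifi <- rep(0, length(masks))
  new("NucleusSet", labels = lab,
      table = data.frame(nucleus_id = seq_along(masks), area_px = areas,
                         area_um2 = areas / pxPerUm^2, dapi_ifi = ifi,
                         gate = "unassigned", flag = ""),
      pxPerUm = pxPerUm, log = list())
}

# A pooled NucleusSet carrying only IFI values (for gating tests).
makeIFISet <- function(ifi) {
  new("NucleusSet", labels = matrix(0L, 1, 1),
      table = data.frame(nucleus_id = seq_along(ifi), area_px = 1,
                         area_um2 = 1, dapi_ifi = ifi,
                         gate = "unassigned"),
      pxPerUm = 1, log = list())
}

# A PADSet from explicit per-PAD masks nested in one nucleus.
makePADSet <- function(masks, nucleusId = 1L, pxPerUm = 1) {
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  areas <- vapply(masks, sum, numeric(1))
  new("PADSet", labels = lab,
      table = data.frame(pad_id = seq_along(masks), nucleus_id = nucleusId,
                         area_px = areas, area_um2 = areas / pxPerUm^2,
                         centromere_count = NA_integer_),
      pxPerUm = pxPerUm, log = list())
}

# Per-cell summary table built directly from numbers.
makeCells <- function(n_pads, mean_area) {
  data.frame(nucleus_id = seq_along(n_pads), n_pads = n_pads,
             mean_area_um2 = mean_area,
             total_area_um2 = n_pads * mean_area,
             sqrt_mean_area = sqrt(mean_area),
             heterogeneity = NA_real_, flag = "")
}

# Rectangle mask helper.
rectMask <- function(nr, nc, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

hashFile <- function(path) {
  unname(tools::md5sum(path))
}
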