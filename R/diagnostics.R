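# Convergence diagnostics: potential scale reduction factor and
# effective sample size for every monitored scalar.

# Gelman-Rubin potential scale reduction over the chains as given
# (clamped at 1 from below; identically copied chains give exactly 1).
rhat_chains <- function(mat) {
  m <- ncol(mat); n <- nrow(mat)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  means <- colMeans(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(max(1, (var_plus + B_over_n / m) / W))
}

# Effective sample size combining within-chain autocorrelations with
# Geyer's initial monotone positive-pair truncation.
ess_chains <- function(mat) {
  m <- ncol(mat); n <- nrow(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  means <- colMeans(mat)
  var_plus <- (n - 1) / n * W + stats::var(means)
  lag_max <- min(n - 2, 500)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(mat[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # sum consecutive pairs until a pair sum turns negative
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}

#' Convergence diagnostics for a fitted model
#'
#' Potential scale reduction (R-hat) and effective sample size for every
#' stored scalar parameter with posterior variation, computed across
#' chains. Scalars with R-hat above the configured threshold (default
#' 1.1) are flagged.
#'
#' @param smp an `fp_samples` object with at least two chains.
#' @return data.frame of class `fp_diagnostics` with columns `param`,
#'   `rhat`, `ess`, `flagged`.
#' @export
diagnostics <- function(smp) {
  if (smp$n_chains < 2) {
    stop("diagnostics require at least 2 chains", call. = FALSE)
  }
  params <- smp$params
  chain <- smp$chain
  thr <- smp$mcmc_cfg$rhat_threshold %||% 1.1
  keep <- which(apply(params, 2, stats::sd) > 0)
  res <- lapply(keep, function(j) {
    mat <- sapply(unique(chain), function(k) params[chain == k, j])
    data.frame(param = colnames(params)[j],
               rhat = rhat_chains(mat),
               ess = ess_chains(mat))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$flagged <- out$rhat > thr
  class(out) <- c("fp_diagnostics", "data.frame")
  out
}
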