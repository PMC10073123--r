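# MCMC convergence diagnostics: split R-hat and effective sample size.
# Standard within/between-chain variance comparison on split chains, and
# ESS from the combined autocorrelation sequence with Geyer's initial
# positive-pair truncation.

split_chains <- function(chains) {
  out <- list()
  for (x in chains) {
    n <- length(x)
    h <- n %/% 2L
    out[[length(out) + 1L]] <- x[seq_len(h)]
    out[[length(out) + 1L]] <- x[(n - h + 1L):n]
  }
  out
}

#' Split R-hat for one scalar parameter
#'
#' @param chains A list of numeric vectors, one per chain (equal length).
#' @return The split-chain potential scale reduction factor; 1 for a
#'   zero-variance (degenerate) parameter.
#' @export
split_rhat <- function(chains) {
  sp <- split_chains(chains)
  m <- length(sp)
  n <- length(sp[[1]])
  means <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size for one scalar parameter
#'
#' @inheritParams split_rhat
#' @return Estimated number of independent draws (capped at the total
#'   draw count).
#' @export
ess_mean <- function(chains) {
  sp <- split_chains(chains)
  m <- length(sp)
  n <- length(sp[[1]])
  total <- m * n
  vars <- vapply(sp, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(total)
  B <- n * stats::var(vapply(sp, mean, numeric(1)))
  var_plus <- (n - 1) / n * W + B / n
  lag_max <- min(n - 2L, 1000L)
  acov <- vapply(sp, function(x) {
    stats::acf(x, lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(lag_max + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while their sum stays positive
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- total / (1 + 2 * s)
  max(1, min(ess, total))
}
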