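# Convergence diagnostics: rank-normalized split-Rhat and bulk/tail
# effective sample sizes, following the rank-normalization recipe that is
# now standard for Hamiltonian Monte Carlo output.

# split each chain (column) in half -> twice the columns
split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  z <- stats::qnorm((rank(m) - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow = nrow(m))
}

rhat_basic <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split-Rhat
#'
#' The maximum of the split-Rhat of the rank-normalized draws and of the
#' rank-normalized folded draws (absolute deviations from the median), so
#' both location and scale disagreements between chains are detected.
#'
#' @param m matrix of draws, iterations x chains.
#' @return scalar Rhat (1 at perfect mixing).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  s <- split_chains(m)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - stats::median(s))))
  max(bulk, folded, na.rm = TRUE)
}

# ESS of the mean of split chains via Geyer's initial monotone sequence
ess_mean <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 4) return(NA_real_)
  vars <- apply(m, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- if (k > 1) n * stats::var(colMeans(m)) else 0
  var_plus <- (n - 1) / n * W + B / n
  acov <- apply(m, 2, function(x)
    stats::acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)) / var_plus   # rho[1] is lag 0
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0; prev <- Inf
  t <- 1
  while (t + 1 <= n) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2
  }
  tau <- max(2 * tau - 1, 1 / n)   # subtract double-counted lag 0
  n * k / tau
}

#' Bulk and tail effective sample size
#'
#' Bulk ESS is the ESS of the rank-normalized split chains; tail ESS is the
#' minimum ESS of the indicator draws for the 5% and 95% quantiles.
#'
#' @param m matrix of draws, iterations x chains.
#' @return `ess_bulk()`/`ess_tail()` return a scalar.
#' @export
ess_bulk <- function(m) {
  m <- as.matrix(m)
  ess_mean(rank_normalize(split_chains(m)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(m) {
  m <- as.matrix(m)
  qs <- stats::quantile(m, c(0.05, 0.95), names = FALSE)
  ess_q <- vapply(qs, function(q) {
    ind <- matrix(as.numeric(m <= q), nrow = nrow(m))
    ess_mean(rank_normalize(split_chains(ind)))
  }, numeric(1))
  min(ess_q)
}
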