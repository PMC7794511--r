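# Posterior summaries of effect sizes and posterior predictive checks.

# pool an iterations x parameters x chains array into a draws matrix
pool_draws <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "zib_fit"))
  d <- fit$draws
  m <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) d[, , ch]))
  if (!is.null(params)) m <- m[, params, drop = FALSE]
  m
}

#' Summarize posterior effect sizes
#'
#' Per coefficient: posterior median, central 66% and 95% credible intervals
#' (linear-interpolation quantiles), and a sign-certainty flag set when the
#' 95% interval excludes zero.
#'
#' @param draws a `zib_fit`, or a draws matrix with one column per
#'   coefficient.
#' @return data frame: parameter, median, l66, u66, l95, u95, sign_certain.
#' @export
summarize_effects <- function(draws) {
  m <- if (inherits(draws, "zib_fit")) pool_draws(draws, coef_names())
       else as.matrix(draws)
  rows <- lapply(colnames(m), function(pn) {
    q <- stats::quantile(m[, pn], c(0.5, 0.17, 0.83, 0.025, 0.975),
                         names = FALSE, type = 7)
    data.frame(parameter = pn, median = q[1], l66 = q[2], u66 = q[3],
               l95 = q[4], u95 = q[5],
               sign_certain = q[4] > 0 | q[5] < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# reconstruct per-cell GP values and mortality probability for one pooled draw
draw_state <- function(fit, row, m = pool_draws(fit)) {
  data <- fit$data
  P <- ncol(data$X); J <- data$n_sites; N <- length(data$y)
  beta <- m[row, 1:P]
  zi_p <- m[row, "zi_p"]
  gp_sd <- m[row, paste0("gp_sd[", data$site_ids, "]")]
  gp_ell <- m[row, paste0("gp_ell[", data$site_ids, "]")]
  v <- m[row, paste0("v[", seq_len(N), "]")]
  f <- numeric(N)
  for (j in seq_len(J)) {
    i <- data$idx[[j]]
    L <- chol_spd(gp_kernel_unit(data$coords[[j]], gp_ell[j]),
                  label = "unit GP kernel")$L
    f[i] <- gp_sd[j] * as.numeric(L %*% v[i])
  }
  list(beta = beta, zi_p = zi_p, gp_sd = gp_sd, gp_ell = gp_ell,
       pi = stats::plogis(as.numeric(data$X %*% beta) + f))
}

#' Posterior predictive check of the dead-count distribution
#'
#' For `n_rep` random posterior draws, simulates a replicated dead count for
#' every cell from the zero-inflated binomial with that draw's cell
#' probabilities and zero-inflation, and compares the replicated fraction of
#' zero-count cells with the observed fraction — the statistic the model is
#' most at risk of missing.
#'
#' @param fit a [fit_model()] result.
#' @param n_rep number of posterior draws to replicate from (default 50).
#' @param seed integer seed.
#' @return object of class `zib_ppc`: `y_rep` (n_rep x cells matrix),
#'   `zero_frac_rep`, `zero_frac_obs`, and `zero_frac_quantile`, the
#'   fraction of replicates with zero fraction below the observed one.
#' @export
posterior_predictive_check <- function(fit, n_rep = 50, seed = 1L) {
  stopifnot(inherits(fit, "zib_fit"), n_rep >= 1)
  data <- fit$data
  n_pool <- fit$meta$draws * fit$meta$chains
  with_seed(seed, {
    rows <- sample.int(n_pool, n_rep, replace = n_rep > n_pool)
    pooled <- pool_draws(fit)
    y_rep <- matrix(NA_integer_, n_rep, length(data$y))
    for (k in seq_len(n_rep)) {
      st <- draw_state(fit, rows[k], pooled)
      z <- stats::runif(length(data$y)) < st$zi_p
      y_rep[k, ] <- ifelse(z, 0L,
                           stats::rbinom(length(data$y), data$n, st$pi))
    }
    zf_rep <- rowMeans(y_rep == 0)
    zf_obs <- mean(data$y == 0)
    structure(list(y_rep = y_rep, zero_frac_rep = zf_rep,
                   zero_frac_obs = zf_obs,
                   zero_frac_quantile = mean(zf_rep < zf_obs)),
              class = "zib_ppc")
  })
}

#' @export
print.zib_ppc <- function(x, ...) {
  cat(sprintf(paste0("<zib_ppc> observed zero-cell fraction %.3f; ",
                     "replicated %.3f-%.3f (central 90%%: %.3f-%.3f)\n"),
              x$zero_frac_obs, min(x$zero_frac_rep), max(x$zero_frac_rep),
              stats::quantile(x$zero_frac_rep, 0.05),
              stats::quantile(x$zero_frac_rep, 0.95)))
  invisible(x)
}
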