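# Independent brute-force oracles used to cross-check the implementation.

# nearest and second-nearest neighbour mean distances by explicit double loop
nn_oracle <- function(x, y) {
  n <- length(x)
  nn1 <- rep(Inf, n); nn2 <- rep(Inf, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < nn1[i]) { nn2[i] <- nn1[i]; nn1[i] <- d }
      else if (d < nn2[i]) nn2[i] <- d
    }
  }
  list(mean_nn1 = mean(nn1), mean_nn2 = mean(nn2))
}

# direct-formula Pearson correlation and RMSE
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}
rmse_oracle <- function(a, b) sqrt(sum((a - b)^2) / length(a))

# naive (non-log-space where feasible) zero-inflated binomial log posterior
naive_log_posterior <- function(params, data, priors) {
  beta <- params$beta; p <- params$zi_p
  f <- if (is.null(params$gp_values)) rep(0, length(data$y))
       else params$gp_values
  eta <- as.numeric(data$X %*% beta) + f
  prob <- 1 / (1 + exp(-eta))
  lik <- ifelse(data$y == 0,
                p + (1 - p) * (1 - prob)^data$n,
                (1 - p) * choose(data$n, data$y) * prob^data$y *
                  (1 - prob)^(data$n - data$y))
  lp <- sum(log(lik))
  # priors: student-t intercept, normal slopes (+ GP term if present)
  df <- priors$intercept[["df"]]; sc <- priors$intercept[["scale"]]
  lp <- lp - (df + 1) / 2 * log(1 + (beta[1] / sc)^2 / df) +
    sum(dnorm(beta[-1], 0, priors$slope_sd, log = TRUE))
  if (!is.null(params$gp_sd) && params$gp_sd > 0) {
    df_s <- priors$gp_sd[["df"]]; sc_s <- priors$gp_sd[["scale"]]
    for (j in seq_len(data$n_sites)) {
      # per-site amplitude prior (scalar amplitudes are shared across sites)
      lp <- lp - (df_s + 1) / 2 * log(1 + (params$gp_sd / sc_s)^2 / df_s)
      co <- data$coords[[j]]
      d2 <- as.matrix(dist(co))^2
      K <- params$gp_sd^2 * exp(-d2 / (2 * params$gp_lengthscale^2)) +
        diag(1e-8 * params$gp_sd^2, nrow(co))
      fj <- f[data$idx[[j]]]
      lp <- lp - 0.5 * (as.numeric(determinant(K)$modulus) +
                        as.numeric(t(fj) %*% solve(K, fj)) +
                        length(fj) * log(2 * base::pi))
      pr <- priors$gp_lengthscale[j, ]
      lp <- lp - (pr[["shape"]] + 1) * log(params$gp_lengthscale) -
        pr[["scale"]] / params$gp_lengthscale
    }
  }
  as.numeric(lp)
}

# small deterministic cell fixture on two sites
toy_model_table <- function(n_per_site = 12, seed = 42) {
  set.seed(seed)
  cells <- do.call(rbind, lapply(c("A", "B"), function(sid) {
    k <- n_per_site
    data.frame(site_id = sid,
               cell_ix = (seq_len(k) - 1L) %% 4L,
               cell_iy = (seq_len(k) - 1L) %/% 4L,
               centroid_x_m = ((seq_len(k) - 1L) %% 4L + 0.5) * 20,
               centroid_y_m = ((seq_len(k) - 1L) %/% 4L + 0.5) * 20,
               y_dead = rbinom(k, 5, 0.3),
               n_host = 5L + rpois(k, 4),
               n_total = 12L + rpois(k, 5),
               prop_host = runif(k, 0.2, 0.9),
               mean_host_height_m = rlnorm(k, log(18), 0.2),
               total_ba_m2 = runif(k, 0.5, 4),
               eligible = TRUE)
  }))
  sites <- data.frame(site_id = c("A", "B"), cwd_z = c(-0.8, 1.1))
  standardize_covariates(cells, sites)$table
}
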