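# MCMC for the zero-inflated binomial GP model.
#
# Sampling parameterization: beta (14), logit(p), per-site log GP amplitude,
# and whitened GP values v with f_j = sd_j * L_j v_j where L_j is the lower
# Cholesky factor of the unit-variance exponentiated-quadratic kernel at the
# site's current length-scale.  These blocks move by Hamiltonian Monte Carlo
# with analytic gradients, a jittered number of leapfrog steps, dual-averaging
# step-size adaptation and a diagonal mass matrix estimated during warmup.
# The per-site log length-scales, whose gradient would require kernel-matrix
# derivatives, move by a random-walk Metropolis step (conditional on the
# whitened values) once per iteration, with proposal scale adapted in warmup.

# ---- internal state helpers -------------------------------------------------

mcmc_unit_chols <- function(data, log_ell) {
  lapply(seq_len(data$n_sites), function(j) {
    K <- gp_kernel_unit(data$coords[[j]], exp(log_ell[j]))
    chol_spd(K, label = paste("unit GP kernel at site", data$site_ids[j]))$L
  })
}

mcmc_gp_values <- function(data, log_sd, v, Ls) {
  f <- numeric(length(data$y))
  for (j in seq_len(data$n_sites)) {
    i <- data$idx[[j]]
    f[i] <- exp(log_sd[j]) * as.numeric(Ls[[j]] %*% v[i])
  }
  f
}

# log posterior (whitened parameterization) and gradient for the HMC block.
# q = c(beta, logit_p, log_sd, v); length-scales enter through Ls.
mcmc_lp_grad <- function(q, data, priors, Ls, grad = TRUE) {
  P <- ncol(data$X); J <- data$n_sites; N <- length(data$y)
  beta <- q[1:P]
  logit_p <- q[P + 1]
  log_sd <- q[(P + 2):(P + 1 + J)]
  v <- q[(P + 1 + J + 1):(P + 1 + J + N)]
  p <- stats::plogis(logit_p)

  f <- mcmc_gp_values(data, log_sd, v, Ls)
  eta <- as.numeric(data$X %*% beta) + f
  parts <- zib_ll_parts(eta, data$y, data$n, p, grad = grad)

  df_i <- priors$intercept[["df"]]; sc_i <- priors$intercept[["scale"]]
  df_s <- priors$gp_sd[["df"]]; sc_s <- priors$gp_sd[["scale"]]
  sd_j <- exp(log_sd)
  lp <- parts$ll +
    lp_student_t(beta[1], df_i, sc_i) +
    sum(stats::dnorm(beta[-1], 0, priors$slope_sd, log = TRUE)) +
    log(p) + log1p(-p) +                            # uniform(0,1) + Jacobian
    sum(lp_student_t(sd_j, df_s, sc_s) + log_sd) +  # half-t + Jacobian
    -0.5 * sum(v^2)
  if (!grad) return(list(lp = lp))

  g <- parts$g_eta
  g_beta <- as.numeric(crossprod(data$X, g))
  g_beta[1] <- g_beta[1] - (df_i + 1) * beta[1] / (df_i * sc_i^2 + beta[1]^2)
  g_beta[-1] <- g_beta[-1] - beta[-1] / priors$slope_sd^2
  g_logit_p <- sum(parts$g_p) * p * (1 - p) + (1 - 2 * p)
  g_log_sd <- numeric(J)
  g_v <- -v
  for (j in seq_len(J)) {
    i <- data$idx[[j]]
    g_log_sd[j] <- sum(g[i] * f[i]) -
      (df_s + 1) * sd_j[j]^2 / (df_s * sc_s^2 + sd_j[j]^2) + 1
    g_v[i] <- g_v[i] + sd_j[j] * as.numeric(crossprod(Ls[[j]], g[i]))
  }
  list(lp = lp, grad = c(g_beta, g_logit_p, g_log_sd, g_v))
}

# per-site log length-scale Metropolis update (conditional on whitened v)
mcmc_update_ell <- function(q, log_ell, Ls, data, priors, step) {
  P <- ncol(data$X); J <- data$n_sites
  beta <- q[1:P]
  p <- stats::plogis(q[P + 1])
  log_sd <- q[(P + 2):(P + 1 + J)]
  v <- q[(P + 1 + J + 1):length(q)]
  eta_fixed <- as.numeric(data$X %*% beta)
  accepted <- logical(J)
  for (j in seq_len(J)) {
    i <- data$idx[[j]]
    prop <- log_ell[j] + stats::rnorm(1, 0, step[j])
    Lp <- tryCatch(
      chol_spd(gp_kernel_unit(data$coords[[j]], exp(prop)),
               label = "proposal kernel")$L,
      error = function(e) NULL)
    if (is.null(Lp)) next
    pr <- priors$gp_lengthscale[j, ]
    f_old <- exp(log_sd[j]) * as.numeric(Ls[[j]] %*% v[i])
    f_new <- exp(log_sd[j]) * as.numeric(Lp %*% v[i])
    ll_old <- zib_ll_parts(eta_fixed[i] + f_old, data$y[i], data$n[i], p,
                           grad = FALSE)$ll
    ll_new <- zib_ll_parts(eta_fixed[i] + f_new, data$y[i], data$n[i], p,
                           grad = FALSE)$ll
    lp_old <- ll_old + lp_invgamma(exp(log_ell[j]), pr[["shape"]],
                                   pr[["scale"]]) + log_ell[j]
    lp_new <- ll_new + lp_invgamma(exp(prop), pr[["shape"]],
                                   pr[["scale"]]) + prop
    if (log(stats::runif(1)) < lp_new - lp_old) {
      log_ell[j] <- prop
      Ls[[j]] <- Lp
      accepted[j] <- TRUE
    }
  }
  list(log_ell = log_ell, Ls = Ls, accepted = accepted)
}

mcmc_leapfrog <- function(q, mom, eps, n_steps, inv_mass, data, priors, Ls) {
  lg <- mcmc_lp_grad(q, data, priors, Ls)
  if (!is.finite(lg$lp)) return(NULL)
  mom <- mom + 0.5 * eps * lg$grad
  for (s in seq_len(n_steps)) {
    q <- q + eps * inv_mass * mom
    lg <- mcmc_lp_grad(q, data, priors, Ls)
    if (!is.finite(lg$lp) || any(!is.finite(lg$grad))) return(NULL)
    mom <- mom + (if (s < n_steps) eps else 0.5 * eps) * lg$grad
  }
  list(q = q, mom = mom, lp = lg$lp)
}

# ---- main fitting routine ---------------------------------------------------

#' Fit the zero-inflated binomial GP mortality model by MCMC
#'
#' Runs `chains` independent chains of `warmup + draws` iterations each and
#' keeps the post-warmup draws.  Convergence is gated on all monitored
#' parameters (coefficients, zero-inflation, GP hyperparameters) having
#' split-Rhat below 1.1 and bulk and tail ESS above 100 times the number of
#' chains; a fit failing the gates is still returned, flagged
#' `converged = FALSE`.
#'
#' Defaults are desk-scale (2 chains, 500 + 500 iterations); the survey-scale
#' configuration (4 chains, 2000 warmup + 3000 draws) is available by
#' argument.
#'
#' @param data a [zib_data()].
#' @param chains number of chains.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param draws retained iterations per chain.
#' @param seed integer seed.
#' @param priors from [default_priors()].
#' @param control list: `leapfrog_range` (default 16:32), `eps0` initial
#'   step size, `accept_target` (default 0.8), `ell_step0` initial
#'   length-scale proposal sd (log scale), `ell_sweeps` Metropolis sweeps
#'   over the length-scales per iteration (default 2).
#' @return object of class `zib_fit`: `draws` (iterations x parameters x
#'   chains array), `summary` (per-parameter median, 66% and 95% intervals,
#'   Rhat, bulk/tail ESS), `converged`, `data`, `priors`, sampler metadata.
#' @export
fit_model <- function(data, chains = 2, warmup = 500, draws = 500,
                      seed = 1L, priors = default_priors(data),
                      control = list()) {
  stopifnot(inherits(data, "zib_data"), chains >= 1, warmup >= 100, draws >= 1)
  ctl <- utils::modifyList(
    list(leapfrog_range = 16:32, eps0 = 0.05, accept_target = 0.8,
         ell_step0 = 0.3, ell_sweeps = 2), control)
  P <- ncol(data$X); J <- data$n_sites; N <- length(data$y)
  par_names <- c(colnames(data$X), "zi_p",
                 paste0("gp_sd[", data$site_ids, "]"),
                 paste0("gp_ell[", data$site_ids, "]"),
                 paste0("v[", seq_len(N), "]"))
  npar <- P + 1 + 2 * J + N
  out <- array(NA_real_, dim = c(draws, npar, chains),
               dimnames = list(NULL, par_names, paste0("chain", 1:chains)))
  accept <- numeric(chains); eps_final <- numeric(chains)

  # shared data-based initialization centre: quasibinomial GLM coefficients
  glm_beta <- tryCatch(
    stats::glm.fit(data$X, data$y / pmax(data$n, 1), weights = data$n,
                   family = stats::binomial())$coefficients,
    error = function(e) rep(0, P))
  glm_beta[!is.finite(glm_beta)] <- 0

  for (ch in seq_len(chains)) {
    set.seed(as.integer((as.numeric(seed) + 104729 * ch) %% 2147483647))
    beta <- glm_beta + stats::rnorm(P, 0, 0.1)
    logit_p <- stats::qlogis(0.05) + stats::rnorm(1, 0, 0.2)
    log_sd <- log(0.3) + stats::rnorm(J, 0, 0.2)
    log_ell <- log(priors$gp_lengthscale[, "scale"] /
                   (priors$gp_lengthscale[, "shape"] + 1)) +
      stats::rnorm(J, 0, 0.2)
    v <- stats::rnorm(N, 0, 0.1)
    q <- c(beta, logit_p, log_sd, v)
    Ls <- mcmc_unit_chols(data, log_ell)

    dim_q <- length(q)
    inv_mass <- rep(1, dim_q)
    eps <- ctl$eps0
    # dual averaging state
    mu <- log(10 * eps); log_eps_bar <- 0; H_bar <- 0
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    ell_step <- rep(ctl$ell_step0, J)
    ell_acc <- numeric(J); ell_try <- 0
    win_lo <- floor(0.3 * warmup); win_hi <- floor(0.8 * warmup)
    win_draws <- matrix(NA_real_, win_hi - win_lo, dim_q)
    n_acc <- 0; n_tot <- 0

    cur <- mcmc_lp_grad(q, data, priors, Ls, grad = FALSE)$lp
    total <- warmup + draws
    for (it in seq_len(total)) {
      mom <- stats::rnorm(dim_q, 0, sqrt(1 / inv_mass))
      n_steps <- sample(ctl$leapfrog_range, 1)
      stepres <- mcmc_leapfrog(q, mom, eps, n_steps, inv_mass, data, priors, Ls)
      alpha <- 0
      if (!is.null(stepres)) {
        h0 <- cur - 0.5 * sum(mom^2 * inv_mass)
        h1 <- stepres$lp - 0.5 * sum(stepres$mom^2 * inv_mass)
        alpha <- min(1, exp(h1 - h0))
        if (stats::runif(1) < alpha) {
          q <- stepres$q
          cur <- stepres$lp
          if (it > warmup) n_acc <- n_acc + 1
        }
      }
      if (it > warmup) n_tot <- n_tot + 1

      if (it <= warmup) {
        # dual averaging on the HMC step size
        m_ <- it
        H_bar <- (1 - 1 / (m_ + t0)) * H_bar +
          (ctl$accept_target - alpha) / (m_ + t0)
        log_eps <- mu - sqrt(m_) / gamma * H_bar
        w <- m_^(-kappa)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
        eps <- exp(log_eps)
        if (it > win_lo && it <= win_hi) win_draws[it - win_lo, ] <- q
        if (it == win_hi) {
          vv <- apply(win_draws, 2, stats::var)
          inv_mass <- pmax(vv, 1e-6)
          mu <- log(10 * eps)   # restart averaging around current step
          H_bar <- 0; log_eps_bar <- log(eps)
        }
        if (it == warmup) eps <- exp(log_eps_bar)
      }

      # length-scale Metropolis within Gibbs
      moved <- FALSE
      for (sw in seq_len(ctl$ell_sweeps)) {
        up <- mcmc_update_ell(q, log_ell, Ls, data, priors, ell_step)
        if (any(up$accepted)) {
          log_ell <- up$log_ell; Ls <- up$Ls
          moved <- TRUE
        }
        ell_acc <- ell_acc + up$accepted
        ell_try <- ell_try + 1
      }
      if (moved)
        cur <- mcmc_lp_grad(q, data, priors, Ls, grad = FALSE)$lp
      if (it <= warmup && it %% 50 == 0) {
        rate <- ell_acc / ell_try
        ell_step <- ell_step * exp(rate - 0.4)
        ell_acc[] <- 0; ell_try <- 0
      }

      if (it > warmup)
        out[it - warmup, , ch] <- c(q[1:P], stats::plogis(q[P + 1]),
                                    exp(q[(P + 2):(P + 1 + J)]),
                                    exp(log_ell),
                                    q[(P + 2 + J):dim_q])
    }
    accept[ch] <- n_acc / max(n_tot, 1)
    eps_final[ch] <- eps
  }

  monitored <- c(colnames(data$X), "zi_p",
                 paste0("gp_sd[", data$site_ids, "]"),
                 paste0("gp_ell[", data$site_ids, "]"))
  summ <- summarize_fit_params(out, monitored)
  converged <- all(summ$rhat < 1.1, na.rm = TRUE) &&
    all(summ$ess_bulk > 100 * chains, na.rm = TRUE) &&
    all(summ$ess_tail > 100 * chains, na.rm = TRUE)
  structure(list(draws = out, summary = summ, converged = converged,
                 data = data, priors = priors,
                 meta = list(chains = chains, warmup = warmup, draws = draws,
                             seed = seed, accept_rate = accept,
                             step_size = eps_final)),
            class = "zib_fit")
}

summarize_fit_params <- function(draws, params) {
  rows <- lapply(params, function(pn) {
    m <- draws[, pn, , drop = FALSE]
    m <- matrix(m, nrow = dim(draws)[1])
    x <- as.numeric(m)
    q <- stats::quantile(x, c(0.5, 0.17, 0.83, 0.025, 0.975), names = FALSE,
                         type = 7)
    data.frame(parameter = pn, median = q[1],
               l66 = q[2], u66 = q[3], l95 = q[4], u95 = q[5],
               rhat = split_rhat(m), ess_bulk = ess_bulk(m),
               ess_tail = ess_tail(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.zib_fit <- function(x, ...) {
  cat(sprintf("<zib_fit> %d chains x %d draws (+%d warmup); converged: %s\n",
              x$meta$chains, x$meta$draws, x$meta$warmup, x$converged))
  main <- x$summary[seq_len(min(15, nrow(x$summary))), ]
  print(main, row.names = FALSE, digits = 3)
  invisible(x)
}
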