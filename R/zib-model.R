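# Zero-inflated binomial mortality model with per-site spatial Gaussian
# processes: likelihood, priors, posterior density, and the MAP/GLM limit.
#
# Response for cell i in site j: with probability p the dead count is 0
# (zero inflation from an independent, unmodelled process); otherwise
# y ~ Binomial(n_i, pi_i) with logit(pi_i) given by 13 fixed effects on
# standardized covariates plus an exact (dense-covariance) Gaussian process
# over the cell centroids of site j.

#' Assemble model data from a standardized model table
#'
#' @param model_table table from [standardize_covariates()] with y_dead,
#'   n_host, site_id, centroid coordinates and the x_* design columns.
#' @return object of class `zib_data`: y, n, X (design matrix), site
#'   (integer index), site_ids, coords (per-site list of centroid matrices),
#'   idx (per-site list of row indices).
#' @export
zib_data <- function(model_table) {
  y <- model_table$y_dead
  n <- model_table$n_host
  if (any(y < 0 | y > n)) stop("need 0 <= y_dead <= n_host in every cell")
  X <- build_design(model_table)
  site_ids <- sort(unique(model_table$site_id))
  site <- match(model_table$site_id, site_ids)
  idx <- split(seq_along(site), site)
  coords <- lapply(idx, function(i)
    cbind(model_table$centroid_x_m[i], model_table$centroid_y_m[i]))
  structure(list(y = as.integer(y), n = as.integer(n), X = X,
                 site = site, site_ids = site_ids,
                 coords = coords, idx = idx, n_sites = length(site_ids)),
            class = "zib_data")
}

#' Fixed-effect linear predictor
#'
#' `logit(pi) = X beta + gp`, exactly the 14-coefficient expansion of the
#' model (intercept, five base covariates, seven two-way interactions, one
#' three-way interaction) plus the site Gaussian-process value.
#'
#' @param beta coefficient vector of length 14 in [coef_names()] order.
#' @param X design matrix from [build_design()].
#' @param gp Gaussian-process values per cell (default 0).
#' @return logit-scale linear predictor per cell.
#' @export
linear_predictor <- function(beta, X, gp = 0) {
  if (length(beta) != ncol(X))
    stop("beta has length ", length(beta), " but design has ", ncol(X),
         " columns")
  as.numeric(X %*% beta) + gp
}

#' Zero-inflated binomial log-probability
#'
#' `log[ p * 1{y = 0} + (1 - p) * C(n, y) pi^y (1 - pi)^(n - y) ]`, computed
#' stably in log space (log-sum-exp for the y = 0 mixture).
#'
#' @param y observed counts, 0 <= y <= n.
#' @param n trial counts.
#' @param pi binomial success probability in \[0, 1\].
#' @param p zero-inflation probability in \[0, 1\].
#' @return log-probabilities, vectorized with recycling.
#' @export
zib_logpmf <- function(y, n, pi, p) {
  k <- max(length(y), length(n), length(pi), length(p))
  y <- rep_len(y, k); n <- rep_len(n, k)
  pi <- rep_len(pi, k); p <- rep_len(p, k)
  if (any(y < 0 | y > n)) stop("need 0 <= y <= n")
  stopifnot(all(pi >= 0 & pi <= 1), all(p >= 0 & p <= 1))
  out <- log1p(-p) + stats::dbinom(y, n, pi, log = TRUE)
  z <- y == 0
  if (any(z)) {
    a <- log(p[z])                                   # -Inf when p = 0
    b <- log1p(-p[z]) + n[z] * log1p(-pi[z])
    m <- pmax(a, b)
    m[is.infinite(m) & m < 0] <- 0                   # both -Inf
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

# log-likelihood and its gradients on the sampling scale (internal).
# eta: logit(pi); returns list(ll, g_eta, g_p) where g_p is d ll / d p.
zib_ll_parts <- function(eta, y, n, p, grad = TRUE) {
  pi <- stats::plogis(eta)
  log1m_pi <- stats::plogis(eta, log.p = TRUE, lower.tail = FALSE)
  z <- y == 0
  ll <- numeric(length(y))
  g_eta <- numeric(length(y))
  g_p <- numeric(length(y))
  if (any(!z)) {
    i <- !z
    ll[i] <- log1p(-p) + stats::dbinom(y[i], n[i], pi[i], log = TRUE)
    if (grad) {
      g_eta[i] <- y[i] - n[i] * pi[i]
      g_p[i] <- -1 / (1 - p)
    }
  }
  if (any(z)) {
    a <- log(p)
    b <- log1p(-p) + n[z] * log1m_pi[z]
    m <- pmax(a, b)
    llz <- m + log(exp(a - m) + exp(b - m))
    ll[z] <- llz
    if (grad) {
      wb <- exp(b - llz)                 # posterior weight of the binomial arm
      g_eta[z] <- -wb * n[z] * pi[z]
      g_p[z] <- (1 - exp(n[z] * log1m_pi[z])) / exp(llz)
    }
  }
  list(ll = sum(ll), g_eta = g_eta, g_p = g_p)
}

#' Default priors for the mortality model
#'
#' Weakly-regularizing stand-ins: intercept Student-t(3, 0, 2.5); slopes
#' Normal(0, 5); zero-inflation p Uniform(0, 1); per-site GP amplitude
#' half-Student-t(3, 0, 2.5); per-site GP length-scale inverse-gamma with
#' shape 3 and scale set so the prior mode is a quarter of the site's
#' coordinate range (so the prior adapts to each site's physical extent).
#'
#' @param data a [zib_data()] (used to set per-site length-scale priors).
#' @param slope_sd prior standard deviation of the 13 slope coefficients.
#' @return list of prior settings consumed by [log_posterior()] and
#'   [fit_model()].
#' @export
default_priors <- function(data, slope_sd = 5) {
  stopifnot(inherits(data, "zib_data"))
  ell <- t(vapply(data$coords, function(co) {
    extent <- max(apply(co, 2, function(v) diff(range(v))), 20)
    a <- 3
    c(shape = a, scale = (a + 1) * extent / 4)
  }, numeric(2)))
  list(intercept = c(df = 3, scale = 2.5),
       slope_sd = slope_sd,
       gp_sd = c(df = 3, scale = 2.5),
       gp_lengthscale = ell)   # one row per site: shape, scale
}

# scalar log-density helpers (unnormalized where constants cancel)
lp_student_t <- function(x, df, scale) {
  -((df + 1) / 2) * log1p((x / scale)^2 / df)
}
lp_invgamma <- function(x, shape, scale) {
  ifelse(x > 0, -(shape + 1) * log(x) - scale / x, -Inf)
}

#' Log posterior density of the mortality model
#'
#' Sum of the zero-inflated binomial log-likelihood over cells, the
#' multivariate-normal log-density of the per-site GP values under the
#' exponentiated-quadratic covariance, and the priors.  This is the
#' natural-parameter version (GP values given directly, not whitened); the
#' sampler works in a transformed space but agrees with this density up to
#' constant Jacobian terms that do not depend on the data.
#'
#' @param params list: `beta` (14), `zi_p`, and when a GP is present
#'   `gp_sd`, `gp_lengthscale` (scalar or per-site) and `gp_values`
#'   (per-cell vector).
#' @param data a [zib_data()].
#' @param priors from [default_priors()].
#' @param include_likelihood set `FALSE` to get the prior density alone.
#' @return scalar log posterior (finite for interior parameter values).
#' @export
log_posterior <- function(params, data, priors = default_priors(data),
                          include_likelihood = TRUE) {
  stopifnot(inherits(data, "zib_data"))
  beta <- params$beta
  p <- params$zi_p
  if (p < 0 || p > 1) return(-Inf)
  gp_sd <- rep_len(if (is.null(params$gp_sd)) 0 else params$gp_sd,
                   data$n_sites)
  gp_ell <- rep_len(if (is.null(params$gp_lengthscale)) 1
                    else params$gp_lengthscale, data$n_sites)
  f <- if (is.null(params$gp_values)) numeric(length(data$y))
       else params$gp_values

  lp <- lp_student_t(beta[1], priors$intercept[["df"]],
                     priors$intercept[["scale"]]) +
    sum(stats::dnorm(beta[-1], 0, priors$slope_sd, log = TRUE))
  # uniform(0,1) prior on p contributes 0
  for (j in seq_len(data$n_sites)) {
    if (gp_sd[j] > 0) {
      lp <- lp + lp_student_t(gp_sd[j], priors$gp_sd[["df"]],
                              priors$gp_sd[["scale"]]) +
        lp_invgamma(gp_ell[j], priors$gp_lengthscale[j, "shape"],
                    priors$gp_lengthscale[j, "scale"])
      K <- gp_covariance(data$coords[[j]], gp_sd[j], gp_ell[j])
      # K already carries its jitter; only escalate if it still fails
      L <- tryCatch(t(chol(K)), error = function(e) NULL)
      if (is.null(L))
        L <- chol_spd(K, label = paste("GP covariance at site",
                                       data$site_ids[j]))$L
      fj <- f[data$idx[[j]]]
      alpha <- forwardsolve(L, fj)
      lp <- lp - sum(log(diag(L))) - 0.5 * sum(alpha^2) -
        0.5 * length(fj) * log(2 * pi)
    }
  }
  if (include_likelihood) {
    eta <- linear_predictor(beta, data$X, f)
    lp <- lp + zib_ll_parts(eta, data$y, data$n, p, grad = FALSE)$ll
  }
  if (!is.finite(lp))
    attr(lp, "note") <- "non-finite log posterior"
  lp
}

#' MAP estimate of the fixed effects in the GLM limit
#'
#' With the zero-inflation probability and the GP amplitude both at zero the
#' model collapses to an ordinary binomial GLM; this optimizes the
#' fixed-effect posterior (binomial likelihood + coefficient priors) by
#' BFGS with analytic gradients.  With weak priors and moderate data the
#' result coincides with `glm(..., family = binomial)` to high accuracy.
#'
#' @param data a [zib_data()].
#' @param priors from [default_priors()].
#' @param include_priors set `FALSE` for the pure maximum likelihood fit.
#' @return named coefficient vector of length 14.
#' @export
fit_map <- function(data, priors = default_priors(data),
                    include_priors = TRUE) {
  stopifnot(inherits(data, "zib_data"))
  X <- data$X; y <- data$y; n <- data$n
  negpost <- function(beta) {
    eta <- as.numeric(X %*% beta)
    ll <- sum(stats::dbinom(y, n, stats::plogis(eta), log = TRUE))
    if (include_priors)
      ll <- ll + lp_student_t(beta[1], priors$intercept[["df"]],
                              priors$intercept[["scale"]]) +
        sum(stats::dnorm(beta[-1], 0, priors$slope_sd, log = TRUE))
    -ll
  }
  neggrad <- function(beta) {
    eta <- as.numeric(X %*% beta)
    g <- as.numeric(crossprod(X, y - n * stats::plogis(eta)))
    if (include_priors) {
      df <- priors$intercept[["df"]]; sc <- priors$intercept[["scale"]]
      g[1] <- g[1] - (df + 1) * beta[1] / (df * sc^2 + beta[1]^2)
      g[-1] <- g[-1] - beta[-1] / priors$slope_sd^2
    }
    -g
  }
  init <- rep(0, ncol(X))
  opt <- stats::optim(init, negpost, neggrad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  stats::setNames(opt$par, colnames(X))
}
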