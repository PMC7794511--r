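test_that("the linear predictor is exactly the printed expansion", {
  tab <- toy_model_table()
  X <- build_design(tab)
  expect_equal(colnames(X), coef_names())

  beta <- rep(0, 14); beta[1] <- 0.7
  expect_equal(linear_predictor(beta, X), rep(0.7, nrow(X)))

  # single-term activations
  X1 <- matrix(0, 1, 14, dimnames = list(NULL, coef_names()))
  X1[1, 1] <- 1; X1[1, "cwd"] <- 2
  b <- rep(0, 14); b[1] <- 0.5; b[2] <- 1
  expect_equal(linear_predictor(b, X1), 2.5)

  X3 <- matrix(0, 1, 14, dimnames = list(NULL, coef_names()))
  X3[1, 1] <- 1; X3[1, "cwd_x_prop_host_x_host_height"] <- 1
  b3 <- rep(0, 14); b3[14] <- 0.2
  expect_equal(linear_predictor(b3, X3), 0.2)

  expect_error(linear_predictor(rep(0, 13), X), "length")
})

test_that("the ZIB log-pmf matches closed-form mixture arithmetic", {
  expect_equal(zib_logpmf(0, 2, 0.5, 0.2), log(0.2 + 0.8 * 0.25),
               tolerance = 1e-12)
  # p = 0 collapses to the plain binomial
  y <- 0:7
  expect_equal(zib_logpmf(y, 7, 0.3, 0), dbinom(y, 7, 0.3, log = TRUE),
               tolerance = 1e-12)
  # p = 1 puts all mass at zero
  expect_equal(zib_logpmf(0, 5, 0.4, 1), 0)
  expect_equal(zib_logpmf(1, 5, 0.4, 1), -Inf)
  expect_error(zib_logpmf(3, 2, 0.5, 0.1), "0 <= y <= n")
})

test_that("the ZIB pmf is normalized over its support", {
  set.seed(2)
  for (rep in 1:50) {
    n <- sample(0:30, 1)
    pi <- runif(1); p <- runif(1)
    total <- sum(exp(zib_logpmf(0:n, n, pi, p)))
    expect_lt(abs(total - 1), 1e-12)
  }
})

test_that("GP covariance follows the exponentiated-quadratic kernel", {
  co <- cbind(c(0, 10, 30), c(0, 0, 0))
  K <- gp_covariance(co, gp_sd = 1, gp_lengthscale = 10, jitter = 0)
  expect_equal(K[1, 1], 1)
  expect_equal(K[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(K[1, 3], exp(-4.5), tolerance = 1e-12)
  expect_true(isSymmetric(K))

  Kj <- gp_covariance(co, gp_sd = 2, gp_lengthscale = 10)
  expect_equal(Kj[1, 1], 4 * (1 + 1e-8), tolerance = 1e-14)

  # symmetric positive definite on random coordinate sets
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    co <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    K <- gp_covariance(co, gp_sd = 0.7, gp_lengthscale = 50)
    expect_true(isSymmetric(K, tol = 1e-12))
    expect_silent(chol(K))
  }
})

test_that("log posterior agrees with a naive oracle on a 10-cell fixture", {
  tab <- toy_model_table(n_per_site = 5)   # 10 cells over 2 sites
  dat <- zib_data(tab)
  priors <- default_priors(dat)
  set.seed(3)
  params <- list(beta = rnorm(14, 0, 0.3), zi_p = 0.15,
                 gp_sd = 0.5, gp_lengthscale = 35,
                 gp_values = rnorm(10, 0, 0.3))
  got <- log_posterior(params, dat, priors)
  want <- naive_log_posterior(params, dat, priors)
  expect_equal(got, want, tolerance = 1e-8)

  # GP-free version too
  params0 <- list(beta = params$beta, zi_p = 0.15)
  expect_equal(log_posterior(params0, dat, priors),
               naive_log_posterior(params0, dat, priors), tolerance = 1e-8)
})

test_that("with no data the posterior is the prior", {
  tab <- toy_model_table(n_per_site = 5)
  dat <- zib_data(tab)
  priors <- default_priors(dat)
  params <- list(beta = rep(0.2, 14), zi_p = 0.4)
  prior_only <- log_posterior(params, dat, priors,
                              include_likelihood = FALSE)
  manual <- -2 * log(1 + (0.2 / 2.5)^2 / 3) +
    sum(dnorm(rep(0.2, 13), 0, 5, log = TRUE))
  expect_equal(prior_only, manual, tolerance = 1e-10)
})

test_that("the posterior falls as an observation moves from its expectation", {
  tab <- toy_model_table(n_per_site = 6)
  dat <- zib_data(tab)
  priors <- default_priors(dat)
  beta <- rep(0, 14); beta[1] <- qlogis(0.5)
  base <- list(beta = beta, zi_p = 0)
  # cell 1: expectation n/2; push y from the centre toward the extreme
  mid <- round(dat$n[1] / 2)
  lps <- sapply(0:dat$n[1], function(yy) {
    d2 <- dat; d2$y[1] <- yy
    log_posterior(base, d2, priors)
  })
  expect_true(which.max(lps) %in% (mid + c(0, 1, 2)))
  # monotone decrease away from the expectation (ties allowed at the mode)
  expect_true(all(diff(lps[(mid + 1):length(lps)]) < 1e-12))
  expect_true(all(diff(lps[1:(mid + 1)]) > -1e-12))
})

test_that("the MAP matches a binomial GLM in the no-GP no-inflation limit", {
  set.seed(9)
  tab <- toy_model_table(n_per_site = 40)
  dat <- zib_data(tab)
  map <- fit_map(dat, include_priors = FALSE)
  glm_fit <- glm(cbind(y, n - y) ~ X - 1,
                 data = list(y = dat$y, n = dat$n, X = dat$X),
                 family = binomial())
  expect_lt(max(abs(map - coef(glm_fit))), 1e-3)
  # the weak priors shift the MAP only marginally
  expect_lt(max(abs(fit_map(dat) - coef(glm_fit))), 0.05)
})

test_that("split-Rhat and ESS behave on degenerate and iid chains", {
  set.seed(10)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(iid), 1.01)
  expect_gt(ess_bulk(iid), 2000)   # iid draws: ESS near the sample size
  expect_gt(ess_tail(iid), 1000)

  # duplicated chain halves with identical trajectories: Rhat about 1
  x <- rnorm(500)
  dup <- cbind(x, x)
  expect_lt(abs(split_rhat(dup) - 1), 0.05)

  # chains at different levels are flagged
  shifted <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(split_rhat(shifted), 1.5)
})

test_that("effect summaries use linear-interpolation quantiles", {
  draws <- matrix((1:100) / 100, ncol = 1,
                  dimnames = list(NULL, "cwd"))
  s <- summarize_effects(draws)
  expect_equal(s$median, 0.505)
  expect_equal(s$l95, as.numeric(quantile((1:100) / 100, 0.025)),
               tolerance = 1e-12)
  expect_equal(s$u95, as.numeric(quantile((1:100) / 100, 0.975)),
               tolerance = 1e-12)
  expect_true(s$l66 > s$l95 && s$u66 < s$u95)

  sym <- matrix(c(-rev(1:500), 1:500) / 100, ncol = 1,
                dimnames = list(NULL, "cwd"))
  s2 <- summarize_effects(sym)
  expect_equal(s2$median, 0, tolerance = 1e-9)
  expect_equal(s2$l95, -s2$u95, tolerance = 1e-9)
  expect_false(s2$sign_certain)
})

test_that("a small fit runs end to end with sane diagnostics and PPC", {
  cfg <- synthetic_config(n_sites = 2, grid_side_cells = 5,
                          cells_per_site = 20,
                          beta = c(-0.8, 0.6, rep(0, 12)),
                          zi_p = 0.1, gp_sd = 0.3, seed = 17)
  ls <- generate_landscape(cfg)
  dat <- zib_data(ls$model_table)
  fit <- fit_model(dat, chains = 2, warmup = 150, draws = 150, seed = 2,
                   control = list(leapfrog_range = 8:16))
  expect_s3_class(fit, "zib_fit")
  expect_equal(dim(fit$draws)[1], 150)
  expect_true(all(is.finite(fit$summary$median)))
  expect_true(all(fit$summary$ess_bulk > 0))
  # 66% interval nested in 95% interval
  expect_true(all(fit$summary$l66 >= fit$summary$l95))
  expect_true(all(fit$summary$u66 <= fit$summary$u95))
  # zi_p draws respect the unit interval
  zp <- as.numeric(fit$draws[, "zi_p", ])
  expect_true(all(zp > 0 & zp < 1))

  ppc <- posterior_predictive_check(fit, n_rep = 10, seed = 5)
  expect_equal(nrow(ppc$y_rep), 10)
  expect_true(all(ppc$y_rep >= 0))
  expect_true(all(t(ppc$y_rep) <= dat$n))
  expect_identical(ppc$zero_frac_rep,
                   posterior_predictive_check(fit, n_rep = 10,
                                              seed = 5)$zero_frac_rep)
  single <- posterior_predictive_check(fit, n_rep = 1, seed = 1)
  expect_equal(nrow(single$y_rep), 1)

  eff <- summarize_effects(fit)
  expect_equal(eff$parameter, coef_names())
})
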