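test_that("landscape mortality matches the intercept-only closed form", {
  # all slopes zero, no zero inflation, no GP: every cell has
  # pi = inverse-logit(beta0); check the pooled dead fraction against the
  # binomial closed form within 3 Monte-Carlo standard errors
  beta <- rep(0, 14); beta[1] <- -0.7
  cfg <- synthetic_config(n_sites = 6, grid_side_cells = 8,
                          beta = beta, zi_p = 0, gp_sd = 0, seed = 21)
  ls <- generate_landscape(cfg)
  el <- ls$cells$eligible
  expect_true(all(abs(ls$cells$true_pi[el] - plogis(-0.7)) < 1e-12))
  n_tot <- sum(ls$cells$n_host[el])
  frac <- sum(ls$cells$y_dead[el]) / n_tot
  p0 <- plogis(-0.7)
  se <- sqrt(p0 * (1 - p0) / n_tot)
  expect_lt(abs(frac - p0), 3 * se)
})

test_that("without a GP, identical covariates give identical probabilities", {
  cfg <- synthetic_config(n_sites = 3, grid_side_cells = 6, gp_sd = 0,
                          seed = 4)
  ls <- generate_landscape(cfg)
  expect_true(all(ls$model_table$gp_value == 0))
  # pi depends only on the design row when gp_sd = 0
  X <- build_design(ls$model_table)
  eta <- as.numeric(X %*% ls$true_beta)
  expect_equal(ls$model_table$true_pi, plogis(eta), tolerance = 1e-12)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- synthetic_config(n_sites = 3, grid_side_cells = 5, seed = 99)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$cells, b$cells)

  sp <- stem_map_spec(seed = 7)
  expect_identical(generate_stem_map(sp), generate_stem_map(sp))

  tr <- generate_stem_map(stem_map_spec(density_per_ha = 50, seed = 3))
  expect_identical(render_crown_spectra(tr, 0.02, seed = 5),
                   render_crown_spectra(tr, 0.02, seed = 5))
})

test_that("zero-inflated counts match the mixture zero probability", {
  # P(y = 0) = zi_p + (1 - zi_p) (1 - pi)^n, checked empirically
  cfg <- synthetic_config(n_sites = 10, grid_side_cells = 10,
                          beta = c(-0.5, rep(0, 13)), zi_p = 0.25,
                          gp_sd = 0, seed = 31)
  ls <- generate_landscape(cfg)
  el <- ls$cells[ls$cells$eligible, ]
  p_zero <- 0.25 + 0.75 * (1 - el$true_pi)^el$n_host
  expected <- mean(p_zero)
  observed <- mean(el$y_dead == 0)
  se <- sqrt(sum(p_zero * (1 - p_zero))) / nrow(el)
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("GP field draws have the covariance of the specified kernel", {
  # replicate GP draws over <= 25 fixed cells and compare the sample
  # covariance against the kernel matrix
  coords <- expand.grid(x = (0:4) * 20 + 10, y = (0:4) * 20 + 10)
  K <- gp_covariance(as.matrix(coords), gp_sd = 0.8, gp_lengthscale = 40,
                     jitter = 0)
  set.seed(8)
  L <- t(chol(K + diag(1e-8, 25)))
  reps <- 4000
  draws <- matrix(rnorm(25 * reps), 25) |> apply(2, function(z) L %*% z)
  S <- tcrossprod(draws) / reps
  expect_lt(max(abs(S - K)), 0.08)  # MC error at 4000 reps
})

test_that("stem maps follow the Poisson-process spec", {
  sp <- stem_map_spec(extent_m = c(xmin = 0, xmax = 100, ymin = 0, ymax = 100),
                      density_per_ha = 400, seed = 12)
  tr <- generate_stem_map(sp)
  expect_lt(abs(nrow(tr) - 400), 3 * sqrt(400))
  expect_true(all(tr$x_m >= 0 & tr$x_m <= 100))
  expect_true(all(tr$crown_radius_m >= 0.5))

  none_dead <- generate_stem_map(stem_map_spec(dead_fraction = 0, seed = 1))
  expect_true(all(none_dead$dead == 0))
  all_host <- generate_stem_map(stem_map_spec(host_fraction = 1, seed = 1))
  expect_true(all(all_host$host == 1))
  expect_true(all(all_host$species == "PIPO"))

  expect_error(generate_stem_map(
    stem_map_spec(extent_m = c(xmin = 0, xmax = 0, ymin = 0, ymax = 10))),
    "zero area")
})

test_that("rendered CHM is a max-composition of crown paraboloids", {
  one <- data.frame(tree_id = 1, x_m = 10, y_m = 10, height_m = 20,
                    species = "PIPO", host = 1, dead = 0, crown_radius_m = 3)
  chm <- render_chm(one, resolution_m = 0.25)
  # apex pixel reaches the tree height within one resolution step
  expect_lt(20 - max(chm$values), 0.25)
  expect_lte(max(chm$values), 20)
  co <- raster_coords(chm)
  peak <- which(chm$values == max(chm$values), arr.ind = TRUE)[1, ]
  expect_lt(abs(co$x[peak[2]] - 10), 0.25)
  expect_lt(abs(co$y[peak[1]] - 10), 0.25)

  two <- rbind(one, data.frame(tree_id = 2, x_m = 40, y_m = 10, height_m = 15,
                               species = "PIPO", host = 1, dead = 0,
                               crown_radius_m = 3))
  chm2 <- render_chm(two, resolution_m = 0.5)
  det <- reference_detector(chm2, window_m = 5, min_height_m = 2)
  expect_equal(nrow(det), 2)
  # max-composition never exceeds the tallest tree
  expect_lte(max(chm2$values), 20)

  empty <- render_chm(one[0, ], resolution_m = 1)
  expect_true(all(empty$values == 0))
})

test_that("crown spectra separate live from dead and respect clipping", {
  tr <- generate_stem_map(stem_map_spec(density_per_ha = 300,
                                        dead_fraction = 0.4, seed = 9))
  # noiseless: live ponderosa crowns sit exactly on the live template
  clean <- render_crown_spectra(tr, noise_sd = 0, seed = 1)
  live_pipo <- clean[clean$dead == 0 & clean$species == "PIPO", ]
  expect_true(all(abs(live_pipo$nir - 0.45) < 1e-12))
  expect_true(all(abs(live_pipo$red - 0.05) < 1e-12))

  noisy <- render_crown_spectra(tr, noise_sd = 0.05, seed = 2)
  bands <- c("blue", "green", "red", "red_edge", "nir")
  expect_true(all(as.matrix(noisy[bands]) >= 0 &
                  as.matrix(noisy[bands]) <= 1))
  idx <- compute_indices(noisy[bands])
  expect_gt(mean(idx$ndvi[noisy$dead == 0]), mean(idx$ndvi[noisy$dead == 1]))
})

test_that("configs round-trip through YAML and rasters through Esri ASCII", {
  cfg <- synthetic_config(n_sites = 3, grid_side_cells = 4, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$beta, cfg$beta)
  expect_identical(generate_landscape(cfg)$cells,
                   generate_landscape(cfg2)$cells)

  r <- pm_raster(matrix(runif(12), 3, 4), origin = c(5, -3), res = 0.5)
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, p2)
  r2 <- read_esri_ascii(p2)
  expect_equal(r2$values, r$values, tolerance = 1e-12)
  expect_equal(r2$origin, r$origin)
  expect_equal(r2$res, r$res)
})
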