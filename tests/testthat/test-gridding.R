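test_that("cell aggregation applies the dead-is-host rule", {
  trees <- data.frame(
    x_m = c(5, 6, 7, 8), y_m = c(5, 6, 7, 8),
    height_m = c(10, 20, 30, 25),
    host = c(1, 1, 0, 0),      # third tree: dead non-host label pre-override
    dead = c(0, 0, 1, 0),
    ba_m2 = c(0.1, 0.2, 0.3, 0.15))
  cells <- rasterize_trees(trees, origin = c(0, 0), cell_m = 20)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$n_total, 4L)
  expect_equal(cells$n_host, 3L)          # 2 live hosts + 1 dead
  expect_equal(cells$y_dead, 1L)
  expect_equal(cells$prop_host, 0.75)
  expect_equal(cells$mean_host_height_m, 20)  # (10 + 20 + 30) / 3
  expect_equal(cells$total_ba_m2, 0.75)

  live_only <- rasterize_trees(trees, origin = c(0, 0), cell_m = 20,
                               prop_dead_as_host = FALSE,
                               height_dead_as_host = FALSE)
  expect_equal(live_only$prop_host, 0.5)
  expect_equal(live_only$mean_host_height_m, 15)
  expect_equal(live_only$n_host, 3L)      # trial count definition unchanged
})

test_that("cells are half-open: a tree at the boundary falls upward", {
  trees <- data.frame(x_m = c(20, 19.999), y_m = c(0, 0), height_m = 10,
                      host = 1, dead = 0)
  cells <- rasterize_trees(trees, origin = c(0, 0), cell_m = 20)
  counts <- cells[order(cells$cell_ix), ]
  expect_equal(counts$cell_ix, c(0, 1))
  expect_equal(counts$n_total, c(1L, 1L))
})

test_that("empty cells are emitted with zero counts and flagged", {
  trees <- data.frame(x_m = c(5, 45), y_m = c(5, 45), height_m = 20,
                      host = 1, dead = 0)
  cells <- rasterize_trees(trees, origin = c(0, 0), cell_m = 20)
  expect_equal(nrow(cells), 9)            # 3 x 3 bounding grid
  empty <- cells[cells$n_total == 0, ]
  expect_equal(nrow(empty), 7)
  expect_true(all(empty$y_dead == 0))
  expect_true(all(is.na(empty$mean_host_height_m)))
  expect_true(all(!empty$eligible))
})

test_that("trees outside an explicit grid extent are dropped with a count", {
  trees <- data.frame(x_m = c(5, 100), y_m = c(5, 5), height_m = 10,
                      host = 1, dead = 0)
  expect_warning(
    cells <- rasterize_trees(trees, origin = c(0, 0), cell_m = 20,
                             dims = c(2, 2)),
    "1 tree")
  expect_equal(sum(cells$n_total), 1L)
})

test_that("tree counts are conserved and order-independent", {
  set.seed(6)
  trees <- data.frame(x_m = runif(200, 0, 100), y_m = runif(200, 0, 100),
                      height_m = runif(200, 5, 40),
                      host = rbinom(200, 1, 0.6), dead = rbinom(200, 1, 0.3),
                      ba_m2 = runif(200, 0.01, 0.5))
  cells <- rasterize_trees(trees, origin = c(0, 0), cell_m = 20)
  expect_equal(sum(cells$n_total), 200L)
  expect_equal(sum(cells$y_dead), sum(trees$dead))
  shuffled <- rasterize_trees(trees[sample(200), ], origin = c(0, 0),
                              cell_m = 20)
  expect_equal(cells, shuffled)

  # prop_host invariant to translating the grid by whole cells
  shifted <- rasterize_trees(trees, origin = c(-40, 20), cell_m = 20)
  a <- cells[cells$n_total > 0, ]
  b <- shifted[shifted$n_total > 0, ]
  a_key <- paste(a$centroid_x_m, a$centroid_y_m)
  b_key <- paste(b$centroid_x_m, b$centroid_y_m)
  expect_setequal(a_key, b_key)
  expect_equal(a$prop_host[order(a_key)], b$prop_host[order(b_key)])
})

test_that("standardization yields unit-scale pooled covariates", {
  tab <- toy_model_table()
  for (col in c("x_cwd", "x_prop_host", "x_host_height", "x_density", "x_ba")) {
    expect_lt(abs(mean(tab[[col]])), 1e-10)
    expect_equal(sd(tab[[col]]), 1, tolerance = 1e-10)
  }
  # interaction columns are products of standardized columns, not recentred
  expect_equal(tab$x_cwd_x_host_height, tab$x_cwd * tab$x_host_height)
  expect_gt(abs(mean(tab$x_prop_host_x_host_height)), 1e-6)
  expect_equal(tab$x_cwd_x_prop_host_x_host_height,
               tab$x_cwd * tab$x_prop_host * tab$x_host_height)
})

test_that("two-value covariates standardize by the sample sd", {
  cells <- data.frame(site_id = c("A", "A"), cell_ix = 0:1, cell_iy = 0,
                      centroid_x_m = c(10, 30), centroid_y_m = 10,
                      y_dead = c(1L, 2L), n_host = c(4L, 5L),
                      n_total = c(10L, 20L),
                      prop_host = c(0.4, 0.25),
                      mean_host_height_m = c(15, 25),
                      total_ba_m2 = c(1, 2), eligible = TRUE)
  sites <- data.frame(site_id = "A", cwd_z = 0.5)
  expect_error(standardize_covariates(cells, sites), "cwd")  # zero variance
  # one cell per site: every covariate has two values {a, b}
  cells$site_id <- c("A", "B")
  sites2 <- data.frame(site_id = c("A", "B"), cwd_z = c(-0.5, 0.5))
  tab <- standardize_covariates(cells, sites2)$table
  # hand check: {10, 20} standardizes to -/+ 1/sqrt(2) with the sample sd
  expect_equal(tab$x_density, c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(abs(tab$x_density[1]), 0.7071, tolerance = 1e-4)
})

test_that("cells without hosts are excluded from the model table", {
  cells <- toy_model_table()
  raw <- cells[c("site_id", "cell_ix", "cell_iy", "centroid_x_m",
                 "centroid_y_m", "y_dead", "n_host", "n_total", "prop_host",
                 "mean_host_height_m", "total_ba_m2")]
  raw$eligible <- TRUE
  raw$n_host[1] <- 0L
  raw$mean_host_height_m[1] <- NA_real_
  sites <- data.frame(site_id = c("A", "B"), cwd_z = c(-0.8, 1.1))
  tab <- standardize_covariates(raw, sites)
  expect_equal(nrow(tab$table), nrow(raw) - 1)
})

test_that("per-site subsampling is capped, unique and seed-stable", {
  cells <- data.frame(site_id = rep(c("A", "B"), c(150, 1000)),
                      cell_id = c(1:150, 1:1000))
  sub <- subsample_cells(cells, k = 200, seed = 9)
  expect_equal(sum(sub$site_id == "A"), 150)   # fewer than k: keep all
  expect_equal(sum(sub$site_id == "B"), 200)
  expect_false(any(duplicated(sub[c("site_id", "cell_id")])))
  expect_identical(sub, subsample_cells(cells, k = 200, seed = 9))
  sub2 <- subsample_cells(cells, k = 200, seed = 10)
  expect_false(identical(sub, sub2))
})

test_that("mortality summaries report percent on the printed scale", {
  s <- summarize_mortality(118879, 452413)
  expect_equal(round(s$percent, 1), 26.3)
  expect_error(summarize_mortality(5, 4))
})
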