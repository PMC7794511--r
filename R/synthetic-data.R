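# Synthetic landscapes, stem maps, canopy rasters and crown spectra with the
# statistical structure the mortality analysis assumes, so every downstream
# stage can be exercised against known ground truth.

# run expr under a fixed seed, restoring the caller's RNG state afterwards so
# generators behave as pure functions of (config, seed)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-site substream seed, kept below 2^31
site_seed <- function(seed, j) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(j)) %% 2147483647)
}

#' Configuration for the synthetic landscape generator
#'
#' Defaults describe the study system the package targets: 32 sites along a
#' climatic-water-deficit (CWD) gradient, each a square grid of 20 x 20 m
#' cells, with mortality generated from the zero-inflated binomial model with
#' a per-site spatial Gaussian process on the logit scale.  The default
#' coefficient vector is the set of reported posterior medians for the
#' Sierra Nevada ponderosa pine system (CWD 0.85, host proportion 0.68, host
#' height 0.25, density -0.01, basal area -0.13, CWD x height 0.54, CWD x
#' host proportion -0.08, CWD x density -0.19, CWD x basal area -0.04, host
#' proportion x density 0.06, height x basal area -0.08, three-way 0.14),
#' with an intercept of -1 giving overall mortality near the observed 26%.
#'
#' @param n_sites number of sites (>= 1).
#' @param grid_side_cells cells per side of the square site grid.
#' @param cells_per_site cells actually generated per site (first
#'   `cells_per_site` cells in row-major order; defaults to the full grid).
#' @param cwd_range range of site CWD z-scores, drawn uniformly.
#' @param beta named vector of the 14 model coefficients ([coef_names()]).
#' @param zi_p zero-inflation probability in \[0, 1\].
#' @param gp_sd per-site Gaussian-process amplitude (log-odds units).
#' @param gp_lengthscale Gaussian-process length-scale (m).
#' @param covariate_distributions list with elements `prop_host`
#'   (Beta shape1/shape2), `density` (negative binomial mu/size, trees per
#'   cell) and `height` (lognormal meanlog/sdlog, m).
#' @param allometry height-to-DBH coefficients (cm per m, cm) used to derive
#'   per-cell basal area from density and mean height.
#' @param ba_noise_sdlog lognormal sd of the multiplicative allometric
#'   residual on per-cell basal area.  Height-to-DBH allometries are noisy,
#'   so cell basal area is not a deterministic function of density and
#'   height; without this residual the three covariates would be nearly
#'   collinear and jointly unidentifiable.
#' @param cell_m cell edge length (m).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 32,
                             grid_side_cells = 15,
                             cells_per_site = grid_side_cells^2,
                             cwd_range = c(-1.5, 1.5),
                             beta = default_beta(),
                             zi_p = 0.1,
                             gp_sd = 0.5,
                             gp_lengthscale = 40,
                             covariate_distributions = list(
                               prop_host = c(shape1 = 2, shape2 = 2),
                               density = c(mu = 20, size = 5),
                               height = c(meanlog = log(18), sdlog = 0.3)),
                             allometry = c(slope_cm_per_m = 2, intercept_cm = 2),
                             ba_noise_sdlog = 0.4,
                             cell_m = 20,
                             seed = 1L) {
  stopifnot(n_sites >= 1, cells_per_site >= 1,
            cells_per_site <= grid_side_cells^2,
            zi_p >= 0, zi_p <= 1, gp_sd >= 0, gp_lengthscale > 0,
            length(cwd_range) == 2, cwd_range[1] <= cwd_range[2],
            length(beta) == 14, ba_noise_sdlog >= 0, cell_m > 0)
  beta <- stats::setNames(as.numeric(beta), coef_names())
  structure(list(n_sites = as.integer(n_sites),
                 grid_side_cells = as.integer(grid_side_cells),
                 cells_per_site = as.integer(cells_per_site),
                 cwd_range = as.numeric(cwd_range),
                 beta = beta, zi_p = zi_p, gp_sd = gp_sd,
                 gp_lengthscale = gp_lengthscale,
                 covariate_distributions = covariate_distributions,
                 allometry = as.numeric(allometry),
                 ba_noise_sdlog = ba_noise_sdlog,
                 cell_m = cell_m, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_beta <- function() {
  stats::setNames(
    c(-1.0, 0.85, 0.68, 0.25, -0.01, -0.13,
      0.54, -0.08, -0.19, -0.04, 0.00, 0.06, -0.08, 0.14),
    coef_names())
}

#' Generate a synthetic multi-site landscape with known mortality
#'
#' Draws per-site CWD z-scores, per-cell covariates, a per-site Gaussian
#' process over cell centroids (dense covariance, exact Cholesky draw), the
#' true mortality probability per cell via the inverse-logit of the model's
#' linear predictor, and zero-inflated binomial dead-tree counts.  All latent
#' quantities (GP draw, true probability, zero-inflation indicator) are kept
#' alongside the data.
#'
#' Covariates are standardized pooled across sites by the same routine the
#' model-fitting side uses ([standardize_covariates()]), so a fit to the
#' generated table estimates coefficients on exactly the generating scale.
#' Cells with no host trees are generated but flagged ineligible; their true
#' probability is undefined and their count is zero by construction.
#'
#' @param config a [synthetic_config()].
#' @return object of class `pm_landscape`: list with `cells` (pooled data
#'   frame), `sites` (site_id, cwd_z), `standardization`, `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    cwd_z <- stats::runif(config$n_sites, config$cwd_range[1],
                          config$cwd_range[2])
    sites <- data.frame(site_id = sprintf("site%02d", seq_len(config$n_sites)),
                        cwd_z = cwd_z, stringsAsFactors = FALSE)

    side <- config$grid_side_cells
    m <- config$cells_per_site
    ix <- (seq_len(side^2) - 1L) %% side
    iy <- (seq_len(side^2) - 1L) %/% side
    ix <- ix[seq_len(m)]; iy <- iy[seq_len(m)]

    cd <- config$covariate_distributions
    cell_list <- vector("list", config$n_sites)
    for (j in seq_len(config$n_sites)) {
      set.seed(site_seed(config$seed, j))
      prop_host <- stats::rbeta(m, cd$prop_host[["shape1"]],
                                cd$prop_host[["shape2"]])
      n_total <- stats::rnbinom(m, mu = cd$density[["mu"]],
                                size = cd$density[["size"]])
      height <- stats::rlnorm(m, cd$height[["meanlog"]], cd$height[["sdlog"]])
      n_host <- as.integer(round(n_total * prop_host))
      dbh <- pmax(0, config$allometry[1] * height + config$allometry[2])
      total_ba <- n_total * basal_area(dbh) *
        stats::rlnorm(m, 0, config$ba_noise_sdlog)
      cell_list[[j]] <- data.frame(
        site_id = sites$site_id[j],
        cell_ix = ix, cell_iy = iy,
        centroid_x_m = (ix + 0.5) * config$cell_m,
        centroid_y_m = (iy + 0.5) * config$cell_m,
        n_total = n_total, n_host = n_host,
        prop_host = ifelse(n_total > 0, n_host / n_total, 0),
        mean_host_height_m = ifelse(n_host > 0, height, NA_real_),
        total_ba_m2 = total_ba,
        stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, cell_list)
    cells$eligible <- cells$n_host > 0

    std <- standardize_covariates(cells, sites)
    tab <- std$table
    X <- build_design(tab)

    # exact per-site GP draw over eligible-cell centroids
    tab$gp_value <- 0
    for (j in seq_len(config$n_sites)) {
      idx <- which(tab$site_id == sites$site_id[j])
      set.seed(site_seed(config$seed, j) + 1L)
      if (config$gp_sd > 0 && length(idx) > 0) {
        K <- gp_covariance(cbind(tab$centroid_x_m[idx], tab$centroid_y_m[idx]),
                           config$gp_sd, config$gp_lengthscale, jitter = 0)
        ch <- chol_spd(K, jitter0 = 1e-8, jitter_max = 1e-4,
                       label = paste("GP covariance at", sites$site_id[j]))
        tab$gp_value[idx] <- as.numeric(ch$L %*% stats::rnorm(length(idx)))
      }
    }

    set.seed(site_seed(config$seed, config$n_sites + 1L))
    eta <- as.numeric(X %*% config$beta) + tab$gp_value
    tab$true_pi <- stats::plogis(eta)
    tab$zero_inflated <- stats::runif(nrow(tab)) < config$zi_p
    tab$y_dead <- ifelse(tab$zero_inflated, 0L,
                         stats::rbinom(nrow(tab), tab$n_host, tab$true_pi))

    # merge latents back onto the full cell table (ineligible cells keep NA)
    key_all <- paste(cells$site_id, cells$cell_ix, cells$cell_iy)
    key_tab <- paste(tab$site_id, tab$cell_ix, tab$cell_iy)
    pos <- match(key_all, key_tab)
    for (col in c("gp_value", "true_pi"))
      cells[[col]] <- ifelse(is.na(pos), NA_real_, tab[[col]][pos])
    cells$zero_inflated <- ifelse(is.na(pos), NA, tab$zero_inflated[pos])
    cells$y_dead <- ifelse(is.na(pos), 0L, tab$y_dead[pos])

    structure(list(cells = cells, model_table = tab, sites = sites,
                   standardization = std$standardization,
                   true_beta = config$beta, config = config),
              class = "pm_landscape")
  })
}

#' @export
print.pm_landscape <- function(x, ...) {
  cat(sprintf("<pm_landscape> %d sites, %d cells (%d with host trees)\n",
              nrow(x$sites), nrow(x$cells), sum(x$cells$eligible)))
  el <- x$cells$eligible
  cat(sprintf("  dead fraction over host trials: %.3f; zero cells: %.3f\n",
              sum(x$cells$y_dead[el]) / sum(x$cells$n_host[el]),
              mean(x$cells$y_dead[el] == 0)))
  invisible(x)
}

#' Specification of a synthetic stem map
#'
#' @param extent_m named vector `c(xmin, xmax, ymin, ymax)` (m).
#' @param density_per_ha expected stem density (trees/ha), > 0.
#' @param height_distribution lognormal meanlog/sdlog of tree height (m).
#' @param host_fraction probability a tree is a host (ponderosa pine).
#' @param dead_fraction probability a tree is dead.
#' @param crown_radius_model `c(slope, intercept)`: crown radius (m) as a
#'   linear function of height (m), floored at 0.5 m.
#' @param seed integer seed.
#' @return object of class `stem_map_spec`.
#' @export
stem_map_spec <- function(extent_m = c(xmin = 0, xmax = 100, ymin = 0, ymax = 100),
                          density_per_ha = 400,
                          height_distribution = c(meanlog = log(15), sdlog = 0.4),
                          host_fraction = 0.6,
                          dead_fraction = 0.2,
                          crown_radius_model = c(slope = 0.08, intercept = 0.5),
                          seed = 1L) {
  stopifnot(length(extent_m) == 4, density_per_ha > 0,
            host_fraction >= 0, host_fraction <= 1,
            dead_fraction >= 0, dead_fraction <= 1)
  extent_m <- stats::setNames(as.numeric(extent_m),
                              c("xmin", "xmax", "ymin", "ymax"))
  structure(list(extent_m = extent_m, density_per_ha = density_per_ha,
                 height_distribution = height_distribution,
                 host_fraction = host_fraction, dead_fraction = dead_fraction,
                 crown_radius_model = as.numeric(crown_radius_model),
                 seed = as.integer(seed)),
            class = "stem_map_spec")
}

non_host_species <- c("ABCO", "CADE", "PILA", "QUKE")

#' Generate a stem map from a homogeneous Poisson process
#'
#' Tree positions are uniform on the extent with a Poisson-distributed total;
#' heights, host flag and live/dead status are drawn independently per tree.
#'
#' @param spec a [stem_map_spec()].
#' @return data frame of tree records: tree_id, x_m, y_m, height_m, species,
#'   host, dead, crown_radius_m.
#' @export
generate_stem_map <- function(spec) {
  stopifnot(inherits(spec, "stem_map_spec"))
  e <- spec$extent_m
  w <- e[["xmax"]] - e[["xmin"]]; h <- e[["ymax"]] - e[["ymin"]]
  if (w <= 0 || h <= 0) stop("stem map extent has zero area")
  with_seed(spec$seed, {
    n <- stats::rpois(1, spec$density_per_ha * w * h / 1e4)
    height <- stats::rlnorm(n, spec$height_distribution[["meanlog"]],
                            spec$height_distribution[["sdlog"]])
    host <- stats::runif(n) < spec$host_fraction
    dead <- stats::runif(n) < spec$dead_fraction
    species <- ifelse(host, "PIPO",
                      sample(non_host_species, n, replace = TRUE))
    data.frame(tree_id = seq_len(n),
               x_m = stats::runif(n, e[["xmin"]], e[["xmax"]]),
               y_m = stats::runif(n, e[["ymin"]], e[["ymax"]]),
               height_m = height,
               species = species,
               host = as.integer(host),
               dead = as.integer(dead),
               crown_radius_m = pmax(0.5, spec$crown_radius_model[1] * height +
                                            spec$crown_radius_model[2]),
               stringsAsFactors = FALSE)
  })
}

#' Render a canopy-height model from a stem map
#'
#' Each tree contributes a paraboloid crown surface of its height and crown
#' radius; the raster value at a pixel is the maximum over all contributing
#' crowns (never their sum), zero where no crown reaches.
#'
#' @param trees tree records with x_m, y_m, height_m, crown_radius_m.
#' @param resolution_m pixel size (m), > 0.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the stem
#'   bounding box padded by the largest crown radius.
#' @return a [pm_raster()].
#' @export
render_chm <- function(trees, resolution_m = 0.25, extent = NULL) {
  stopifnot(resolution_m > 0)
  if (nrow(trees) == 0) {
    if (is.null(extent)) extent <- c(0, 10, 0, 10)
  } else if (is.null(extent)) {
    pad <- max(trees$crown_radius_m) + resolution_m
    extent <- c(min(trees$x_m) - pad, max(trees$x_m) + pad,
                min(trees$y_m) - pad, max(trees$y_m) + pad)
  }
  nc <- max(1L, ceiling((extent[2] - extent[1]) / resolution_m))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / resolution_m))
  v <- matrix(0, nr, nc)
  xs <- extent[1] + (seq_len(nc) - 0.5) * resolution_m
  ys <- extent[3] + (nr - seq_len(nr) + 0.5) * resolution_m  # row 1 = top
  for (t in seq_len(nrow(trees))) {
    r <- trees$crown_radius_m[t]; h <- trees$height_m[t]
    cols <- which(abs(xs - trees$x_m[t]) <= r)
    rows <- which(abs(ys - trees$y_m[t]) <= r)
    if (length(cols) == 0 || length(rows) == 0) next
    dx2 <- (xs[cols] - trees$x_m[t])^2
    dy2 <- (ys[rows] - trees$y_m[t])^2
    d2 <- outer(dy2, dx2, "+")
    z <- h * (1 - d2 / r^2)
    z[z < 0] <- 0
    v[rows, cols] <- pmax(v[rows, cols], z)
  }
  pm_raster(v, origin = c(extent[1], extent[3]), res = resolution_m)
}

# five-band reflectance templates: a green-vegetation signature for live
# crowns (high NIR, low red) and a dry/gray signature for dead crowns
# (reduced NIR, raised red).  Live crowns get small species-specific offsets;
# dead crowns are spectrally indistinct across species.
spectral_templates <- function() {
  live <- c(blue = 0.04, green = 0.08, red = 0.05, red_edge = 0.20, nir = 0.45)
  dead <- c(blue = 0.10, green = 0.13, red = 0.15, red_edge = 0.20, nir = 0.25)
  offsets <- list(
    PIPO = c(blue = 0, green = 0, red = 0, red_edge = 0, nir = 0),
    ABCO = c(blue = 0, green = 0.01, red = 0, red_edge = 0.01, nir = 0.03),
    CADE = c(blue = 0, green = 0.015, red = 0.005, red_edge = -0.01, nir = -0.02),
    PILA = c(blue = 0.005, green = 0, red = 0, red_edge = 0.005, nir = 0.01),
    QUKE = c(blue = 0, green = 0.02, red = -0.01, red_edge = 0.02, nir = 0.05))
  list(live = live, dead = dead, offsets = offsets)
}

#' Render per-crown spectral band means for a stem map
#'
#' Live crowns are drawn around a green-vegetation reflectance template and
#' dead crowns around a dry/gray template, with small species offsets for
#' live crowns, Gaussian noise, and clipping to \[0, 1\].
#'
#' @param trees tree records with species and dead columns.
#' @param noise_sd Gaussian noise standard deviation (reflectance units), >= 0.
#' @param seed integer seed.
#' @return data frame: crown_id, species, dead, blue, green, red, red_edge, nir.
#' @export
render_crown_spectra <- function(trees, noise_sd = 0.02, seed = 1L) {
  stopifnot(noise_sd >= 0)
  tpl <- spectral_templates()
  bands <- names(tpl$live)
  with_seed(seed, {
    n <- nrow(trees)
    base <- matrix(NA_real_, n, length(bands), dimnames = list(NULL, bands))
    for (i in seq_len(n)) {
      if (trees$dead[i] == 1) {
        base[i, ] <- tpl$dead
      } else {
        off <- tpl$offsets[[trees$species[i]]]
        if (is.null(off)) off <- 0
        base[i, ] <- tpl$live + off
      }
    }
    noisy <- base + matrix(stats::rnorm(n * length(bands), 0, noise_sd),
                           n, length(bands))
    noisy[] <- pmin(1, pmax(0, noisy))
    out <- data.frame(crown_id = trees$tree_id, species = trees$species,
                      dead = trees$dead, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(noisy))
  })
}
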