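# Aggregation of classified trees to 20 x 20 m grid cells, construction and
# standardization of the model covariate table, and per-site subsampling.

#' Aggregate classified trees to grid cells
#'
#' Trees are assigned to half-open square cells `[x0 + k*cell, x0 + (k+1)*cell)`
#' by `floor((coord - origin) / cell_m)`.  Per cell the function computes the
#' dead count `y_dead`, the host trial count `n_host` (live host trees plus
#' **all** dead trees, which are assumed to be ponderosa pine hosts), the
#' total count, the proportion of hosts, the mean host height (over the same
#' dead-inclusive host set by default), and the total basal area over all
#' trees.  Cells with zero trees inside the bounding index rectangle are
#' emitted with zero counts and an ineligibility flag.
#'
#' @param trees tree records: x_m, y_m, height_m, host (0/1), dead (0/1),
#'   optionally ba_m2 and site_id.
#' @param origin `c(x0, y0)` of the grid (m); default floors the per-site
#'   minimum coordinates to a `cell_m` multiple.
#' @param cell_m cell edge length (m), default 20.
#' @param dims optional `c(nx, ny)` grid extent in cells; trees falling
#'   outside are dropped with a warning reporting the count.
#' @param prop_dead_as_host count dead trees as hosts in `prop_host`
#'   (default TRUE, consistent with the trial-count definition); if FALSE
#'   the proportion uses live hosts only.
#' @param height_dead_as_host include dead trees in the mean host height
#'   (default TRUE); if FALSE the mean is over live hosts only.
#' @return data frame of grid cells: site_id, cell_ix, cell_iy,
#'   centroid_x_m, centroid_y_m, y_dead, n_host, n_total, prop_host,
#'   mean_host_height_m, total_ba_m2, eligible.
#' @export
rasterize_trees <- function(trees, origin = NULL, cell_m = 20, dims = NULL,
                            prop_dead_as_host = TRUE,
                            height_dead_as_host = TRUE) {
  stopifnot(cell_m > 0,
            all(c("x_m", "y_m", "height_m", "host", "dead") %in% names(trees)))
  if (!"site_id" %in% names(trees)) trees$site_id <- "site01"
  if (!"ba_m2" %in% names(trees)) trees$ba_m2 <- NA_real_
  out <- list()
  for (sid in unique(trees$site_id)) {
    tr <- trees[trees$site_id == sid, ]
    org <- if (is.null(origin))
      c(floor(min(tr$x_m) / cell_m), floor(min(tr$y_m) / cell_m)) * cell_m
    else as.numeric(origin)
    ix <- floor((tr$x_m - org[1]) / cell_m)
    iy <- floor((tr$y_m - org[2]) / cell_m)
    if (!is.null(dims)) {
      inside <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2]
      if (any(!inside))
        warning(sprintf("site %s: %d tree(s) outside the grid extent dropped",
                        sid, sum(!inside)))
      tr <- tr[inside, ]; ix <- ix[inside]; iy <- iy[inside]
      rng_x <- c(0L, dims[1] - 1L); rng_y <- c(0L, dims[2] - 1L)
    } else {
      rng_x <- range(ix); rng_y <- range(iy)
    }
    grid <- expand.grid(cell_ix = rng_x[1]:rng_x[2],
                        cell_iy = rng_y[1]:rng_y[2])
    key <- paste(ix, iy)
    gkey <- paste(grid$cell_ix, grid$cell_iy)
    agg <- function(f) vapply(gkey, function(k) {
      s <- key == k
      if (!any(s)) return(f(tr[FALSE, ]))
      f(tr[s, , drop = FALSE])
    }, numeric(1), USE.NAMES = FALSE)

    n_total <- agg(function(d) nrow(d))
    y_dead <- agg(function(d) sum(d$dead == 1))
    n_live_host <- agg(function(d) sum(d$host == 1 & d$dead == 0))
    n_host <- n_live_host + y_dead
    mean_h <- agg(function(d) {
      hs <- if (height_dead_as_host) d$dead == 1 | (d$host == 1 & d$dead == 0)
            else d$host == 1 & d$dead == 0
      if (!any(hs)) return(NA_real_)
      mean(d$height_m[hs])
    })
    total_ba <- agg(function(d) if (nrow(d) == 0) 0 else sum(d$ba_m2))
    prop_num <- if (prop_dead_as_host) n_host else n_live_host
    out[[sid]] <- data.frame(
      site_id = sid,
      cell_ix = grid$cell_ix, cell_iy = grid$cell_iy,
      centroid_x_m = org[1] + (grid$cell_ix + 0.5) * cell_m,
      centroid_y_m = org[2] + (grid$cell_iy + 0.5) * cell_m,
      y_dead = as.integer(y_dead), n_host = as.integer(n_host),
      n_total = as.integer(n_total),
      prop_host = ifelse(n_total > 0, prop_num / n_total, NA_real_),
      mean_host_height_m = mean_h,
      total_ba_m2 = total_ba,
      eligible = n_host > 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardize the model covariates and build interaction columns
#'
#' Joins site-level CWD z-scores onto the cell table, drops cells with no
#' host trees (their mean host height, a required covariate, is undefined),
#' and centres/scales each of the five base covariates over all included
#' cells pooled across sites (sample sd; site CWD is replicated to cells
#' before pooling).  The eight interaction columns are products of the
#' **standardized** base columns and are deliberately not re-centred, so a
#' product column generally has nonzero mean.
#'
#' @param cells grid-cell table from [rasterize_trees()] (or the synthetic
#'   generator): needs site_id, prop_host, mean_host_height_m, n_total,
#'   total_ba_m2, n_host, y_dead, centroid coordinates.
#' @param sites data frame: site_id, cwd_z.
#' @param drop_no_host drop cells with `n_host == 0` (default TRUE).
#' @return list with `table` (model table: identifiers, raw covariates, and
#'   x_* design columns in coefficient order) and `standardization` (data
#'   frame of per-covariate center and scale).
#' @export
standardize_covariates <- function(cells, sites, drop_no_host = TRUE) {
  stopifnot(all(c("site_id", "cwd_z") %in% names(sites)))
  tab <- cells
  tab$cwd_z <- sites$cwd_z[match(tab$site_id, sites$site_id)]
  if (anyNA(tab$cwd_z)) stop("missing site CWD for some cells")
  if (drop_no_host) tab <- tab[tab$n_host > 0, , drop = FALSE]
  raw <- list(cwd = tab$cwd_z,
              prop_host = tab$prop_host,
              host_height = tab$mean_host_height_m,
              density = tab$n_total,
              ba = tab$total_ba_m2)
  std <- data.frame(covariate = names(raw),
                    center = NA_real_, scale = NA_real_)
  for (i in seq_along(raw)) {
    v <- raw[[i]]
    if (anyNA(v)) stop("non-finite covariate values in ", names(raw)[i])
    s <- stats::sd(v)
    if (!(s > 0)) stop("zero variance in covariate ", names(raw)[i])
    std$center[i] <- mean(v); std$scale[i] <- s
    tab[[paste0("x_", names(raw)[i])]] <- (v - mean(v)) / s
  }
  tab$x_cwd_x_host_height <- tab$x_cwd * tab$x_host_height
  tab$x_cwd_x_prop_host <- tab$x_cwd * tab$x_prop_host
  tab$x_cwd_x_density <- tab$x_cwd * tab$x_density
  tab$x_cwd_x_ba <- tab$x_cwd * tab$x_ba
  tab$x_prop_host_x_host_height <- tab$x_prop_host * tab$x_host_height
  tab$x_prop_host_x_density <- tab$x_prop_host * tab$x_density
  tab$x_host_height_x_ba <- tab$x_host_height * tab$x_ba
  tab$x_cwd_x_prop_host_x_host_height <-
    tab$x_cwd * tab$x_prop_host * tab$x_host_height
  rownames(tab) <- NULL
  list(table = tab, standardization = std)
}

#' Random per-site subsample of grid cells
#'
#' Uniform sampling without replacement of up to `k` eligible cells per
#' site; sites with `k` or fewer eligible cells keep all of them.
#' Deterministic under `seed`.
#'
#' @param cells grid-cell table with site_id and an `eligible` column
#'   (missing column means all cells eligible).
#' @param k cells to keep per site (default 200).
#' @param seed integer seed.
#' @return subset of `cells`.
#' @export
subsample_cells <- function(cells, k = 200, seed = 1L) {
  stopifnot(k >= 1)
  if (!"eligible" %in% names(cells)) cells$eligible <- TRUE
  cells <- cells[cells$eligible, , drop = FALSE]
  with_seed(seed, {
    keep <- unlist(lapply(sort(unique(cells$site_id)), function(sid) {
      idx <- which(cells$site_id == sid)
      if (length(idx) <= k) idx else sort(sample(idx, k))
    }))
    cells[keep, , drop = FALSE]
  })
}

#' Overall mortality fraction from dead and total counts
#'
#' @param n_dead number of dead trees.
#' @param n_total total number of trees, >= n_dead.
#' @return list with n_dead, n_total, fraction and percent (fraction x 100).
#' @export
summarize_mortality <- function(n_dead, n_total) {
  stopifnot(n_dead >= 0, n_total >= n_dead)
  list(n_dead = n_dead, n_total = n_total,
       fraction = n_dead / n_total, percent = 100 * n_dead / n_total)
}
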