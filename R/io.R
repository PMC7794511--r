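# Plain-text interchange: tree tables and cell tables as CSV, generator
# configurations as YAML.  (Canopy rasters travel as Esri ASCII grids; see
# write_esri_ascii().)

tree_csv_columns <- c("site_id", "tree_id", "x_m", "y_m", "height_m",
                      "species", "host", "dead", "crown_radius_m")

#' Read and write tree tables as CSV
#'
#' @param trees tree records data frame.
#' @param path file path.
#' @return `read_tree_csv` returns the tree data frame; writers return
#'   `path` invisibly.
#' @export
write_tree_csv <- function(trees, path) {
  if (!"site_id" %in% names(trees)) trees$site_id <- "site01"
  keep <- intersect(tree_csv_columns, names(trees))
  utils::write.csv(trees[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_m", "y_m", "height_m")
  missing <- setdiff(need, names(tr))
  if (length(missing) > 0)
    stop("tree CSV lacks columns: ", paste(missing, collapse = ", "))
  tr
}

#' Read and write grid-cell tables as CSV
#'
#' @param cells grid-cell data frame (from [rasterize_trees()] or the
#'   synthetic generator).
#' @param path file path.
#' @return `read_cells_csv` returns the cell data frame; writers return
#'   `path` invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  ce <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "cell_ix", "cell_iy", "y_dead", "n_host", "n_total")
  missing <- setdiff(need, names(ce))
  if (length(missing) > 0)
    stop("cell CSV lacks columns: ", paste(missing, collapse = ", "))
  ce
}

#' Read and write a synthetic-landscape configuration as YAML
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @return `read_synthetic_config` returns a `synthetic_config`; the writer
#'   returns `path` invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  x$beta <- as.list(x$beta)
  x$covariate_distributions <- lapply(x$covariate_distributions, as.list)
  # 17 significant digits: doubles survive the round trip exactly
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- yaml::read_yaml(path)
  cd <- lapply(x$covariate_distributions, unlist)
  synthetic_config(n_sites = x$n_sites,
                   grid_side_cells = x$grid_side_cells,
                   cells_per_site = x$cells_per_site,
                   cwd_range = unlist(x$cwd_range),
                   beta = unlist(x$beta),
                   zi_p = x$zi_p, gp_sd = x$gp_sd,
                   gp_lengthscale = x$gp_lengthscale,
                   covariate_distributions = cd,
                   allometry = unlist(x$allometry),
                   ba_noise_sdlog = x$ba_noise_sdlog,
                   cell_m = x$cell_m, seed = x$seed)
}
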