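# Benchmarking tree-detection outputs against ground plots: a reference
# local-maxima detector, per-metric Pearson correlation / RMSE / median error,
# and the 5%-of-best tally rule for choosing among detector candidates.
#
# Comparison is at the level of plot-summary structure metrics, NOT
# tree-by-tree matching: a detector is judged by how well the stand structure
# it implies matches the stand structure measured on the ground.

#' Reference local-maxima treetop detector
#'
#' A pixel is a detection iff its canopy-height value is at least
#' `min_height_m` and is the maximum within the square window of side
#' `window_m` centred on it; ties within a window are broken in favour of the
#' first pixel in row-major order.  Returns pixel-centre coordinates and the
#' canopy-height value at each detection.
#'
#' @param chm a [pm_raster()] canopy-height model.
#' @param window_m moving-window side length (m), >= the raster resolution.
#' @param min_height_m minimum treetop height (m), >= 0.
#' @return data frame: x_m, y_m, height_m (possibly empty).
#' @export
reference_detector <- function(chm, window_m, min_height_m = 2) {
  stopifnot(inherits(chm, "pm_raster"), min_height_m >= 0)
  if (window_m < chm$res)
    stop("window_m must be at least the raster resolution")
  v <- chm$values
  nr <- nrow(v); nc <- ncol(v)
  half <- max(1L, floor(window_m / (2 * chm$res)))
  cand <- which(v >= min_height_m & v > 0, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rows <- max(1L, r - half):min(nr, r + half)
    cols <- max(1L, c - half):min(nc, c + half)
    w <- v[rows, cols, drop = FALSE]
    m <- max(w)
    if (v[r, c] < m) next
    # tie-break: this pixel must be the first row-major occurrence of the max
    tie <- which(w == m, arr.ind = TRUE)
    rm_idx <- (rows[tie[, 1]] - 1L) * nc + cols[tie[, 2]]
    keep[k] <- ((r - 1L) * nc + c) == min(rm_idx)
  }
  cand <- cand[keep, , drop = FALSE]
  co <- raster_coords(chm)
  data.frame(x_m = co$x[cand[, 2]], y_m = co$y[cand[, 1]],
             height_m = v[cand])
}

structure_metric_names <- function() {
  c("total_count", "count_gt15m", "mean_height_m", "p25_height_m",
    "p75_height_m", "mean_nn1_m", "mean_nn2_m")
}

#' Compare aerial against ground structure metrics
#'
#' For each of the seven structure metrics, computes the Pearson correlation
#' and RMSE between aerial (detector-derived) and ground plot values, and the
#' median of (air - ground) so that a positive median error indicates an
#' overestimate by the aerial workflow.  Plots where either value is missing
#' are dropped metric-wise; a metric with zero variance on either side has an
#' undefined correlation, recorded as `NA`.
#'
#' @param air_metrics,ground_metrics data frames from
#'   [structure_metrics_table()], sharing the same `plot_id` set.
#' @param algorithm_id label for this detector candidate.
#' @param params optional named list of the candidate's parameter values.
#' @return object of class `pm_eval` with a per-metric data frame.
#' @export
evaluate_detection <- function(air_metrics, ground_metrics,
                               algorithm_id = "detector", params = list()) {
  if (!setequal(air_metrics$plot_id, ground_metrics$plot_id))
    stop("air and ground tables must cover the same plots")
  g <- ground_metrics[match(air_metrics$plot_id, ground_metrics$plot_id), ]
  mets <- intersect(structure_metric_names(), names(air_metrics))
  rows <- lapply(mets, function(m) {
    a <- air_metrics[[m]]; b <- g[[m]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    r <- NA_real_
    if (length(a) >= 3 && stats::sd(a) > 0 && stats::sd(b) > 0)
      r <- stats::cor(a, b)
    data.frame(metric = m,
               pearson_r = r,
               rmse = if (length(a) > 0) sqrt(mean((a - b)^2)) else NA_real_,
               median_error = if (length(a) > 0) stats::median(a - b)
                              else NA_real_,
               n_plots = length(a),
               stringsAsFactors = FALSE)
  })
  structure(list(algorithm_id = algorithm_id, params = params,
                 metrics = do.call(rbind, rows)),
            class = "pm_eval")
}

#' @export
print.pm_eval <- function(x, ...) {
  cat(sprintf("<pm_eval> %s\n", x$algorithm_id))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Select the best detector candidate by the 5%-of-best tally rule
#'
#' For each structure metric, a candidate is marked if its Pearson
#' correlation is within 5% of the highest correlation across candidates
#' (`r >= 0.95 * max r`, only for metrics whose best correlation is
#' positive), and/or if its RMSE is within 5% of the lowest
#' (`rmse <= 1.05 * min rmse`).  Each candidate's tally is the number of
#' metrics where it reaches at least one of the two thresholds
#' (`mode = "either"`, the default) or both (`mode = "both"`); the winner has
#' the maximum tally.  Tally ties are broken by higher mean correlation
#' across metrics, then by input order.
#'
#' @param results list of [evaluate_detection()] results on the same metric
#'   set.
#' @param mode `"either"` or `"both"`: how the correlation and RMSE criteria
#'   combine into the per-metric tally.
#' @return list with `winner` (a `pm_eval`), `winner_id`, and `table`, a data
#'   frame of per-candidate tallies and flags.
#' @export
select_best <- function(results, mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (length(results) == 0) stop("no candidates to select from")
  stopifnot(all(vapply(results, inherits, logical(1), "pm_eval")))
  mets <- results[[1]]$metrics$metric
  for (r in results)
    if (!identical(r$metrics$metric, mets))
      stop("all candidates must be evaluated on the same metric set")

  r_mat <- vapply(results, function(r) r$metrics$pearson_r,
                  numeric(length(mets)))
  rmse_mat <- vapply(results, function(r) r$metrics$rmse,
                     numeric(length(mets)))
  r_mat <- matrix(r_mat, nrow = length(mets))
  rmse_mat <- matrix(rmse_mat, nrow = length(mets))

  max_r <- apply(r_mat, 1, function(z) if (all(is.na(z))) NA_real_
                                       else max(z, na.rm = TRUE))
  min_rmse <- apply(rmse_mat, 1, function(z) if (all(is.na(z))) NA_real_
                                             else min(z, na.rm = TRUE))
  within_r <- sweep(r_mat, 1, 0.95 * max_r, ">=")
  within_r[is.na(within_r)] <- FALSE
  within_r[is.na(max_r) | max_r <= 0, ] <- FALSE  # criterion undefined
  within_rmse <- sweep(rmse_mat, 1, 1.05 * min_rmse, "<=")
  within_rmse[is.na(within_rmse)] <- FALSE

  hit <- if (mode == "either") within_r | within_rmse
         else within_r & within_rmse
  # metrics undefined for every candidate do not count toward the tally
  defined <- !(is.na(max_r) & is.na(min_rmse))
  tally <- colSums(hit[defined, , drop = FALSE])
  mean_r <- colMeans(r_mat, na.rm = TRUE)

  ord <- order(-tally, -mean_r, seq_along(results))
  win <- ord[1]
  tab <- data.frame(algorithm_id = vapply(results, `[[`, "", "algorithm_id"),
                    tally = tally, mean_pearson_r = mean_r,
                    winner = seq_along(results) == win,
                    stringsAsFactors = FALSE)
  list(winner = results[[win]], winner_id = tab$algorithm_id[win],
       table = tab,
       within5_r = within_r, within5_rmse = within_rmse, mode = mode)
}
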