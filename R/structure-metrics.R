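# Plot-level forest-structure metrics used to validate individual-tree
# detection: tree counts, height summaries, and mean nearest-neighbour
# distances within a circular plot footprint.

#' Circular plot footprint
#'
#' The default radius of 11.42 m corresponds to the 0.041-ha circular field
#' plots of the monitoring network this package targets.
#'
#' @param center_x_m,center_y_m plot centre in projected coordinates (m).
#' @param radius_m plot radius (m), > 0.
#' @return object of class `plot_footprint`.
#' @export
plot_footprint <- function(center_x_m, center_y_m, radius_m = 11.42) {
  stopifnot(radius_m > 0)
  structure(list(center_x_m = center_x_m, center_y_m = center_y_m,
                 radius_m = radius_m),
            class = "plot_footprint")
}

#' Clip a stem map to a plot footprint
#'
#' Retains trees whose horizontal Euclidean distance from the plot centre is
#' at most the radius (closed ball: a tree exactly on the boundary is kept).
#'
#' @param trees tree records with x_m, y_m.
#' @param footprint a [plot_footprint()].
#' @return the subset of `trees` inside the footprint.
#' @export
clip_to_footprint <- function(trees, footprint) {
  stopifnot(inherits(footprint, "plot_footprint"))
  if (nrow(trees) == 0) return(trees)
  d <- sqrt((trees$x_m - footprint$center_x_m)^2 +
            (trees$y_m - footprint$center_y_m)^2)
  trees[d <= footprint$radius_m, , drop = FALSE]
}

#' Seven plot-level forest-structure metrics
#'
#' Computes, for one clipped stem map: total tree count; count of trees
#' strictly taller than 15 m; mean, 25th- and 75th-percentile height
#' (percentiles by linear interpolation between order statistics); and the
#' mean distance to the first and second nearest neighbour (2-D horizontal
#' distances within the clipped set only, no edge correction).
#'
#' Metrics that are undefined for small stands are returned as `NA` rather
#' than silently zero: height summaries need at least 1 tree, first-neighbour
#' distance at least 2, second-neighbour distance at least 3.
#'
#' @param trees tree records with x_m, y_m, height_m (and optionally `dead`).
#' @param live_only if `TRUE`, drop dead trees before computing any metric.
#' @return one-row data frame: total_count, count_gt15m, mean_height_m,
#'   p25_height_m, p75_height_m, mean_nn1_m, mean_nn2_m.
#' @export
compute_structure_metrics <- function(trees, live_only = FALSE) {
  if (live_only && "dead" %in% names(trees))
    trees <- trees[trees$dead == 0, , drop = FALSE]
  n <- nrow(trees)
  if (n > 0 && any(is.na(trees$height_m)))
    stop("all trees must have a height")
  out <- data.frame(total_count = n,
                    count_gt15m = if (n > 0) sum(trees$height_m > 15) else 0L,
                    mean_height_m = NA_real_, p25_height_m = NA_real_,
                    p75_height_m = NA_real_, mean_nn1_m = NA_real_,
                    mean_nn2_m = NA_real_)
  if (n >= 1) {
    out$mean_height_m <- mean(trees$height_m)
    q <- stats::quantile(trees$height_m, c(0.25, 0.75), type = 7, names = FALSE)
    out$p25_height_m <- q[1]
    out$p75_height_m <- q[2]
  }
  if (n >= 2) {
    d <- as.matrix(stats::dist(cbind(trees$x_m, trees$y_m)))
    diag(d) <- Inf
    nn1 <- apply(d, 1, min)
    out$mean_nn1_m <- mean(nn1)
    if (n >= 3) {
      nn2 <- apply(d, 1, function(row) sort(row, partial = 2)[2])
      out$mean_nn2_m <- mean(nn2)
    }
  }
  out
}

#' Structure metrics for many plots at once
#'
#' Clips the stem map to each plot footprint and computes the seven metrics,
#' returning one row per plot.  This is the shape consumed by
#' [evaluate_detection()].
#'
#' @param trees tree records (x_m, y_m, height_m, ...).
#' @param plots data frame: plot_id, center_x_m, center_y_m and optionally
#'   radius_m (default 11.42 m).
#' @param live_only passed to [compute_structure_metrics()].
#' @return data frame with plot_id plus the seven metric columns.
#' @export
structure_metrics_table <- function(trees, plots, live_only = FALSE) {
  if (!"radius_m" %in% names(plots)) plots$radius_m <- 11.42
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    fp <- plot_footprint(plots$center_x_m[i], plots$center_y_m[i],
                         plots$radius_m[i])
    cbind(data.frame(plot_id = plots$plot_id[i]),
          compute_structure_metrics(clip_to_footprint(trees, fp),
                                    live_only = live_only))
  })
  do.call(rbind, rows)
}
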