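# Calibration stages: drone-to-field height bias correction, per-species
# height-to-DBH allometry with basal area, and site CWD z-scoring against a
# species-range reference distribution.

#' Fit drone-to-field height calibrations by live/dead status
#'
#' Drone photogrammetry underestimates the heights of dead, needleless trees
#' (their narrow tops are poorly reconstructed) and field methods can
#' overestimate live-tree heights, so field height is regressed on drone
#' height separately for live and dead trees.  Only pairs with drone height
#' strictly above `fit_threshold_m` (default 20 m) enter the fit; the
#' resulting correction is applied to all trees by
#' [apply_height_calibration()].
#'
#' @param pairs data frame: drone_height_m, field_height_m, status
#'   (`"live"`/`"dead"`).
#' @param fit_threshold_m minimum drone-measured height used in fitting (m).
#' @return object of class `height_calibration`: per-status list of slope,
#'   intercept, fit_threshold_m, n_pairs.
#' @export
fit_height_calibration <- function(pairs, fit_threshold_m = 20) {
  stopifnot(all(c("drone_height_m", "field_height_m", "status") %in%
                names(pairs)))
  out <- list()
  for (st in unique(pairs$status)) {
    sub <- pairs[pairs$status == st & pairs$drone_height_m > fit_threshold_m, ]
    if (nrow(sub) < 2)
      stop(sprintf("fewer than 2 pairs above %g m for status '%s'",
                   fit_threshold_m, st))
    if (stats::sd(sub$drone_height_m) == 0)
      stop(sprintf("singular fit for status '%s': all drone heights identical",
                   st))
    fit <- stats::lm(field_height_m ~ drone_height_m, data = sub)
    out[[st]] <- list(status = st,
                      slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      fit_threshold_m = fit_threshold_m,
                      n_pairs = nrow(sub))
  }
  structure(out, class = "height_calibration")
}

#' Apply a height calibration to a tree table
#'
#' Corrected height = slope x drone height + intercept, by status, applied
#' to **all** trees (not only those above the fitting threshold), floored at
#' zero.
#'
#' @param trees tree records with height_m and either a `status` column
#'   (`"live"`/`"dead"`) or a 0/1 `dead` column.
#' @param calibration a [fit_height_calibration()] result.
#' @return `trees` with height_m replaced by the corrected height (the
#'   uncorrected value is kept as `height_uncal_m`).
#' @export
apply_height_calibration <- function(trees, calibration) {
  stopifnot(inherits(calibration, "height_calibration"))
  status <- if ("status" %in% names(trees)) trees$status
            else ifelse(trees$dead == 1, "dead", "live")
  missing <- setdiff(unique(status), names(calibration))
  if (length(missing) > 0)
    stop("no calibration for status: ", paste(missing, collapse = ", "))
  slope <- vapply(status, function(s) calibration[[s]]$slope, numeric(1))
  icept <- vapply(status, function(s) calibration[[s]]$intercept, numeric(1))
  trees$height_uncal_m <- trees$height_m
  trees$height_m <- pmax(0, slope * trees$height_m + icept)
  trees
}

#' Per-species height-to-DBH allometry from field trees
#'
#' Ordinary least squares of DBH (cm) on height (m), fitted per species on
#' field trees above the field inclusion threshold (DBH > 6.35 cm).  Species
#' with fewer than `min_n` usable trees are skipped with a warning.
#'
#' @param field_trees data frame: species, height_m, dbh_cm.
#' @param min_dbh_cm field inclusion rule (cm); trees at or below are
#'   excluded from fitting.
#' @param min_n minimum trees per species (default 3).
#' @return object of class `allometry`: per-species list of slope
#'   (cm DBH per m height), intercept (cm), r2, n.
#' @export
fit_allometry <- function(field_trees, min_dbh_cm = 6.35, min_n = 3) {
  stopifnot(all(c("species", "height_m", "dbh_cm") %in% names(field_trees)))
  field_trees <- field_trees[field_trees$dbh_cm > min_dbh_cm, ]
  out <- list()
  for (sp in unique(field_trees$species)) {
    sub <- field_trees[field_trees$species == sp, ]
    if (nrow(sub) < min_n) {
      warning(sprintf("species '%s' skipped: only %d trees (need >= %d)",
                      sp, nrow(sub), min_n))
      next
    }
    if (stats::sd(sub$height_m) == 0)
      stop(sprintf("singular allometry for species '%s': constant heights", sp))
    fit <- stats::lm(dbh_cm ~ height_m, data = sub)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((sub$dbh_cm - mean(sub$dbh_cm))^2)
    out[[sp]] <- list(species = sp,
                      slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                      n = nrow(sub))
  }
  structure(out, class = "allometry")
}

#' Predict DBH from height using a fitted allometry
#'
#' Dead trees are assumed to be ponderosa pine, so callers should pass
#' species `"PIPO"` for dead trees.  Predictions are floored at 0 cm.
#'
#' @param allometry a [fit_allometry()] result.
#' @param species character vector of species codes.
#' @param height_m tree heights (m).
#' @return predicted DBH (cm).
#' @export
predict_dbh <- function(allometry, species, height_m) {
  stopifnot(inherits(allometry, "allometry"),
            length(species) == length(height_m))
  missing <- setdiff(unique(species), names(allometry))
  if (length(missing) > 0)
    stop("no allometry for species: ", paste(missing, collapse = ", "))
  slope <- vapply(species, function(s) allometry[[s]]$slope, numeric(1))
  icept <- vapply(species, function(s) allometry[[s]]$intercept, numeric(1))
  pmax(0, slope * height_m + icept)
}

#' Basal area of a stem from its DBH
#'
#' The standard geometric definition: the cross-sectional area at breast
#' height, \eqn{\pi (DBH/2)^2}, returned in square metres for DBH in cm.
#'
#' @param dbh_cm diameter at breast height (cm), >= 0.
#' @return basal area (m^2).
#' @export
basal_area <- function(dbh_cm) {
  if (any(dbh_cm < 0, na.rm = TRUE)) stop("DBH must be non-negative")
  pi * (dbh_cm / 200)^2
}

#' Reference distribution for CWD z-scoring
#'
#' Wraps a vector of climatic-water-deficit values (mm) spanning the host
#' species' climatic range (e.g. CWD at herbarium-record locations) and
#' precomputes its mean and sample (n-1) standard deviation.
#'
#' @param values_mm numeric vector of reference CWD values (mm), n >= 2 with
#'   positive spread.
#' @return object of class `cwd_reference`.
#' @export
cwd_reference <- function(values_mm) {
  values_mm <- as.numeric(values_mm)
  stopifnot(length(values_mm) >= 2)
  s <- stats::sd(values_mm)
  if (!(s > 0)) stop("reference CWD values have zero spread")
  structure(list(values = values_mm, mean = mean(values_mm), sd = s),
            class = "cwd_reference")
}

#' Site CWD z-score against a reference distribution
#'
#' z = (site - reference mean) / reference sample sd.  A z-score of +1 means
#' the site is one standard deviation hotter/drier than the mean of the
#' reference distribution.
#'
#' @param site_cwd_mm site CWD values (mm), vectorized.
#' @param reference a [cwd_reference()].
#' @return unitless z-scores.
#' @export
cwd_zscore <- function(site_cwd_mm, reference) {
  stopifnot(inherits(reference, "cwd_reference"))
  (site_cwd_mm - reference$mean) / reference$sd
}
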