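# Vegetation indices, per-crown mean reflectance extraction, and the k-fold
# cross-validated classification harness for live/dead and host/non-host
# labels with a pluggable classifier.

#' Five canonical vegetation indices from band means
#'
#' NDVI = (NIR - Red) / (NIR + Red); NDRE = (NIR - RedEdge) /
#' (NIR + RedEdge); RGI = Red / Green; CI_rededge = NIR / RedEdge - 1;
#' CI_green = NIR / Green - 1.  A zero denominator yields `NA` for that
#' index, never an infinity.
#'
#' @param bands data frame (or one-row-coercible named list) with columns
#'   blue, green, red, red_edge, nir, all surface reflectance in \[0, 1\].
#' @return data frame with columns ndvi, ndre, rgi, ci_rededge, ci_green.
#' @export
compute_indices <- function(bands) {
  bands <- as.data.frame(as.list(bands))
  need <- c("green", "red", "red_edge", "nir")
  missing <- setdiff(need, names(bands))
  if (length(missing) > 0)
    stop("missing bands: ", paste(missing, collapse = ", "))
  sdiv <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  data.frame(
    ndvi = sdiv(bands$nir - bands$red, bands$nir + bands$red),
    ndre = sdiv(bands$nir - bands$red_edge, bands$nir + bands$red_edge),
    rgi = sdiv(bands$red, bands$green),
    ci_rededge = sdiv(bands$nir, bands$red_edge) - 1,
    ci_green = sdiv(bands$nir, bands$green) - 1)
}

#' Five-band reflectance stack
#'
#' @param blue,green,red,red_edge,nir co-registered [pm_raster()] objects of
#'   identical dimensions, origin and resolution.
#' @return object of class `band_stack`.
#' @export
band_stack <- function(blue, green, red, red_edge, nir) {
  bands <- list(blue = blue, green = green, red = red,
                red_edge = red_edge, nir = nir)
  for (b in bands) stopifnot(inherits(b, "pm_raster"))
  ref <- bands[[1]]
  for (b in bands[-1])
    if (!identical(dim(b$values), dim(ref$values)) ||
        !isTRUE(all.equal(b$origin, ref$origin)) || b$res != ref$res)
      stop("all bands must share dimensions, origin and resolution")
  structure(bands, class = "band_stack")
}

# logical vector: which pixel centres fall inside the crown
crown_pixel_mask <- function(xs, ys, crown) {
  if (!is.null(crown$polygon)) {
    pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
    inside <- mgcv::in.out(crown$polygon, pts)
    matrix(inside, nrow = length(ys), ncol = length(xs))
  } else {
    dx2 <- (xs - crown$x_m)^2
    dy2 <- (ys - crown$y_m)^2
    outer(dy2, dx2, "+") <= crown$radius_m^2
  }
}

#' Extract per-crown mean band values and indices
#'
#' For each crown, averages the pixels whose centres fall inside the crown
#' geometry (pixel-centre-in rule) in each of the five bands, then computes
#' the five vegetation indices.  By default indices are computed **from the
#' band means** (the ten-variable design: five band means + five indices of
#' those means); `per_pixel_indices = TRUE` instead averages per-pixel index
#' maps within the crown.
#'
#' A crown capturing zero pixel centres gets `NA` features and is flagged by
#' `n_pixels = 0`.
#'
#' @param stack a [band_stack()].
#' @param crowns either a data frame of circles (crown_id, x_m, y_m,
#'   radius_m) or a named list of polygon vertex matrices (columns x, y).
#' @param per_pixel_indices compute indices per pixel and then average,
#'   instead of from band means.
#' @return data frame: crown_id, n_pixels, the five band means, the five
#'   indices.
#' @export
extract_crown_features <- function(stack, crowns, per_pixel_indices = FALSE) {
  stopifnot(inherits(stack, "band_stack"))
  co <- raster_coords(stack$blue)
  if (is.data.frame(crowns)) {
    crown_list <- lapply(seq_len(nrow(crowns)), function(i)
      list(crown_id = crowns$crown_id[i], x_m = crowns$x_m[i],
           y_m = crowns$y_m[i], radius_m = crowns$radius_m[i],
           polygon = NULL))
  } else {
    crown_list <- lapply(names(crowns), function(id)
      list(crown_id = id, polygon = as.matrix(crowns[[id]])))
  }
  band_names <- names(stack)
  rows <- lapply(crown_list, function(cr) {
    mask <- crown_pixel_mask(co$x, co$y, cr)
    n_px <- sum(mask)
    out <- data.frame(crown_id = cr$crown_id, n_pixels = n_px)
    if (n_px == 0) {
      for (b in band_names) out[[b]] <- NA_real_
      return(cbind(out, compute_indices(out[band_names])))
    }
    means <- vapply(band_names, function(b) mean(stack[[b]]$values[mask]),
                    numeric(1))
    for (b in band_names) out[[b]] <- means[[b]]
    if (per_pixel_indices) {
      px <- as.data.frame(lapply(stack, function(b) b$values[mask]))
      idx <- compute_indices(px)
      cbind(out, as.data.frame(lapply(idx, mean)))
    } else {
      cbind(out, compute_indices(as.list(means)))
    }
  })
  do.call(rbind, rows)
}

#' Default pluggable classifier: regularized (ridge) logistic regression
#'
#' Meets the fit/predict contract of [crossval_classify()]: `fit(x, y)`
#' returns a model, `predict(model, x)` returns predicted class labels.
#' Binary labels use a binomial model, more than two classes a multinomial
#' one.  Heavier learners (boosted logistic regression, regularized
#' discriminant analysis, random forests, ...) can be supplied through the
#' same contract.
#'
#' @param lambda ridge penalty at which predictions are made.
#' @return list with `fit` and `predict` functions.
#' @export
ridge_logistic_classifier <- function(lambda = 1e-3) {
  list(
    fit = function(x, y) {
      y <- factor(y)
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      glmnet::glmnet(as.matrix(x), y, family = fam, alpha = 0,
                     lambda = sort(unique(c(10, 1, 0.1, 0.01, lambda)),
                                   decreasing = TRUE))
    },
    predict = function(model, x) {
      as.character(predict(model, as.matrix(x), s = lambda, type = "class"))
    })
}

#' Stratified k-fold cross-validated classification
#'
#' Splits the data into k folds stratified by class (so every class is
#' present in every training fold), fits the classifier on each training
#' split and scores the held-out fold.  The classifier is pluggable: any
#' list with `fit(x, y) -> model` and `predict(model, x) -> labels`.
#'
#' @param features data frame or matrix of numeric predictors.
#' @param labels class labels (coerced to factor); every class must have at
#'   least `k` members.
#' @param k number of folds, >= 2.
#' @param classifier a fit/predict pair; default
#'   [ridge_logistic_classifier()].
#' @param seed integer seed for fold assignment.
#' @return list: `accuracy` (overall held-out), `fold_accuracy`, `confusion`
#'   (summed confusion table), `fold_confusion` (per-fold list),
#'   `predictions` data frame.
#' @export
crossval_classify <- function(features, labels, k = 5,
                              classifier = ridge_logistic_classifier(),
                              seed = 1L) {
  stopifnot(k >= 2)
  labels <- factor(labels)
  x <- as.matrix(features)
  if (anyNA(x)) stop("features must be complete (no NA)")
  tab <- table(labels)
  if (any(tab < k))
    stop("stratification failure: class(es) with fewer than k members: ",
         paste(names(tab)[tab < k], collapse = ", "))
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  preds <- character(length(labels))
  fold_acc <- numeric(k)
  fold_conf <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    model <- classifier$fit(x[tr, , drop = FALSE], labels[tr])
    p <- classifier$predict(model, x[te, , drop = FALSE])
    preds[te] <- p
    fold_acc[f] <- mean(p == as.character(labels[te]))
    fold_conf[[f]] <- table(observed = labels[te],
                            predicted = factor(p, levels = levels(labels)))
  }
  list(accuracy = mean(preds == as.character(labels)),
       fold_accuracy = fold_acc,
       confusion = Reduce(`+`, fold_conf),
       fold_confusion = fold_conf,
       predictions = data.frame(observed = labels, predicted = preds,
                                fold = folds, stringsAsFactors = FALSE))
}

#' Assign host status after live/dead and species classification
#'
#' Implements the classification cascade for the western pine beetle system:
#' crowns are first classified live/dead; species classification applies to
#' live crowns only; a live crown is a host iff it is ponderosa pine
#' (`"PIPO"`), and **all dead crowns are treated as hosts** (dead trees are
#' assumed to be ponderosa pine).
#'
#' @param dead integer/logical vector of live(0)/dead(1) calls.
#' @param species character vector of species calls for live crowns (values
#'   for dead crowns are ignored).
#' @return integer host flag (1 = host).
#' @export
assign_host_status <- function(dead, species) {
  stopifnot(length(dead) == length(species))
  as.integer(dead == 1 | species == "PIPO")
}
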