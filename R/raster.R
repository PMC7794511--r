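#' Single-band raster in projected metre coordinates
#'
#' A minimal in-memory raster used for canopy-height models and reflectance
#' bands.  Values are stored as a matrix whose first row is the *top* (largest
#' y) of the scene, matching the row order of the Esri ASCII grid format.
#'
#' @param values numeric matrix; `values[1, 1]` is the top-left pixel.
#' @param origin numeric length-2, `c(x, y)` of the lower-left corner (m).
#' @param res pixel size in metres (square pixels).
#' @return an object of class `pm_raster`.
#' @export
pm_raster <- function(values, origin = c(0, 0), res = 1) {
  stopifnot(is.matrix(values), is.numeric(values), length(origin) == 2,
            is.numeric(res), length(res) == 1, res > 0)
  structure(list(values = values, origin = as.numeric(origin), res = res),
            class = "pm_raster")
}

#' @export
print.pm_raster <- function(x, ...) {
  cat(sprintf("<pm_raster> %d x %d pixels, res %.3g m, origin (%.6g, %.6g)\n",
              nrow(x$values), ncol(x$values), x$res, x$origin[1], x$origin[2]))
  cat(sprintf("  value range: [%.6g, %.6g]\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Pixel-centre coordinates of a raster
#'
#' @param r a `pm_raster`.
#' @return list with `x` (by column, increasing) and `y` (by row, decreasing:
#'   `y[1]` is the centre of the top row).
#' @export
raster_coords <- function(r) {
  stopifnot(inherits(r, "pm_raster"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$origin[1] + (seq_len(nc) - 0.5) * r$res,
       y = r$origin[2] + (nr - seq_len(nr) + 0.5) * r$res)
}

#' Write / read a raster as an Esri ASCII grid
#'
#' Plain-text interchange for canopy-height models; this is the classic
#' `ncols/nrows/xllcorner/...` header followed by rows from the top of the
#' scene down.
#'
#' @param r a `pm_raster`.
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a `pm_raster`.
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "pm_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", format(r$origin[1], digits = 15)),
           paste("yllcorner", format(r$origin[2], digits = 15)),
           paste("cellsize", format(r$res, digits = 15)),
           paste("NODATA_value", nodata))
  body <- apply(v, 1, function(row) paste(format(row, digits = 15, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  body <- lines[-(1:6)]
  v <- matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
              nrow = nrows, ncol = ncols, byrow = TRUE)
  v[v == val[["nodata_value"]]] <- NA_real_
  pm_raster(v, origin = c(val[["xllcorner"]], val[["yllcorner"]]),
            res = val[["cellsize"]])
}
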