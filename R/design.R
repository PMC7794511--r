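#' Coefficient names of the mortality model
#'
#' The fixed-effect structure of the zero-inflated binomial mortality model:
#' an intercept, five standardized base covariates (site climatic water
#' deficit z-score, proportion of host trees, mean host height, overall tree
#' density, overall basal area), seven two-way interactions and one three-way
#' interaction, in the canonical order used throughout the package.
#'
#' @return character vector of length 14.
#' @export
coef_names <- function() {
  c("intercept",
    "cwd",
    "prop_host",
    "host_height",
    "density",
    "ba",
    "cwd_x_host_height",
    "cwd_x_prop_host",
    "cwd_x_density",
    "cwd_x_ba",
    "prop_host_x_host_height",
    "prop_host_x_density",
    "host_height_x_ba",
    "cwd_x_prop_host_x_host_height")
}

# standardized column names expected in a model table, in coefficient order
# (without the intercept)
design_columns <- function() {
  paste0("x_", coef_names()[-1])
}

#' Build the fixed-effect design matrix from a model table
#'
#' @param model_table data frame holding the standardized covariate columns
#'   `x_cwd`, `x_prop_host`, ... as produced by [standardize_covariates()].
#' @return numeric matrix with one column per coefficient (intercept first),
#'   column names from [coef_names()].
#' @export
build_design <- function(model_table) {
  cols <- design_columns()
  missing <- setdiff(cols, names(model_table))
  if (length(missing) > 0)
    stop("model table lacks design columns: ", paste(missing, collapse = ", "))
  X <- cbind(1, as.matrix(model_table[cols]))
  colnames(X) <- coef_names()
  X
}
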