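#' Construct a protein feature matrix
#'
#' The unified analysis container of the package: a numeric proteins x
#' features matrix plus per-column bookkeeping. Categorical features must
#' already be expanded to 0/1 indicator columns (see [assemble_features()],
#' which does this for you); `base_feature` records which original feature
#' each indicator column came from.
#'
#' @param values numeric matrix with unique rownames (protein ids) and
#'   colnames (feature names).
#' @param kinds character vector, one of `"continuous"` or `"categorical"`
#'   per column (recycled if length 1).
#' @param heavy_tailed logical per column: should [log_transform()] apply a
#'   `log(1 + x)` transform to this column?
#' @param base_feature character per column: provenance feature name
#'   (defaults to the column name itself).
#' @param metadata free-form list (imputation records etc.).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kinds = "continuous", heavy_tailed = FALSE,
                           base_feature = NULL, metadata = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames (protein ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique colnames (feature names)")
  p <- ncol(values)
  kinds <- rep_len(as.character(kinds), p)
  if (!all(kinds %in% c("continuous", "categorical")))
    stop("kinds must be 'continuous' or 'categorical'")
  heavy_tailed <- rep_len(as.logical(heavy_tailed), p)
  base_feature <- base_feature %||% colnames(values)
  base_feature <- rep_len(as.character(base_feature), p)
  names(kinds) <- names(heavy_tailed) <- names(base_feature) <- colnames(values)
  structure(
    list(values = values, kinds = kinds, heavy_tailed = heavy_tailed,
         base_feature = base_feature, metadata = metadata),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d proteins x %d features (%d continuous, %d categorical indicators, %d heavy-tailed)\n",
              nrow(x$values), ncol(x$values),
              sum(x$kinds == "continuous"), sum(x$kinds == "categorical"),
              sum(x$heavy_tailed)))
  if (length(x$metadata$imputed_counts))
    cat("  imputed entries:", sum(unlist(x$metadata$imputed_counts)), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Protein identifiers of a feature matrix
#' @param fm a `feature_matrix`.
#' @return character vector of protein ids (row order).
#' @export
protein_ids <- function(fm) rownames(fm$values)

#' Feature names of a feature matrix
#' @param fm a `feature_matrix`.
#' @return character vector of column names.
#' @export
feature_names <- function(fm) colnames(fm$values)
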