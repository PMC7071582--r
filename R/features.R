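#' Read a gene x tissue expression matrix from TSV
#'
#' First column is the gene id, remaining columns are tissues; a header row
#' is required. Values must be non-negative linear-scale expression levels
#' (e.g. TPM).
#'
#' @param path path to a tab-separated file.
#' @return an `expression_matrix`: numeric matrix, rownames = gene ids.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expression matrix needs at least 2 tissue columns")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m)
}

#' Construct an expression matrix object
#'
#' @param values numeric gene x tissue matrix, rownames = unique gene ids,
#'   at least 2 tissue columns, all values >= 0.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("at least 2 tissues are required")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids must be unique rownames")
  if (anyNA(values) || any(values < 0)) stop("expression values must be non-negative")
  structure(values, class = c("expression_matrix", "matrix"))
}

#' Tissue-specificity entropy of expression profiles
#'
#' Shannon entropy of each gene's normalized expression profile:
#' \deqn{E(g) = -\frac{1}{S_g}\sum_{i=1}^{N} e_{ig} \log_2 \frac{e_{ig}}{S_g}}
#' where \eqn{e_{ig}} is expression of gene g in tissue i, N the number of
#' tissues and \eqn{S_g = \sum_i e_{ig}}. Ranges from 0 (expressed in a
#' single tissue) to \eqn{\log_2 N} (uniform profile). Zero terms contribute
#' 0; genes with \eqn{S_g = 0} get `NA`.
#'
#' @param expr an [expression_matrix()].
#' @return named numeric vector of per-gene entropies (bits).
#' @export
tissue_entropy <- function(expr) {
  m <- unclass(expr)
  if (ncol(m) < 2) stop("at least 2 tissues are required")
  s <- rowSums(m)
  p <- m / s
  terms <- p * log2(p)
  terms[m == 0] <- 0 # 0 * log2(0) := 0
  e <- -rowSums(terms)
  e[s == 0] <- NA_real_
  e <- pmin(pmax(e, 0), log2(ncol(m))) # clamp numerical fuzz at the bounds
  names(e) <- rownames(m)
  e
}

#' Average per-gene entropies over expression sources
#'
#' Per gene, the mean over the sources in which the gene has a non-missing
#' entropy; a gene missing (or `NA`) in every source stays `NA`.
#'
#' @param entropies list of named numeric vectors, one per expression source.
#' @return named numeric vector over the union of gene ids.
#' @export
average_entropy <- function(entropies) {
  if (!is.list(entropies) || length(entropies) == 0)
    stop("need at least one entropy source")
  genes <- unique(unlist(lapply(entropies, names)))
  if (is.null(genes)) stop("entropy vectors must be named by gene id")
  acc <- matrix(NA_real_, nrow = length(genes), ncol = length(entropies),
                dimnames = list(genes, NULL))
  for (k in seq_along(entropies)) acc[names(entropies[[k]]), k] <- entropies[[k]]
  out <- rowMeans(acc, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Log-transform heavy-tailed feature columns
#'
#' Columns flagged `heavy_tailed` are replaced by `log(1 + x)`; the offset
#' keeps zero-valued entries (e.g. centralities of isolated proteins)
#' representable. Other columns pass through unchanged.
#'
#' @param fm a [feature_matrix()].
#' @return a `feature_matrix` with transformed columns.
#' @export
log_transform <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- which(fm$heavy_tailed)
  if (length(idx)) {
    sub <- fm$values[, idx, drop = FALSE]
    if (any(sub < 0, na.rm = TRUE))
      stop("negative value in a heavy-tailed column; log transform undefined")
    fm$values[, idx] <- log1p(sub)
  }
  fm
}

#' Min-max scale every feature column to [0, 1]
#'
#' Each column is mapped affinely by `(f - f_min) / (f_max - f_min)` using
#' its non-missing minimum and maximum. Constant columns (max == min) carry
#' no information and map to all zeros; all-missing columns are dropped with
#' a warning.
#'
#' @param fm a [feature_matrix()].
#' @return a rescaled `feature_matrix`.
#' @export
min_max_scale <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- fm$values
  lo <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
  hi <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
  all_na <- !is.finite(lo) & !is.finite(hi)
  if (any(all_na)) {
    warning("dropping all-missing feature column(s): ",
            paste(colnames(m)[all_na], collapse = ", "))
    keep <- !all_na
    m <- m[, keep, drop = FALSE]
    lo <- lo[keep]; hi <- hi[keep]
    fm$kinds <- fm$kinds[keep]
    fm$heavy_tailed <- fm$heavy_tailed[keep]
    fm$base_feature <- fm$base_feature[keep]
  }
  rng <- hi - lo
  for (j in seq_len(ncol(m))) {
    m[, j] <- if (rng[j] > 0) (m[, j] - lo[j]) / rng[j] else 0
  }
  fm$values <- m
  fm
}

#' Read a protein feature table with an optional metadata sidecar
#'
#' The TSV's first column is the protein id. The YAML sidecar may declare
#' `feature_kinds:` (a map from feature name to `continuous`/`categorical`)
#' and `heavy_tailed:` (a list of feature names). Character columns are
#' treated as categorical regardless.
#'
#' @param path path to the feature TSV.
#' @param meta_path optional path to a YAML sidecar.
#' @return a data.frame (first column `protein_id`) carrying `kinds` and
#'   `heavy_tailed` attributes, ready for [assemble_features()].
#' @export
read_feature_table <- function(path, meta_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "protein_id"
  kinds <- NULL
  heavy <- character()
  if (!is.null(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    kinds <- unlist(meta$feature_kinds)
    heavy <- as.character(unlist(meta$heavy_tailed))
  }
  attr(df, "kinds") <- kinds
  attr(df, "heavy_tailed") <- heavy
  df
}

one_hot <- function(x, base_name) {
  lev <- sort(unique(as.character(x[!is.na(x)])))
  cols <- lapply(lev, function(l) as.numeric(x == l))
  m <- do.call(cbind, cols)
  colnames(m) <- paste(base_name, lev, sep = ".")
  m
}

#' Assemble per-protein feature sources into one feature matrix
#'
#' Outer-joins a list of sources on protein id, one-hot encodes categorical
#' columns, and imputes missing numeric entries with the column median
#' computed over proteins *not* listed in `exclude_from_impute` (pass the
#' positive training set there to avoid leaking its statistics into the
#' imputation). Sources may be data.frames with a `protein_id` first column
#' (optionally carrying `kinds` / `heavy_tailed` attributes, see
#' [read_feature_table()]), or named numeric vectors, or numeric matrices /
#' data.frames with protein-id rownames.
#'
#' @param sources named list of sources; a vector source takes its feature
#'   name from the list name.
#' @param exclude_from_impute protein ids excluded from median computation.
#' @param heavy_tailed feature names to flag heavy-tailed, in addition to
#'   any flags carried by the sources.
#' @param impute impute missing entries? (default TRUE)
#' @return a [feature_matrix()] over the union of protein ids.
#' @export
assemble_features <- function(sources, exclude_from_impute = character(),
                              heavy_tailed = character(), impute = TRUE) {
  if (!is.list(sources) || length(sources) == 0) stop("need at least one source")
  tabs <- list()   # per-source: list(ids, cols = named list of numeric, kind, heavy, base)
  for (k in seq_along(sources)) {
    src <- sources[[k]]
    src_name <- names(sources)[k] %||% paste0("source", k)
    if (is.numeric(src) && is.null(dim(src))) {
      if (is.null(names(src))) stop("vector sources must be named by protein id")
      src <- data.frame(protein_id = names(src), v = unname(src),
                        stringsAsFactors = FALSE)
      names(src)[2] <- src_name
    } else if (is.matrix(src)) {
      if (is.null(rownames(src))) stop("matrix sources must have protein-id rownames")
      src <- data.frame(protein_id = rownames(src), as.data.frame(src),
                        stringsAsFactors = FALSE, check.names = FALSE)
    } else if (is.data.frame(src) && !identical(names(src)[1], "protein_id")) {
      if (!is.null(rownames(src)) && !identical(rownames(src), as.character(seq_len(nrow(src))))) {
        src <- cbind(protein_id = rownames(src), src, stringsAsFactors = FALSE)
      } else names(src)[1] <- "protein_id"
    }
    declared_kinds <- attr(sources[[k]], "kinds")
    declared_heavy <- attr(sources[[k]], "heavy_tailed") %||% character()
    ids <- as.character(src$protein_id)
    if (anyDuplicated(ids)) stop("duplicate protein_id within a source")
    cols <- list(); kind <- character(); heavy <- logical(); base <- character()
    for (nm in setdiff(names(src), "protein_id")) {
      x <- src[[nm]]
      declared <- unname(declared_kinds[nm]) %||% NA_character_
      if (is.character(x) || is.factor(x) || identical(declared, "categorical")) {
        oh <- one_hot(x, nm)
        for (j in seq_len(ncol(oh))) {
          cn <- colnames(oh)[j]
          cols[[cn]] <- oh[, j]
          kind[cn] <- "categorical"; heavy[cn] <- FALSE; base[cn] <- nm
        }
      } else {
        cols[[nm]] <- as.numeric(x)
        kind[nm] <- "continuous"
        heavy[nm] <- nm %in% declared_heavy
        base[nm] <- nm
      }
    }
    tabs[[k]] <- list(ids = ids, cols = cols, kind = kind, heavy = heavy, base = base)
  }

  all_cols <- unlist(lapply(tabs, function(t) names(t$cols)))
  if (anyDuplicated(all_cols))
    stop("duplicate feature name across sources: ",
         paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "))

  ids <- unique(unlist(lapply(tabs, `[[`, "ids")))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(all_cols),
              dimnames = list(ids, all_cols))
  kinds <- character(); heavy <- logical(); base <- character()
  for (t in tabs) {
    for (nm in names(t$cols)) m[t$ids, nm] <- t$cols[[nm]]
    kinds <- c(kinds, t$kind); heavy <- c(heavy, t$heavy); base <- c(base, t$base)
  }
  heavy[names(heavy) %in% heavy_tailed | base %in% heavy_tailed] <- TRUE

  imputed_counts <- list()
  if (impute && anyNA(m)) {
    bg <- setdiff(ids, exclude_from_impute)
    if (length(bg) == 0) bg <- ids
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (any(miss)) {
        med <- median(m[bg, j], na.rm = TRUE)
        if (is.na(med)) med <- median(m[, j], na.rm = TRUE)
        m[miss, j] <- med
        imputed_counts[[colnames(m)[j]]] <- sum(miss)
      }
    }
  }

  feature_matrix(m, kinds = kinds, heavy_tailed = heavy, base_feature = base,
                 metadata = list(imputed_counts = imputed_counts,
                                 impute_background_excluded = exclude_from_impute))
}
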