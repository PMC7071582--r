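TARGET_STATUSES <- c("approved", "clinical", "research", "withdrawn")

#' Read a drug-target catalog
#'
#' Four tab-separated columns with header: `target_id`, `drug_id`, `status`
#' (one of approved / clinical / research / withdrawn) and free-text
#' `indication`. This is a deliberately simplified dialect of TTD/DrugBank
#' exports; mapping those databases onto it is a one-off upstream step.
#'
#' @param path path to the catalog TSV.
#' @return a validated data.frame of class `target_catalog`.
#' @export
read_target_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  target_catalog(df)
}

#' Construct/validate a target catalog
#' @param df data.frame with columns `target_id`, `drug_id`, `status`,
#'   `indication`; (target_id, drug_id) pairs must be unique.
#' @return the validated data.frame, classed `target_catalog`.
#' @export
target_catalog <- function(df) {
  need <- c("target_id", "drug_id", "status", "indication")
  if (!all(need %in% names(df))) stop("catalog needs columns: ", paste(need, collapse = ", "))
  df$status <- tolower(as.character(df$status))
  bad <- setdiff(unique(df$status), TARGET_STATUSES)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[, c("target_id", "drug_id")]))
    stop("duplicate (target_id, drug_id) pairs")
  class(df) <- c("target_catalog", "data.frame")
  df
}

#' Partition the universe into positives, clinical holdout and negative pool
#'
#' Positives: targets with at least one *approved* drug whose indication
#' matches the filter. Clinical holdout: targets with at least one matching
#' *clinical-trial* drug and no approved drug of any indication. Negative
#' pool: the universe minus all approved-drug targets (regardless of
#' indication) minus the clinical holdout. The three sets are disjoint by
#' construction; targets absent from the universe are ignored.
#'
#' @param catalog a [target_catalog()].
#' @param universe character vector of protein ids under study.
#' @param indication_pattern case-insensitive regular expression selecting
#'   the indication of interest (e.g. `"onco|cancer|leukemia"`); `""`
#'   matches everything.
#' @return list of class `study_sets` with `positives`, `clinical_holdout`,
#'   `negative_pool`.
#' @export
build_study_sets <- function(catalog, universe, indication_pattern = "") {
  stopifnot(inherits(catalog, "target_catalog"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  matches <- grepl(indication_pattern, catalog$indication, ignore.case = TRUE)
  approved_any <- unique(catalog$target_id[catalog$status == "approved"])
  positives <- unique(catalog$target_id[catalog$status == "approved" & matches])
  clinical <- unique(catalog$target_id[catalog$status == "clinical" & matches])
  positives <- intersect(universe, positives)
  holdout <- setdiff(intersect(universe, clinical), approved_any)
  pool <- setdiff(universe, union(intersect(universe, approved_any), holdout))
  if (length(positives) == 0) stop("no positive (approved, matching-indication) targets in the universe")
  structure(list(positives = positives, clinical_holdout = holdout,
                 negative_pool = pool),
            class = "study_sets")
}

#' @export
print.study_sets <- function(x, ...) {
  cat(sprintf("study_sets: %d positives, %d clinical holdout, %d negative pool\n",
              length(x$positives), length(x$clinical_holdout), length(x$negative_pool)))
  invisible(x)
}
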