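#' Read a GMT gene-set file as an ontology category
#'
#' One set per line: set id, description, then tab-separated member ids.
#'
#' @param path path to a `.gmt` file.
#' @param name category name (default: filename without extension).
#' @return an `ontology_category`: list with `name`, `sets` (named list of
#'   member-id vectors) and `total_count` (number of sets, the maximum rank).
#' @export
read_gmt <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT file")
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- ids
  ontology_category(name %||% sub("\\.gmt$", "", basename(path)), sets)
}

#' Construct an ontology category
#' @param name category name (e.g. `"biological_process"`).
#' @param sets named list: set id -> character vector of member protein ids.
#' @return an object of class `ontology_category`.
#' @export
ontology_category <- function(name, sets) {
  if (length(sets) == 0) stop("a category needs at least one set")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) stop("sets must be uniquely named")
  structure(list(name = name, sets = sets, total_count = length(sets)),
            class = "ontology_category")
}

#' Fisher over-representation p-value of a gene set
#'
#' One-sided Fisher exact test for over-representation of `positives` in
#' `set_members`, i.e. the hypergeometric upper-tail probability
#' P(X >= overlap) with X ~ Hypergeom(N = |universe|, K = |positives|,
#' n = |set|).
#'
#' @param set_members,positives,universe character vectors of protein ids;
#'   both sets must be subsets of the universe.
#' @return p-value in (0, 1].
#' @export
fisher_enrichment <- function(set_members, positives, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  set_members <- unique(set_members)
  positives <- unique(positives)
  if (!all(positives %in% universe)) stop("positives must be a subset of the universe")
  if (!all(set_members %in% universe)) stop("set members must be a subset of the universe")
  N <- length(universe)
  K <- length(positives)
  n <- length(set_members)
  k <- length(intersect(set_members, positives))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank a category's sets by enrichment against the positive set
#'
#' Sets overlapping at least one positive are ranked 1..k by ascending
#' Fisher over-representation p-value (ties broken lexicographically by set
#' id); every zero-overlap set is assigned the maximum rank, equal to the
#' total number of sets in the category.
#'
#' @param cat an [ontology_category()].
#' @param positives positive training protein ids (never include evaluation
#'   holdout targets here: ranks feed the feature matrix).
#' @param universe background protein ids for the enrichment test.
#' @return data.frame (`set_id`, `p_value`, `overlap`, `rank`) of class
#'   `ranked_ontology`, with the category `name` and `total_count` attached
#'   as attributes.
#' @export
rank_ontologies <- function(cat, positives, universe) {
  stopifnot(inherits(cat, "ontology_category"))
  universe <- unique(universe)
  positives <- unique(intersect(positives, universe))
  ids <- names(cat$sets)
  p <- vapply(cat$sets, function(s)
    fisher_enrichment(intersect(s, universe), positives, universe), 0)
  overlap <- vapply(cat$sets, function(s) length(intersect(s, positives)), 0L)
  rank <- rep(cat$total_count, length(ids))
  hit <- overlap > 0
  if (any(hit)) {
    o <- order(p[hit], ids[hit]) # ties by lexicographic set id
    rank[hit][o] <- seq_len(sum(hit))
  }
  out <- data.frame(set_id = ids, p_value = unname(p),
                    overlap = unname(overlap), rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "name") <- cat$name
  attr(out, "total_count") <- cat$total_count
  class(out) <- c("ranked_ontology", "data.frame")
  out
}

#' Ontology rank score of one protein
#'
#' Mean of the three smallest ranks among the sets the protein belongs to,
#' padding with the category's maximum rank (`total_count`) when it belongs
#' to fewer than three sets; a protein in no set scores `total_count`.
#' Lower scores mean stronger membership in positive-enriched sets.
#'
#' @param protein a protein id.
#' @param cat the [ontology_category()] the ranking was computed for.
#' @param ranked the matching [rank_ontologies()] result.
#' @return a scalar score in `[1, total_count]`.
#' @export
score_protein <- function(protein, cat, ranked) {
  ranks <- ranked$rank[vapply(cat$sets[ranked$set_id], function(s) protein %in% s, TRUE)]
  top3 <- c(sort(ranks), rep(cat$total_count, 3))[1:3]
  mean(top3)
}

#' Ontology rank scores for many proteins
#'
#' Vectorized [score_protein()]: one column of rank scores per protein.
#'
#' @param proteins protein ids to score.
#' @param cat an [ontology_category()].
#' @param ranked the matching [rank_ontologies()] result.
#' @return named numeric vector of scores.
#' @export
ontology_scores <- function(proteins, cat, ranked) {
  # invert membership once: protein -> ranks of its sets
  rank_by_set <- setNames(ranked$rank, ranked$set_id)
  member_ranks <- new.env(parent = emptyenv())
  for (sid in names(cat$sets)) {
    r <- rank_by_set[[sid]]
    for (pid in cat$sets[[sid]]) {
      assign(pid, c(get0(pid, envir = member_ranks, inherits = FALSE), r),
             envir = member_ranks)
    }
  }
  out <- vapply(proteins, function(pid) {
    ranks <- get0(pid, envir = member_ranks, inherits = FALSE) %||% numeric()
    mean(c(sort(ranks), rep(cat$total_count, 3))[1:3])
  }, 0)
  names(out) <- proteins
  out
}
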