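#' Read a scored protein interaction edge table
#'
#' Three tab- or space-separated columns: protein a, protein b, score
#' (STRING protein-links dialect). A header row is detected automatically
#' (third field non-numeric).
#'
#' @param path path to the edge file.
#' @return data.frame with columns `protein_a`, `protein_b`, `score`.
#' @export
read_edge_table <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "[\t ]+")[[1]]
  has_header <- length(fields) >= 3 && is.na(suppressWarnings(as.numeric(fields[3])))
  df <- read.table(path, header = has_header, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge table needs 3 columns: protein_a, protein_b, score")
  df <- df[, 1:3]
  names(df) <- c("protein_a", "protein_b", "score")
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  df$score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(df$score) || any(!is.finite(df$score))) stop("edge scores must be finite")
  df
}

dedup_pairs <- function(edges) {
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  # keep max score per unordered pair
  o <- order(key, -edges$score)
  e <- data.frame(protein_a = a[o], protein_b = b[o], score = edges$score[o],
                  stringsAsFactors = FALSE)
  e[!duplicated(key[o]), , drop = FALSE]
}

#' Keep the top-scoring fraction of interactions
#'
#' Deduplicates unordered pairs (keeping the maximum score per pair), then
#' retains the `ceiling(fraction * n)` highest-scored records. Edges tied
#' with the cutoff score are all retained, so the result is independent of
#' input ordering.
#'
#' @param edges edge data.frame (`protein_a`, `protein_b`, `score`).
#' @param fraction fraction of edges to keep, in (0, 1]; the confidence
#'   filter applied before centrality computation (default elsewhere: 0.1,
#'   i.e. the top decile).
#' @return filtered edge data.frame.
#' @export
filter_top_fraction <- function(edges, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (nrow(edges) == 0) stop("empty edge table")
  e <- dedup_pairs(edges)
  k <- ceiling(fraction * nrow(e))
  cutoff <- sort(e$score, decreasing = TRUE)[k]
  out <- e[e$score >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an undirected interaction network from an edge table
#'
#' Self-loops are dropped and reciprocal/duplicate pairs collapsed; the
#' resulting graph is simple, undirected and unweighted (scores are used
#' only for the upstream threshold).
#'
#' @param edges edge data.frame (`protein_a`, `protein_b`, optional `score`).
#' @return an [igraph::graph] object.
#' @export
build_network <- function(edges) {
  el <- cbind(as.character(edges$protein_a), as.character(edges$protein_b))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Five centrality features per protein
#'
#' Computes, on the unweighted simple graph: degree; unnormalized
#' betweenness (pairs counted once); classical closeness per connected
#' component, `(n_comp - 1) / sum(within-component distances)` (isolated
#' nodes get 0); PageRank with damping 0.85; and eigenvector centrality of
#' the largest component scaled to max 1 (0 elsewhere). Proteins in
#' `universe` that are absent from the graph get 0 in every column.
#'
#' @param g an igraph graph from [build_network()].
#' @param universe protein ids the output table must cover (default: the
#'   graph's nodes).
#' @return data.frame with rownames = universe and columns `degree`,
#'   `betweenness`, `closeness`, `pagerank`, `eigen`.
#' @export
compute_centralities <- function(g, universe = NULL) {
  nodes <- igraph::V(g)$name
  universe <- universe %||% nodes
  n <- length(nodes)
  deg <- bet <- clo <- pr <- eig <- setNames(numeric(n), nodes)
  if (n > 0) {
    deg[] <- igraph::degree(g)
    bet[] <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      members <- nodes[comp$membership == ci]
      if (length(members) == 1) { clo[members] <- 0; next }
      d <- igraph::distances(g, v = members, to = members)
      clo[members] <- (length(members) - 1) / rowSums(d)
    }
    pr[] <- igraph::page_rank(g, damping = 0.85)$vector
    giant <- nodes[comp$membership == which.max(comp$csize)]
    if (length(giant) >= 2) {
      sub <- igraph::induced_subgraph(g, giant)
      ev <- igraph::eigen_centrality(sub)$vector # scaled so max = 1
      eig[igraph::V(sub)$name] <- ev
    } else if (length(giant) == 1) {
      eig[giant] <- 1
    }
  }
  out <- as.data.frame(matrix(
    0, nrow = length(universe), ncol = 5,
    dimnames = list(universe, c("degree", "betweenness", "closeness",
                                "pagerank", "eigen"))))
  present <- intersect(universe, nodes)
  out[present, ] <- cbind(deg[present], bet[present], clo[present],
                          pr[present], eig[present])
  out
}
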