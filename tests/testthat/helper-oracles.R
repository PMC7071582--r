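# Independent brute-force oracles. These deliberately avoid the code paths
# (and libraries) used by the implementation they check.

withr_tempdir <- function() {
  d <- tempfile("dts")
  dir.create(d)
  d
}

# quick feature_matrix from a plain matrix
make_fm <- function(m, kinds = "continuous", heavy = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("pr%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  feature_matrix(m, kinds = kinds, heavy_tailed = heavy)
}

# adjacency matrix from an edge data.frame (undirected, simple)
edges_to_adj <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  a <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    u <- edges$protein_a[i]; v <- edges$protein_b[i]
    if (u != v) { a[u, v] <- 1L; a[v, u] <- 1L }
  }
  a
}

# all-pairs shortest-path distances by Floyd-Warshall
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  d[adj == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# number of shortest paths between every pair, by DP over path length
bf_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n, dimnames = dimnames(adj))
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  if (maxd >= 1) {
    for (len in seq_len(maxd)) {
      for (s in seq_len(n)) for (t in seq_len(n)) {
        if (d[s, t] == len) {
          # shortest paths extend via neighbors of t one step closer to s
          pred <- which(adj[, t] == 1L & d[s, ] == len - 1)
          sigma[s, t] <- sum(sigma[s, pred])
        }
      }
    }
  }
  sigma
}

# unnormalized betweenness: sum over unordered pairs {s,t} (v not endpoint)
# of the fraction of s-t shortest paths passing through v
bf_betweenness <- function(edges) {
  adj <- edges_to_adj(edges)
  d <- bf_distances(adj)
  sigma <- bf_path_counts(adj, d)
  n <- nrow(adj)
  b <- setNames(numeric(n), rownames(adj))
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || !is.finite(d[s, t])) next
    if (d[s, v] + d[v, t] == d[s, t])
      b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  b
}

# classical closeness per connected component; isolated nodes 0
bf_closeness <- function(edges) {
  adj <- edges_to_adj(edges)
  d <- bf_distances(adj)
  vapply(seq_len(nrow(adj)), function(v) {
    comp <- which(is.finite(d[v, ]))
    comp <- setdiff(comp, v)
    if (length(comp) == 0) 0 else length(comp) / sum(d[v, comp])
  }, 0) |> setNames(rownames(adj))
}

# hypergeometric upper tail by explicit choose() sum
bf_fisher <- function(N, K, n, k) {
  js <- k:min(n, K)
  js <- js[js >= 0 & (n - js) <= (N - K)]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# AUC by enumerating positive-negative score pairs (ties count 1/2)
bf_auc <- function(pos_scores, neg_scores) {
  cmp <- outer(pos_scores, neg_scores, function(a, b)
    ifelse(a > b, 1, ifelse(a == b, 0.5, 0)))
  mean(cmp)
}

# fixed fixture set of small graphs (<= 8 nodes) as edge data.frames
small_graph_fixtures <- function() {
  ed <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(protein_a = m[, 1], protein_b = m[, 2], stringsAsFactors = FALSE)
  }
  fixtures <- list(
    path4 = ed("a","b", "b","c", "c","d"),
    star6 = ed("c","l1", "c","l2", "c","l3", "c","l4", "c","l5"),
    cycle5 = ed("a","b", "b","c", "c","d", "d","e", "e","a"),
    k4 = ed("a","b", "a","c", "a","d", "b","c", "b","d", "c","d"),
    two_comp = ed("a","b", "b","c", "x","y"),
    barbell = ed("a","b", "b","c", "a","c", "c","d", "d","e", "e","f", "d","f"),
    tree8 = ed("r","a", "r","b", "a","c", "a","d", "b","e", "b","f", "f","g")
  )
  # deterministic random graphs on 6-8 nodes
  seeds <- c(11L, 23L, 37L, 51L, 68L)
  for (s in seeds) {
    set.seed(s)
    n <- sample(6:8, 1)
    nodes <- letters[seq_len(n)]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) keep[1] <- TRUE
    fixtures[[paste0("rand", s)]] <-
      data.frame(protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
                 stringsAsFactors = FALSE)
  }
  fixtures
}

# tiny synthetic scenario for fast end-to-end tests
small_scenario <- function(seed = 42, ...) {
  scenario_config(n_proteins = 120, n_positives = 12, n_clinical = 8,
                  n_features_informative = 3, n_features_noise = 7,
                  n_ontology_sets = 10, n_tissues = 8, edges_per_node = 6,
                  seed = seed, ...)
}

run_config_for <- function(paths, out_dir, n_models = 30, n_trees = 60, seed = 7, ...) {
  run_config(paths = paths[c("features", "feature_meta", "expression",
                             "edges", "ontologies", "catalog")],
             out_dir = out_dir, n_models = n_models, n_trees = n_trees,
             seed = seed, ...)
}
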