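test_that("filter_top_fraction keeps the ceiling, dedups pairs, retains cutoff ties", {
  set.seed(5)
  e <- data.frame(protein_a = paste0("a", 1:20), protein_b = paste0("b", 1:20),
                  score = sample(100:900, 20), stringsAsFactors = FALSE)
  top2 <- filter_top_fraction(e, 0.1)
  expect_equal(nrow(top2), 2L)
  expect_equal(sort(top2$score, decreasing = TRUE),
               sort(e$score, decreasing = TRUE)[1:2])
  expect_equal(nrow(filter_top_fraction(e, 1.0)), 20L)

  # ranks 1-3 share the cutoff score at fraction 0.1 of 10 edges -> keep 3
  e2 <- data.frame(protein_a = paste0("x", 1:10), protein_b = paste0("y", 1:10),
                   score = c(900, 900, 900, sort(runif(7, 100, 800))),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(filter_top_fraction(e2, 0.1)), 3L)
  # result independent of row order
  perm <- e2[sample(1:10), ]
  expect_equal(sort(paste(filter_top_fraction(perm, 0.1)$protein_a)),
               sort(paste(filter_top_fraction(e2, 0.1)$protein_a)))

  # reciprocal duplicates collapse to the max score before the cut
  e3 <- data.frame(protein_a = c("u", "v", "u", "w"),
                   protein_b = c("v", "u", "w", "z"),
                   score = c(500, 800, 300, 100), stringsAsFactors = FALSE)
  out <- filter_top_fraction(e3, 1.0)
  expect_equal(nrow(out), 3L)
  expect_equal(out$score[out$protein_a == "u" & out$protein_b == "v"], 800)

  expect_error(filter_top_fraction(e, 0), "fraction")
  expect_error(filter_top_fraction(e, 1.2), "fraction")
})

test_that("build_network yields a simple undirected graph", {
  e <- data.frame(protein_a = c("a", "b", "a", "c"),
                  protein_b = c("b", "a", "a", "d"), stringsAsFactors = FALSE)
  g <- build_network(e)
  expect_equal(igraph::ecount(g), 2L)        # a-b collapsed, a-a dropped
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))
})

test_that("centralities match printed anchors", {
  path4 <- data.frame(protein_a = c("a", "b", "c"), protein_b = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  cen <- compute_centralities(build_network(path4))
  expect_equal(cen["b", "betweenness"], 2)  # pairs {a,c}, {a,d}
  star <- data.frame(protein_a = rep("c", 5), protein_b = paste0("l", 1:5),
                     stringsAsFactors = FALSE)
  cen_star <- compute_centralities(build_network(star))
  expect_equal(cen_star["c", "closeness"], 1)
  two <- data.frame(protein_a = "a", protein_b = "b", stringsAsFactors = FALSE)
  cen2 <- compute_centralities(build_network(two))
  expect_equal(cen2$pagerank, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("betweenness and closeness equal brute-force oracles on all small fixtures", {
  for (nm in names(small_graph_fixtures())) {
    edges <- small_graph_fixtures()[[nm]]
    cen <- compute_centralities(build_network(edges))
    bf_b <- bf_betweenness(edges)
    bf_c <- bf_closeness(edges)
    expect_equal(cen[names(bf_b), "betweenness"], unname(bf_b),
                 tolerance = 1e-10, label = paste("betweenness", nm),
                 ignore_attr = TRUE)
    expect_equal(cen[names(bf_c), "closeness"], unname(bf_c),
                 tolerance = 1e-10, label = paste("closeness", nm),
                 ignore_attr = TRUE)
  }
})

test_that("centrality invariants: pagerank sum, relabeling, universe fill, degree growth", {
  edges <- small_graph_fixtures()$barbell
  cen <- compute_centralities(build_network(edges), universe = c(letters[1:6], "zz"))
  expect_equal(sum(cen$pagerank), 1, tolerance = 1e-6)
  expect_equal(unname(unlist(cen["zz", ])), rep(0, 5))
  expect_true(all(cen$eigen <= 1) && any(cen$eigen == 1))

  # relabeling invariance
  relab <- edges
  map <- setNames(paste0("node_", seq_along(letters)), letters)
  relab$protein_a <- unname(map[relab$protein_a])
  relab$protein_b <- unname(map[relab$protein_b])
  cen_r <- compute_centralities(build_network(relab))
  orig_names <- rownames(cen[rownames(cen) != "zz", ])
  expect_equal(unname(as.matrix(cen_r[map[orig_names], ])),
               unname(as.matrix(cen[orig_names, ])), tolerance = 1e-9)

  # adding an edge never decreases either endpoint's degree
  more <- rbind(edges, data.frame(protein_a = "a", protein_b = "f"))
  cen_m <- compute_centralities(build_network(more))
  expect_true(all(cen_m[c("a", "f"), "degree"] >= cen[c("a", "f"), "degree"]))
})

test_that("eigenvector centrality is confined to the largest component", {
  edges <- small_graph_fixtures()$two_comp  # a-b-c and x-y
  cen <- compute_centralities(build_network(edges))
  expect_equal(cen[c("x", "y"), "eigen"], c(0, 0), ignore_attr = TRUE)
  expect_equal(max(cen[c("a", "b", "c"), "eigen"]), 1)
})

test_that("edge table reader detects headers and rejects bad scores", {
  dir <- withr_tempdir()
  f1 <- file.path(dir, "h.tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", "a\tb\t900", "b\tc\t150"), f1)
  e1 <- read_edge_table(f1)
  expect_equal(nrow(e1), 2L)
  expect_equal(e1$score, c(900, 150))
  f2 <- file.path(dir, "nh.tsv")
  writeLines(c("a\tb\t900", "b\tc\t150"), f2)
  expect_equal(read_edge_table(f2), e1)
})
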