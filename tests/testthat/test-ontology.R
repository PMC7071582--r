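test_that("fisher_enrichment matches printed anchors", {
  universe <- paste0("p", 1:20)
  positives <- universe[1:5]
  # a 5-member set containing all 5 positives: P(X >= 5) = 1/C(20,5)
  expect_equal(fisher_enrichment(universe[1:5], positives, universe),
               1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap -> p = 1
  expect_equal(fisher_enrichment(universe[6:10], positives, universe), 1)
  # set = universe -> overlap forced -> p = 1
  expect_equal(fisher_enrichment(universe, positives, universe), 1)
  expect_error(fisher_enrichment("a", "a", character()), "empty universe")
})

test_that("fisher_enrichment equals the hypergeometric tail-sum oracle on many tables", {
  for (N in c(5, 12, 19, 30)) {
    universe <- paste0("u", seq_len(N))
    for (K in c(1, floor(N / 3), floor(N / 2))) {
      if (K < 1) next
      positives <- universe[seq_len(K)]
      for (n in c(1, floor(N / 4), floor(N / 2), N)) {
        if (n < 1) next
        for (k in 0:min(n, K)) {
          if (n - k > N - K) next
          set_members <- c(positives[seq_len(k)],
                           setdiff(universe, positives)[seq_len(n - k)])
          expect_equal(fisher_enrichment(set_members, positives, universe),
                       bf_fisher(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  # spot-check against stats::fisher.test one-sided
  ft <- fisher.test(matrix(c(4, 2, 3, 11), 2), alternative = "greater")
  expect_equal(fisher_enrichment(paste0("u", 1:6), paste0("u", c(1:4, 7:9)),
                                 paste0("u", 1:20)),
               ft$p.value, tolerance = 1e-10)
})

test_that("adding a positive to a set never increases its p-value", {
  universe <- paste0("u", 1:25)
  positives <- universe[1:6]
  others <- universe[7:25]
  for (size in c(3, 8, 12)) {
    for (k in 0:(size - 1)) {
      if (k >= 6 || size - k > length(others)) next
      base_set <- c(positives[seq_len(k)], others[seq_len(size - k)])
      grown <- c(positives[seq_len(k + 1)], others[seq_len(size - k - 1)])
      expect_lte(fisher_enrichment(grown, positives, universe),
                 fisher_enrichment(base_set, positives, universe) + 1e-12)
    }
  }
})

test_that("rank_ontologies ranks overlapping sets and applies the max-rank rule", {
  universe <- paste0("p", 1:40)
  positives <- universe[1:6]
  sets <- list(strong = universe[1:6],          # all positives
               medium = c(universe[1:2], universe[20:25]),
               none = universe[30:35],
               weak = c(universe[3], universe[10:18]))
  cat_ <- ontology_category("mf", sets)
  ranked <- rank_ontologies(cat_, positives, universe)
  by_id <- setNames(ranked$rank, ranked$set_id)
  expect_equal(unname(by_id["strong"]), 1)
  expect_equal(unname(by_id["none"]), 4)  # total_count
  expect_setequal(by_id[c("medium", "weak")], c(2, 3))
  expect_true(all(ranked$rank >= 1 & ranked$rank <= cat_$total_count))
  # ordering follows ascending p-value among overlapping sets
  hit <- ranked[ranked$overlap > 0, ]
  expect_equal(order(hit$p_value), order(hit$rank))

  # ties broken lexicographically by set id
  tie_sets <- list(bbb = universe[1:3], aaa = universe[1:3], zzz = universe[30:32])
  tie_ranked <- rank_ontologies(ontology_category("x", tie_sets), positives, universe)
  by_id2 <- setNames(tie_ranked$rank, tie_ranked$set_id)
  expect_equal(unname(by_id2[c("aaa", "bbb", "zzz")]), c(1, 2, 3))
})

test_that("a 114-set category assigns rank 114 to zero-overlap sets", {
  universe <- paste0("p", 1:200)
  positives <- universe[1:10]
  sets <- c(list(hit = universe[1:10]),
            setNames(lapply(1:113, function(i) universe[100 + (i %% 50)]),
                     sprintf("mf_%03d", 1:113)))
  cat_ <- ontology_category("molecular_function", sets)
  expect_equal(cat_$total_count, 114)
  ranked <- rank_ontologies(cat_, positives, universe)
  expect_equal(ranked$rank[ranked$set_id == "hit"], 1)
  expect_true(all(ranked$rank[ranked$overlap == 0] == 114))
})

test_that("score_protein averages the three best ranks with max-rank padding", {
  universe <- paste0("p", 1:60)
  positives <- universe[1:5]
  # 50-set category engineered so specific sets hold specific ranks
  sets <- setNames(lapply(1:50, function(i) {
    if (i <= 10) c(positives[seq_len(max(1, 11 - i))], universe[20 + i])
    else universe[40 + (i %% 10)]
  }), sprintf("s%02d", 1:50))
  cat_ <- ontology_category("bp", sets)
  ranked <- rank_ontologies(cat_, positives, universe)

  # oracle: recompute the score by hand for several proteins
  rank_of <- setNames(ranked$rank, ranked$set_id)
  for (pid in c(universe[1], universe[21], universe[45], "p60")) {
    in_sets <- names(Filter(function(s) pid %in% s, sets))
    expected <- mean(c(sort(rank_of[in_sets]), rep(50, 3))[1:3])
    expect_equal(score_protein(pid, cat_, ranked), unname(expected))
  }
  # vectorized scoring agrees with the scalar one
  scores <- ontology_scores(universe, cat_, ranked)
  expect_equal(unname(scores["p21"]), score_protein("p21", cat_, ranked))
  expect_true(all(scores >= 1 & scores <= 50))
  # protein in no set scores total_count
  expect_equal(unname(scores["p60"]), 50)

  # explicit padding anchors
  mini <- ontology_category("m", list(a = "x", b = c("x", "y"), c1 = "q",
                                      d = "q", e = "q", f = "q", g = "q",
                                      h = "q", i = "q", j = "q"))
  r2 <- rank_ontologies(mini, positives = "x", universe = c("x", "y", "q", "z"))
  expect_equal(score_protein("y", mini, r2),
               (r2$rank[r2$set_id == "b"] + 10 + 10) / 3)
})

test_that("GMT round trip", {
  dir <- withr_tempdir()
  path <- file.path(dir, "bp.gmt")
  writeLines(c("set1\tdesc one\tp1\tp2\tp3", "set2\tdesc two\tp2\tp4"), path)
  cat_ <- read_gmt(path)
  expect_equal(cat_$name, "bp")
  expect_equal(cat_$total_count, 2)
  expect_setequal(cat_$sets$set2, c("p2", "p4"))
})
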