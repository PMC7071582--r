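test_that("tissue entropy matches the closed form and its printed anchors", {
  m <- rbind(single = c(0, 7, 0, 0),
             uniform = c(5, 5, 5, 5),
             skew = c(3, 1, 0, 0))
  colnames(m) <- paste0("t", 1:4)
  e <- tissue_entropy(expression_matrix(m))
  expect_equal(unname(e["single"]), 0)
  expect_equal(unname(e["uniform"]), 2)
  # two-tissue (3, 1) profile, independent evaluation of the formula
  e2 <- tissue_entropy(expression_matrix(
    matrix(c(3, 1), 1, dimnames = list("g", c("a", "b")))))
  expect_equal(unname(e2), -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(unname(e2), 0.8113, tolerance = 1e-4)
})

test_that("entropy handles zero totals, bounds and scale invariance", {
  set.seed(11)
  n_tissues <- 7
  m <- matrix(rgamma(40 * n_tissues, 1, 1), nrow = 40)
  m[m < 0.4] <- 0               # sparsity, exercises the 0*log(0) convention
  m[1, ] <- 0                   # silent gene
  rownames(m) <- paste0("g", 1:40); colnames(m) <- paste0("t", 1:n_tissues)
  e <- tissue_entropy(expression_matrix(m))
  expect_true(is.na(e["g1"]))
  ok <- !is.na(e)
  expect_true(all(e[ok] >= 0 & e[ok] <= log2(n_tissues)))
  # equality at the bounds iff single-tissue / uniform
  nnz <- rowSums(m > 0)
  expect_equal(unname(e[ok] == 0), unname(nnz[ok] == 1))
  # invariant to positive rescaling
  e_scaled <- tissue_entropy(expression_matrix(m * 37.5))
  expect_equal(e, e_scaled, tolerance = 1e-12)
  # oracle: entropy of the normalized profile
  g <- m[5, ]
  p <- g[g > 0] / sum(g)
  expect_equal(unname(e["g5"]), -sum(p * log2(p)), tolerance = 1e-12)
  expect_error(tissue_entropy(expression_matrix(m[, 1, drop = FALSE])), "2 tissues")
})

test_that("average_entropy averages over available sources only", {
  a <- c(g1 = 1.5, g2 = 0.8, g3 = NA)
  b <- c(g1 = 1.0, g4 = 2.0)
  expect_equal(average_entropy(list(a))[["g1"]], 1.5)
  avg <- average_entropy(list(a, b))
  expect_equal(avg[["g1"]], 1.25)
  expect_equal(avg[["g2"]], 0.8)  # missing in source b
  expect_equal(avg[["g4"]], 2.0)
  expect_true(is.na(avg[["g3"]]))  # missing everywhere
  expect_error(average_entropy(list()), "at least one")
})

test_that("log_transform applies log1p to flagged columns only", {
  m <- cbind(net = c(0, exp(1) - 1, 10), other = c(42, -3, 7))
  fm <- make_fm(m, heavy = c(TRUE, FALSE))
  out <- log_transform(fm)
  expect_equal(unname(out$values[, "net"]), c(0, 1, log1p(10)))
  expect_equal(unname(out$values[, "other"]), c(42, -3, 7))
  fm_bad <- make_fm(cbind(net = c(-1, 2, 3)), heavy = TRUE)
  expect_error(log_transform(fm_bad), "negative")
})

test_that("min_max_scale maps to [0,1], zeros constants, is idempotent and rank-preserving", {
  m <- cbind(a = c(5, 10, 15), b = c(7, 7, 7), c = rnorm(3))
  out <- min_max_scale(make_fm(m))
  expect_equal(unname(out$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out$values[, "b"]), c(0, 0, 0))
  expect_true(all(out$values >= 0 & out$values <= 1))
  # idempotent on non-constant scaled columns
  out2 <- min_max_scale(out)
  expect_equal(out2$values[, c("a", "c")], out$values[, c("a", "c")])
  # log then scale preserves within-column order
  set.seed(3)
  x <- rgamma(20, 0.5, 0.1)
  fm <- make_fm(cbind(net = x), heavy = TRUE)
  scaled <- min_max_scale(log_transform(fm))
  expect_equal(order(scaled$values[, 1]), order(x))
  # all-missing column dropped with a warning
  fm_na <- make_fm(cbind(a = c(1, 2, 3), bad = c(NA_real_, NA, NA)))
  expect_warning(dropped <- min_max_scale(fm_na), "bad")
  expect_equal(feature_names(dropped), "a")
})

test_that("assemble_features joins, one-hot encodes and imputes", {
  s1 <- data.frame(protein_id = c("p1", "p2", "p3"), mw = c(10, 20, 30),
                   stringsAsFactors = FALSE)
  s2 <- data.frame(protein_id = c("p1", "p2", "p3"), loc = c("mem", "nuc", "cyt"),
                   stringsAsFactors = FALSE)
  fm <- assemble_features(list(a = s1, b = s2))
  expect_equal(dim(fm$values), c(3L, 4L)) # mw + 3 indicator columns
  expect_setequal(feature_names(fm), c("mw", "loc.mem", "loc.nuc", "loc.cyt"))
  expect_equal(unname(fm$kinds[c("mw", "loc.mem")]), c("continuous", "categorical"))
  expect_equal(unname(fm$base_feature["loc.nuc"]), "loc")
  expect_equal(sum(fm$values["p2", c("loc.mem", "loc.nuc", "loc.cyt")]), 1)

  # disjoint single-column sources over the same proteins -> 3x2
  v1 <- c(p1 = 1, p2 = 2, p3 = 3)
  v2 <- c(p1 = 9, p2 = 8, p3 = 7)
  fm2 <- assemble_features(list(x = v1, y = v2))
  expect_equal(dim(fm2$values), c(3L, 2L))

  # outer join + median imputation over non-excluded proteins
  v3 <- c(p1 = 5, p2 = 6)          # p3, p4 missing here
  v4 <- c(p1 = 1, p2 = 2, p3 = 3, p4 = 10)
  fm3 <- assemble_features(list(u = v3, w = v4), exclude_from_impute = "p1")
  expect_equal(unname(fm3$values["p3", "u"]), 6) # median of {p2: 6} only
  expect_equal(fm3$metadata$imputed_counts$u, 2L)

  expect_error(assemble_features(list(x = unname(v1))), "named")
  expect_error(assemble_features(list(x = v1, x2 = data.frame(protein_id = "p1", x = 1))),
               "duplicate feature name")
})

test_that("feature table reader round-trips kinds and heavy-tail flags", {
  dir <- withr_tempdir()
  tsv <- file.path(dir, "f.tsv")
  yml <- file.path(dir, "f.yaml")
  writeLines(c("protein_id\tmw\tess", "p1\t10\t1", "p2\t20\t0"), tsv)
  yaml::write_yaml(list(feature_kinds = list(ess = "categorical"),
                        heavy_tailed = list("mw")), yml)
  ft <- read_feature_table(tsv, yml)
  fm <- assemble_features(list(ft))
  expect_true(fm$heavy_tailed[["mw"]])
  expect_equal(unname(fm$kinds[c("ess.0", "ess.1")]), rep("categorical", 2))
})
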