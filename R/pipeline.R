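#' Full-workflow run configuration
#'
#' @param paths named list of input paths: `features`, optional
#'   `feature_meta` (YAML sidecar), `expression` (character vector, one TSV
#'   per source), `edges`, `ontologies` (named character vector of GMT
#'   paths; names become category names), `catalog`.
#' @param out_dir output directory.
#' @param edge_fraction top fraction of scored interactions kept before
#'   centrality computation (default 0.1, the top decile).
#' @param indication_pattern case-insensitive regex matched against catalog
#'   indications to define the positive/holdout sets.
#' @param heavy_tailed feature names flagged for the `log(1+x)` transform;
#'   the defaults are the unbounded network centralities (closeness and
#'   eigenvector centrality are already bounded).
#' @param n_models,n_trees,mtry,seed ensemble settings, see
#'   [ensemble_config()].
#' @param tune_mtry tune mtry by out-of-bag error on the first replicate's
#'   training set before fitting the ensemble?
#' @return list of class `run_config`.
#' @export
run_config <- function(paths, out_dir, edge_fraction = 0.1,
                       indication_pattern = "onco|cancer|leukemi|lymphoma|tumor",
                       heavy_tailed = c("degree", "betweenness", "pagerank"),
                       n_models = 10000, n_trees = 1000, mtry = "auto",
                       seed = 1, tune_mtry = FALSE) {
  if (edge_fraction <= 0 || edge_fraction > 1) stop("edge_fraction must be in (0, 1]")
  structure(list(paths = paths, out_dir = out_dir,
                 edge_fraction = edge_fraction,
                 indication_pattern = indication_pattern,
                 heavy_tailed = heavy_tailed,
                 n_models = n_models, n_trees = n_trees, mtry = mtry,
                 seed = seed, tune_mtry = tune_mtry),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `paths:` is a map
#' of the five inputs (`expression` and `ontologies` may be lists).
#'
#' @param path YAML file.
#' @param overrides named list overriding fields after parsing (CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y$paths$expression <- unlist(y$paths$expression)
  y$paths$ontologies <- unlist(y$paths$ontologies)
  for (nm in names(overrides)) y[[nm]] <- overrides[[nm]]
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the complete druggability-scoring workflow
#'
#' Executes feature assembly, network centralities, ontology rank scoring,
#' target-set construction, ensemble training and holdout evaluation, then
#' writes `scores.tsv`, `importance.tsv`, `roc_points.tsv`,
#' `evaluation.json`, `feature_tests.tsv` and `manifest.json` (input
#' checksums, config, seed derivation) under `config$out_dir`. Nothing is
#' written if any stage fails.
#'
#' @param config a [run_config()] or path to its YAML representation.
#' @return (invisibly) list with `result` (the `druggability_result`),
#'   `evaluation`, `sets`, `fm` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  for (f in unlist(p[c("features", "expression", "edges", "ontologies", "catalog")]))
    if (!file.exists(f)) stop(sprintf("[stage inputs] missing input file: %s", f), call. = FALSE)

  ft <- stage("features", read_feature_table(p$features, p$feature_meta))
  universe <- as.character(ft$protein_id)

  entropy <- stage("entropy", {
    ents <- lapply(p$expression, function(path) tissue_entropy(read_expression(path)))
    average_entropy(ents)
  })

  centr <- stage("network", {
    edges <- read_edge_table(p$edges)
    kept <- filter_top_fraction(edges, config$edge_fraction)
    compute_centralities(build_network(kept), universe)
  })

  sets <- stage("targets", {
    catalog <- read_target_catalog(p$catalog)
    build_study_sets(catalog, universe, config$indication_pattern)
  })

  onto <- stage("ontology", {
    gmts <- p$ontologies
    if (is.null(names(gmts)) || any(!nzchar(names(gmts))))
      names(gmts) <- sub("\\.gmt$", "", basename(gmts))
    cols <- lapply(names(gmts), function(nm) {
      cat_ <- read_gmt(gmts[[nm]], name = nm)
      ranked <- rank_ontologies(cat_, sets$positives, universe)
      ontology_scores(universe, cat_, ranked)
    })
    names(cols) <- paste0("onto_", names(gmts))
    cols
  })

  fm <- stage("assemble", {
    sources <- c(list(annotations = ft, tissue_entropy = entropy,
                      centralities = as.matrix(centr)), onto)
    fm <- assemble_features(sources, exclude_from_impute = sets$positives,
                            heavy_tailed = config$heavy_tailed)
    min_max_scale(log_transform(fm))
  })

  cfg <- ensemble_config(n_models = config$n_models, n_trees = config$n_trees,
                         mtry = config$mtry, seed = config$seed)
  if (isTRUE(config$tune_mtry)) {
    cfg$mtry <- stage("tune_mtry", {
      neg <- sample_negatives(sets$negative_pool, length(sets$positives),
                              derive_seed(cfg$seed, 0L))
      tune_mtry(fm, sets$positives, neg, cfg)
    })
  }

  result <- stage("ensemble", fit_predict_ensemble(fm, sets, cfg))

  evaluation <- stage("evaluate", {
    ev <- if (length(sets$clinical_holdout) > 0)
      evaluate_holdout(result$scores, sets) else NULL
    tests <- feature_tests(fm, sets$positives, sets$negative_pool)
    list(holdout = ev, feature_tests = tests)
  })

  out <- stage("write", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      scores = file.path(config$out_dir, "scores.tsv"),
      importance = file.path(config$out_dir, "importance.tsv"),
      feature_tests = file.path(config$out_dir, "feature_tests.tsv"),
      manifest = file.path(config$out_dir, "manifest.json"))
    write_tsv(data.frame(protein_id = names(result$scores),
                         score = unname(result$scores)), paths$scores)
    write_tsv(data.frame(feature = names(result$importance),
                         mean_gini_decrease = unname(result$importance)),
              paths$importance)
    write_tsv(evaluation$feature_tests, paths$feature_tests)
    ev <- evaluation$holdout
    if (!is.null(ev)) {
      paths$roc_points <- file.path(config$out_dir, "roc_points.tsv")
      paths$evaluation <- file.path(config$out_dir, "evaluation.json")
      write_tsv(ev$roc_points, paths$roc_points)
      jsonlite::write_json(
        list(auc = ev$auc, sensitivity = ev$sensitivity,
             specificity = ev$specificity, accuracy = ev$accuracy,
             threshold = ev$threshold, n_positive = ev$n_positive,
             n_negative = ev$n_negative),
        paths$evaluation, auto_unbox = TRUE, digits = NA)
    }
    inputs <- unlist(p)
    manifest <- list(
      package_version = as.character(utils::packageVersion("dtscore")),
      config = unclass(config)[setdiff(names(unclass(config)), "paths")],
      inputs = as.list(setNames(unname(tools::md5sum(inputs)), inputs)),
      seed_derivation = "replicate m uses derive_seed(seed, m); Lehmer mixing mod 2^31-1",
      replicate_seeds_head = result$replicate_seeds[seq_len(min(10, length(result$replicate_seeds)))],
      study_sets = list(n_positives = length(sets$positives),
                        n_clinical_holdout = length(sets$clinical_holdout),
                        n_negative_pool = length(sets$negative_pool)))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
    paths
  })

  invisible(list(result = result, evaluation = evaluation, sets = sets,
                 fm = fm, paths = out))
}
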