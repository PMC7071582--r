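#' Synthetic scenario configuration
#'
#' Describes a synthetic world with known ground truth that emulates the
#' statistical structure separating drug targets from other proteins:
#' shifted feature distributions, hub-biased network placement, enrichment
#' in "cancer-like" ontology sets and elevated tissue specificity for
#' positives (and for the clinical holdout, which by construction resembles
#' the positives - that resemblance is what makes holdout AUC a recovery
#' metric).
#'
#' @param n_proteins number of proteins in the universe.
#' @param n_positives approved-target positives.
#' @param n_clinical clinical-holdout targets.
#' @param n_features_informative informative continuous features, shifted
#'   by `effect_size` (a standardized mean shift, i.e. Cohen's d) for
#'   positives/clinical.
#' @param n_features_noise other features; 3 of them are categorical (one
#'   with level frequencies shifted proportionally to `effect_size`, two
#'   pure noise), the rest iid standard normal.
#' @param effect_size standardized mean shift of informative features.
#' @param network_hub_bias extra preferential-attachment propensity of
#'   positives/clinical: their attachment weight is multiplied by
#'   `1 + network_hub_bias`.
#' @param n_ontology_sets gene sets per ontology category (three categories
#'   are emitted); half of each category's sets are "cancer-like".
#' @param ontology_enrichment odds multiplier for positive/clinical
#'   membership in cancer-like sets.
#' @param n_tissues tissues in each expression source (two sources are
#'   emitted, sharing the specificity assignment but with independent
#'   noise).
#' @param tissue_specific_fraction fraction of background genes that are
#'   tissue-specific (one dominant tissue).
#' @param tissue_specificity_bias multiplier on that fraction for
#'   positives/clinical (1 = no bias; part of the "all effects off" null).
#' @param n_offtarget_approved pool proteins given an approved
#'   non-oncology drug (excluded from the negative pool by construction).
#' @param edges_per_node attachment edges added per protein in the
#'   preferential-attachment growth.
#' @param seed integer seed; identical configs produce byte-identical files.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_proteins = 500, n_positives = 30, n_clinical = 20,
                            n_features_informative = 5, n_features_noise = 25,
                            effect_size = 1.0, network_hub_bias = 2.0,
                            n_ontology_sets = 40, ontology_enrichment = 5.0,
                            n_tissues = 20, tissue_specific_fraction = 0.3,
                            tissue_specificity_bias = 3,
                            n_offtarget_approved = 5, edges_per_node = 20,
                            seed = 1) {
  cfg <- list(n_proteins = n_proteins, n_positives = n_positives,
              n_clinical = n_clinical,
              n_features_informative = n_features_informative,
              n_features_noise = n_features_noise, effect_size = effect_size,
              network_hub_bias = network_hub_bias,
              n_ontology_sets = n_ontology_sets,
              ontology_enrichment = ontology_enrichment, n_tissues = n_tissues,
              tissue_specific_fraction = tissue_specific_fraction,
              tissue_specificity_bias = tissue_specificity_bias,
              n_offtarget_approved = n_offtarget_approved,
              edges_per_node = edges_per_node, seed = as.integer(seed))
  if (cfg$n_positives + cfg$n_clinical >= cfg$n_proteins)
    stop("n_positives + n_clinical must be smaller than n_proteins")
  if (cfg$effect_size < 0 || cfg$network_hub_bias < 0 || cfg$ontology_enrichment <= 0)
    stop("effect sizes must be non-negative (enrichment positive)")
  if (cfg$n_features_noise < 3) stop("need at least 3 noise features")
  class(cfg) <- "scenario_config"
  cfg
}

#' The all-effects-off null scenario
#'
#' Same sizes as [scenario_config()] defaults but no feature shift, no hub
#' bias, no ontology enrichment and no tissue-specificity bias; end-to-end
#' holdout AUC on this world should hover around 0.5.
#'
#' @param ... overrides passed on to [scenario_config()].
#' @return a `scenario_config`.
#' @export
null_scenario_config <- function(...) {
  scenario_config(effect_size = 0, network_hub_bias = 0,
                  ontology_enrichment = 1, tissue_specificity_bias = 1, ...)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate the five pipeline inputs plus ground-truth labels
#'
#' Emits, under `out_dir`: `features.tsv` + `features_meta.yaml`,
#' `expression_a.tsv` and `expression_b.tsv`, `edges.tsv`, three GMT files
#' (`biological_process.gmt`, `molecular_function.gmt`,
#' `signaling_pathway.gmt`), `catalog.tsv` and `truth_labels.tsv`. Files
#' are byte-identical for identical configurations.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a named list of the emitted paths, shaped like the
#'   `paths` entry of [run_config()].
#' @export
generate_scenario <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    roles <- sample(ids, cfg$n_positives + cfg$n_clinical)
    positives <- roles[seq_len(cfg$n_positives)]
    clinical <- roles[cfg$n_positives + seq_len(cfg$n_clinical)]
    shifted <- ids %in% c(positives, clinical) # clinical resemble positives
    background <- setdiff(ids, c(positives, clinical))

    ## (a) feature table ---------------------------------------------------
    feat <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
    for (j in seq_len(cfg$n_features_informative))
      feat[[sprintf("sig_cont_%02d", j)]] <-
        rnorm(n, mean = ifelse(shifted, cfg$effect_size, 0), sd = 1)
    n_cont_noise <- cfg$n_features_noise - 3
    for (j in seq_len(n_cont_noise))
      feat[[sprintf("noise_cont_%02d", j)]] <- rnorm(n)
    # categorical with level frequencies shifted in proportion to the effect
    base_p <- c(A = 0.5, B = 0.3, C = 0.2)
    w <- base_p * exp(cfg$effect_size * c(-1, 0, 1))
    shift_p <- w / sum(w)
    feat$shifted_cat <- ifelse(shifted,
                               sample(names(base_p), n, TRUE, prob = shift_p),
                               sample(names(base_p), n, TRUE, prob = base_p))
    feat$noise_cat_1 <- sample(c("lvl1", "lvl2", "lvl3"), n, TRUE,
                               prob = c(0.4, 0.35, 0.25))
    feat$noise_cat_2 <- sample(c("yes", "no"), n, TRUE, prob = c(0.3, 0.7))
    write_tsv(feat, file.path(out_dir, "features.tsv"))
    yaml::write_yaml(
      list(feature_kinds = as.list(setNames(
             c("categorical", "categorical", "categorical"),
             c("shifted_cat", "noise_cat_1", "noise_cat_2"))),
           heavy_tailed = list()),
      file.path(out_dir, "features_meta.yaml"))

    ## (b) expression, two sources -----------------------------------------
    ts_prob <- ifelse(shifted,
                      pmin(1, cfg$tissue_specific_fraction * cfg$tissue_specificity_bias),
                      cfg$tissue_specific_fraction)
    specific <- runif(n) < ts_prob
    dominant <- sample.int(cfg$n_tissues, n, replace = TRUE)
    tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
    expr_source <- function() {
      m <- matrix(rgamma(n * cfg$n_tissues, shape = 5, rate = 1), nrow = n)
      for (i in which(specific)) {
        m[i, ] <- rgamma(cfg$n_tissues, shape = 0.3, rate = 1)
        m[i, dominant[i]] <- rgamma(1, shape = 20, rate = 0.2)
      }
      round(m, 3)
    }
    ea <- expr_source()
    eb <- expr_source()
    # two silent genes in source A only: exercises the missing-entropy path
    ea[match(background[1:2], ids), ] <- 0
    for (nm in list(c("expression_a.tsv", "ea"), c("expression_b.tsv", "eb"))) {
      m <- if (nm[2] == "ea") ea else eb
      df <- data.frame(gene_id = ids, m, stringsAsFactors = FALSE)
      names(df) <- c("gene_id", tissues)
      write_tsv(df, file.path(out_dir, nm[1]))
    }

    ## (c) interaction edges: preferential attachment with hub bias --------
    m_att <- cfg$edges_per_node
    ord <- sample(ids)
    hubw <- ifelse(ord %in% c(positives, clinical), 1 + cfg$network_hub_bias, 1)
    deg <- setNames(numeric(n), ord)
    m0 <- min(m_att + 1, n)
    ea_list <- vector("list", n)
    ring <- cbind(ord[seq_len(m0)], ord[c(seq_len(m0)[-1], 1)])
    deg[ring[, 1]] <- deg[ring[, 1]] + 1
    deg[ring[, 2]] <- deg[ring[, 2]] + 1
    ea_list[[1]] <- ring
    if (n > m0) {
      for (i in (m0 + 1):n) {
        existing <- seq_len(i - 1)
        k <- min(m_att, i - 1)
        wts <- (deg[existing] + 1) * hubw[existing]
        pick <- sample(existing, k, prob = wts)
        ea_list[[i]] <- cbind(ord[i], ord[pick])
        deg[ord[i]] <- deg[ord[i]] + k
        deg[ord[pick]] <- deg[ord[pick]] + 1
      }
    }
    edges <- do.call(rbind, ea_list[!vapply(ea_list, is.null, TRUE)])
    scores <- round(runif(nrow(edges), 150, 999))
    # sprinkle reciprocal duplicates with a lower score: exercises dedup
    dup <- seq_len(nrow(edges)) %% 97 == 0
    edf <- data.frame(protein1 = c(edges[, 1], edges[dup, 2]),
                      protein2 = c(edges[, 2], edges[dup, 1]),
                      combined_score = c(scores, pmax(150, scores[dup] - 5)),
                      stringsAsFactors = FALSE)
    write_tsv(edf, file.path(out_dir, "edges.tsv"))

    ## (d) ontology GMT files ----------------------------------------------
    cats <- c("biological_process", "molecular_function", "signaling_pathway")
    gmt_paths <- character(0)
    for (cat_name in cats) {
      lines <- character(cfg$n_ontology_sets)
      for (s in seq_len(cfg$n_ontology_sets)) {
        cancer_like <- s <= cfg$n_ontology_sets / 2
        q <- runif(1, 0.02, 0.08)
        p_mem <- ifelse(shifted & cancer_like,
                        pmin(0.9, q * cfg$ontology_enrichment), q)
        members <- ids[runif(n) < p_mem]
        set_id <- sprintf("%s_%s_%02d", substr(cat_name, 1, 2),
                          if (cancer_like) "cancerlike" else "set", s)
        lines[s] <- paste(c(set_id, paste0("synthetic ", cat_name, " set"),
                            members), collapse = "\t")
      }
      path <- file.path(out_dir, paste0(cat_name, ".gmt"))
      writeLines(lines, path)
      gmt_paths[cat_name] <- path
    }

    ## (e) drug-target catalog ---------------------------------------------
    rows <- list()
    for (i in seq_along(positives)) {
      rows[[length(rows) + 1]] <- data.frame(
        target_id = positives[i], drug_id = sprintf("D_appr_%03d", i),
        status = "approved", indication = "oncology")
      if (i %% 3 == 0) # some approved targets also carry a clinical drug
        rows[[length(rows) + 1]] <- data.frame(
          target_id = positives[i], drug_id = sprintf("D_clin_x%03d", i),
          status = "clinical", indication = "oncology")
    }
    for (i in seq_along(clinical))
      rows[[length(rows) + 1]] <- data.frame(
        target_id = clinical[i], drug_id = sprintf("D_clin_%03d", i),
        status = "clinical", indication = "oncology")
    offt <- background[2 + seq_len(cfg$n_offtarget_approved)]
    for (i in seq_along(offt))
      rows[[length(rows) + 1]] <- data.frame(
        target_id = offt[i], drug_id = sprintf("D_card_%03d", i),
        status = "approved", indication = "hypertension")
    extra <- background[2 + cfg$n_offtarget_approved + 1:5]
    rows[[length(rows) + 1]] <- data.frame(
      target_id = extra[1:3], drug_id = sprintf("D_res_%03d", 1:3),
      status = "research", indication = "oncology")
    rows[[length(rows) + 1]] <- data.frame(
      target_id = extra[4:5], drug_id = sprintf("D_wd_%03d", 1:2),
      status = "withdrawn", indication = "oncology")
    catalog <- do.call(rbind, rows)
    write_tsv(catalog, file.path(out_dir, "catalog.tsv"))

    ## ground truth ---------------------------------------------------------
    truth <- data.frame(
      protein_id = ids,
      label = ifelse(ids %in% positives, "positive",
                     ifelse(ids %in% clinical, "clinical", "background")),
      tissue_specific = as.integer(specific),
      stringsAsFactors = FALSE)
    write_tsv(truth, file.path(out_dir, "truth_labels.tsv"))

    invisible(list(
      features = file.path(out_dir, "features.tsv"),
      feature_meta = file.path(out_dir, "features_meta.yaml"),
      expression = c(file.path(out_dir, "expression_a.tsv"),
                     file.path(out_dir, "expression_b.tsv")),
      edges = file.path(out_dir, "edges.tsv"),
      ontologies = gmt_paths,
      catalog = file.path(out_dir, "catalog.tsv"),
      truth = file.path(out_dir, "truth_labels.tsv")))
  })
}
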