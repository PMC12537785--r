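#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates simulate -> preprocess -> balanced cross-validated
#' classification (network and random-forest arms) -> saliency analysis ->
#' titer regression -> exploratory summaries, from a single master seed,
#' and writes every report as a plain-text artifact. Running twice with
#' the same master seed produces byte-identical output files.
#'
#' All sub-seeds (cohort assignment, signature placement, undersampling,
#' fold assignment, weight initialisation, batch shuffling) are derived
#' from `seed` by fixed offsets and logged in `run_log.json` together with
#' any instances discarded by undersampling.
#'
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param design optional [cohort_design()]; default is the scaled-down
#'   cohort (24 animals, 8 groups).
#' @param spec optional [signature_spec()]; default as documented there.
#' @param k folds for classification CV (default 3 for the scaled-down
#'   cohort).
#' @param epochs,hidden network training size for the classification arm.
#' @param ntree random-forest size.
#' @param titer_k,titer_epochs titer-regression CV settings.
#' @param n_top size of the saliency top/bottom gene sets.
#' @param instance_mode passed to [build_instances()].
#' @return (invisibly) a list with the in-memory results: `study`, `prep`,
#'   `cv_mlp`, `cv_forest`, `saliency`, `ranking`, `correlations`,
#'   `titer_cv`, `pca`.
#' @export
run_all <- function(out_dir, seed = 1L,
                    design = NULL, spec = NULL, k = 3L,
                    epochs = 200L, hidden = 100L, ntree = 500L,
                    titer_k = 3L, titer_epochs = 1000L, n_top = 100L,
                    instance_mode = "per_sample") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  seeds <- list(cohort = seed, signature = seed + 1L, titer = seed + 2L,
                folds = seed + 3L, mlp = seed + 4L, forest = seed + 5L,
                titer_cv = seed + 6L)
  if (is.null(design)) design <- cohort_design(n_animals = 24L,
                                               seed = seeds$cohort)
  if (is.null(spec)) spec <- signature_spec(seed = seeds$signature)

  study <- simulate_study(design, spec, titer_seed = seeds$titer)
  write_study(study, file.path(out_dir, "inputs"))

  prep <- preprocess_expression(study$expr, study$meta,
                                study$truth$ortholog_map, study$truth$panel)

  inst <- build_instances(prep$fold_change, study$meta, mode = instance_mode)
  folds <- make_balanced_folds(inst$labels, k = k, seed = seeds$folds)
  cv_mlp <- cross_validate_classifier(inst$x, inst$labels, folds,
                                      mlp_factory(hidden = hidden,
                                                  epochs = epochs,
                                                  seed = seeds$mlp))
  cv_forest <- cross_validate_classifier(inst$x, inst$labels, folds,
                                         forest_factory(ntree = ntree,
                                                        seed = seeds$forest))

  sal <- saliency_across_folds(cv_mlp$models)
  ranking <- rank_genes(normalize01(sal$mean), n = n_top)
  correlations <- intergroup_correlation(prep$fold_change, study$meta, ranking)

  titer_cv <- cross_validate_titer(prep$fold_change, study$meta, study$titers,
                                   k = titer_k, seed = seeds$titer_cv,
                                   epochs = titer_epochs)

  pca <- run_pca(prep$fold_change, n_components = min(5L,
                                                      min(dim(prep$fold_change))))

  # ---- reports -------------------------------------------------------
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = TRUE, quote = FALSE)
  wcsv(cv_mlp$confusion, "confusion_network.csv")
  wcsv(cv_forest$confusion, "confusion_forest.csv")
  utils::write.csv(correlations, file.path(out_dir, "correlation_report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(titer_cv$evaluation$by_group,
                   file.path(out_dir, "titer_group_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(pca$scores),
                              pca$scores[, 1:2, drop = FALSE]),
                   file.path(out_dir, "pca_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  write_expression_tsv(sal$mean, file.path(out_dir, "saliency_mean.tsv"))
  writeLines(ranking$top_set, file.path(out_dir, "genes_top.txt"))
  writeLines(ranking$bottom_set, file.path(out_dir, "genes_bottom.txt"))

  jsonlite::write_json(
    list(seed = seed, seeds = seeds,
         discarded_by_undersampling = folds$discarded,
         class_size = folds$class_size,
         stage_counts = lapply(prep$reports, function(r)
           r[c("stage", "n_in", "n_retained", "n_removed")]),
         network_accuracy = cv_mlp$metrics$accuracy,
         forest_accuracy = cv_forest$metrics$accuracy,
         per_fold_accuracy = cv_mlp$per_fold_accuracy,
         titer_rmse = titer_cv$evaluation$rmse,
         titer_pearson_r = titer_cv$evaluation$pearson_r,
         pca_explained = pca$explained),
    file.path(out_dir, "run_log.json"), digits = NA, auto_unbox = TRUE)

  invisible(list(study = study, prep = prep, cv_mlp = cv_mlp,
                 cv_forest = cv_forest, saliency = sal, ranking = ranking,
                 correlations = correlations, titer_cv = titer_cv, pca = pca))
}
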