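# Shared fixtures, built once per test run.
#
# `small_study()`: a compact cohort (16 animals, 8 groups, 600 genes,
# 150-gene panel) used by unit tests where only structure matters.
# `study_conditions()`: the full scaled-down study (24 animals, 2,000
# genes, 300-gene panel, 40 planted genes/group, effect 2.0, noise 0.5,
# groups 6/7 sharing 75% of their signature, seed 7) together with its
# preprocessing output and the 3-fold balanced CV of the network and
# forest classifiers; cached because several test files assert on it.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(seed = 42L, ...) {
  signature_spec(n_genes = 600L, panel_size = 150L, planted_per_group = 15L,
                 n_common = 40L, seed = seed, ...)
}

small_study <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_study(cohort_design(16L, seed = 42L),
                                      small_spec(), n_drivers = 10L,
                                      titer_seed = 42L)
  }
  .fixtures$small
}

small_prep <- function() {
  if (is.null(.fixtures$small_prep)) {
    s <- small_study()
    .fixtures$small_prep <- preprocess_expression(
      s$expr, s$meta, s$truth$ortholog_map, s$truth$panel)
  }
  .fixtures$small_prep
}

study_conditions <- function() {
  if (is.null(.fixtures$full)) {
    s <- simulate_study(cohort_design(24L, seed = 7L),
                        signature_spec(seed = 7L), titer_seed = 7L)
    prep <- preprocess_expression(s$expr, s$meta, s$truth$ortholog_map,
                                  s$truth$panel)
    inst <- build_instances(prep$fold_change, s$meta)
    folds <- make_balanced_folds(inst$labels, k = 3L, seed = 7L)
    cv_mlp <- cross_validate_classifier(
      inst$x, inst$labels, folds, mlp_factory(epochs = 300L, seed = 7L))
    cv_forest <- cross_validate_classifier(
      inst$x, inst$labels, folds, forest_factory(seed = 7L))
    .fixtures$full <- list(study = s, prep = prep, inst = inst,
                           folds = folds, cv_mlp = cv_mlp,
                           cv_forest = cv_forest)
  }
  .fixtures$full
}

# metadata for hand-built toy matrices: one sample per column id, with the
# stated group/timepoint labels
toy_meta <- function(sample_id, group, timepoint,
                     animal_id = paste0("A", seq_along(sample_id)),
                     dose = 1L) {
  data.frame(sample_id = sample_id, animal_id = animal_id,
             group = factor(group), dose = as.integer(dose),
             timepoint = factor(timepoint,
                                levels = c("pre", "day1", "day7")),
             stringsAsFactors = FALSE)
}

# inject weights into an initialized network and mark it trained, for
# hand-evaluated forward/saliency cases
manual_mlp <- function(W1, b1, W2, b2, head = "softmax",
                       feature_names = NULL, output_names = NULL) {
  m <- mlp_init(ncol(W1), nrow(W1), nrow(W2), head,
                feature_names = feature_names, output_names = output_names)
  m$W1 <- W1; m$b1 <- b1; m$W2 <- W2; m$b2 <- b2
  m$trained <- TRUE
  m
}
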