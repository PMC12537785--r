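#' Describe a vaccination cohort
#'
#' A cohort design fixes the number of animals, their allocation to adjuvant
#' groups, and the blood-draw schedule: every animal is sampled at three
#' timepoints (pre-dose, day 1, day 7) around each of two vaccine doses,
#' giving six sampling occasions per animal.
#'
#' When `group_sizes` is not given, animals are split as evenly as possible
#' across groups and any remainder is assigned to groups 6 and 7 first, so
#' that the default cohort reproduces the majority-class structure of the
#' study design this emulates (groups 6 and 7 over-represented, hence the
#' undersampling step in [make_balanced_folds()]).
#'
#' @param n_animals total number of animals.
#' @param n_groups number of adjuvant groups (default 8).
#' @param group_sizes optional integer vector of per-group animal counts;
#'   must sum to `n_animals`.
#' @param doses number of vaccine doses (default 2).
#' @param timepoints ordered sampling labels relative to each dose.
#' @param seed integer seed controlling the randomized group assignment.
#' @return an object of class `cohort_design`.
#' @seealso [generate_cohort()]
#' @export
cohort_design <- function(n_animals = 60L, n_groups = 8L, group_sizes = NULL,
                          doses = 2L, timepoints = c("pre", "day1", "day7"),
                          seed = 1L) {
  if (n_animals < 1) stop("n_animals must be positive", call. = FALSE)
  if (n_groups < 2) stop("n_groups must be at least 2", call. = FALSE)
  if (doses < 1) stop("doses must be positive", call. = FALSE)
  if (is.null(group_sizes)) {
    base <- n_animals %/% n_groups
    rem <- n_animals %% n_groups
    group_sizes <- rep(base, n_groups)
    if (rem > 0) {
      # remainder cycles over groups 6 and 7 (the study's majority groups)
      # so the default cohort has them over-represented
      pref <- c(6L, 7L)
      pref <- pref[pref <= n_groups]
      if (length(pref) == 0) pref <- seq_len(n_groups)
      bump <- tabulate(rep_len(pref, rem), nbins = n_groups)
      group_sizes <- group_sizes + bump
    }
  }
  if (length(group_sizes) != n_groups)
    stop("group_sizes must have one entry per group", call. = FALSE)
  if (any(group_sizes <= 0))
    stop("group_sizes must be positive", call. = FALSE)
  if (sum(group_sizes) != n_animals)
    stop("group_sizes must sum to n_animals", call. = FALSE)
  structure(list(n_animals = as.integer(n_animals),
                 n_groups = as.integer(n_groups),
                 group_sizes = as.integer(group_sizes),
                 doses = as.integer(doses),
                 timepoints = timepoints,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate sample metadata for a cohort
#'
#' Randomly assigns animals to adjuvant groups (reproducibly under the
#' design seed) and expands the blood-draw schedule: one sample row per
#' (animal, dose, timepoint) combination.
#'
#' @param design a [cohort_design()].
#' @return a data.frame with columns `sample_id`, `animal_id`, `group`
#'   (factor), `dose` (integer) and `timepoint` (factor with the design's
#'   level order).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  animals <- sprintf("A%03d", seq_len(design$n_animals))
  # random assignment: permute animals, then fill groups to their sizes
  perm <- sample(animals)
  group_of <- rep.int(seq_len(design$n_groups), design$group_sizes)
  names(group_of) <- perm
  group_of <- group_of[animals]

  grid <- expand.grid(timepoint = design$timepoints,
                      dose = seq_len(design$doses),
                      animal_id = animals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_d%d_%s", grid$animal_id, grid$dose, grid$timepoint),
    animal_id = grid$animal_id,
    group = factor(group_of[grid$animal_id], levels = seq_len(design$n_groups)),
    dose = as.integer(grid$dose),
    timepoint = factor(grid$timepoint, levels = design$timepoints),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- NULL
  meta
}

#' Specify planted expression signatures
#'
#' Fixes the dimensions and effect structure of a synthetic expression
#' matrix. Expression is simulated on the log10 scale and exponentiated to
#' FPKM, so configured effect sizes are in the same units as the pipeline's
#' transformed data. Structure planted in the panel:
#' \itemize{
#'   \item per-group signatures: `planted_per_group` genes per group are
#'     shifted by `effect_size` at post-dose timepoints in that group only;
#'   \item confusable pairs: `shared_pairs` forces stated group pairs to
#'     share a fraction of their planted genes (e.g. the two MPL-containing
#'     groups sharing most of their signature);
#'   \item a common response: `n_common` panel genes are shifted by
#'     `common_effect` post-dose in every group — the shared (alum-driven)
#'     vaccination signature that makes non-discriminative genes correlate
#'     across groups;
#'   \item below-detection genes: a fraction `below_frac` of all genes has
#'     baseline expression below the low-intensity filter threshold
#'     everywhere, to exercise the filter.
#' }
#'
#' @param n_genes total simulated genes.
#' @param panel_size size of the immune gene panel (genes the analysis keeps).
#' @param planted_per_group discriminative genes planted per group.
#' @param effect_size post-dose shift (log10 units) of planted genes.
#' @param noise_sd per-sample, per-gene gaussian noise sd (log10 units).
#' @param shared_pairs list of `list(pair = c(a, b), frac = f)` entries.
#' @param n_common,common_effect size and shift of the shared response.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   expression (log10 units) for detectable genes.
#' @param below_frac,below_mean,below_sd below-detection gene fraction and
#'   baseline distribution (transformed values stay below -1).
#' @param map_fraction fraction of simulated genes with a human ortholog.
#' @param seed integer seed.
#' @return an object of class `signature_spec`.
#' @export
signature_spec <- function(n_genes = 2000L, panel_size = 300L,
                           planted_per_group = 40L, effect_size = 2,
                           noise_sd = 0.5,
                           shared_pairs = list(list(pair = c(6L, 7L), frac = 0.75)),
                           n_common = 100L, common_effect = 1,
                           baseline_mean = 1, baseline_sd = 0.5,
                           below_frac = 0.2, below_mean = -1.5, below_sd = 0.2,
                           map_fraction = 0.9, seed = 1L) {
  if (n_genes < panel_size)
    stop("n_genes must be at least panel_size", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (n_common + planted_per_group > panel_size)
    stop("panel_size too small for n_common plus planted_per_group",
         call. = FALSE)
  for (sp in shared_pairs) {
    if (length(sp$pair) != 2 || sp$frac < 0 || sp$frac > 1)
      stop("shared_pairs entries need a 2-vector pair and frac in [0,1]",
           call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 panel_size = as.integer(panel_size),
                 planted_per_group = as.integer(planted_per_group),
                 effect_size = effect_size, noise_sd = noise_sd,
                 shared_pairs = shared_pairs,
                 n_common = as.integer(n_common), common_effect = common_effect,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 below_frac = below_frac, below_mean = below_mean,
                 below_sd = below_sd,
                 map_fraction = map_fraction, seed = as.integer(seed)),
            class = "signature_spec")
}

#' Generate a synthetic FPKM expression matrix
#'
#' Simulates log10 expression as gene baseline + planted group effects +
#' common post-dose response + gaussian noise, then exponentiates to FPKM
#' (`pmax(10^z - 0.01, 0)`), so that the pipeline transform
#' `log10(FPKM + 0.01) + 0.01` recovers `z + 0.01` exactly for all values in
#' the detectable range. Pre-dose samples carry no group or common effect.
#'
#' Alongside the matrix it returns the ground-truth registry needed by
#' recovery tests: the ortholog map (source gene id to human symbol), the
#' immune panel (human symbols, all mapped and detectable), the planted gene
#' sets per group and the common-response set.
#'
#' @param meta sample metadata from [generate_cohort()].
#' @param spec a [signature_spec()].
#' @return a list with elements `expr` (genes x samples FPKM matrix, source
#'   gene ids as rownames) and `truth` (registry list).
#' @export
generate_expression <- function(meta, spec) {
  stopifnot(inherits(spec, "signature_spec"))
  n_groups <- nlevels(meta$group)
  if (spec$planted_per_group * n_groups > spec$n_genes)
    stop("planted_per_group x n_groups exceeds n_genes", call. = FALSE)
  set.seed(spec$seed)

  ng <- spec$n_genes
  src_ids <- sprintf("NHPG%05d", seq_len(ng))
  symbols <- sprintf("G%05d", seq_len(ng))

  n_below <- round(spec$below_frac * ng)
  below <- sort(sample.int(ng, n_below))
  is_below <- seq_len(ng) %in% below

  baseline <- numeric(ng)
  baseline[!is_below] <- stats::rnorm(ng - n_below, spec$baseline_mean,
                                      spec$baseline_sd)
  baseline[is_below] <- pmin(stats::rnorm(n_below, spec$below_mean,
                                          spec$below_sd), -1.2)

  n_mapped <- round(spec$map_fraction * ng)
  mapped <- sort(sample.int(ng, n_mapped))

  eligible <- setdiff(intersect(mapped, which(!is_below)), integer(0))
  if (length(eligible) < spec$panel_size)
    stop("not enough mapped, detectable genes for the panel", call. = FALSE)
  panel_idx <- sort(sample(eligible, spec$panel_size))

  common_idx <- sort(sample(panel_idx, spec$n_common))
  plant_pool <- setdiff(panel_idx, common_idx)
  planted <- lapply(seq_len(n_groups), function(g)
    sort(sample(plant_pool, spec$planted_per_group)))
  for (sp in spec$shared_pairs) {
    a <- sp$pair[1]; b <- sp$pair[2]
    n_shared <- round(sp$frac * spec$planted_per_group)
    shared <- sample(planted[[a]], n_shared)
    own_pool <- setdiff(plant_pool, planted[[a]])
    own <- sample(own_pool, spec$planted_per_group - n_shared)
    planted[[b]] <- sort(c(shared, own))
  }

  # genes x groups effect matrix (post-dose only)
  effect <- matrix(0, ng, n_groups)
  for (g in seq_len(n_groups)) effect[planted[[g]], g] <- spec$effect_size
  effect[common_idx, ] <- effect[common_idx, ] + spec$common_effect

  ns <- nrow(meta)
  post <- meta$timepoint != "pre"
  grp <- as.integer(meta$group)
  z <- matrix(baseline, ng, ns)
  for (s in seq_len(ns)) if (post[s]) z[, s] <- z[, s] + effect[, grp[s]]
  if (spec$noise_sd > 0)
    z <- z + matrix(stats::rnorm(ng * ns, 0, spec$noise_sd), ng, ns)

  expr <- pmax(10^z - 0.01, 0)
  dimnames(expr) <- list(src_ids, meta$sample_id)

  truth <- list(
    ortholog_map = data.frame(source_id = src_ids[mapped],
                              human_symbol = symbols[mapped],
                              stringsAsFactors = FALSE),
    panel = symbols[panel_idx],
    planted = stats::setNames(lapply(planted, function(i) symbols[i]),
                              paste0("group", seq_len(n_groups))),
    planted_source = stats::setNames(lapply(planted, function(i) src_ids[i]),
                                     paste0("group", seq_len(n_groups))),
    common = symbols[common_idx],
    below_detection = src_ids[below],
    symbol_of = stats::setNames(symbols, src_ids)
  )
  list(expr = expr, truth = truth)
}

#' Specify the expression-to-titer generative model
#'
#' Antibody titers for the nine HPV VLP types are generated as a linear map
#' from the day-1 (transformed) expression of a set of driver genes, plus a
#' per-animal baseline and a second-dose boost:
#' \deqn{titer(a, h, 12) = base(a, h) + B[h, ] x_a + e}
#' \deqn{titer(a, h, 36) = base(a, h) + B[h, ] x_a + boost + e}
#' where `x_a` is animal `a`'s day-1-after-dose-1 driver expression. With
#' `titer_noise_sd = 0` the titers are a deterministic function of day-1
#' expression.
#'
#' @param driver_genes character vector of source gene ids driving titers.
#' @param coefficients optional 9 x n_drivers matrix; drawn N(0, coef_sd)
#'   when `NULL`.
#' @param dose_boost additive shift applied to week-36 titers.
#' @param titer_noise_sd gaussian noise sd on titers.
#' @param baseline_mean,baseline_sd per-(animal, type) day-0 baseline level.
#' @param coef_sd sd of randomly drawn coefficients.
#' @param seed integer seed.
#' @return an object of class `titer_model`.
#' @export
titer_model <- function(driver_genes, coefficients = NULL, dose_boost = 2,
                        titer_noise_sd = 0.5, baseline_mean = 5,
                        baseline_sd = 1, coef_sd = 1, seed = 1L) {
  hpv_types <- c(6L, 11L, 16L, 18L, 31L, 33L, 45L, 52L, 58L)
  nd <- length(driver_genes)
  if (nd < 1) stop("driver_genes must be non-empty", call. = FALSE)
  if (is.null(coefficients)) {
    set.seed(seed)
    coefficients <- matrix(stats::rnorm(9 * nd, 0, coef_sd), 9, nd)
  }
  if (!all(dim(coefficients) == c(9, nd)))
    stop("coefficients must be 9 x length(driver_genes)", call. = FALSE)
  dimnames(coefficients) <- list(paste0("HPV", hpv_types), driver_genes)
  structure(list(driver_genes = driver_genes, coefficients = coefficients,
                 dose_boost = dose_boost, titer_noise_sd = titer_noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 hpv_types = hpv_types, seed = as.integer(seed)),
            class = "titer_model")
}

#' Generate an antibody titer table from expression
#'
#' Emits one row per (animal, HPV type, week) with weeks 0 (pre-vaccination
#' baseline), 12 and 36. Week-12 and week-36 titers are the linear map of
#' the animal's day-1-after-dose-1 transformed driver expression described
#' in [titer_model()].
#'
#' @param meta sample metadata from [generate_cohort()].
#' @param expr FPKM matrix from [generate_expression()].
#' @param tm a [titer_model()].
#' @param pseudo pseudo-count used when transforming driver expression.
#' @return a data.frame `animal_id`, `hpv_type`, `week`, `value`.
#' @export
generate_titers <- function(meta, expr, tm, pseudo = 0.01) {
  stopifnot(inherits(tm, "titer_model"))
  missing <- setdiff(tm$driver_genes, rownames(expr))
  if (length(missing) > 0)
    stop("driver gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(tm$seed + 1L)
  animals <- unique(meta$animal_id)
  day1 <- meta$sample_id[meta$dose == 1L & meta$timepoint == "day1"]
  names(day1) <- meta$animal_id[meta$dose == 1L & meta$timepoint == "day1"]
  if (!all(animals %in% names(day1)))
    stop("every animal needs a day-1 sample after dose 1", call. = FALSE)

  x <- log10(expr[tm$driver_genes, day1[animals], drop = FALSE] + pseudo) + pseudo
  signal <- tm$coefficients %*% x          # 9 x animals
  na <- length(animals); nt <- length(tm$hpv_types)

  base <- matrix(stats::rnorm(nt * na, tm$baseline_mean, tm$baseline_sd),
                 nt, na)
  noise <- function() {
    if (tm$titer_noise_sd > 0)
      matrix(stats::rnorm(nt * na, 0, tm$titer_noise_sd), nt, na)
    else matrix(0, nt, na)
  }
  w12 <- base + signal + noise()
  w36 <- base + signal + tm$dose_boost + noise()

  long <- function(m, week) data.frame(
    animal_id = rep(animals, each = nt),
    hpv_type = rep(tm$hpv_types, na),
    week = week,
    value = as.vector(m),
    stringsAsFactors = FALSE)
  out <- rbind(long(base, 0L), long(w12, 12L), long(w36, 36L))
  rownames(out) <- NULL
  out
}

#' Simulate a complete adjuvant study
#'
#' One-call wrapper: cohort metadata, expression matrix with ground truth,
#' and titer table, all reproducible from the seeds embedded in the design,
#' signature and titer specifications.
#'
#' @param design a [cohort_design()].
#' @param spec a [signature_spec()].
#' @param n_drivers number of planted genes driving titers.
#' @param titer_noise_sd,dose_boost passed to [titer_model()].
#' @param titer_seed seed for the titer model (defaults to the signature
#'   seed).
#' @return a list `meta`, `expr`, `truth`, `titer_model`, `titers`.
#' @export
simulate_study <- function(design = cohort_design(),
                           spec = signature_spec(),
                           n_drivers = 20L, titer_noise_sd = 0.5,
                           dose_boost = 2, titer_seed = spec$seed) {
  meta <- generate_cohort(design)
  ge <- generate_expression(meta, spec)
  plant_src <- unique(unlist(ge$truth$planted_source, use.names = FALSE))
  if (n_drivers > length(plant_src))
    stop("n_drivers exceeds the number of planted genes", call. = FALSE)
  set.seed(spec$seed + 101L)
  drivers <- sort(sample(plant_src, n_drivers))
  tm <- titer_model(drivers, titer_noise_sd = titer_noise_sd,
                    dose_boost = dose_boost, seed = titer_seed)
  titers <- generate_titers(meta, ge$expr, tm)
  list(meta = meta, expr = ge$expr, truth = ge$truth, titer_model = tm,
       titers = titers)
}
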