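test_that("cohort generation yields one sample per animal, dose and timepoint", {
  meta <- generate_cohort(cohort_design(n_animals = 60L, seed = 3L))
  expect_equal(nrow(meta), 360L)                 # 60 animals x 2 doses x 3 draws
  expect_equal(length(unique(meta$animal_id)), 60L)
  expect_false(anyDuplicated(meta$sample_id) > 0)
  counts <- table(meta$animal_id)
  expect_true(all(counts == 6L))
  # default allocation puts the remainder in groups 6 and 7
  per_group <- table(meta$group[meta$dose == 1 & meta$timepoint == "pre"])
  expect_equal(as.integer(per_group), c(7L, 7L, 7L, 7L, 7L, 9L, 9L, 7L))
})

test_that("equal group sizes force one animal per group", {
  meta <- generate_cohort(cohort_design(n_animals = 8L, seed = 1L))
  expect_true(all(table(unique(meta[, c("animal_id", "group")])$group) == 1L))
})

test_that("cohort generation is deterministic under the design seed", {
  d <- cohort_design(n_animals = 20L, seed = 11L)
  expect_identical(generate_cohort(d), generate_cohort(d))
  d2 <- cohort_design(n_animals = 20L, seed = 12L)
  expect_false(identical(generate_cohort(d), generate_cohort(d2)))
})

test_that("invalid designs are rejected with the offending field named", {
  expect_error(cohort_design(n_animals = 0), "n_animals")
  expect_error(cohort_design(n_groups = 1), "n_groups")
  expect_error(cohort_design(group_sizes = c(3, -1, rep(1, 6)),
                             n_animals = 8), "group_sizes")
  expect_error(cohort_design(group_sizes = rep(2, 8), n_animals = 10),
               "sum")
})

test_that("zero-noise expression carries planted effects exactly", {
  meta <- generate_cohort(cohort_design(8L, seed = 5L))
  spec <- small_spec(seed = 5L, noise_sd = 0, effect_size = 2)
  ge <- generate_expression(meta, spec)
  expect_true(all(ge$expr >= 0))
  t <- transform_fpkm(ge$expr)
  sym <- ge$truth$symbol_of
  for (g in 1:8) {
    animal <- meta$animal_id[meta$group == g][1]
    pre <- t[, paste0(animal, "_d1_pre")]
    day1 <- t[, paste0(animal, "_d1_day1")]
    planted_src <- names(sym)[sym %in% ge$truth$planted[[g]]]
    # planted genes shift by exactly the effect size in their group
    expect_equal(unname(day1[planted_src] - pre[planted_src]),
                 rep(2, length(planted_src)), tolerance = 1e-12)
  }
  # pre-dose samples carry no group effect: two animals in different groups
  # have identical pre-dose profiles under zero noise
  a1 <- meta$animal_id[meta$group == 1][1]
  a2 <- meta$animal_id[meta$group == 2][1]
  expect_equal(unname(t[, paste0(a1, "_d1_pre")]),
               unname(t[, paste0(a2, "_d1_pre")]))
})

test_that("null effect leaves group means equal within sampling error", {
  meta <- generate_cohort(cohort_design(32L, seed = 6L))
  spec <- small_spec(seed = 6L, effect_size = 0, common_effect = 0,
                     noise_sd = 0.5)
  ge <- generate_expression(meta, spec)
  t <- transform_fpkm(ge$expr)
  day1 <- meta$timepoint == "day1"
  g1 <- rowMeans(t[, meta$sample_id[day1 & meta$group == 1], drop = FALSE])
  g2 <- rowMeans(t[, meta$sample_id[day1 & meta$group == 2], drop = FALSE])
  # 4 animals x 2 doses per group: contrast sd = sqrt(2) * 0.5/sqrt(8)
  sd_contrast <- sqrt(2) * 0.5 / sqrt(8)
  expect_lt(mean(abs(g1 - g2)), 1.2 * sd_contrast)  # E|N(0,s)| = 0.8 s
  expect_lt(max(abs(g1 - g2)), 5 * sd_contrast)     # 600 genes
})

test_that("planted mean shift converges to the configured effect size", {
  # Monte-Carlo check at n = 200 animals: empirical day1-minus-pre shift of
  # planted genes within 0.1 of the configured effect
  meta <- generate_cohort(cohort_design(200L, seed = 8L))
  spec <- signature_spec(n_genes = 300L, panel_size = 120L,
                         planted_per_group = 10L, n_common = 20L,
                         noise_sd = 0.5, effect_size = 2, seed = 8L)
  ge <- generate_expression(meta, spec)
  t <- transform_fpkm(ge$expr)
  fc <- fold_change(t, meta)
  m <- meta[match(colnames(fc), meta$sample_id), ]
  sym <- ge$truth$symbol_of
  shifts <- vapply(1:8, function(g) {
    planted_src <- names(sym)[sym %in% ge$truth$planted[[g]]]
    mean(fc[planted_src, m$group == g & m$timepoint == "day1"])
  }, numeric(1))
  expect_true(all(abs(shifts - 2) < 0.1))
  # non-planted, non-common genes: group-mean contrast near 0 (3 x SEM)
  inert <- setdiff(rownames(fc),
                   names(sym)[sym %in% c(unlist(ge$truth$planted),
                                         ge$truth$common)])
  n_per <- sum(m$group == 1 & m$timepoint == "day1")
  # fold change doubles the noise variance; the two-group contrast doubles
  # it again: sem = 2 * noise_sd / sqrt(n)
  sem <- 2 * 0.5 / sqrt(n_per)
  c12 <- rowMeans(fc[inert, m$group == 1 & m$timepoint == "day1"]) -
    rowMeans(fc[inert, m$group == 2 & m$timepoint == "day1"])
  expect_lt(mean(abs(c12) > 3 * sem), 0.015)
})

test_that("oversized planted sets are rejected", {
  meta <- generate_cohort(cohort_design(8L, seed = 1L))
  expect_error(signature_spec(n_genes = 300L, panel_size = 300L,
                              planted_per_group = 100L, n_common = 250L),
               "panel_size")
  spec <- small_spec(seed = 1L)
  spec$planted_per_group <- 200L     # 200 x 8 > 600
  expect_error(generate_expression(meta, spec), "n_genes")
})

test_that("zero-noise titers reproduce the linear map of day-1 expression", {
  s <- small_study()
  meta <- s$meta
  tm0 <- titer_model(s$titer_model$driver_genes,
                     coefficients = s$titer_model$coefficients,
                     dose_boost = 0, titer_noise_sd = 0, seed = 9L)
  titers <- generate_titers(meta, s$expr, tm0)
  post <- subtract_titer_baseline(titers)
  # week 36 == week 12 when dose_boost = 0 and there is no noise
  w12 <- post[post$week == 12, ]
  w36 <- post[post$week == 36, ]
  expect_equal(w12$value, w36$value)
  # baseline-subtracted titers equal the coefficient map exactly
  x <- log10(s$expr[tm0$driver_genes,
                    paste0(unique(meta$animal_id), "_d1_day1")] + 0.01) + 0.01
  expected <- tm0$coefficients %*% x
  for (i in seq_len(nrow(w12))) {
    a <- w12$animal_id[i]; h <- paste0("HPV", w12$hpv_type[i])
    expect_equal(w12$value[i], expected[h, match(a, unique(meta$animal_id))],
                 tolerance = 1e-10)
  }
})

test_that("zero coefficients give titers uncorrelated with expression", {
  s <- small_study()
  meta60 <- generate_cohort(cohort_design(60L, seed = 13L))
  ge <- generate_expression(meta60, small_spec(seed = 13L))
  drivers <- rownames(ge$expr)[1:10]
  tm <- titer_model(drivers,
                    coefficients = matrix(0, 9, 10),
                    titer_noise_sd = 1, seed = 13L)
  titers <- generate_titers(meta60, ge$expr, tm)
  post <- subtract_titer_baseline(titers)
  x <- colMeans(log10(ge$expr[drivers,
                              paste0(unique(meta60$animal_id), "_d1_day1")] +
                        0.01))
  names(x) <- unique(meta60$animal_id)
  w12 <- post[post$week == 12, ]
  expect_lt(abs(cor(x[w12$animal_id], w12$value)), 0.2)
})

test_that("missing driver genes are rejected by name", {
  s <- small_study()
  tm <- titer_model(c(s$titer_model$driver_genes, "NOPE999"), seed = 1L)
  expect_error(generate_titers(s$meta, s$expr, tm), "NOPE999")
})

test_that("the full simulated study is bit-identical under one seed", {
  d <- cohort_design(8L, seed = 21L)
  sp <- small_spec(seed = 21L)
  s1 <- simulate_study(d, sp, n_drivers = 5L, titer_seed = 21L)
  s2 <- simulate_study(d, sp, n_drivers = 5L, titer_seed = 21L)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$titers, s2$titers)
  expect_identical(s1$truth, s2$truth)
})
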