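test_that("with no effects and no noise, samples differ only by their global shift", {
  cfg <- synthetic_config(seed = 3, n_benign = 4, n_malignant = 4,
                          n_metastatic = 1, n_brca1_benign = 0,
                          n_brca1_malignant = 0, noise_sd = 0)
  sim <- generate_cohort(cfg)
  m <- sim$cq$cq
  # each sample's offset from the first sample is the same for every assay
  offsets <- m - matrix(m[1, ], nrow(m), ncol(m), byrow = TRUE)
  expect_true(all(abs(offsets - offsets[, 1]) < 1e-12))
})

test_that("an injected 2-fold change lowers Cq by exactly one cycle", {
  fc <- data.frame(mir_id = "hsa-miR-652-5p", contrast = "malignant", fc = 2)
  cfg <- synthetic_config(seed = 5, n_benign = 3, n_malignant = 3,
                          n_metastatic = 0, n_brca1_benign = 0,
                          n_brca1_malignant = 0, noise_sd = 0,
                          sample_effect_sd = 0, fold_changes = fc)
  sim <- generate_cohort(cfg)
  mal <- sim$metadata$sample_id[sim$metadata$group == "malignant"]
  ben <- sim$metadata$sample_id[sim$metadata$group == "benign"]
  target <- sim$cq$cq[, "hsa-miR-652-5p"]
  expect_equal(unique(target[ben]) - unique(target[mal]), 1)
  # a reference miR is untouched by the group effect
  ref <- sim$cq$cq[, "ref-miR-1"]
  expect_equal(unname(ref[ben[1]]), unname(ref[mal[1]]))
})

test_that("the generator is deterministic in its seed", {
  cfg <- synthetic_config(seed = 1, n_benign = 5, n_malignant = 5,
                          n_metastatic = 2, n_brca1_benign = 1,
                          n_brca1_malignant = 1, haemolysis_fraction = 0.2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- synthetic_config(seed = 2, n_benign = 5, n_malignant = 5,
                           n_metastatic = 2, n_brca1_benign = 1,
                           n_brca1_malignant = 1, haemolysis_fraction = 0.2)
  expect_false(identical(generate_cohort(cfg2)$cq$cq, a$cq$cq))
})

test_that("fold changes cannot be placed on reference assays", {
  fc <- data.frame(mir_id = "ref-miR-1", contrast = "malignant", fc = 2)
  expect_error(generate_cohort(
    synthetic_config(seed = 1, n_benign = 2, n_malignant = 2,
                     n_metastatic = 0, n_brca1_benign = 0,
                     n_brca1_malignant = 0, fold_changes = fc)),
    "reference miRs carry no group effect")
})

test_that("pooling averages linear abundance, not cycles", {
  tab <- make_cq(rbind(c(25, 24, 30), c(25, 26, NA)),
                 sample_names = c("p1", "p2"))
  pooled <- pool_samples(tab, list(g1 = c("p1", "p2")))
  # identical members: idempotent
  expect_equal(pooled$cq["g1", "a1"], 25, ignore_attr = TRUE)
  # 24 and 26 pool to -log2((2^-24 + 2^-26)/2)
  expect_equal(unname(pooled$cq["g1", "a2"]), 25 - log2(1.25),
               tolerance = 1e-12)
  expect_equal(unname(pooled$cq["g1", "a2"]), 24.678, tolerance = 1e-4)
  # an undetected member is excluded from the mean
  expect_equal(unname(pooled$cq["g1", "a3"]), 30)
})

test_that("pooling rejects empty pools and propagates all-missing", {
  tab <- make_cq(rbind(c(NA, 20), c(NA, 21)), sample_names = c("p1", "p2"))
  expect_error(pool_samples(tab, list(g1 = character())), "empty pool")
  expect_error(pool_samples(tab, list()), "no pools")
  expect_error(pool_samples(tab, list(g1 = c("p1", "nope"))), "not in Cq table")
  pooled <- pool_samples(tab, list(g1 = c("p1", "p2")))
  expect_true(is.na(pooled$cq["g1", "a1"]))
})

test_that("assign_pools builds within-stratum pools of 2-3 members", {
  cfg <- discovery_config(seed = 2)
  meta <- generate_cohort(cfg)$metadata
  pools <- assign_pools(meta, pool_size = 3)
  expect_true(all(lengths(pools) %in% 2:3))
  # pools never mix diagnosis strata
  for (p in names(pools)) {
    g <- unique(meta$group[meta$sample_id %in% pools[[p]]])
    expect_length(g, 1)
  }
  expect_setequal(unlist(pools), meta$sample_id)
})

test_that("simulated microarray panels reflect abundance and are seed-stable", {
  cfg <- synthetic_config(seed = 4, n_benign = 4, n_malignant = 4,
                          n_metastatic = 0, n_brca1_benign = 0,
                          n_brca1_malignant = 0, absent_fraction = 0,
                          background_sd = 0)
  sim <- generate_cohort(cfg)
  pooled <- pool_samples(sim$cq, assign_pools(sim$metadata, 2))
  panel <- generate_microarray_panel(cfg, pooled)
  expect_identical(panel$intensity,
                   generate_microarray_panel(cfg, pooled)$intensity)
  # with zero background noise and no forced-absent miRs, every spot with
  # signal clears the (mean + 2*0) threshold
  expect_true(all(present_call(panel)))

  cfg2 <- synthetic_config(seed = 4, n_benign = 4, n_malignant = 4,
                           n_metastatic = 0, n_brca1_benign = 0,
                           n_brca1_malignant = 0, absent_fraction = 0.2,
                           background_sd = 0)
  panel2 <- generate_microarray_panel(cfg2, pooled)
  absent <- attr(panel2, "absent_mirs")
  expect_gt(length(absent), 0)
  # forced-absent miRs sit exactly at background: absent under strict >
  expect_false(any(present_call(panel2)[absent, ]))
})

test_that("dilution series follow the efficiency-slope closed form", {
  s <- generate_dilution_series(100, points = 5, start_cq = 20)
  expect_equal(diff(s$cq), rep(1 / log10(2), 4), tolerance = 1e-12)
  expect_equal(unname(diff(s$cq)[1]), 3.3219, tolerance = 1e-4)
  fit <- stats::lm(cq ~ log10_dilution, data = s)
  expect_equal(unname(stats::coef(fit)[2]), -1 / log10(2), tolerance = 1e-12)
  expect_error(generate_dilution_series(-5), "positive")
  expect_error(generate_dilution_series(100, points = 2), "at least 3")
  # noiseless series invert exactly through the efficiency estimator
  est <- assay_efficiency(generate_dilution_series(92.5, points = 5))
  expect_equal(est$efficiency_pct, 92.5, tolerance = 1e-9)
})
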