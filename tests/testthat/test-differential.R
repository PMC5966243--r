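test_that("Mann-Whitney U and exact p match hand enumeration", {
  # complete separation of 3 vs 3: U = 0, 2 of 20 labelings as extreme
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  # 2 vs 2: U = 0, p = 2/6
  res2 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res2$u, 0)
  expect_equal(res2$p, 1 / 3, tolerance = 1e-12)
  # identical multisets: null, p = 1
  res3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$p, 1, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(), c(1, 2)), "non-empty")
})

test_that("exact Mann-Whitney agrees with the full-enumeration oracle", {
  set.seed(21)
  for (i in 1:40) {
    na <- sample(2:7, 1)
    nb <- sample(2:7, 1)
    vals <- sample(1:60, na + nb)  # tie-free
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    got <- mann_whitney(a, b)
    want <- oracle_mwu(a, b)
    expect_equal(got$u, want$u)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("BH step-up rejects the documented hand cases", {
  params <- stats_params(fdr_q = 0.10)
  res <- bh_fdr(c(0.001, 0.02, 0.03, 0.5), params)
  expect_equal(sort(res$critical), c(0.025, 0.05, 0.075, 0.10))
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$adjusted, p.adjust(c(0.001, 0.02, 0.03, 0.5), "BH"))

  one <- bh_fdr(0.04, params)
  expect_equal(one$critical, 0.10)
  expect_true(one$reject)
  expect_equal(one$adjusted, 0.04)

  all1 <- bh_fdr(rep(1, 5), params)
  expect_false(any(all1$reject))
  expect_equal(all1$adjusted, rep(1, 5))

  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH properties: step-up equals adjusted<=q, monotone in q, adjusted>=raw", {
  set.seed(22)
  for (i in 1:20) {
    p <- runif(sample(3:25, 1))^2
    q1 <- stats_params(fdr_q = 0.05)
    q2 <- stats_params(fdr_q = 0.2)
    r1 <- bh_fdr(p, q1)
    r2 <- bh_fdr(p, q2)
    expect_identical(r1$reject, r1$adjusted <= 0.05)
    expect_identical(r2$reject, r2$adjusted <= 0.2)
    expect_true(all(r2$reject[r1$reject]))  # monotone non-decreasing in q
    expect_true(all(r1$adjusted >= p))
  }
})

test_that("contrasts resolve arms from metadata and control the FDR family", {
  cfg <- synthetic_config(
    seed = 30, n_benign = 12, n_malignant = 12, n_metastatic = 6,
    n_brca1_benign = 0, n_brca1_malignant = 0, noise_sd = 0.3,
    fold_changes = data.frame(mir_id = "hsa-miR-652-5p",
                              contrast = "malignant", fc = 2.5))
  sim <- generate_cohort(cfg)
  rel <- median_normalize(sim$cq)
  res <- run_contrast(rel, sim$metadata, "malignant_vs_benign")
  expect_s3_class(res, "differential_result")
  expect_equal(nrow(res), 18)  # the candidate family, not the references
  hit <- res[res$mir_id == "hsa-miR-652-5p", ]
  expect_gt(hit$fold_change, 1.8)
  expect_true(hit$significant_fdr)
  expect_equal(res$significant_raw, res$p_raw < 0.05)

  met <- run_contrast(rel, sim$metadata, "metastatic_vs_nonmetastatic")
  expect_equal(attr(met, "n_a"), 6)
  expect_equal(attr(met, "n_b"), 6)
  expect_error(run_contrast(rel, sim$metadata, "no_such_contrast"),
               "unknown contrast")
})

test_that("contrast arms of size below 2 are contract errors", {
  cfg <- synthetic_config(seed = 31, n_benign = 4, n_malignant = 4,
                          n_metastatic = 1, n_brca1_benign = 1,
                          n_brca1_malignant = 0)
  sim <- generate_cohort(cfg)
  rel <- median_normalize(sim$cq)
  expect_error(run_contrast(rel, sim$metadata, "metastatic_vs_nonmetastatic"),
               "at least 2 samples")
  expect_error(run_contrast(rel, sim$metadata, "brca1_benign_vs_wildtype"),
               "at least 2 samples")
})

test_that("Spearman correlation handles ranks, ties and degenerate input", {
  expect_equal(spearman_correlation(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1)
  # d^2 sum of 4 over n = 4: rho = 1 - 6*4/(4*15) = 0.6
  res <- spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  expect_warning(out <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("exact categorical tests match margin-fixed enumeration", {
  # diagonal 2x2: 2 of the 252 margin-fixed tables are as extreme
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(categorical_tests(tab), 2 / choose(10, 5), tolerance = 1e-9)
  # identical rows: p = 1
  expect_equal(categorical_tests(matrix(c(3, 3, 2, 2), 2, 2)), 1)
  # symmetric 2x3: p = 1
  expect_equal(categorical_tests(matrix(2, 2, 3)), 1)
  expect_error(categorical_tests(matrix(1, 3, 3)), "unsupported shape")
  expect_error(categorical_tests(matrix(c(1.5, 1, 1, 1), 2, 2)), "integers")
})

test_that("categorical tests agree with the enumeration oracle on small tables", {
  # every 2x2 count table with total <= 12
  parts <- expand.grid(a = 0:12, b = 0:12, c = 0:12)
  parts <- parts[parts$a + parts$b + parts$c <= 12, ]
  mism <- 0
  for (k in seq_len(nrow(parts))) {
    for (n in (parts$a[k] + parts$b[k] + parts$c[k]):12) {
      tab <- matrix(c(parts$a[k], parts$b[k], parts$c[k],
                      n - parts$a[k] - parts$b[k] - parts$c[k]), 2, 2)
      if (abs(categorical_tests(tab) - oracle_exact_2xc(tab)) > 1e-9) {
        mism <- mism + 1
      }
    }
  }
  expect_equal(mism, 0)
  # a handful of 2x3 and 2x4 tables against the same oracle
  tabs <- list(matrix(c(4, 0, 1, 3, 0, 4), 2, 3),
               matrix(c(2, 1, 3, 2, 0, 3), 2, 3),
               matrix(c(1, 2, 2, 1, 3, 0, 0, 3), 2, 4))
  for (tab in tabs) {
    expect_equal(categorical_tests(tab), oracle_exact_2xc(tab),
                 tolerance = 1e-9)
  }
})
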