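test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.04, 5)), rep(0.04, 5))
  set.seed(5)
  for (n in c(2, 3, 5, 20)) {
    p <- runif(n)
    expect_equal(adjust_bh(p), oracle_bh(p))
    perm <- sample(n)
    expect_equal(adjust_bh(p[perm]), oracle_bh(p)[perm])  # permutation equiv
  }
  expect_error(adjust_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_bh(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("summary-statistic t-test is exact pooled/Welch arithmetic", {
  r <- ttest_from_summary(10, 10.3, 1.5, 10, 11.3, 1.8)
  expect_equal(r$df, 18)
  expect_equal(r$p_value, 0.1939, tolerance = 3e-4)

  same <- ttest_from_summary(8, 5, 1, 8, 5, 1)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # equal n, equal sd: Welch reduces to pooled
  a <- ttest_from_summary(9, 2, 1.3, 9, 3, 1.3, variance = "pooled")
  b <- ttest_from_summary(9, 2, 1.3, 9, 3, 1.3, variance = "welch")
  expect_equal(a$t, b$t)
  expect_equal(a$df, b$df)
  expect_error(ttest_from_summary(2, 1, 0, 2, 1, 1), "positive")
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 1), "n >= 2")
})

test_that("feature-level tests detect a 3 SD shift and report effects", {
  set.seed(21)
  hits <- 0
  for (i in 1:20) {
    m <- matrix(rnorm(24 * 5), 5, 24)
    m[1, 13:24] <- m[1, 13:24] + 3
    rownames(m) <- sprintf("FFA(1%d:0)", 2:6)
    colnames(m) <- paste0("s", 1:24)
    res <- test_features(wide_tbl(m), two_group_samples(colnames(m), 12))
    if (res$p_value[res$feature == "FFA(12:0)"] < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 20 * 0.99 - 1)  # >= 99% power at n = 12/group
})

test_that("effects are reported as disease minus control", {
  m <- matrix(0, 1, 8, dimnames = list("FFA(16:0)", paste0("s", 1:8)))
  m[1, ] <- c(rnorm(4, 0, 0.1), rnorm(4, 2, 0.1))
  res <- test_features(wide_tbl(m), two_group_samples(colnames(m), 4))
  expect_gt(res$effect, 1.5)  # CKD higher than CTL -> positive effect
})

test_that("single-feature strata degenerate to the per-feature t-test", {
  set.seed(9)
  m <- matrix(rnorm(16), 2, 8,
              dimnames = list(c("FFA(16:0)", "SM(36:1)"), paste0("s", 1:8)))
  samples <- two_group_samples(paste0("s", 1:8), 4)
  cls <- fit_class_effects(wide_tbl(m), samples, stratify_by = "none")
  feats <- test_features(wide_tbl(m), samples)
  res <- tidy(cls)
  expect_equal(res$model, c("fixed", "fixed"))
  for (f in c("FFA(16:0)", "SM(36:1)")) {
    i <- which(res$class_code == parse_lipids(f)$class_code)
    j <- which(feats$feature == f)
    expect_equal(res$p_value[i], feats$p_value[j])
    expect_equal(res$effect[i], feats$effect[j])
  }
})

test_that("identical group distributions give a null class effect", {
  set.seed(13)
  vals <- matrix(rnorm(6 * 6), 6, 6)
  m <- cbind(vals, vals)  # CKD samples copy CTL exactly
  rownames(m) <- sprintf("PC(3%d:1)", 1:6)
  colnames(m) <- paste0("s", 1:12)
  fit <- fit_class_effects(wide_tbl(m), two_group_samples(colnames(m), 6),
                           stratify_by = "none")
  res <- tidy(fit)
  expect_equal(res$effect, 0, tolerance = 1e-8)
  expect_gt(res$p_value, 0.9)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("programmed saturation-contrast shifts are recovered through the pipeline", {
  cfg <- study_config(seed = 31, tissues = "PM",
                      panel = c(FFA = 16, PC = 30, SM = 20),
                      effects = tibble::tibble(
                        tissue = "PM", class_code = c("FFA", "FFA"),
                        saturation = c("saturated", "unsaturated"),
                        shift = c(0.8, -0.8)),
                      correlation_blocks = NULL, missing_rate = 0)
  st <- generate_study(cfg)
  z <- st$peak_areas$PM |>
    quantify_areas(st$standards, st$is_map) |>
    normalize_samples(st$samples) |>
    preprocess_abundance(samples = st$samples)
  res <- tidy(fit_class_effects(z, st$samples, stratify_by = "saturation"))
  sat <- res[res$stratum == "saturated FFA", ]
  uns <- res[res$stratum == "unsaturated FFA", ]
  expect_gt(sat$effect, 0)
  expect_lt(uns$effect, 0)
  expect_lt(sat$q_value, 0.05)
  expect_lt(uns$q_value, 0.05)
})

test_that("mixed-model p-values are calibrated under the group null", {
  # scaled-down null: 20 features in 4 classes, 12+12 samples, 40 replicates
  set.seed(17)
  feats <- c(sprintf("FFA(%d:0)", 11:15), sprintf("PC(3%d:1)", 1:5),
             sprintf("SM(3%d:1)", 1:5), sprintf("PG(3%d:1)", 1:5))
  ps <- replicate(40, {
    m <- matrix(rnorm(20 * 24), 20, 24,
                dimnames = list(feats, paste0("s", 1:24)))
    fit <- fit_class_effects(wide_tbl(m), two_group_samples(colnames(m), 12),
                             stratify_by = "none")
    tidy(fit)$p_value
  })
  frac <- mean(unlist(ps) < 0.05)
  n_tests <- length(unlist(ps))
  half <- 2.58 * sqrt(0.05 * 0.95 / n_tests)
  expect_lt(abs(frac - 0.05), half + 0.02)  # binomial 99% bounds (+ lmer slack)
})

test_that("significance accounting reproduces percent arithmetic", {
  mk <- function(n, nsig, prefix) tibble::tibble(
    feature = paste0(prefix, seq_len(n)),
    significant = seq_len(n) <= nsig)
  out <- summarize_significance(mk(364, 50, "f"), mk(481, 58, "f"),
                                labels = c("plasma", "PM"))
  expect_equal(out$percent, c(13.7, 12.1))
  expect_equal(attr(out, "n_shared_features"), 364)
  expect_equal(attr(out, "n_shared_significant"), 50)
  none <- summarize_significance(mk(10, 0, "a"), mk(10, 0, "b"))
  expect_equal(none$percent, c(0, 0))
})
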