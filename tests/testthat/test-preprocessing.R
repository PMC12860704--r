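test_that("missingness filter reads 'below 50%' strictly", {
  m <- matrix(1, 3, 10, dimnames = list(c("a", "b", "c"), paste0("s", 1:10)))
  m[1, 1:6] <- NA    # 60% missing -> dropped
  m[2, 1:5] <- NA    # exactly 50% -> dropped (strict boundary)
  rownames(m) <- c("FFA(16:0)", "FFA(18:0)", "FFA(18:1)")
  out <- filter_missing(wide_tbl(m))
  expect_equal(out$feature, "FFA(18:1)")
  dropped <- attr(out, "dropped_features")
  expect_setequal(dropped$feature, c("FFA(16:0)", "FFA(18:0)"))
  expect_error(filter_missing(wide_tbl(m), max_missing = 0), "\\(0, 1\\]")
})

test_that("missingness is assessed within tissue", {
  m <- matrix(1, 1, 8, dimnames = list("FFA(16:0)", paste0("s", 1:8)))
  m[1, 1:3] <- NA    # 75% missing in tissue A, 0% in tissue B
  samples <- tibble::tibble(sample_id = paste0("s", 1:8),
                            tissue = rep(c("A", "B"), each = 4))
  expect_equal(nrow(filter_missing(wide_tbl(m), samples)), 0)
  expect_equal(nrow(filter_missing(wide_tbl(m))), 1)  # 37.5% pooled
})

test_that("KNN imputation matches the brute-force oracle", {
  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(rnorm(80), 10, 8,
                dimnames = list(sprintf("FFA(%d:0)", 10 + 1:10),
                                paste0("s", 1:8)))
    m[sample(80, 5)] <- NA
    got <- impute_knn(wide_tbl(m), k = 3)
    expect_equal(as.matrix(got[-1]), oracle_knn(m, 3), ignore_attr = TRUE)
    # observed cells untouched
    expect_equal(as.matrix(got[-1])[!is.na(m)], m[!is.na(m)])
  }
})

test_that("KNN identity and exact-duplicate neighbour cases", {
  m <- matrix(rnorm(40), 5, 8)
  rownames(m) <- sprintf("PC(3%d:1)", 1:5)
  expect_identical(impute_knn(wide_tbl(m), k = 2), wide_tbl(m))

  m2 <- m
  m2[2, ] <- m2[1, ]          # row 2 duplicates row 1
  m2[1, 3] <- NA
  got <- impute_knn(wide_tbl(m2), k = 1)
  expect_equal(got[[4]][1], unname(m2[2, 3]))  # column 4 = sample s3
})

test_that("class-wise sum normalization yields per-class fractions", {
  m <- matrix(c(2, 3, 5, 4), 4, 1,
              dimnames = list(c("FFA(16:0)", "FFA(18:0)", "FFA(18:1)",
                                "SM(36:1)"), "s1"))
  out <- normalize_class_sum(set_stage(wide_tbl(m), "normalized"))
  expect_equal(out$s1, c(0.2, 0.3, 0.5, 1))   # singleton class -> 1
  expect_equal(abundance_stage(out), "class_fraction")

  set.seed(3)
  big <- matrix(rexp(60), 12, 5)
  rownames(big) <- c(sprintf("FFA(%d:0)", 11:16), sprintf("PC(3%d:2)", 1:6))
  colnames(big) <- paste0("s", 1:5)
  frac <- normalize_class_sum(set_stage(wide_tbl(big), "normalized"))
  fm <- as.matrix(frac[-1])
  cls <- parse_lipids(frac$feature)$class_code
  expect_equal(unname(rowsum(fm, cls)), matrix(1, 2, 5))
  expect_true(all(fm >= 0 & fm <= 1))

  # scale invariance: rescaling one sample's class block changes nothing
  big2 <- big
  big2[1:6, 2] <- big2[1:6, 2] * 37
  frac2 <- normalize_class_sum(set_stage(wide_tbl(big2), "normalized"))
  expect_equal(frac2, frac, ignore_attr = TRUE)

  zero <- big; zero[1:6, 3] <- 0
  expect_error(normalize_class_sum(set_stage(wide_tbl(zero), "normalized")),
               "sums to zero in sample 's3'")
})

test_that("logit transform is clamped and exact at known points", {
  m <- matrix(c(0.5, 1.0, 0.2), 3, 1,
              dimnames = list(c("FFA(16:0)", "SM(36:1)", "PC(34:1)"), "s1"))
  out <- transform_logit(set_stage(wide_tbl(m), "class_fraction"), eps = 1e-6)
  expect_equal(out$s1[1], 0)
  expect_equal(out$s1[2], log((1 - 1e-6) / 1e-6))
  expect_equal(out$s1[3], log(0.25), tolerance = 1e-10)
  expect_true(all(is.finite(out$s1)))
})

test_that("z-scoring standardizes rows with the n-1 convention", {
  m <- matrix(rnorm(24, 5, 3), 4, 6)
  rownames(m) <- sprintf("FFA(1%d:0)", 3:6)
  z <- scale_features(wide_tbl(m))
  zm <- as.matrix(z[-1])
  expect_equal(unname(rowMeans(zm)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zm, 1, sd)), rep(1, 4), tolerance = 1e-12)

  two <- matrix(c(1, 3), 1, 2, dimnames = list("FFA(16:0)", c("s1", "s2")))
  expect_equal(scale_features(wide_tbl(two))$s1, -sqrt(2) / 2)

  const <- rbind(m, `SM(36:1)` = 2)
  expect_warning(zc <- scale_features(wide_tbl(const)), "constant")
  expect_false("SM(36:1)" %in% zc$feature)
})

test_that("stage order is enforced", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(sprintf("FFA(1%d:0)", 4:6), paste0("s", 1:4)))
  z <- scale_features(wide_tbl(m))
  expect_error(transform_logit(z), "stage 'zscore'")
  expect_error(normalize_class_sum(z), "stage 'zscore'")
})

test_that("the full chain equals hand composition on clean input", {
  set.seed(11)
  m <- matrix(rexp(48, 0.1), 6, 8)
  rownames(m) <- sprintf("FFA(%d:0)", 11:16)
  colnames(m) <- paste0("s", 1:8)
  tbl <- set_stage(wide_tbl(m), "normalized")
  auto <- preprocess_abundance(tbl, eps = 1e-6)
  hand <- tbl |>
    normalize_class_sum() |>
    transform_logit(eps = 1e-6) |>
    scale_features()
  expect_equal(auto, hand, ignore_attr = TRUE)
  expect_equal(abundance_stage(auto), "zscore")
  log_ <- attr(auto, "stage_log")
  expect_equal(log_$n_features[log_$stage == "input"], 6)
})
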