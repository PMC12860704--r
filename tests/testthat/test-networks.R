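test_that("Pearson network handles degenerate and null correlations", {
  set.seed(3)
  base <- rnorm(12)
  m <- rbind(`FFA(16:0)` = base, `FFA(18:0)` = base,      # exact duplicate
             `PC(34:1)` = rnorm(12))
  colnames(m) <- paste0("s", 1:12)
  net <- pearson_network(wide_tbl(m))
  dup <- net$edges[net$edges$from == "FFA(16:0)" &
                     net$edges$to == "FFA(18:0)", ]
  expect_equal(dup$estimate, 1)
  expect_true(is.finite(dup$p_value) && dup$p_value < 1e-10)
  expect_true(dup$significant)

  # r = 0 by construction -> z = 0, p = 1
  o <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  rownames(o) <- c("FFA(16:0)", "PC(34:1)")
  net0 <- pearson_network(wide_tbl(o))
  expect_equal(net0$edges$p_value, 1)
  expect_error(pearson_network(wide_tbl(o[, 1:3])), "n <= 3")
})

test_that("Fisher-Z p agrees with a permutation oracle on independent data", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12)
  r_obs <- cor(x, y)
  p_perm <- mean(replicate(4000, abs(cor(x, sample(y))) >= abs(r_obs)))
  m <- rbind(`FFA(16:0)` = x, `PC(34:1)` = y)
  colnames(m) <- paste0("s", 1:12)
  p_fz <- pearson_network(wide_tbl(m))$edges$p_value
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_fz - p_perm), 0.05 + 3 * mc_se)
})

test_that("Fisher-Z p is monotone in |r| and in n", {
  r <- seq(0.05, 0.95, by = 0.1)
  p <- lipidflow:::.fisher_z_p(r, 12)
  expect_true(all(diff(p) < 0))
  ns <- c(5, 10, 20, 50, 200)
  pn <- lipidflow:::.fisher_z_p(0.4, ns)
  expect_true(all(diff(pn) < 0))
})

test_that("DSPC recovers a chain graph and nulls the indirect edge", {
  x <- generate_ggm(1000, chain_precision(3, 0.45), seed = 5,
                    feature_names = c("A", "B", "C"))
  set.seed(5)
  net <- dspc_network(x)
  ed <- net$edges
  ab <- ed[ed$from == "A" & ed$to == "B", ]
  bc <- ed[ed$from == "B" & ed$to == "C", ]
  ac <- ed[ed$from == "A" & ed$to == "C", ]
  expect_true(ab$significant && bc$significant)
  expect_false(ac$significant)
  expect_equal(ab$estimate, 0.45, tolerance = 0.08)
  expect_equal(ac$estimate, 0, tolerance = 0.08)
})

test_that("DSPC converges to the sample partial correlation when n >> p", {
  x <- generate_ggm(2000, chain_precision(8, 0.3), seed = 19)
  set.seed(19)
  net <- dspc_network(x)
  m <- as.matrix(x[-1])
  prec <- solve(cov(t(m)))
  d <- sqrt(diag(prec))
  pc_sample <- -prec / outer(d, d)
  ut <- upper.tri(pc_sample)
  expect_lt(max(abs(net$edges$estimate - pc_sample[ut])), 0.05)
})

test_that("DSPC null calibration is near the nominal edge rate", {
  x <- generate_ggm(200, diag(15), seed = 23)
  set.seed(23)
  net <- dspc_network(x, alpha = 0.1)
  frac <- mean(net$edges$p_value < 0.1)
  half <- 2.58 * sqrt(0.1 * 0.9 / nrow(net$edges))
  expect_lt(abs(frac - 0.1), half)
})

test_that("group-restricted correlation blocks surface in the FFA profile", {
  ok <- 0
  for (seed in 1:10) {
    cfg <- study_config(
      seed = seed, tissues = "PM",
      panel = c(FFA = 16, TAG = 40, PC = 20, SM = 15),
      effects = NULL, missing_rate = 0,
      correlation_blocks = list(list(
        strata = c("unsaturated FFA", "unsaturated TAG",
                   "polyunsaturated TAG"),
        loading = 0.9, groups = "CKD")))
    st <- generate_study(cfg)
    conc <- quantify_areas(st$peak_areas$PM, st$standards, st$is_map)
    # standardized log concentrations: the scale the latent block acts on
    # (per-sample protein normalization would add a shared factor that the
    # full chain removes again via class-sum normalization)
    logged <- conc
    logged[-1] <- log(conc[-1])
    z <- scale_features(set_stage(logged, "normalized"))
    prof <- function(g) ffa_correlation_profile(
      select_group(z, st$samples, g), ffa_saturation = "unsaturated")
    ckd <- prof("CKD"); ctl <- prof("CTL")
    tag_ckd <- ckd[ckd$stratum == "unsaturated TAG", ]
    tag_ctl <- ctl[ctl$stratum == "unsaturated TAG", ]
    if (tag_ckd$significant && tag_ckd$r > 0 && !tag_ctl$significant) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 9)  # >= 90% of seeds
})

test_that("orthogonal classes rarely reach the |r| > 0.7 bar at n = 12", {
  set.seed(29)
  hits <- 0
  for (i in 1:60) {
    m <- rbind(matrix(rnorm(36), 3, 12), matrix(rnorm(36), 3, 12))
    rownames(m) <- c(sprintf("FFA(1%d:1)", 4:6), sprintf("PC(3%d:1)", 1:3))
    colnames(m) <- paste0("s", 1:12)
    p <- ffa_correlation_profile(wide_tbl(m), ffa_saturation = "unsaturated")
    if (abs(p$r[p$stratum == "unsaturated PC"]) >= 0.7) hits <- hits + 1
  }
  expect_lte(hits / 60, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 60))
})

test_that("edge-contingency comparison matches Fisher enumeration", {
  mk_net <- function(sig) {
    edges <- tibble::tibble(
      from = c("A", "A", "A", "B", "B", "C"),
      to   = c("B", "C", "D", "C", "D", "D"),
      estimate = 0.5, p_value = 0.5, q_value = 0.5,
      significant = sig)
    lipidflow:::.new_network(tibble::tibble(feature = c("A", "B", "C", "D")),
                             edges, "dspc", NA_character_, 10, 0.1)
  }
  na <- mk_net(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  nb <- mk_net(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  cmp <- compare_edges(na, nb)
  expect_equal(cmp$p_value, oracle_fisher(5, 1, 1, 5), tolerance = 1e-12)

  ident <- compare_edges(na, na)
  expect_equal(ident$odds_ratio, 1, tolerance = 1e-4)
  expect_equal(ident$p_value, 1)

  # balanced table -> p = 1; node filter restricts the universe
  cmp_a <- compare_edges(na, nb, nodes = "A")
  expect_equal(cmp_a$n_edges, 3)
  expect_error(compare_edges(na, nb, nodes = "Z"), "empty edge universe")
})

test_that("network export round-trips and formats are well-formed", {
  set.seed(31)
  m <- matrix(rnorm(48), 4, 12,
              dimnames = list(c("FFA(16:0)", "FFA(18:1)", "PC(34:1)",
                                "SM(36:1)"), paste0("s", 1:12)))
  net <- pearson_network(wide_tbl(m), group_label = "CTL")
  csv <- tempfile(fileext = ".csv")
  export_network(net, csv, "edge_csv")
  back <- read_network_csv(csv)
  expect_equal(back$edges, net$edges, tolerance = 1e-12)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$kind, net$kind)
  expect_equal(back$n_samples, net$n_samples)

  sif <- tempfile(fileext = ".sif")
  net3 <- net
  net3$edges$significant <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  export_network(net3, sif, "sif")
  expect_length(readLines(sif), 3)

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  expect_true(any(grepl("graphml", readLines(gml, n = 5))))

  empty <- net
  empty$edges <- net$edges[0, ]
  csv2 <- tempfile(fileext = ".csv")
  export_network(empty, csv2, "edge_csv")
  expect_equal(nrow(read_network_csv(csv2)$edges), 0)
  expect_error(export_network(net, csv, "dot"), "arg")
})
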