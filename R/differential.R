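# Group-effect inference: per-feature tests, class/subclass-level linear
# mixed models, summary-statistic t-tests, and significance accounting.

# two-level group factor with the control level first
.group_factor <- function(g, reference = NULL) {
  f <- factor(g)
  if (is.null(reference)) {
    reference <- intersect(c("CTL", "sham", "control", "WT"), levels(f))[1]
  }
  if (!is.null(reference) && !is.na(reference) && reference %in% levels(f)) {
    f <- stats::relevel(f, reference)
  }
  f
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1, order-preserving
#' with the input). Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-feature two-group tests
#'
#' Welch two-sample t-test per feature on the standardized (z-score) scale.
#' The effect is the disease-minus-reference group mean difference in SD
#' units. Significance is called on the raw p-value at `alpha` (the counting
#' rule used for feature-level tallies), with BH-adjusted values reported
#' alongside.
#'
#' @param data Z-scored abundance tibble.
#' @param samples Sample metadata with `sample_id` and `group`.
#' @param alpha Raw-p significance threshold; default 0.01.
#' @param reference Reference (control) group label; defaults to `"CTL"` or
#'   `"sham"` when present, else the first factor level.
#' @return Tibble: `feature`, `effect`, `p_value`, `q_value`, `significant`.
#' @export
test_features <- function(data, samples, alpha = 0.01, reference = NULL) {
  m <- .as_matrix(data)
  grp <- .group_factor(samples$group[match(colnames(m), samples$sample_id)],
                       reference)
  if (nlevels(grp) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(grp) < 2)) stop("each group needs n >= 2", call. = FALSE)
  ref <- levels(grp)[1]

  res <- apply(m, 1, function(x) {
    tt <- stats::t.test(x[grp != ref], x[grp == ref])
    c(effect = unname(diff(rev(tt$estimate))), p = tt$p.value)
  })
  out <- tibble::tibble(
    feature = rownames(m),
    effect = unname(res["effect", ]),
    p_value = unname(res["p", ]),
    q_value = unname(adjust_bh(res["p", ]))
  )
  out$significant <- out$p_value < alpha
  out
}

#' Class/subclass-level group-effect models
#'
#' Pools all feature-level standardized observations within a lipid class
#' (optionally split into saturation and/or chain-length strata) and fits a
#' linear mixed model: response = z-score, fixed effect = group, random
#' intercept = lipid species. This respects within-class feature correlation
#' while borrowing strength across species. A stratum with a single feature
#' degenerates to the per-feature t-test (`model = "fixed"`). P-values for
#' the group effect are Wald (normal approximation for the mixed fit);
#' BH adjustment runs across all strata tested.
#'
#' @param data Z-scored abundance tibble.
#' @param samples Sample metadata (`sample_id`, `group`).
#' @param annotation Optional annotation from [parse_lipids()].
#' @param stratify_by `"none"`, `"saturation"`, `"chain_length"` or `"both"`.
#'   Saturation splits into saturated vs unsaturated (mono + poly);
#'   chain length uses the ffa scheme.
#' @param model `"mixed"` (default) or `"fixed"` (ordinary linear model,
#'   ignoring species correlation).
#' @param reference Reference (control) group label; defaults to `"CTL"` or
#'   `"sham"` when present.
#' @return An object of class `"class_effect_fit"`. Use [tidy()] for the
#'   per-stratum table and [glance()] for a one-row summary.
#' @export
fit_class_effects <- function(data, samples, annotation = NULL,
                              stratify_by = c("saturation", "none",
                                              "chain_length", "both"),
                              model = c("mixed", "fixed"),
                              reference = NULL) {
  stratify_by <- match.arg(stratify_by)
  model <- match.arg(model)
  if (is.null(annotation)) annotation <- parse_lipids(data$feature)
  ann <- annotation[match(data$feature, annotation$feature), ]

  long <- abundance_long(data) |>
    dplyr::left_join(samples[c("sample_id", "group")], by = "sample_id") |>
    dplyr::mutate(
      class_code = ann$class_code[match(.data$feature, data$feature)],
      saturation = as.character(
        ann$saturation[match(.data$feature, data$feature)]),
      carbons = ann$total_carbons[match(.data$feature, data$feature)]
    )
  long$group <- .group_factor(long$group, reference)
  if (nlevels(long$group) != 2) stop("exactly two groups required", call. = FALSE)

  sat2 <- ifelse(long$saturation == "saturated", "saturated", "unsaturated")
  chain <- classify_chain_length(pmax(long$carbons, 2), scheme = "ffa")
  long$stratum <- switch(stratify_by,
    none = long$class_code,
    saturation = paste(sat2, long$class_code),
    chain_length = paste(chain, long$class_code),
    both = paste(sat2, chain, long$class_code)
  )

  rows <- purrr::map(split(long, long$stratum), function(d) {
    if (length(unique(d$group)) < 2) {
      warning("stratum '", d$stratum[1], "' present in one group only; skipped",
              call. = FALSE)
      return(NULL)
    }
    nf <- length(unique(d$feature))
    if (nf == 1 || model == "fixed") {
      if (nf == 1) {
        tt <- stats::t.test(value ~ group, data = d)
        est <- unname(diff(tt$estimate))  # level2 - level1 = disease - ref
        se <- tt$stderr
        p <- tt$p.value
      } else {
        fit <- stats::lm(value ~ group, data = d)
        cf <- summary(fit)$coefficients
        est <- cf[2, 1]; se <- cf[2, 2]; p <- cf[2, 4]
      }
      used <- "fixed"
    } else {
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ group + (1 | feature), data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
      cf <- summary(fit)$coefficients
      est <- cf[2, 1]; se <- cf[2, 2]
      p <- 2 * stats::pnorm(-abs(cf[2, 3]))
      used <- "mixed"
    }
    tibble::tibble(stratum = d$stratum[1], class_code = d$class_code[1],
                   effect = est, se = se, p_value = p,
                   n_features = nf, model = used)
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- adjust_bh(res$p_value)
  res <- res[order(res$p_value), ]

  structure(
    list(results = res, stratify_by = stratify_by, model = model,
         groups = levels(long$group),
         n_samples = length(unique(long$sample_id))),
    class = "class_effect_fit")
}

#' @export
#' @method print class_effect_fit
print.class_effect_fit <- function(x, ...) {
  cat(sprintf("Class-level group-effect fit (%s model, stratified by %s)\n",
              x$model, x$stratify_by))
  cat(sprintf("  effect = %s - %s on the z-score scale; %d strata, %d samples\n",
              x$groups[2], x$groups[1], nrow(x$results), x$n_samples))
  print(x$results, ...)
  invisible(x)
}

#' Tidy a class-level fit
#'
#' @param x A `"class_effect_fit"` from [fit_class_effects()].
#' @param ... Unused.
#' @return Per-stratum tibble: `stratum`, `class_code`, `effect` (group
#'   difference on the z-score scale), `se`, `p_value`, `q_value`,
#'   `n_features`, `model`.
#' @export
tidy.class_effect_fit <- function(x, ...) x$results

#' Glance at a class-level fit
#'
#' @param x A `"class_effect_fit"`.
#' @param ... Unused.
#' @return One-row tibble: strata counts, significant strata (BH q < 0.05),
#'   model and stratification.
#' @export
glance.class_effect_fit <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x$results),
    n_significant = sum(x$results$q_value < 0.05),
    model = x$model,
    stratify_by = x$stratify_by,
    n_samples = x$n_samples
  )
}

#' Effect plot for a class-level fit
#'
#' Dot-and-whisker plot of stratum effects (disease minus reference, z-score
#' scale) with 95% Wald intervals, coloured by BH significance.
#'
#' @param object A `"class_effect_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_effect_fit <- function(object, ...) {
  d <- object$results
  d$stratum <- stats::reorder(d$stratum, d$effect)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = .data$stratum,
                                  colour = .data$q_value < 0.05)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$effect - 1.96 * .data$se,
      xmax = .data$effect + 1.96 * .data$se)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey40"),
                                 name = "BH q < 0.05") +
    ggplot2::labs(x = "group effect (z-score scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Two-sample t-test from summary statistics
#'
#' For published tables reporting only n, mean and SD per group. Pooled
#' variance by default: `t = (m1 - m2) / sqrt(sp2 (1/n1 + 1/n2))` with
#' `sp2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` on
#' `n1 + n2 - 2` degrees of freedom; a Welch-Satterthwaite variant is
#' available. Vectorized over rows.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summary statistics (n >= 2,
#'   sd > 0).
#' @param variance `"pooled"` or `"welch"`.
#' @return Tibble with `t`, `df`, `p_value` (two-tailed).
#' @export
#' @examples
#' ttest_from_summary(18, 23.1, 2.8, 18, 20.3, 2.5)
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                               variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (any(n1 < 2 | n2 < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sd1 <= 0 | sd2 <= 0)) stop("standard deviations must be positive",
                                     call. = FALSE)
  if (variance == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  tibble::tibble(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Cross-tissue significance accounting
#'
#' Tallies detected and significantly altered features per tissue, the
#' percentage (one decimal), and the overlap between tissues: shared
#' detected features and features significant in both.
#'
#' @param results_a,results_b Per-feature result tibbles from
#'   [test_features()] for the two tissues.
#' @param labels Length-2 character vector of tissue labels.
#' @return Tibble with one row per tissue (`n_detected`, `n_significant`,
#'   `percent`) and attributes `n_shared_features`, `n_shared_significant`.
#' @export
summarize_significance <- function(results_a, results_b,
                                   labels = c("tissue_a", "tissue_b")) {
  per <- function(r, lab) tibble::tibble(
    tissue = lab,
    n_detected = nrow(r),
    n_significant = sum(r$significant),
    percent = round(100 * sum(r$significant) / nrow(r), 1)
  )
  out <- dplyr::bind_rows(per(results_a, labels[1]), per(results_b, labels[2]))
  shared <- intersect(results_a$feature, results_b$feature)
  sig_a <- results_a$feature[results_a$significant]
  sig_b <- results_b$feature[results_b$significant]
  attr(out, "n_shared_features") <- length(shared)
  attr(out, "n_shared_significant") <- length(intersect(sig_a, sig_b))
  out
}
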