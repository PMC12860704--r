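# The declared preprocessing chain:
# missingness filter -> KNN imputation -> TAG collapse ->
# class-wise sum normalization -> logit -> z-score.

#' Filter features by missingness
#'
#' Features are retained only when their missing fraction is strictly below
#' `max_missing` ("below 50%" is read literally: exactly half missing is
#' dropped). When sample metadata with several tissues is supplied, the
#' fraction is computed within each tissue and a feature must pass in every
#' tissue, since detected panels differ between e.g. plasma and macrophages.
#'
#' @param data Abundance tibble at stage `"concentration"` or `"normalized"`.
#' @param samples Optional sample metadata (`sample_id`, `tissue`).
#' @param max_missing Missing-fraction threshold in (0, 1]; default 0.5.
#' @return Filtered tibble; the attribute `"dropped_features"` records the
#'   dropped features and their worst-tissue missing fraction.
#' @export
filter_missing <- function(data, samples = NULL, max_missing = 0.5) {
  stopifnot(is.data.frame(data), "feature" %in% names(data))
  if (!is.numeric(max_missing) || max_missing <= 0 || max_missing > 1) {
    stop("`max_missing` must be in (0, 1]", call. = FALSE)
  }
  m <- .as_matrix(data)
  scol <- colnames(m)
  tissue <- if (is.null(samples)) rep("all", length(scol)) else {
    samples$tissue[match(scol, samples$sample_id)]
  }
  frac <- vapply(split(seq_along(scol), tissue), function(idx) {
    rowMeans(is.na(m[, idx, drop = FALSE]))
  }, numeric(nrow(m)))
  if (!is.matrix(frac)) frac <- matrix(frac, nrow = nrow(m))
  worst <- apply(frac, 1, max)
  keep <- worst < max_missing

  out <- data[keep, , drop = FALSE]
  attr(out, "stage") <- attr(data, "stage")
  attr(out, "dropped_features") <- tibble::tibble(
    feature = data$feature[!keep], missing_fraction = unname(worst[!keep]))
  out
}

#' K-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean value, in that sample, of the
#' `k` nearest features. Nearness is root-mean-square Euclidean distance
#' between per-feature standardized profiles over pairwise co-observed
#' samples; only features observed in the target sample are candidate
#' neighbours. A feature with no usable neighbour falls back to its own
#' observed median (with a warning). Observed cells are never altered.
#'
#' @param data Abundance tibble; every feature should already pass the
#'   missingness filter.
#' @param k Number of neighbours (default 10, capped at the number of
#'   available candidates).
#' @return Tibble with no missing cells, same stage.
#' @export
impute_knn <- function(data, k = 10) {
  stopifnot(is.data.frame(data), "feature" %in% names(data), k >= 1)
  m <- .as_matrix(data)
  if (!anyNA(m)) return(data)
  if (k >= nrow(m)) stop("`k` must be smaller than the number of features",
                         call. = FALSE)

  mu <- rowMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 1, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  z <- (m - mu) / sd_

  imputed <- m
  fallback <- character()
  na_rows <- which(rowSums(is.na(m)) > 0)
  for (i in na_rows) {
    # rms distance to every other feature over co-observed samples
    diff2 <- sweep(z, 2, z[i, ], `-`)^2
    nshared <- rowSums(!is.na(diff2))
    d <- sqrt(rowSums(diff2, na.rm = TRUE) / nshared)
    d[i] <- Inf
    d[nshared == 0] <- Inf
    for (s in which(is.na(m[i, ]))) {
      cand <- which(is.finite(d) & !is.na(m[, s]))
      if (!length(cand)) {
        imputed[i, s] <- stats::median(m[i, ], na.rm = TRUE)
        fallback <- c(fallback, rownames(m)[i])
        next
      }
      nn <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      imputed[i, s] <- mean(m[nn, s])
    }
  }
  if (length(fallback)) {
    warning("median fallback for feature(s) without co-observed neighbours: ",
            paste(unique(fallback), collapse = ", "), call. = FALSE)
  }
  .from_matrix(imputed, data)
}

#' Class-wise sum normalization
#'
#' Divides each lipid's abundance by the total abundance of its class within
#' the same sample, yielding class fractions in \[0, 1\] that sum to 1 per
#' class per sample. Scale-invariant: rescaling a sample's class block leaves
#' its fractions unchanged.
#'
#' @param data Abundance tibble at stage `"normalized"`, no missing cells.
#' @param annotation Optional annotation from [parse_lipids()].
#' @return Class-fraction tibble, stage `"class_fraction"`.
#' @export
normalize_class_sum <- function(data, annotation = NULL) {
  stopifnot(is.data.frame(data), "feature" %in% names(data))
  m <- .as_matrix(data)
  if (anyNA(m)) stop("missing cells present; impute before sum normalization",
                     call. = FALSE)
  if (is.null(annotation)) annotation <- parse_lipids(data$feature)
  cls <- annotation$class_code[match(data$feature, annotation$feature)]

  totals <- rowsum(m, cls)
  if (any(totals == 0)) {
    bad <- which(totals == 0, arr.ind = TRUE)
    stop(sprintf("class '%s' sums to zero in sample '%s'",
                 rownames(totals)[bad[1, 1]], colnames(totals)[bad[1, 2]]),
         call. = FALSE)
  }
  frac <- m / totals[cls, , drop = FALSE]
  out <- .from_matrix(frac, data)
  .advance_stage(out, c("normalized", NA), "class_fraction")
}

#' Logit transformation of class fractions
#'
#' `log(p / (1 - p))` after clamping `p` into `[eps, 1 - eps]` so singleton
#' classes (fraction exactly 1) stay finite. The default `eps` is half the
#' smallest nonzero fraction in the table, floored at 1e-6 — data-adaptive
#' and monotone.
#'
#' @param data Class-fraction tibble (stage `"class_fraction"`).
#' @param eps Clamp width; `NULL` for the adaptive default.
#' @return Logit-scale tibble, stage `"logit"`.
#' @export
transform_logit <- function(data, eps = NULL) {
  m <- .as_matrix(data)
  if (is.null(eps)) {
    nz <- m[!is.na(m) & m > 0]
    eps <- if (length(nz)) max(min(nz) / 2, 1e-6) else 1e-6
  }
  stopifnot(eps > 0, eps < 0.5)
  p <- pmin(pmax(m, eps), 1 - eps)
  out <- .from_matrix(log(p / (1 - p)), data)
  .advance_stage(out, "class_fraction", "logit")
}

#' Per-feature z-score standardization
#'
#' Centres and scales each feature across samples using the sample (n-1)
#' standard deviation. Features constant across samples (zero SD, e.g. a
#' singleton class clamped at both ends) carry no information and are
#' dropped with a warning.
#'
#' @param data Abundance tibble, typically at stage `"logit"`.
#' @return Standardized tibble, stage `"zscore"`.
#' @export
scale_features <- function(data) {
  m <- .as_matrix(data)
  if (anyNA(m)) stop("missing cells present; impute before z-scoring",
                     call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (m - rowMeans(m)) / sds
  out <- .from_matrix(z, data)
  .advance_stage(out, c("logit", "class_fraction", "normalized", NA), "zscore")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: missingness filter, KNN imputation, TAG isotopomer
#' collapse, class-wise sum normalization, logit transformation, z-scoring.
#' The chain is deterministic. Per-stage feature counts are recorded in the
#' `"stage_log"` attribute.
#'
#' @param data Abundance tibble at stage `"normalized"` (use
#'   [quantify_areas()] and [normalize_samples()] first).
#' @param samples Optional sample metadata for within-tissue missingness.
#' @param max_missing,k,eps Stage parameters; see the individual verbs.
#' @return Z-scored tibble, stage `"zscore"`, with `"stage_log"` and
#'   `"tag_mapping"` attributes.
#' @export
preprocess_abundance <- function(data, samples = NULL, max_missing = 0.5,
                                 k = 10, eps = NULL) {
  log_ <- list()
  note <- function(x, stage) {
    log_[[length(log_) + 1]] <<- tibble::tibble(stage = stage,
                                                n_features = nrow(x))
    x
  }
  out <- data |>
    note("input") |>
    filter_missing(samples, max_missing) |> note("filtered") |>
    impute_knn(k = min(k, max(1, nrow(data) - 1))) |>
    collapse_tag_isotopomers() |> note("tag_collapsed")
  mapping <- attr(out, "tag_mapping")
  out <- out |>
    normalize_class_sum() |>
    transform_logit(eps = eps) |>
    scale_features() |> note("zscore")
  attr(out, "stage_log") <- dplyr::bind_rows(log_)
  attr(out, "tag_mapping") <- mapping
  out
}
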