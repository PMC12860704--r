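# Correlation networks: marginal Pearson/Fisher-Z/BH and debiased sparse
# partial correlation (DSPC), plus group comparison and file export.

.new_network <- function(nodes, edges, kind, group_label, n_samples,
                         alpha, r_min = NA_real_) {
  structure(
    list(nodes = nodes, edges = edges, kind = kind,
         group_label = group_label, n_samples = n_samples,
         alpha = alpha, r_min = r_min),
    class = "lipid_network")
}

#' @export
#' @method print lipid_network
print.lipid_network <- function(x, ...) {
  cat(sprintf("<lipid_network: %s%s, %d nodes, %d edges (%d significant), n = %d>\n",
              x$kind,
              if (is.na(x$group_label)) "" else paste0(" / ", x$group_label),
              nrow(x$nodes), nrow(x$edges), sum(x$edges$significant),
              x$n_samples))
  invisible(x)
}

#' Tidy a lipid network
#'
#' @param x A `"lipid_network"`.
#' @param ... Unused.
#' @return The edge tibble: `from`, `to`, `estimate`, `p_value`, `q_value`,
#'   `significant`.
#' @export
tidy.lipid_network <- function(x, ...) x$edges

#' Glance at a lipid network
#'
#' @param x A `"lipid_network"`.
#' @param ... Unused.
#' @return One-row tibble of node/edge counts and the significance rule.
#' @export
glance.lipid_network <- function(x, ...) {
  tibble::tibble(kind = x$kind, group = x$group_label,
                 n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_significant = sum(x$edges$significant),
                 n_samples = x$n_samples, alpha = x$alpha, r_min = x$r_min)
}

#' Plot a lipid network
#'
#' Significant edges drawn on a Fruchterman-Reingold layout, coloured by the
#' sign of the (partial) correlation.
#'
#' @param object A `"lipid_network"`.
#' @param significant_only Drop non-significant edges (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lipid_network <- function(object, significant_only = TRUE, ...) {
  ed <- object$edges
  if (significant_only) ed <- ed[ed$significant, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[c("from", "to")], directed = FALSE,
    vertices = object$nodes$feature)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nd <- tibble::tibble(feature = object$nodes$feature,
                       x = xy[, 1], y = xy[, 2])
  ed2 <- ed |>
    dplyr::left_join(nd, by = c(from = "feature")) |>
    dplyr::left_join(nd, by = c(to = "feature"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed2,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$estimate > 0),
      alpha = 0.6) +
    ggplot2::geom_point(data = nd, ggplot2::aes(.data$x, .data$y),
                        size = 2, colour = "grey30") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "#2166AC"),
                                 name = "positive") +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s network%s", object$kind,
                                  if (is.na(object$group_label)) "" else
                                    paste0(" - ", object$group_label)))
}

# Fisher-Z two-tailed p for a Pearson r at sample size n
.fisher_z_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r) * sqrt(n - 3)
  pmax(2 * stats::pnorm(-abs(z)), 1e-300)  # keep p in (0, 1] for BH
}

#' Marginal Pearson correlation network
#'
#' Scores every unordered feature pair with the Pearson correlation; tests
#' each against zero via the Fisher Z-transformation (`z = atanh(r)`,
#' standard error `1/sqrt(n - 3)`, two-tailed normal p); adjusts across all
#' pairs with Benjamini-Hochberg. An edge is significant when the adjusted
#' p-value is below `alpha` AND `|r|` exceeds `r_min` (the conjunctive
#' reporting rule).
#'
#' @param data Z-scored abundance tibble (features x samples); rows become
#'   network nodes.
#' @param group_label Optional label for the network (e.g. `"CKD"`).
#' @param alpha BH-adjusted significance level; default 0.05.
#' @param r_min Absolute-correlation floor for significance; default 0.7.
#' @return A `"lipid_network"` of kind `"pearson"`.
#' @export
pearson_network <- function(data, group_label = NA_character_,
                            alpha = 0.05, r_min = 0.7) {
  m <- .as_matrix(data)
  n <- ncol(m)
  if (n <= 3) stop("Fisher Z undefined for n <= 3 samples", call. = FALSE)
  keep <- apply(m, 1, stats::sd) > 0
  if (!all(keep)) {
    warning("excluding constant feature(s): ",
            paste(rownames(m)[!keep], collapse = ", "), call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  cm <- stats::cor(t(m))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  p <- .fisher_z_p(r, n)
  q <- adjust_bh(p)
  edges <- tibble::tibble(
    from = rownames(cm)[ut[, 1]], to = rownames(cm)[ut[, 2]],
    estimate = r, p_value = p, q_value = q,
    significant = q < alpha & abs(r) > r_min)
  .new_network(tibble::tibble(feature = rownames(cm)), edges, "pearson",
               group_label, n, alpha, r_min)
}

#' Debiased sparse partial correlation (DSPC) network
#'
#' High-dimensional partial-correlation inference via the desparsified
#' nodewise lasso: each feature is lasso-regressed on all others (penalty
#' chosen per node by k-fold cross-validation), the relaxed inverse-
#' covariance estimate is assembled from the nodewise coefficients, and a
#' de-biasing correction restores asymptotically normal entries, giving an
#' estimate, standard error and p-value for every edge even when the number
#' of features exceeds the number of samples. Edges with `p < alpha` are
#' flagged significant. Symmetry is enforced by construction of the
#' debiased estimator.
#'
#' @param data Z-scored abundance tibble (features x samples).
#' @param group_label Optional label.
#' @param alpha Per-edge p-value threshold; default 0.1 (the conventional
#'   liberal threshold for exploratory network contrasts).
#' @param nfolds Cross-validation folds for the per-node penalty; default 10.
#' @return A `"lipid_network"` of kind `"dspc"`, with `estimate` the
#'   debiased partial correlation.
#' @export
dspc_network <- function(data, group_label = NA_character_, alpha = 0.1,
                         nfolds = 10) {
  m <- .as_matrix(data)
  p_ <- nrow(m)
  n <- ncol(m)
  if (n < 6) stop("DSPC needs at least 6 samples", call. = FALSE)
  if (p_ < 3) stop("DSPC needs at least 3 features", call. = FALSE)
  keep <- apply(m, 1, stats::sd) > 0
  if (!all(keep)) {
    warning("excluding constant feature(s): ",
            paste(rownames(m)[!keep], collapse = ", "), call. = FALSE)
    m <- m[keep, , drop = FALSE]
    p_ <- nrow(m)
  }

  X <- scale(t(m))                       # n x p, columns standardized
  feats <- rownames(m)
  Sigma <- crossprod(X) / n

  Theta <- matrix(0, p_, p_)
  for (j in seq_len(p_)) {
    cv <- glmnet::cv.glmnet(X[, -j, drop = FALSE], X[, j],
                            nfolds = min(nfolds, n), standardize = FALSE,
                            intercept = FALSE, grouped = n >= 3 * min(nfolds, n))
    lam <- cv$lambda.min
    gam <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    resid <- X[, j] - X[, -j, drop = FALSE] %*% gam
    tau2 <- sum(resid^2) / n + lam * sum(abs(gam))
    Theta[j, j] <- 1 / tau2
    Theta[j, -j] <- -gam / tau2
  }

  # de-biased (desparsified) precision estimate, symmetric by construction
  Tm <- Theta + t(Theta) - t(Theta) %*% Sigma %*% Theta
  dT <- pmax(diag(Tm), 1e-12)
  pcor <- -Tm / sqrt(outer(dT, dT))
  diag(pcor) <- 1
  pcor <- pmin(pmax(pcor, -1), 1)

  # asymptotic variance of precision entries: (T_ii T_jj + T_ij^2) / n
  se <- sqrt((outer(dT, dT) + Tm^2) / n)
  z <- Tm / se
  pmat <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)

  ut <- which(upper.tri(Tm), arr.ind = TRUE)
  pv <- pmat[ut]
  edges <- tibble::tibble(
    from = feats[ut[, 1]], to = feats[ut[, 2]],
    estimate = pcor[ut], p_value = pv, q_value = adjust_bh(pv),
    significant = pv < alpha)
  .new_network(tibble::tibble(feature = feats), edges, "dspc",
               group_label, n, alpha)
}

#' Correlation profile of an FFA stratum against other lipid classes
#'
#' Averages standardized feature levels within each saturation-by-class
#' stratum, then correlates the chosen free-fatty-acid stratum (saturated or
#' unsaturated) with every other stratum. Significance follows the marginal
#' rule: BH-adjusted Fisher-Z p below `alpha` and `|r|` above `r_min`.
#'
#' @param data Z-scored abundance tibble.
#' @param annotation Optional annotation from [parse_lipids()].
#' @param ffa_saturation `"unsaturated"` (default) or `"saturated"`.
#' @param alpha,r_min Significance rule; defaults 0.05 and 0.7.
#' @param level `"class_mean"` (default) correlates stratum means;
#'   `"feature"` correlates the FFA stratum mean with individual features.
#' @return Tibble: `stratum`, `r`, `p_value`, `q_value`, `significant`.
#' @export
ffa_correlation_profile <- function(data, annotation = NULL,
                                    ffa_saturation = c("unsaturated",
                                                       "saturated"),
                                    alpha = 0.05, r_min = 0.7,
                                    level = c("class_mean", "feature")) {
  ffa_saturation <- match.arg(ffa_saturation)
  level <- match.arg(level)
  if (is.null(annotation)) annotation <- parse_lipids(data$feature)
  ann <- annotation[match(data$feature, annotation$feature), ]
  m <- .as_matrix(data)
  n <- ncol(m)
  if (n <= 3) stop("Fisher Z undefined for n <= 3 samples", call. = FALSE)

  sat2 <- ifelse(as.character(ann$saturation) == "saturated",
                 "saturated", "unsaturated")
  stratum <- paste(sat2, ann$class_code)
  means <- rowsum(m, stratum) / as.vector(table(stratum)[sort(unique(stratum))])

  ffa_name <- paste(ffa_saturation, "FFA")
  if (!ffa_name %in% rownames(means)) {
    stop(sprintf("no '%s' features in the panel", ffa_name), call. = FALSE)
  }
  ref <- means[ffa_name, ]

  targets <- if (level == "class_mean") {
    means[setdiff(rownames(means), ffa_name), , drop = FALSE]
  } else {
    m[stratum != ffa_name, , drop = FALSE]
  }
  r <- as.vector(stats::cor(ref, t(targets)))
  p <- .fisher_z_p(r, n)
  q <- adjust_bh(p)
  tibble::tibble(
    stratum = rownames(targets), r = r, p_value = p, q_value = q,
    significant = q < alpha & abs(r) > r_min)
}

#' Compare significant-edge frequencies between two networks
#'
#' Builds the 2x2 contingency table of significant versus non-significant
#' edges in each network over a common edge universe — by default every
#' candidate pair incident to the supplied node set that is present in both
#' networks — and applies a two-sided Fisher exact test. An odds ratio below
#' 1 for (network A vs B) means network A has proportionally fewer
#' significant edges (e.g. a loss of interactions in disease).
#'
#' @param net_a,net_b Two `"lipid_network"` objects built on the same
#'   feature universe (typically the two study groups).
#' @param nodes Optional character vector restricting the universe to edges
#'   incident to these nodes (e.g. the unsaturated FFA features).
#' @return One-row tibble: counts `sig_a`, `nonsig_a`, `sig_b`, `nonsig_b`,
#'   `odds_ratio` (conditional MLE), `p_value`, `n_edges` in the universe.
#' @export
compare_edges <- function(net_a, net_b, nodes = NULL) {
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "|")
  ea <- net_a$edges; eb <- net_b$edges
  common <- intersect(key(ea), key(eb))
  if (!is.null(nodes)) {
    ka <- key(ea)
    inc <- ka[ea$from %in% nodes | ea$to %in% nodes]
    common <- intersect(common, inc)
  }
  if (!length(common)) stop("empty edge universe after filtering",
                            call. = FALSE)
  sa <- ea$significant[match(common, key(ea))]
  sb <- eb$significant[match(common, key(eb))]
  tab <- matrix(c(sum(sa), sum(!sa), sum(sb), sum(!sb)), nrow = 2,
                dimnames = list(c("significant", "non_significant"),
                                c(net_a$group_label, net_b$group_label)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble::tibble(
    sig_a = sum(sa), nonsig_a = sum(!sa),
    sig_b = sum(sb), nonsig_b = sum(!sb),
    odds_ratio = unname(ft$estimate), p_value = ft$p.value,
    n_edges = length(common))
}

#' Export a network to file
#'
#' `edge_csv` is lossless (metadata and node list travel in `#` header
#' lines; [read_network_csv()] restores an identical object). `sif` writes
#' one significant edge per line for Cytoscape-style tools; `graphml`
#' carries all edge attributes.
#'
#' @param net A `"lipid_network"`.
#' @param path Output file path.
#' @param format `"edge_csv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_csv", "sif",
                                                 "graphml")) {
  format <- match.arg(format)
  if (format == "edge_csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# kind: %s", net$kind),
      sprintf("# group_label: %s", net$group_label),
      sprintf("# n_samples: %d", net$n_samples),
      sprintf("# alpha: %.17g", net$alpha),
      sprintf("# r_min: %.17g", net$r_min),
      sprintf("# nodes: %s", paste(net$nodes$feature, collapse = ";"))
    ), con)
    utils::write.csv(as.data.frame(net$edges), con, row.names = FALSE)
  } else if (format == "sif") {
    ed <- net$edges[net$edges$significant, , drop = FALSE]
    writeLines(sprintf("%s\t%s\t%s", ed$from, net$kind, ed$to), path)
  } else {
    g <- igraph::graph_from_data_frame(
      as.data.frame(net$edges), directed = FALSE,
      vertices = net$nodes$feature)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from edge-CSV
#'
#' @param path File written by [export_network()] with `format = "edge_csv"`.
#' @return The restored `"lipid_network"`.
#' @export
read_network_csv <- function(path) {
  hdr <- readLines(path)
  hdr <- hdr[startsWith(hdr, "# ")]
  get <- function(k) sub(sprintf("^# %s: ", k), "",
                         hdr[startsWith(hdr, sprintf("# %s:", k))])
  edges <- tibble::as_tibble(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
  edges$significant <- as.logical(edges$significant)
  gl <- get("group_label")
  .new_network(
    tibble::tibble(feature = strsplit(get("nodes"), ";", fixed = TRUE)[[1]]),
    edges, get("kind"), if (gl == "NA") NA_character_ else gl,
    as.integer(get("n_samples")), as.numeric(get("alpha")),
    as.numeric(get("r_min")))
}
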