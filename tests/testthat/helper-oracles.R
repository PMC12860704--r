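# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# KNN imputation by full enumeration: standardize features, rms distance
# over co-observed samples, average the k nearest observed neighbours.
oracle_knn <- function(m, k) {
  mu <- apply(m, 1, mean, na.rm = TRUE)
  sd_ <- apply(m, 1, sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  z <- sweep(sweep(m, 1, mu, "-"), 1, sd_, "/")
  out <- m
  for (i in seq_len(nrow(m))) for (s in seq_len(ncol(m))) {
    if (!is.na(m[i, s])) next
    d <- rep(Inf, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i || is.na(m[j, s])) next
      shared <- which(!is.na(z[i, ]) & !is.na(z[j, ]))
      if (!length(shared)) next
      d[j] <- sqrt(mean((z[i, shared] - z[j, shared])^2))
    }
    cand <- which(is.finite(d))
    if (!length(cand)) {
      out[i, s] <- median(m[i, ], na.rm = TRUE)
    } else {
      nn <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      out[i, s] <- mean(m[nn, s])
    }
  }
  out
}

# BH step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (same "at most as probable" rule as fisher.test)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

edge_key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))

# small wide abundance tibble from a matrix
wide_tbl <- function(m, stage = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  out <- dplyr::bind_cols(tibble::tibble(feature = rownames(m)),
                          tibble::as_tibble(as.data.frame(m)))
  if (!is.null(stage)) out <- set_stage(out, stage)
  out
}

# minimal two-group sample sheet for n per group
two_group_samples <- function(ids, n_per_group = length(ids) / 2) {
  tibble::tibble(sample_id = ids,
                 group = rep(c("CTL", "CKD"), each = n_per_group),
                 tissue = "PM", protein_mass = 100, volume = NA_real_)
}
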