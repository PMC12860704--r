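# Synthetic-study generator: emulates a two-group targeted-lipidomics study
# (disease vs control; plasma + peritoneal macrophages) with class-level
# effect directions, abundance-dependent missingness, latent correlation
# blocks, acylcarnitine ratio shifts, isotopomer distributions and qPCR
# tables, so the whole analysis is testable without any external data.

# --- fixed panel pieces ------------------------------------------------------

.FFA_SPECIES <- c("12:0", "14:0", "14:1", "16:0", "16:1", "18:0", "18:1",
                  "18:2", "18:3", "20:0", "20:4", "20:5", "22:0", "22:6",
                  "24:0", "24:1")

.AC_SPECIES <- c("2:0", "3:0", "4:0", "4:1", "5:0", "6:0", "6:1", "8:0",
                 "8:1", "10:0", "10:1", "10:2", "12:0", "12:1", "14:0",
                 "14:1", "14:2", "16:0", "16:1", "16:2", "16:3", "18:0",
                 "18:1", "18:2", "18:3", "20:0", "20:1", "20:2", "20:4")

.SN_POOL <- c("FA14:0", "FA16:0", "FA16:1", "FA18:0", "FA18:1", "FA18:2",
              "FA20:4")

# targeted-panel class sizes (generator defaults, not validation constraints)
.PANEL_SIZES <- c(
  CE = 19, MAG = 1, DAG = 39, TAG = 445, FFA = 16, PC = 65, PE = 47,
  `PE-O` = 19, `PE-P` = 41, PI = 22, PG = 24, LPC = 11, PS = 26, LPS = 1,
  LPE = 10, SM = 27, HCER = 9, LCER = 6, DCER = 6, CER = 10, AC = 29
)

# carbon ranges used to invent plausible species per class
.CLASS_CARBONS <- list(
  CE = seq(14, 24, 2), MAG = 16:18, DAG = seq(28, 40, 2),
  PC = seq(30, 44, 2), PE = seq(30, 44, 2), `PE-O` = seq(32, 44, 2),
  `PE-P` = seq(32, 44, 2), PI = seq(32, 42, 2), PG = seq(30, 44, 2),
  LPC = seq(14, 24, 2), PS = seq(32, 44, 2), LPS = 18, LPE = seq(16, 24, 2),
  SM = seq(30, 44, 2), HCER = seq(32, 42, 2), LCER = seq(32, 42, 2),
  DCER = seq(32, 42, 2), CER = seq(32, 42, 2)
)

.default_effects <- function(shift = 0.8) {
  tibble::tribble(
    ~tissue,  ~class_code, ~saturation,   ~shift,
    "PM",     "FFA",       "saturated",    shift,
    "PM",     "FFA",       "unsaturated", -shift,
    "PM",     "PG",        "all",          shift,
    "PM",     "PE",        "all",          shift,
    "PM",     "PE-O",      "saturated",    shift,
    "PM",     "PE-P",      "saturated",    shift,
    "PM",     "PE-O",      "unsaturated", -shift,
    "PM",     "PE-P",      "unsaturated", -shift,
    "PM",     "TAG",       "all",         -shift,
    "PM",     "DAG",       "all",         -shift,
    "PM",     "SM",        "all",         -shift,
    "PM",     "PC",        "all",         -shift,
    "plasma", "PG",        "all",          shift,
    "plasma", "PE",        "all",          shift,
    "plasma", "PC",        "all",          shift,
    "plasma", "FFA",       "saturated",   -shift,
    "plasma", "FFA",       "unsaturated",  shift,
    "plasma", "TAG",       "all",          shift
  )
}

#' Synthetic study configuration
#'
#' Defaults encode the emulated design: two groups (CTL, CKD) of 12, plasma
#' and peritoneal macrophage (PM) panels of ~900 features across 21 classes
#' (TAG as 445 isotopomers over 95 compositions), class/saturation-stratum
#' effect directions mirroring the disease phenotype (e.g. saturated FFA up
#' and unsaturated FFA down in macrophages), abundance-dependent
#' missingness, a latent correlation block linking unsaturated FFA and TAG
#' in the control group only (emulating a loss of lipid interactions in
#' disease), a reduced long-to-intermediate acylcarnitine ratio in disease,
#' equal-by-group deuterium enrichment, and a 5-fold disease induction of
#' Acsl1 with 2-fold inflammatory cytokines.
#'
#' @param seed Integer RNG seed; identical configs give identical studies.
#' @param n_per_group Samples per group per tissue (default 12).
#' @param tissues Character subset of `c("PM", "plasma", "liver")`.
#' @param panel Named integer vector of features per class.
#' @param effects Tibble (`tissue`, `class_code`, `saturation`
#'   in `"saturated"`/`"unsaturated"`/`"all"`, `shift` in SD units) of
#'   programmed group effects on the log-concentration scale; `NULL` for no
#'   effects.
#' @param effect_size Magnitude used by the default effect map (SD units).
#' @param missing_rate Target overall missing-cell fraction (default 0.05).
#' @param missing_mechanism `"abundance_dependent"` (logistic in mean log
#'   concentration, emulating limit-of-detection censoring) or `"MCAR"`.
#' @param correlation_blocks List of blocks, each
#'   `list(strata = c("unsaturated FFA", ...), loading = , groups = )`;
#'   `NULL` for none; `"default"` for the control-only FFA-TAG block.
#' @param sigma Biological log-scale SD of each feature (default 0.4).
#' @param ac_ratio_shift Multiplier applied to long-chain acylcarnitines in
#'   the disease group (default 0.7, i.e. a 30% ratio reduction).
#' @param dnl_enrichment Named per-tissue total palmitate enrichment
#'   (defaults plasma 0.15, PM 0.10, liver 0.25; equal across groups).
#' @param dnl_n,ct_n Mice per group for the labelling and qPCR arms.
#' @param ct_fold_changes Named disease-vs-control fold changes for the
#'   qPCR arm.
#' @param ct_noise_sd SD of Ct technical noise (cycles); 0 gives exact
#'   fold-change recovery.
#' @param plasma_detect_fraction Fraction of the panel detected in plasma.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L, n_per_group = 12L,
                         tissues = c("PM", "plasma"),
                         panel = .PANEL_SIZES,
                         effects = "default",
                         effect_size = 0.8,
                         missing_rate = 0.05,
                         missing_mechanism = c("abundance_dependent", "MCAR"),
                         correlation_blocks = "default",
                         sigma = 0.4,
                         ac_ratio_shift = 0.7,
                         dnl_enrichment = c(plasma = 0.15, PM = 0.10,
                                            liver = 0.25),
                         dnl_n = 5L, ct_n = 6L,
                         ct_fold_changes = c(Acsl1 = 5, Acsl3 = 1, Acsl4 = 1,
                                             Acsl5 = 1, Acsl6 = 1, Il1b = 2,
                                             Il6 = 2, Tnf = 2),
                         ct_noise_sd = 0.15,
                         plasma_detect_fraction = 0.75) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (identical(effects, "default")) effects <- .default_effects(effect_size)
  if (identical(correlation_blocks, "default")) {
    correlation_blocks <- list(list(
      strata = c("unsaturated FFA", "unsaturated TAG", "polyunsaturated TAG"),
      loading = 0.9, groups = "CTL"))
  }
  stopifnot(n_per_group >= 2, all(panel > 0), sigma > 0,
            missing_rate >= 0, missing_rate < 0.5)
  structure(list(
    seed = as.integer(seed), n_per_group = as.integer(n_per_group),
    tissues = tissues, panel = panel, effects = effects,
    missing_rate = missing_rate, missing_mechanism = missing_mechanism,
    correlation_blocks = correlation_blocks, sigma = sigma,
    ac_ratio_shift = ac_ratio_shift, dnl_enrichment = dnl_enrichment,
    dnl_n = as.integer(dnl_n), ct_n = as.integer(ct_n),
    ct_fold_changes = ct_fold_changes, ct_noise_sd = ct_noise_sd,
    plasma_detect_fraction = plasma_detect_fraction),
    class = "study_config")
}

# deterministic panel construction (no RNG): species per class in a fixed
# (double-bond, carbon) order so every class has saturated members
.build_panel <- function(panel) {
  rows <- list()
  for (cls in names(panel)) {
    n <- panel[[cls]]
    if (cls == "FFA") {
      sp <- .FFA_SPECIES[seq_len(min(n, length(.FFA_SPECIES)))]
      nm <- sprintf("FFA(%s)", sp)
    } else if (cls == "AC") {
      sp <- .AC_SPECIES[seq_len(min(n, length(.AC_SPECIES)))]
      nm <- sprintf("AC(%s)", sp)
    } else if (cls == "TAG") {
      # 95 compositions; db cycles fastest so truncated panels stay mixed
      grid <- expand.grid(db = 0:4, cc = seq(44, 62, 1))
      sizes <- rep(4L, nrow(grid))
      extra <- n - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      nm <- unlist(Map(function(cc, db, k) {
        sprintf("TAG%d:%d-%s", cc, db, .SN_POOL[seq_len(k)])
      }, grid$cc, grid$db, sizes))
      nm <- nm[seq_len(n)]
    } else {
      ccs <- .CLASS_CARBONS[[cls]]
      if (is.null(ccs)) ccs <- seq(30, 44, 2)
      grid <- expand.grid(cc = ccs, db = 0:8)
      grid <- grid[order(grid$db, grid$cc), ]
      grid <- grid[seq_len(min(n, nrow(grid))), ]
      nm <- if (cls %in% c("PE-O", "PE-P")) {
        sprintf("PE(%s-%d:%d)", substr(cls, 4, 4), grid$cc, grid$db)
      } else {
        sprintf("%s(%d:%d)", cls, grid$cc, grid$db)
      }
    }
    rows[[cls]] <- nm
  }
  feats <- unlist(rows, use.names = FALSE)
  parse_lipids(feats)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# logistic LOD-style per-feature missingness, calibrated to the target rate
.missing_probs <- function(mu_logc, rate, mechanism) {
  if (rate <= 0) return(rep(0, length(mu_logc)))
  if (mechanism == "MCAR") return(rep(rate, length(mu_logc)))
  s <- max(stats::sd(mu_logc), 1e-8) * 0.5
  f <- function(lod) mean(stats::plogis((lod - mu_logc) / s)) - rate
  lod <- stats::uniroot(f, c(min(mu_logc) - 20 * s, max(mu_logc) + 20 * s))$root
  pmin(stats::plogis((lod - mu_logc) / s), 0.45)
}

#' Generate a complete synthetic study
#'
#' Draws log-normal concentrations per feature with class-level baselines
#' spanning ~3 orders of magnitude, applies the programmed group shifts on
#' the log scale, injects latent-factor correlation blocks (optionally in
#' one group only), back-computes vendor-style peak areas through the
#' internal-standard relation (so [quantify_areas()] inverts the generator
#' to machine precision), censors cells per the missingness mechanism, and
#' emits acylcarnitine, isotopomer and qPCR tables with programmed truths.
#'
#' @param config A [study_config()].
#' @return A list: `peak_areas` (named list of wide tibbles per tissue),
#'   `standards`, `is_map`, `samples`, `annotation`, `ac_profiles`,
#'   `isotopomers`, `ct`, `truth` (programmed concentrations and effect
#'   parameters), and `config`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  ann_all <- .build_panel(config$panel)
  lip_ann <- ann_all[ann_all$class_code != "AC", ]

  # class geometric means span ~3 decades; per-feature baseline around them
  classes <- unique(lip_ann$class_code)
  class_mu <- stats::setNames(stats::runif(length(classes), 0, log(1000)),
                              classes)
  base_mu <- class_mu[lip_ann$class_code] +
    stats::rnorm(nrow(lip_ann), 0, 0.8)

  sat2 <- ifelse(as.character(lip_ann$saturation) == "saturated",
                 "saturated", "unsaturated")
  stratum2 <- paste(sat2, lip_ann$class_code)
  stratum3 <- paste(as.character(lip_ann$saturation), lip_ann$class_code)

  samples <- list(); peak_areas <- list(); truth_conc <- list()
  standards <- list()
  is_map <- tibble::tibble(class_code = classes,
                           is_id = paste0("IS_", classes))
  lipid_tissues <- intersect(config$tissues, c("PM", "plasma"))

  for (tis in lipid_tissues) {
    keep <- rep(TRUE, nrow(lip_ann))
    if (tis == "plasma" && config$plasma_detect_fraction < 1) {
      keep <- stats::runif(nrow(lip_ann)) < config$plasma_detect_fraction
      keep[lip_ann$class_code == "FFA"] <- TRUE  # keep the focal class intact
    }
    ann <- lip_ann[keep, ]
    nf <- nrow(ann)
    ids <- c(sprintf("%s_CTL_%02d", tis, seq_len(config$n_per_group)),
             sprintf("%s_CKD_%02d", tis, seq_len(config$n_per_group)))
    grp <- rep(c("CTL", "CKD"), each = config$n_per_group)
    ns <- length(ids)

    # programmed shift per feature (SD units on the log scale)
    shift <- rep(0, nf)
    eff <- config$effects
    if (!is.null(eff) && nrow(eff)) {
      eff_t <- eff[eff$tissue == tis, , drop = FALSE]
      for (i in seq_len(nrow(eff_t))) {
        hit <- ann$class_code == eff_t$class_code[i] &
          (eff_t$saturation[i] == "all" |
             sat2[keep] == eff_t$saturation[i])
        shift[hit] <- eff_t$shift[i]
      }
    }

    logc <- matrix(base_mu[keep], nf, ns) +
      config$sigma * outer(shift, as.numeric(grp == "CKD"))
    eps <- matrix(stats::rnorm(nf * ns), nf, ns)

    # latent blocks: shared factor replaces part of the noise for members
    if (length(config$correlation_blocks)) {
      for (blk in config$correlation_blocks) {
        mem <- stratum2[keep] %in% blk$strata |
          stratum3[keep] %in% blk$strata
        if (!any(mem)) next
        in_grp <- grp %in% blk$groups
        if (!any(in_grp)) next
        fct <- stats::rnorm(sum(in_grp))
        lam <- blk$loading
        eps[mem, in_grp] <- lam * matrix(fct, sum(mem), sum(in_grp),
                                         byrow = TRUE) +
          sqrt(1 - lam^2) * eps[mem, in_grp]
      }
    }
    conc <- exp(logc + config$sigma * eps)
    dimnames(conc) <- list(ann$feature, ids)

    # vendor peak areas: per-class internal standard with instrument drift
    is_area <- matrix(exp(stats::rnorm(length(classes) * ns, log(1e5), 0.2)),
                      length(classes), ns,
                      dimnames = list(classes, ids))
    is_conc <- stats::setNames(rep(2, length(classes)), classes)
    areas <- conc * is_area[ann$class_code, ] / is_conc[ann$class_code]

    pm <- .missing_probs(rowMeans(log(conc)), config$missing_rate,
                         config$missing_mechanism)
    drop <- matrix(stats::runif(nf * ns), nf, ns) < pm
    areas[drop] <- NA_real_

    samples[[tis]] <- tibble::tibble(
      sample_id = ids, group = grp, tissue = tis,
      protein_mass = if (tis == "plasma") NA_real_ else
        exp(stats::rnorm(ns, log(100), 0.25)),
      volume = if (tis == "plasma") 50 else NA_real_)
    standards[[tis]] <- tibble::tibble(
      is_id = rep(paste0("IS_", classes), ns),
      sample_id = rep(ids, each = length(classes)),
      peak_area = as.vector(is_area),
      concentration = rep(unname(is_conc), ns))
    pa <- tibble::as_tibble(as.data.frame(areas))
    pa <- dplyr::bind_cols(tibble::tibble(feature = ann$feature), pa)
    peak_areas[[tis]] <- set_stage(pa, "raw")
    tc <- tibble::as_tibble(as.data.frame(conc))
    truth_conc[[tis]] <- dplyr::bind_cols(
      tibble::tibble(feature = ann$feature), tc)
  }

  # acylcarnitine arm (macrophages)
  ac_ann <- ann_all[ann_all$class_code == "AC", ]
  ac_ids <- c(sprintf("AC_CTL_%02d", seq_len(config$n_per_group)),
              sprintf("AC_CKD_%02d", seq_len(config$n_per_group)))
  ac_grp <- rep(c("CTL", "CKD"), each = config$n_per_group)
  win <- classify_chain_length(ac_ann$total_carbons, "acylcarnitine")
  ac <- purrr::map2_dfr(ac_ids, ac_grp, function(id, g) {
    ab <- exp(stats::rnorm(nrow(ac_ann), log(10), 0.3))
    if (g == "CKD") ab[win == "long"] <- ab[win == "long"] *
        config$ac_ratio_shift
    tibble::tibble(sample_id = id, group = g,
                   feature = ac_ann$feature,
                   carbons = ac_ann$total_carbons,
                   double_bonds = ac_ann$total_double_bonds,
                   abundance = ab)
  })

  # deuterium-labelling arm: Dirichlet isotopomer draws, triplicate
  labw <- c(0.55, 0.14, 0.03, 0.02)           # sum(k * labw) = 1
  iso <- purrr::map_dfr(names(config$dnl_enrichment), function(tis) {
    if (!tis %in% config$tissues && tis != "liver") return(NULL)
    tgt <- config$dnl_enrichment[[tis]]
    centre <- c(1 - tgt * sum(labw), tgt * labw)
    ids <- c(sprintf("DNL_%s_CTL_%02d", tis, seq_len(config$dnl_n)),
             sprintf("DNL_%s_CKD_%02d", tis, seq_len(config$dnl_n)))
    grp <- rep(c("CTL", "CKD"), each = config$dnl_n)
    purrr::map2_dfr(ids, grp, function(id, g) {
      reps <- t(vapply(1:3, function(r) .rdirichlet1(2000 * centre),
                       numeric(5)))
      tibble::tibble(sample_id = id, group = g, tissue = tis,
                     replicate_id = 1:3,
                     E0 = reps[, 1], E1 = reps[, 2], E2 = reps[, 3],
                     E3 = reps[, 4], E4 = reps[, 5])
    })
  })

  # qPCR arm: programmed disease fold changes against Gapdh
  ct_ids <- c(sprintf("CT_CTL_%02d", seq_len(config$ct_n)),
              sprintf("CT_CKD_%02d", seq_len(config$ct_n)))
  ct_grp <- rep(c("CTL", "CKD"), each = config$ct_n)
  ct <- purrr::map_dfr(names(config$ct_fold_changes), function(gene) {
    fc <- config$ct_fold_changes[[gene]]
    tibble::tibble(
      sample_id = ct_ids, group = ct_grp, target_gene = gene,
      ct_housekeeping = 18 + stats::rnorm(length(ct_ids), 0,
                                          config$ct_noise_sd),
      ct_target = 24 - log2(fc) * (ct_grp == "CKD") +
        stats::rnorm(length(ct_ids), 0, config$ct_noise_sd))
  })

  list(
    peak_areas = peak_areas,
    standards = dplyr::bind_rows(standards),
    is_map = is_map,
    samples = dplyr::bind_rows(samples),
    annotation = ann_all,
    ac_profiles = ac,
    isotopomers = iso,
    ct = ct,
    truth = list(concentrations = truth_conc, effects = config$effects,
                 correlation_blocks = config$correlation_blocks,
                 ac_ratio_shift = config$ac_ratio_shift,
                 dnl_enrichment = config$dnl_enrichment,
                 ct_fold_changes = config$ct_fold_changes),
    config = config)
}

#' Sample from a Gaussian graphical model
#'
#' Draws `n` observations from a multivariate normal with the given
#' precision (inverse covariance) matrix — the test harness for partial-
#' correlation network inference. The true edge set (nonzero off-diagonal
#' precision entries) is attached as the `"true_edges"` attribute.
#'
#' @param n Number of samples (> 0).
#' @param precision Positive-definite precision matrix.
#' @param seed Optional integer seed.
#' @param feature_names Optional node names (default V1..Vp).
#' @return Wide abundance tibble (features x samples), stage `"zscore"`
#'   left unset; attribute `"true_edges"` is a tibble of `from`/`to` pairs.
#' @export
generate_ggm <- function(n, precision, seed = NULL, feature_names = NULL) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  precision <- as.matrix(precision)
  p <- nrow(precision)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix must be positive definite",
                         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(p))

  R <- chol(solve(precision))              # Sigma = R'R
  X <- matrix(stats::rnorm(n * p), n, p) %*% R
  m <- t(X)
  dimnames(m) <- list(feature_names, paste0("s", seq_len(n)))

  ut <- which(upper.tri(precision) & abs(precision) > 1e-10, arr.ind = TRUE)
  out <- dplyr::bind_cols(tibble::tibble(feature = feature_names),
                          tibble::as_tibble(as.data.frame(m)))
  attr(out, "true_edges") <- tibble::tibble(
    from = feature_names[ut[, 1]], to = feature_names[ut[, 2]])
  out
}

#' Chain-graph precision matrix
#'
#' Tridiagonal precision with unit diagonal and constant partial
#' correlation `rho` between consecutive nodes; positive definite for
#' `|rho| < 0.5`.
#'
#' @param p Number of nodes.
#' @param rho Partial correlation of consecutive nodes (default 0.35).
#' @return A `p x p` precision matrix.
#' @export
chain_precision <- function(p, rho = 0.35) {
  stopifnot(p >= 2, abs(rho) < 0.5)
  m <- diag(p)
  for (i in seq_len(p - 1)) m[i, i + 1] <- m[i + 1, i] <- -rho
  m
}

#' Write a synthetic study to a CSV bundle
#'
#' Writes every table of a [generate_study()] result as CSV plus a
#' `manifest.json` (config echo, seed, file digests) so reruns with the same
#' seed can be verified byte-identical.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    path
  }
  paths <- c(
    unlist(purrr::imap(study$peak_areas,
                       ~ wr(.x, paste0("peak_areas_", .y)))),
    wr(study$standards, "standards"), wr(study$is_map, "is_map"),
    wr(study$samples, "samples"), wr(study$annotation, "annotation"),
    wr(study$ac_profiles, "ac_profiles"),
    wr(study$isotopomers, "isotopomers"), wr(study$ct, "ct"))
  manifest <- list(
    seed = study$config$seed,
    n_per_group = study$config$n_per_group,
    tissues = study$config$tissues,
    files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                    basename(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
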