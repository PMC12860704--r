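# Fatty-acid metabolism metrics: acylcarnitine beta-oxidation ratio,
# deuterium-labelled de novo lipogenesis, delta-delta-Ct fold changes.

#' Long-to-intermediate acylcarnitine ratio
#'
#' The ratio of summed long-chain (C16-C20) to summed intermediate-chain
#' (C5-C14) acylcarnitine abundance, a per-sample proxy of fatty-acid
#' beta-oxidation efficiency (lower = more impaired). Species outside both
#' carbon windows are excluded; unsaturated species count in their window
#' regardless of double-bond number. The ratio is invariant to rescaling
#' all abundances. Raw within-sample sums are used — a ratio of
#' standardized values would not be scale-meaningful.
#'
#' @param data Tibble of acylcarnitine measurements with columns
#'   `sample_id`, `carbons`, `abundance` (non-negative; `double_bonds`
#'   optional and unused by the windows).
#' @return Tibble with `sample_id` and `ratio`.
#' @export
#' @examples
#' acylcarnitine_ratio(tibble::tibble(
#'   sample_id = "s1", carbons = c(18, 8, 4), abundance = c(4, 2, 7)))
acylcarnitine_ratio <- function(data) {
  stopifnot(all(c("sample_id", "carbons", "abundance") %in% names(data)))
  if (any(data$abundance < 0)) stop("abundances must be non-negative",
                                    call. = FALSE)
  out <- data |>
    dplyr::mutate(window = classify_chain_length(.data$carbons,
                                                 "acylcarnitine")) |>
    dplyr::summarise(
      long = sum(.data$abundance[.data$window == "long"]),
      intermediate = sum(.data$abundance[.data$window == "intermediate"]),
      n_long = sum(.data$window == "long"),
      n_intermediate = sum(.data$window == "intermediate"),
      .by = "sample_id")
  if (any(out$n_long == 0) || any(out$n_intermediate == 0)) {
    stop("each sample needs at least one species in both carbon windows",
         call. = FALSE)
  }
  if (any(out$intermediate == 0)) {
    stop("zero intermediate-chain sum; ratio undefined for sample(s): ",
         paste(out$sample_id[out$intermediate == 0], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(sample_id = out$sample_id,
                 ratio = out$long / out$intermediate)
}

#' Total palmitate deuterium enrichment
#'
#' After heavy-water labelling, newly synthesized palmitate carries 1-4
#' deuteriums. Total enrichment is the mass-shift-weighted sum of the
#' fractional isotopomer distribution: `E1 + 2 E2 + 3 E3 + 4 E4`. Natural-
#' abundance correction of M+1/M+2 is not applied (reported as a known
#' limitation of the relative measure).
#'
#' @param data Tibble with fractional isotopomer columns `E0`-`E4`
#'   (each row one measurement, fractions summing to 1), or a numeric
#'   matrix/data frame of the same five columns.
#' @return Numeric vector of total enrichments, one per row.
#' @export
#' @examples
#' palmitate_enrichment(tibble::tibble(
#'   E0 = 0.7, E1 = 0.1, E2 = 0.1, E3 = 0.05, E4 = 0.05))
palmitate_enrichment <- function(data) {
  cols <- c("E0", "E1", "E2", "E3", "E4")
  stopifnot(all(cols %in% names(data)))
  f <- as.matrix(data[cols])
  if (any(f < 0)) stop("isotopomer fractions must be non-negative",
                       call. = FALSE)
  tot <- rowSums(f)
  if (any(abs(tot - 1) > 1e-6)) {
    stop("isotopomer fractions must sum to 1 (tolerance 1e-6)", call. = FALSE)
  }
  as.numeric(f %*% c(0, 1, 2, 3, 4))
}

#' De novo lipogenesis rate from replicate isotopomer measurements
#'
#' Each sample is measured in (nominally) triplicate; the sample's DNL value
#' is the arithmetic mean of per-replicate total palmitate enrichments.
#' A single replicate is accepted with a warning.
#'
#' @param data Tibble with columns `sample_id`, `E0`-`E4`, and optionally
#'   `tissue` and `replicate_id`.
#' @return Tibble with one row per sample (and tissue, if present):
#'   `n_replicates`, `enrichment`.
#' @export
dnl_rate <- function(data) {
  stopifnot("sample_id" %in% names(data))
  data$enrichment <- palmitate_enrichment(data)
  keys <- intersect(c("sample_id", "tissue"), names(data))
  out <- data |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     enrichment = mean(.data$enrichment),
                     .by = dplyr::all_of(keys))
  if (any(out$n_replicates < 3)) {
    warning("sample(s) with fewer than 3 replicates: ",
            paste(out$sample_id[out$n_replicates < 3], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each record, `dCt = Ct_target - Ct_housekeeping`; `ddCt` subtracts the
#' reference-group mean dCt (per target gene); fold change is `2^-ddCt`.
#' By construction the geometric mean fold change of the reference group
#' is 1 for every gene.
#'
#' @param data Tibble with columns `sample_id`, `group`, `target_gene`,
#'   `ct_target`, `ct_housekeeping`.
#' @param reference_group Group label serving as baseline (e.g. `"CTL"`).
#' @return Tibble with `sample_id`, `group`, `target_gene`, `dct`, `ddct`,
#'   `fold_change`.
#' @export
fold_change_ddct <- function(data, reference_group) {
  req <- c("sample_id", "group", "target_gene", "ct_target",
           "ct_housekeeping")
  stopifnot(all(req %in% names(data)))
  if (anyNA(data$ct_target) || anyNA(data$ct_housekeeping)) {
    stop("Ct values must be finite and non-missing", call. = FALSE)
  }
  if (!reference_group %in% data$group) {
    stop(sprintf("reference group '%s' not present", reference_group),
         call. = FALSE)
  }
  data |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_housekeeping) |>
    dplyr::mutate(
      ddct = .data$dct -
        mean(.data$dct[.data$group == reference_group]),
      .by = "target_gene") |>
    dplyr::mutate(fold_change = 2^(-.data$ddct)) |>
    dplyr::select(dplyr::all_of(c("sample_id", "group", "target_gene",
                                  "dct", "ddct", "fold_change")))
}
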