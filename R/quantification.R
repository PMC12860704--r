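# Internal-standard quantification and per-sample normalization.

#' Quantify peak areas against class internal standards
#'
#' Each lipid's concentration is its peak area divided by the peak area of
#' its class's internal standard in the same sample, multiplied by the known
#' spiked concentration of that standard. Quantification is linear in peak
#' area; missing areas stay missing (imputation is a later, declared step).
#'
#' @param areas Wide peak-area tibble: `feature` column + one column per
#'   sample. Stage `"raw"`.
#' @param standards Tibble of internal-standard measurements with columns
#'   `is_id`, `sample_id`, `peak_area` (> 0), `concentration` (> 0).
#' @param is_map Tibble mapping `class_code` to `is_id`; every class present
#'   in `areas` must be covered (vendor panels do not publish this mapping,
#'   so it is a required configuration input).
#' @param annotation Optional annotation from [parse_lipids()].
#' @return Concentration tibble of the same shape, stage `"concentration"`.
#' @export
quantify_areas <- function(areas, standards, is_map, annotation = NULL) {
  stopifnot(is.data.frame(areas), "feature" %in% names(areas))
  req <- c("is_id", "sample_id", "peak_area", "concentration")
  if (!all(req %in% names(standards))) {
    stop("`standards` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("class_code", "is_id") %in% names(is_map))) {
    stop("`is_map` needs columns class_code, is_id", call. = FALSE)
  }
  if (is.null(annotation)) annotation <- parse_lipids(areas$feature)
  ann <- annotation[match(areas$feature, annotation$feature), ]

  missing_cls <- setdiff(unique(ann$class_code), is_map$class_code)
  if (length(missing_cls)) {
    stop("no internal standard mapped for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  if (any(standards$peak_area <= 0, na.rm = TRUE) || anyNA(standards$peak_area)) {
    stop("internal standard peak areas must be strictly positive", call. = FALSE)
  }
  if (any(standards$concentration <= 0)) {
    stop("internal standard concentrations must be strictly positive",
         call. = FALSE)
  }

  scol <- .sample_cols(areas)
  feat_is <- is_map$is_id[match(ann$class_code, is_map$class_code)]

  out <- areas
  for (s in scol) {
    std <- standards[standards$sample_id == s, ]
    idx <- match(feat_is, std$is_id)
    if (anyNA(idx)) {
      stop(sprintf("sample '%s': internal standard(s) %s not measured", s,
                   paste(unique(feat_is[is.na(idx)]), collapse = ", ")),
           call. = FALSE)
    }
    out[[s]] <- areas[[s]] / std$peak_area[idx] * std$concentration[idx]
  }
  .advance_stage(out, c("raw", NA), "concentration")
}

#' Normalize concentrations to protein content or plasma volume
#'
#' Cell-pellet tissues (peritoneal macrophages, liver) are normalized to
#' total protein mass of the pellet; plasma to the sampled volume
#' (canonically 50 ul).
#'
#' @param data Concentration tibble (stage `"concentration"`).
#' @param samples Sample metadata with columns `sample_id`, `tissue`
#'   (`"plasma"`, `"PM"` or `"liver"`), and `protein_mass` (ug, required for
#'   PM/liver) or `volume` (ul, required for plasma).
#' @return Normalized tibble, stage `"normalized"`.
#' @export
normalize_samples <- function(data, samples) {
  stopifnot(is.data.frame(data), "feature" %in% names(data))
  scol <- .sample_cols(data)
  idx <- match(scol, samples$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(scol[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta <- samples[idx, ]
  denom <- ifelse(meta$tissue == "plasma",
                  if ("volume" %in% names(meta)) meta$volume else NA_real_,
                  if ("protein_mass" %in% names(meta)) meta$protein_mass else NA_real_)
  bad <- is.na(denom) | denom <= 0
  if (any(bad)) {
    stop("missing or non-positive normalization denominator for sample(s): ",
         paste(scol[bad], collapse = ", "), call. = FALSE)
  }
  out <- data
  out[scol] <- purrr::map2(data[scol], denom, `/`)
  .advance_stage(out, c("concentration", NA), "normalized")
}
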