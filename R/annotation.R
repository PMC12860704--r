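# Lipid shorthand parsing and classification.

# Class registry: 21 targeted-panel classes. CER and AC are measured on a
# separate LC/MS method but live in the same registry.
.LIPID_CLASSES <- c(
  "CE", "MAG", "DAG", "TAG", "FFA", "PC", "PE", "PE-O", "PE-P", "PI", "PG",
  "LPC", "PS", "LPS", "LPE", "SM", "HCER", "LCER", "DCER", "CER", "AC"
)

#' Lipid class registry
#'
#' The closed vocabulary of lipid classes recognised by the package:
#' cholesterol esters (CE), mono-/di-/triacylglycerols (MAG, DAG, TAG),
#' free fatty acids (FFA), glycerophospholipids (PC, PE, PI, PG, PS and the
#' lyso forms LPC, LPE, LPS), ether-linked PE (plasmanyl PE-O, plasmenyl
#' PE-P), sphingomyelin (SM), ceramides (CER) and modified ceramides
#' (HCER, LCER, DCER), and acylcarnitines (AC).
#'
#' @return A character vector of the 21 registered class codes.
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() .LIPID_CLASSES

#' Parse lipid shorthand names
#'
#' Parses vendor-style shorthand such as `"FFA(16:0)"`, `"PE(P-18:0/20:4)"`,
#' `"CE 18:2"` or the per-acyl TAG isotopomer form `"TAG52:2-FA18:1"` into a
#' structured annotation. Chain-resolved forms (`CLASS(c1:d1/c2:d2[/c3:d3])`)
#' are summed to total carbons and double bonds. An `O-`/`P-` prefix on the
#' first chain marks an ether linkage and is only legal for PE, where it
#' re-classes the species as PE-O (plasmanyl) or PE-P (plasmenyl).
#' Class codes are matched case-insensitively; whitespace is tolerated.
#'
#' @param x Character vector of lipid names, or a data frame whose first
#'   column (or the column named by `feature_col`) holds them.
#' @param feature_col Column holding the names when `x` is a data frame.
#' @return A tibble with one row per input name: `feature` (the raw name),
#'   `class_code`, `total_carbons`, `total_double_bonds`, `ether_type`
#'   (`"none"`, `"O"` or `"P"`), `sn_fatty_acid` (the named acyl chain of a
#'   TAG isotopomer feature, else `NA`), and `saturation`.
#' @export
#' @examples
#' parse_lipids(c("FFA(16:0)", "PE(P-18:0/20:4)", "TAG52:2-FA18:1"))
parse_lipids <- function(x, feature_col = "feature") {
  if (is.data.frame(x)) {
    col <- if (feature_col %in% names(x)) feature_col else names(x)[1]
    x <- x[[col]]
  }
  stopifnot(is.character(x))
  if (anyNA(x) || any(!nzchar(trimws(x)))) {
    stop("lipid names must be non-empty and non-missing", call. = FALSE)
  }
  out <- purrr::map(x, .parse_one_lipid)
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      saturation = classify_saturation(.data$total_double_bonds)
    )
}

.parse_one_lipid <- function(raw) {
  s <- trimws(raw)

  # TAG isotopomer: TAGcc:db-FAcc:db (also accepts TAG(cc:db)-FAcc:db)
  m <- regmatches(s, regexec(
    "^(?i)(TAG)\\s*\\(?\\s*(\\d+)\\s*:\\s*(\\d+)\\s*\\)?\\s*-\\s*FA\\s*(\\d+)\\s*:\\s*(\\d+)\\s*$",
    s, perl = TRUE))[[1]]
  if (length(m)) {
    return(.new_species(raw, "TAG", as.integer(m[3]), as.integer(m[4]),
                        "none", sprintf("FA%s:%s", m[5], m[6])))
  }

  # General: CLASS(chains) or CLASS chains, chains = [O-|P-]cc:db[/cc:db...]
  m <- regmatches(s, regexec(
    "^([A-Za-z-]+)\\s*\\(\\s*([^()]+)\\s*\\)\\s*$|^([A-Za-z-]+)\\s*([0-9OPop][0-9OPop:/ -]*)$",
    s, perl = TRUE))[[1]]
  if (!length(m)) {
    stop(sprintf("cannot parse lipid name '%s'", raw), call. = FALSE)
  }
  cls_raw <- if (nzchar(m[2])) m[2] else m[4]
  chains <- trimws(if (nzchar(m[2])) m[3] else m[5])

  ether <- "none"
  em <- regmatches(chains, regexec("^(?i)([OP])-\\s*(.*)$", chains, perl = TRUE))[[1]]
  if (length(em)) {
    ether <- toupper(em[2])
    chains <- em[3]
  }

  cls <- .match_class(cls_raw, raw)

  # ether prefix only meaningful for PE; promote PE + O-/P- to PE-O/PE-P
  if (ether != "none") {
    if (cls == "PE") cls <- paste0("PE-", ether)
    if (!cls %in% c("PE-O", "PE-P")) {
      stop(sprintf("ether prefix '%s-' not allowed for class %s in '%s'",
                   ether, cls, raw), call. = FALSE)
    }
    if (substr(cls, 4, 4) != ether) {
      stop(sprintf("ether prefix '%s-' conflicts with class %s in '%s'",
                   ether, cls, raw), call. = FALSE)
    }
  }
  if (cls %in% c("PE-O", "PE-P")) ether <- substr(cls, 4, 4)

  parts <- strsplit(chains, "/", fixed = TRUE)[[1]]
  cc <- db <- 0L
  for (p in parts) {
    pm <- regmatches(p, regexec("^\\s*(\\d+)\\s*:\\s*(\\d+)\\s*$", p))[[1]]
    if (!length(pm)) {
      stop(sprintf("malformed acyl chain token '%s' in '%s'", trimws(p), raw),
           call. = FALSE)
    }
    cc <- cc + as.integer(pm[2])
    db <- db + as.integer(pm[3])
  }
  .new_species(raw, cls, cc, db, ether, NA_character_)
}

.match_class <- function(code, raw) {
  hit <- match(toupper(trimws(code)), toupper(.LIPID_CLASSES))
  if (is.na(hit)) {
    stop(sprintf("unknown lipid class '%s' in '%s' (not in registry)",
                 trimws(code), raw), call. = FALSE)
  }
  .LIPID_CLASSES[hit]
}

.new_species <- function(raw, cls, cc, db, ether, sn) {
  if (cc < 2L) stop(sprintf("'%s': total carbons must be >= 2", raw), call. = FALSE)
  if (db > cc) stop(sprintf("'%s': double bonds exceed carbons", raw), call. = FALSE)
  tibble::tibble(
    feature = raw, class_code = cls, total_carbons = cc,
    total_double_bonds = db, ether_type = ether, sn_fatty_acid = sn
  )
}

#' Render a parsed lipid back to canonical shorthand
#'
#' Canonical forms are `CLASS(CC:DB)` for totals and `TAGCC:DB-FAcc:db` for
#' TAG isotopomer features; PE-O/PE-P render as `PE(O-CC:DB)` / `PE(P-CC:DB)`.
#' `parse_lipids(render_lipid_name(parse_lipids(x)))` is the identity on the
#' structured fields.
#'
#' @param ann Annotation tibble as returned by [parse_lipids()].
#' @return Character vector of canonical names.
#' @export
render_lipid_name <- function(ann) {
  mapply(function(cls, cc, db, sn) {
    if (cls == "TAG" && !is.na(sn)) {
      sprintf("TAG%d:%d-%s", cc, db, sn)
    } else if (cls %in% c("PE-O", "PE-P")) {
      sprintf("PE(%s-%d:%d)", substr(cls, 4, 4), cc, db)
    } else {
      sprintf("%s(%d:%d)", cls, cc, db)
    }
  }, ann$class_code, ann$total_carbons, ann$total_double_bonds,
     ann$sn_fatty_acid, USE.NAMES = FALSE)
}

#' Saturation category from double-bond count
#'
#' `saturated` (0 double bonds), `monounsaturated` (1) or `polyunsaturated`
#' (2 or more). "Unsaturated" groupings used elsewhere in the package are the
#' union of the latter two.
#'
#' @param double_bonds Integer vector of total double-bond counts.
#' @return Factor with levels saturated, monounsaturated, polyunsaturated.
#' @export
#' @examples
#' classify_saturation(c(0, 1, 4))
classify_saturation <- function(double_bonds) {
  stopifnot(is.numeric(double_bonds), all(double_bonds >= 0))
  factor(
    dplyr::case_when(
      double_bonds == 0 ~ "saturated",
      double_bonds == 1 ~ "monounsaturated",
      TRUE ~ "polyunsaturated"
    ),
    levels = c("saturated", "monounsaturated", "polyunsaturated")
  )
}

#' Chain-length category
#'
#' Under the acylcarnitine scheme, carbons 5-14 are `intermediate` and 16-20
#' `long` (the two windows of the beta-oxidation ratio); anything outside both
#' windows is `excluded` from the ratio. Under the ffa scheme, C16-C24 is
#' `long` and anything shorter `short`.
#'
#' @param carbons Integer vector of total carbon counts.
#' @param scheme `"acylcarnitine"` or `"ffa"`.
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_chain_length(c(8, 15, 18), scheme = "acylcarnitine")
classify_chain_length <- function(carbons, scheme = c("acylcarnitine", "ffa")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(carbons), all(carbons >= 2))
  if (scheme == "acylcarnitine") {
    dplyr::case_when(
      carbons >= 5 & carbons <= 14 ~ "intermediate",
      carbons >= 16 & carbons <= 20 ~ "long",
      TRUE ~ "excluded"
    )
  } else {
    ifelse(carbons >= 16 & carbons <= 24, "long", "short")
  }
}

#' Collapse TAG isotopomer features
#'
#' Targeted panels report each triacylglycerol once per named constituent
#' acyl chain ("isotopomers" in vendor usage), so a single TAG composition
#' appears several times. All TAG features sharing the same total
#' carbon:double-bond composition are summed into one `TAGCC:DB` feature;
#' non-TAG features pass through untouched. Per-sample total TAG abundance is
#' conserved exactly.
#'
#' @param data Wide abundance tibble: a `feature` column plus one numeric
#'   column per sample.
#' @param annotation Optional annotation from [parse_lipids()]; parsed from
#'   `data$feature` when omitted.
#' @return A tibble like `data` with the TAG block collapsed. The attribute
#'   `"tag_mapping"` holds a tibble mapping each collapsed feature to its
#'   member features; the `"stage"` attribute of `data` is carried over.
#' @export
collapse_tag_isotopomers <- function(data, annotation = NULL) {
  stopifnot(is.data.frame(data), "feature" %in% names(data))
  if (is.null(annotation)) annotation <- parse_lipids(data$feature)
  ann <- annotation[match(data$feature, annotation$feature), ]

  is_tag <- ann$class_code == "TAG"
  if (!any(is_tag)) {
    attr(data, "tag_mapping") <- tibble::tibble(
      collapsed = character(), member = character())
    return(data)
  }

  scol <- setdiff(names(data), "feature")
  tag <- data[is_tag, , drop = FALSE]
  tag_name <- sprintf("TAG%d:%d", ann$total_carbons[is_tag],
                      ann$total_double_bonds[is_tag])
  # bare TAGcc:db rows (no sn tag) colliding with a collapsed group of the
  # same composition would double-count silently
  bare <- is.na(ann$sn_fatty_acid[is_tag])
  if (any(bare) && any(tag_name[bare] %in% tag_name[!bare])) {
    stop("untagged TAG feature collides with a collapsed isotopomer group: ",
         paste(unique(tag_name[bare][tag_name[bare] %in% tag_name[!bare]]),
               collapse = ", "), call. = FALSE)
  }

  collapsed <- tag |>
    dplyr::mutate(.group = tag_name) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(scol), ~ sum(.x)),
      .by = ".group") |>
    dplyr::rename(feature = ".group")

  mapping <- tibble::tibble(collapsed = tag_name, member = tag$feature)

  # keep non-TAG rows in place, collapsed TAG block at first TAG position
  first_tag <- which(is_tag)[1]
  before <- data[seq_len(nrow(data)) < first_tag & !is_tag, , drop = FALSE]
  after <- data[seq_len(nrow(data)) > first_tag & !is_tag, , drop = FALSE]
  out <- dplyr::bind_rows(before, collapsed, after)
  attr(out, "stage") <- attr(data, "stage")
  attr(out, "tag_mapping") <- mapping
  out
}

#' Annotate a feature panel
#'
#' Convenience wrapper: parse every feature name and return the annotation
#' table (class, carbons, double bonds, ether type, saturation), suitable for
#' writing as a CSV sidecar.
#'
#' @param features Character vector of feature names, or a wide abundance
#'   tibble with a `feature` column.
#' @return Annotation tibble, one row per feature.
#' @export
annotate_features <- function(features) {
  if (is.data.frame(features)) features <- features$feature
  parse_lipids(features)
}
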