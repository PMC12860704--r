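# Stage tracking for wide abundance tibbles.
#
# An abundance table is an ordinary tibble: a `feature` column plus one
# numeric column per sample. The processing stage travels in the "stage"
# attribute and advances through a fixed order; pipeline verbs check it so
# out-of-order application fails loudly rather than silently producing
# nonsense (e.g. logit before sum normalization).

.STAGES <- c("raw", "concentration", "normalized", "class_fraction",
             "logit", "zscore")

#' Get or set the processing stage of an abundance table
#'
#' @param data Wide abundance tibble.
#' @param value One of `"raw"`, `"concentration"`, `"normalized"`,
#'   `"class_fraction"`, `"logit"`, `"zscore"`.
#' @return `abundance_stage()` returns the stage string (or `NA` if unset);
#'   `set_stage()` returns `data` with the attribute set.
#' @export
abundance_stage <- function(data) {
  s <- attr(data, "stage", exact = TRUE)
  if (is.null(s)) NA_character_ else s
}

#' @rdname abundance_stage
#' @export
set_stage <- function(data, value) {
  value <- match.arg(value, .STAGES)
  attr(data, "stage") <- value
  data
}

# check current stage is allowed, advance to `to`
.advance_stage <- function(data, allowed, to) {
  s <- abundance_stage(data)
  if (!is.na(s) && !s %in% allowed) {
    stop(sprintf("abundance table is at stage '%s'; expected %s", s,
                 paste(sprintf("'%s'", allowed), collapse = " or ")),
         call. = FALSE)
  }
  set_stage(data, to)
}

.sample_cols <- function(data) setdiff(names(data), "feature")

.as_matrix <- function(data) {
  m <- as.matrix(data[.sample_cols(data)])
  rownames(m) <- data$feature
  m
}

.from_matrix <- function(m, template) {
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(feature = rownames(m)), out)
  attr(out, "stage") <- attr(template, "stage")
  out
}

#' Pivot an abundance table to long form
#'
#' @param data Wide abundance tibble (`feature` + one column per sample).
#' @return Long tibble with columns `feature`, `sample_id`, `value`.
#' @export
abundance_long <- function(data) {
  tidyr::pivot_longer(data, -"feature", names_to = "sample_id",
                      values_to = "value")
}
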