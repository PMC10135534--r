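`%||%` <- function(a, b) if (is.null(a)) b else a

KNOWN_LABELS <- c("male", "female", "focal_male", "couple")

#' Normalise a class label
#'
#' Labels outside the four known classes (`male`, `female`, `focal_male`,
#' `couple`) are mapped to `"unknown"`; unknown tracks travel through the
#' pipeline but are excluded from evaluation, consistent with the open-world
#' one-class design.
#'
#' @param label character vector of raw labels.
#' @return character vector over the five admissible labels.
#' @keywords internal
normalise_label <- function(label) {
  label <- as.character(label)
  label[is.na(label) | !(label %in% KNOWN_LABELS)] <- "unknown"
  label
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))
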