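# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# autosomal p-arms with no assessable array content (acrocentric short arms)
ACROCENTRIC_P <- c(13L, 14L, 15L, 21L, 22L)

AUTOSOMES <- 1:22

#' Percentage of a count over a denominator, rounded to the nearest integer
#'
#' Cohort tables in this field report `n (x%)` with variable-specific
#' denominators; this is the rounding convention used throughout the
#' package's summaries.
#'
#' @param n count (non-negative).
#' @param denom denominator; `0` yields `NA`.
#' @return numeric percentage on the 0-100 scale, rounded to an integer.
#' @examples
#' count_percent(94, 314) # 30
#' @export
count_percent <- function(n, denom) {
  stopifnot(all(n >= 0, na.rm = TRUE), all(denom >= 0, na.rm = TRUE))
  out <- ifelse(denom == 0, NA_real_, round(100 * n / denom))
  as.numeric(out)
}
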