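#' Round half away from zero
#'
#' Rounding convention used for the human-readable summary and interpretation
#' arithmetic (mean deaths per county, percentile units per additional death):
#' ties at .5 round away from zero, so 4.5 -> 5 and -4.5 -> -5, unlike base
#' [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(4.5, -4.5, 40.9))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log(sum(exp(x))) per row of a matrix, guarded against overflow
.row_logsumexp <- function(A) {
  m <- apply(A, 1L, max)
  m + log(rowSums(exp(A - m)))
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
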