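# Shared numeric helpers.

#' Harmonic-type sums used by neutrality statistics
#'
#' `harmonic(n)` is \eqn{\sum_{i=1}^{n} 1/i}; `harmonic2(n)` the corresponding
#' sum of squared reciprocals.
#'
#' @param n Non-negative integer.
#' @return Numeric scalar.
#' @keywords internal
#' @noRd
harmonic <- function(n) if (n < 1) 0 else sum(1 / seq_len(n))

#' @noRd
harmonic2 <- function(n) if (n < 1) 0 else sum(1 / seq_len(n)^2)

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
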