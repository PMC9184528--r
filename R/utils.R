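#' Convert an error probability to a Phred score
#'
#' @param p Probability of error, in `[0, 1]`.
#' @param cap Maximum score returned (probabilities of 0 would otherwise map
#'   to `Inf`).
#' @return Numeric vector of Phred scores, `-10 * log10(p)`, capped.
#' @export
phred <- function(p, cap = 100) {
  q <- -10 * log10(pmax(p, 10^(-cap / 10)))
  pmin(q, cap)
}

#' Format an integer copy-number tuple as a string
#'
#' Tuples are printed comma-separated, e.g. `"2,2"` for two copies with two
#' chromosomes each.
#'
#' @param t Integer vector.
#' @return Length-1 character.
#' @export
tuple_str <- function(t) paste(t, collapse = ",")

#' Parse a copy-number tuple string
#'
#' @param s Character vector of comma-separated tuples.
#' @return List of integer vectors.
#' @export
tuple_parse <- function(s) lapply(strsplit(s, ","), as.integer)

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 0-based half-open interval as a human-readable string (1-based inclusive)
interval_str <- function(contig, start, end) {
  sprintf("%s:%d-%d", contig, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_paracn <- function(...) stop(sprintf(...), call. = FALSE)
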