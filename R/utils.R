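# Internal grouped-vector helpers. All assume `g` is sorted so that equal
# group keys are contiguous (callers order their data first).

`%||%` <- function(a, b) if (is.null(a)) b else a

# logical: TRUE at the first row of each contiguous group
.group_first <- function(g) {
  n <- length(g)
  if (n == 0L) return(logical(0))
  c(TRUE, g[-1L] != g[-n])
}

# cumulative sum restarting at each group boundary
.cumsum_by <- function(x, g) {
  first <- .group_first(g)
  cs <- cumsum(x)
  base <- c(0, cs)[which(first)]
  lens <- diff(c(which(first), length(g) + 1L))
  cs - rep(base, lens)
}

# running maximum restarting at each group boundary; x numeric
.cummax_by <- function(x, g) {
  if (length(x) == 0L) return(x)
  first <- .group_first(g)
  gi <- cumsum(first)
  big <- (max(x) - min(x) + 1)
  cummax(x + gi * big) - gi * big
}

# per-group any(): returns logical named by group key, in first-appearance order
.any_by <- function(x, g) {
  s <- rowsum(as.integer(x), g, reorder = FALSE)
  out <- s[, 1L] > 0L
  names(out) <- rownames(s)
  out
}

.sum_by <- function(x, g) {
  s <- rowsum(as.numeric(x), g, reorder = FALSE)
  out <- s[, 1L]
  names(out) <- rownames(s)
  out
}

#' Percentage with report-style rounding
#'
#' The rounding convention used across the package's summary tables:
#' integer percentages in partition-style summaries, one decimal in
#' completeness tables. Returns `NA` when the denominator is zero.
#'
#' @param n numerator count(s).
#' @param total denominator count(s).
#' @param digits decimal places to round to (0 for partition summaries,
#'   1 for completeness tables).
#' @return numeric percentage(s) in `[0, 100]`, `NA` where `total == 0`.
#' @examples
#' share_pct(381, 2281)      # 17
#' share_pct(1, 3, digits = 1)  # 33.3
#' @export
share_pct <- function(n, total, digits = 0) {
  out <- round(100 * as.numeric(n) / as.numeric(total), digits)
  out[!is.finite(out)] <- NA_real_
  unname(out)
}

.as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

DAYS_PER_YEAR <- 365.25
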