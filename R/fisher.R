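#' Vectorized two-sided Fisher exact p-value for 2x2 tables
#'
#' Computes, for each table \code{rbind(c(a, b), c(c, d))}, the two-sided
#' Fisher exact p-value as the sum of hypergeometric point probabilities
#' no larger than that of the observed table (with the customary relative
#' tolerance for floating-point ties). Used where many tables must be
#' tested at once, e.g. the per-cytosine scan of [call_dmrs()]; single
#' tables elsewhere in the package go through [stats::fisher.test()].
#'
#' @param a,b,c,d Non-negative integer vectors (recycled): cell counts,
#'   rows = groups, columns = (success, failure).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0, na.rm = TRUE))
    stopf("fisher_exact_p: negative cell count")
  vapply(seq_len(n), function(i) {
    if (anyNA(c(a[i], b[i], c[i], d[i]))) return(NA_real_)
    m <- a[i] + c[i]          # column-1 margin
    nn <- b[i] + d[i]         # column-2 margin
    k <- a[i] + b[i]          # row-1 margin
    if (m + nn == 0) return(1)
    lo <- max(0, k - nn); hi <- min(k, m)
    xs <- lo:hi
    probs <- stats::dhyper(xs, m, nn, k)
    p_obs <- probs[xs == a[i]]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

# Two-sided Fisher p for a single 2x2 table via stats::fisher.test.
fisher_p_2x2 <- function(tab) {
  if (any(tab < 0)) stopf("negative count in 2x2 table")
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

# Mann-Whitney U (Wilcoxon rank-sum) two-sided p. Exact enumeration-based
# null when both groups are small and tie-free; otherwise the normal
# approximation with tie correction (and continuity correction).
mann_whitney_p <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0)
    stopf("mann_whitney_p: empty group")
  use_exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
  # degenerate null (all observations tied): no evidence either way
  if (!is.finite(p)) p <- 1
  p
}
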