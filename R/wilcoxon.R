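# Wilcoxon wrappers with a fixed, reproducible exact/approximate policy:
# exact distribution when all group sizes are <= 25 and there are no ties,
# normal approximation with tie and continuity correction otherwise.
# Degenerate inputs (no variation) return P = 1 by contract.

#' Wilcoxon rank-sum test (two independent groups)
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (for `x` vs `y`).
#' @return list with `statistic` (W) and `p.value`.
#' @export
wilcox_ranksum <- function(x, y, alternative = "two.sided") {
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  exact <- length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Wilcoxon signed-rank test (paired samples)
#'
#' Zero differences are dropped, as in the standard procedure; if every
#' difference is zero, `P = 1` is returned by contract.
#'
#' @param x,y paired numeric samples (`x - y` is tested against zero).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `statistic` (V) and `p.value`.
#' @export
wilcox_signedrank <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) return(list(statistic = 0, p.value = 1))
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
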