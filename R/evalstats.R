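# Cohort-level comparison of two viewing-angle sets (method vs reference):
# per-group summaries, a normality-gated two-sample test, and the paired
# absolute angle differences binned at 3 and 5 degrees.

#' Bin absolute angle differences
#'
#' Left-closed, right-open bins with an overflow bin: for the default edges
#' `c(3, 5)` the proportions of differences in \[0, 3), \[3, 5) and
#' \[5, Inf) degrees.
#'
#' @param diffs non-negative angle differences (degrees).
#' @param edges strictly increasing bin boundaries (degrees).
#' @return named numeric vector of proportions summing to 1.
#' @examples
#' differenceBins(c(1, 2, 4, 6, 9))  # 0.4, 0.2, 0.4
#' @export
differenceBins <- function(diffs, edges = c(3, 5)) {
  if (!length(diffs)) stop("empty difference vector")
  if (any(diffs < 0)) stop("angle differences must be non-negative")
  if (length(edges) < 1L || any(diff(edges) <= 0) || any(edges <= 0))
    stop("edges must be strictly increasing positive boundaries")
  idx <- findInterval(diffs, edges)  # 0 below first edge; left-closed
  counts <- tabulate(idx + 1L, nbins = length(edges) + 1L)
  lab <- c(sprintf("[0,%g)", edges[1L]),
           if (length(edges) > 1L)
             sprintf("[%g,%g)", edges[-length(edges)], edges[-1L]),
           sprintf("[%g,Inf)", edges[length(edges)]))
  structure(counts / length(diffs), names = lab)
}

#' Compare two case-paired angle sets
#'
#' Normality of each sample is assessed with the Shapiro-Wilk test at the
#' same `alpha` as the significance threshold; if both samples pass, group
#' means are compared with an unpaired two-sided t-test, otherwise with a
#' Mann-Whitney U test. A constant sample (zero variance) fails the gate.
#' The per-case absolute differences `|a_i - b_i|` are computed separately
#' and binned at the `edges` boundaries.
#'
#' Note the two-sample test is unpaired (it compares group means), while the
#' difference bins are paired by case; both views of the data are reported.
#'
#' @param a,b equal-length (n >= 3) angle vectors (degrees), paired by case.
#' @param alpha significance level for both the normality gate and the test.
#' @param edges bin boundaries for [differenceBins()].
#' @return an [AngleComparison-class].
#' @examples
#' set.seed(1)
#' cmp <- compareAngleSets(rnorm(20, 46, 5), rnorm(20, 45, 5))
#' cmp@testUsed
#' @export
compareAngleSets <- function(a, b, alpha = 0.05, edges = c(3, 5)) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired cases")
  if (anyNA(a) || anyNA(b)) stop("angle sets must not contain NA")
  swp <- function(x) {
    if (sd(x) == 0) return(NA_real_)  # constant sample: gate fails
    shapiro.test(x)$p.value
  }
  sp <- c(swp(a), swp(b))
  normal <- !anyNA(sp) && all(sp > alpha)
  if (normal) {
    ht <- t.test(a, b, var.equal = TRUE)
    testUsed <- "t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    testUsed <- "Mann-Whitney U"
  }
  d <- abs(a - b)
  new("AngleComparison", meanA = mean(a), meanB = mean(b),
      sdA = sd(a), sdB = sd(b), pValue = unname(ht$p.value),
      testUsed = testUsed, shapiroP = sp, absDifferences = d,
      bins = differenceBins(d, edges), alpha = alpha)
}

setMethod("show", "AngleComparison", function(object) {
  cat(sprintf(paste0(
    "AngleComparison (n = %d): %.2f +/- %.2f vs %.2f +/- %.2f deg\n",
    "  %s p = %.4g (alpha = %g; Shapiro-Wilk p = %s)\n",
    "  |difference| bins: %s\n"),
    length(object@absDifferences), object@meanA, object@sdA, object@meanB,
    object@sdB, object@testUsed, object@pValue, object@alpha,
    paste(signif(object@shapiroP, 3), collapse = ", "),
    paste(sprintf("%s %.2f", names(object@bins), object@bins),
          collapse = "; ")))
})
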