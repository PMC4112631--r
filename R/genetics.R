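#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Tests observed progeny counts per phenotype class against a Mendelian
#' expected ratio (e.g. 1 mutant : 3 wild type for non-complementation in an
#' F1 of two heterozygous carriers). Pearson statistic, df = classes - 1, no
#' continuity correction.
#'
#' @param observed non-negative integer counts per class.
#' @param ratio expected ratio, positive reals of the same length (scale
#'   free: `c(1, 3)` and `c(25, 75)` are equivalent).
#' @return list `chi2`, `df`, `p`, `expected`.
#' @examples
#' segregation_chi2(c(9, 39), c(1, 3))    # p ~ 0.32
#' segregation_chi2(c(47, 148), c(1, 3))  # p ~ 0.77
#' @export
segregation_chi2 <- function(observed, ratio = c(1, 3)) {
  if (length(observed) != length(ratio) || length(observed) < 2L) {
    stop("observed and ratio must have equal length >= 2")
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed counts must be non-negative with positive total")
  }
  if (any(ratio <= 0)) stop("expected ratio classes must be positive")
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = ratio / sum(ratio)))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = unname(ht$expected))
}

#' Mean and standard error of a measurement group
#'
#' SEM = sample standard deviation (n - 1 denominator) / sqrt(n).
#'
#' @param values numeric vector, length >= 2.
#' @return list `n`, `mean`, `sem`.
#' @examples
#' group_summary(c(3.89, 6.09, 5.14))  # wild-type leaf starch, mg/g FW
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("group_summary needs at least 2 non-missing values")
  }
  n <- length(values)
  list(n = n, mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

#' Fold effect between two group means
#'
#' Ratio of two means, rounded half away from zero to `decimals` places (the
#' convention used for the printed starch fold effects).
#'
#' @param numerator,denominator group means; denominator must be positive.
#' @param decimals decimal places for the reported ratio.
#' @return the rounded ratio.
#' @examples
#' fold_effect(15.94, 3.89)  # 4.1
#' @export
fold_effect <- function(numerator, denominator, decimals = 1) {
  if (!is.numeric(denominator) || denominator <= 0) {
    stop("denominator must be positive")
  }
  round_half_away(numerator / denominator, decimals)
}

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Two-group Student t-test
#'
#' Pooled-variance (equal variance) two-sided t-test by default; a paired
#' variant for equal-length samples.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param equal_variance pool the variances (classic Student test).
#' @param paired paired test (requires equal lengths).
#' @return list `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, equal_variance = TRUE, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (paired && length(a) != length(b)) {
    stop("paired test requires samples of equal length")
  }
  ht <- stats::t.test(a, b, var.equal = equal_variance, paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
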