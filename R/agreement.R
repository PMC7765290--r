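# Validation statistics: Pearson correlation with Fisher-z confidence
# interval and Cohen strength strata, two-way mixed intraclass correlation
# coefficients, and paired t-tests on baseline vs follow-up scores.

#' Classify correlation strength (Cohen strata)
#'
#' On |r|: < 0.1 negligible, [0.1, 0.3) small, [0.3, 0.5) medium,
#' [0.5, 1] large.
#'
#' @param r Numeric vector with |r| <= 1.
#' @return Character vector of strength labels.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| cannot exceed 1")
  vapply(r, function(v) {
    a <- abs(v)
    if (is.na(a)) NA_character_
    else if (a < 0.1) "negligible"
    else if (a < 0.3) "small"
    else if (a < 0.5) "medium"
    else "large"
  }, character(1L))
}

#' Pearson product-moment correlation with CI, p-value and strength
#'
#' Two-sided p from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom; 95% CI by Fisher z transform, z +/- qnorm(0.975)/sqrt(n - 3),
#' back-transformed.
#'
#' @param x,y Paired numeric vectors, n >= 3, each with positive variance.
#' @return List of class `correlation_result`: `r`, `n`, `ci95`, `p`,
#'   `strength`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- atanh(r)
  half <- stats::qnorm(0.975) / sqrt(n - 3)
  ci <- tanh(c(z - half, z + half))
  structure(list(r = r, n = n, ci95 = c(lower = ci[1], upper = ci[2]),
                 p = p, strength = classify_correlation(r)),
            class = "correlation_result")
}

#' Two-way mixed intraclass correlation coefficients
#'
#' From the two-way ANOVA decomposition of a complete targets x raters grid
#' (rows = targets, columns = raters). The consistency form (default) gives
#' ICC(3,1) and ICC(3,k):
#' `sicc = (MS_rows - MS_err) / (MS_rows + (k - 1) * MS_err)` and
#' `aicc = (MS_rows - MS_err) / MS_rows`. The absolute-agreement form adds
#' the rater mean square to the denominators.
#'
#' @param ratings Numeric matrix or data frame, one row per target, one
#'   column per rater; no missing cells.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return List of class `icc_result`: `sicc` (single measure), `aicc`
#'   (average measure), `k_raters`, `n_targets`, `ms_rows`, `ms_error`,
#'   `type`.
#' @export
icc_two_way <- function(ratings, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("incomplete ratings grid")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 raters")
  long <- data.frame(
    value = as.vector(m),
    target = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  a <- stats::anova(stats::lm(value ~ target + rater, data = long))
  msr <- a["target", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  if (type == "consistency") {
    sicc <- (msr - mse) / (msr + (k - 1) * mse)
    aicc <- (msr - mse) / msr
  } else {
    sicc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    aicc <- (msr - mse) / (msr + (msc - mse) / n)
  }
  structure(list(sicc = sicc, aicc = aicc, k_raters = k, n_targets = n,
                 ms_rows = msr, ms_error = mse, type = type),
            class = "icc_result")
}

#' Paired t-test on baseline vs follow-up scores
#'
#' Two-sided paired t-test on complete cases, with differences taken as
#' `x_t0 - x_t1` (same sign convention as the change scores). Identical
#' timepoints (all differences zero) return t = 0, p = 1; zero-variance
#' differences with a nonzero mean make the test statistic undefined and
#' raise an error.
#'
#' @param x_t0,x_t1 Paired numeric vectors, n >= 2.
#' @return List of class `paired_test_result`: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x_t0, x_t1) {
  if (length(x_t0) != length(x_t1)) stop("x_t0 and x_t1 must be paired")
  n <- length(x_t0)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x_t0 - x_t1
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(structure(list(t = 0, df = n - 1L, p = 1, mean_diff = 0),
                       class = "paired_test_result"))
    stop("zero-variance differences: p-value undefined")
  }
  tt <- stats::t.test(x_t0, x_t1, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(d)),
            class = "paired_test_result")
}
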