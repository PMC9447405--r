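#' Spearman rank correlation with significance
#'
#' Monotone-association statistic between two paired measurement series
#' (e.g. pipeline net intensities vs reference instrument values). On
#' tie-free data the rank-difference formula
#' `r = 1 - 6 * sum(d^2) / (N * (N^2 - 1))` is used, where `d` is the
#' per-pair rank difference and `N` the number of pairs. When ties are
#' present, average ranks are assigned and `r` is the Pearson correlation
#' of the two rank vectors (the two definitions coincide on tie-free
#' data). Significance defaults to the two-sided t-approximation
#' `t = r * sqrt((N - 2) / (1 - r^2))` on `N - 2` degrees of freedom; an
#' exact p-value (AS 89) is available for small samples via
#' `pMethod = "exact"`. `r = +/-1` yields `p = 0` by convention.
#'
#' @param x,y numeric vectors of equal length, no missing values.
#' @param pMethod `"t"` (default) or `"exact"` (delegates to
#'   [stats::cor.test()]; tie-free data, N <= 1290).
#' @return a list of class `"spearmanResult"`: `r`, `N`, `p_value`,
#'   `method` (`"eq_rankdiff"` tie-free, `"rank_pearson"` with ties).
#' @examples
#' spearmanCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
spearmanCorrelation <- function(x, y, pMethod = c("t", "exact")) {
  pMethod <- match.arg(pMethod)
  if (length(x) != length(y))
    stop("x and y must have equal length (got ", length(x), " and ",
         length(y), ")")
  n <- length(x)
  if (n < 2L) stop("at least 2 pairs are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (!ties) {
    d <- rx - ry
    r <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    method <- "eq_rankdiff"
  } else {
    r <- stats::cor(rx, ry)
    method <- "rank_pearson"
  }
  p <- if (abs(r) >= 1) {
    0
  } else if (pMethod == "exact") {
    if (ties) stop("exact p-values require tie-free data")
    stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (n < 3L) {
    NA_real_
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, N = n, p_value = p, method = method),
            class = "spearmanResult")
}

#' @export
print.spearmanResult <- function(x, ...) {
  cat(sprintf("Spearman rank correlation (%s)\n", x$method))
  cat(sprintf("  r = %.4f, N = %d, p = %.4g\n", x$r, x$N, x$p_value))
  invisible(x)
}

#' Ordinary least-squares calibration line
#'
#' Fits `y ~ x` by OLS and reports slope, intercept and the coefficient
#' of determination `R^2 = 1 - SS_res / SS_tot`, the agreement summary
#' used alongside the rank correlation when validating pipeline output
#' against a reference method.
#'
#' @param x,y numeric vectors of equal length, `N >= 2`, `x` not
#'   constant.
#' @return a list of class `"regressionResult"`: `slope`, `intercept`,
#'   `r_squared`, `N`.
#' @export
linearCalibration <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least 2 points are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0) stop("x is constant: no regression line exists")
  fit <- stats::lm(y ~ x)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ssTot > 0) 1 - ssRes / ssTot else 1,
                 N = length(x)),
            class = "regressionResult")
}

#' @export
print.regressionResult <- function(x, ...) {
  cat(sprintf("Linear calibration: y = %.4g x + %.4g, R^2 = %.4f, N = %d\n",
              x$slope, x$intercept, x$r_squared, x$N))
  invisible(x)
}

#' Two-group comparison
#'
#' Two-sided test for a difference between two independent groups (e.g.
#' patient vs healthy-control spot intensities). Default is the
#' Mann-Whitney (Wilcoxon rank-sum) test, exact for small tie-free
#' samples and normal-approximated otherwise; Welch's t-test is
#' available as an alternative.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return two-sided p-value (numeric scalar).
#' @examples
#' compareGroups(c(1, 2), c(3, 4))  # exact Mann-Whitney: p = 1/3
#' @export
compareGroups <- function(a, b, test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  if (length(a) < 1L || length(b) < 1L)
    stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
  } else {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }
}
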