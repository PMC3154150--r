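#' Hotelling's T-squared test
#'
#' Two-sample (default) or one-sample Hotelling's T-squared, the multivariate
#' generalization of the t-test, used here to compare the objective vectors
#' of evolved run representatives against random-search representatives.
#' For two samples of sizes `n1`, `n2` in dimension `d` with pooled
#' covariance `S`, `T2 = n1 n2 / (n1 + n2) * (m1 - m2)' S^-1 (m1 - m2)` and
#' `F = T2 (n1 + n2 - d - 1) / (d (n1 + n2 - 2))` follows an F distribution
#' on `(d, n1 + n2 - d - 1)` degrees of freedom under the null of equal
#' means. The statistic is invariant under any common affine transformation
#' of both samples.
#'
#' @param x numeric matrix, one observation per row (vectors are treated as
#'   one-column matrices).
#' @param y second sample for the two-sample test, or `NULL` for the
#'   one-sample test against `mu`.
#' @param mu null mean vector for the one-sample test (default 0).
#' @return an object of class `"htest"` with the `T2` and `F` statistics,
#'   degrees of freedom and p-value.
#' @examples
#' a <- matrix(rnorm(60), 20, 3)
#' b <- matrix(rnorm(60, mean = 1), 20, 3)
#' hotellingT2(a, b)
#' @export
hotellingT2 <- function(x, y = NULL, mu = 0) {
  x <- rbind(x)
  d <- ncol(x)
  if (!is.null(y)) {
    y <- rbind(y)
    if (ncol(y) != d)
      stop("samples must have the same number of objective components")
    n1 <- nrow(x); n2 <- nrow(y)
    if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
    if (n1 + n2 <= d + 1)
      stop("combined sample size must exceed dimension + 1 for the F test")
    S <- ((n1 - 1) * stats::cov(x) + (n2 - 1) * stats::cov(y)) / (n1 + n2 - 2)
    diff <- colMeans(x) - colMeans(y)
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("pooled covariance is singular; drop collinear or constant ",
           "objective components (or compare fewer components)",
           call. = FALSE))
    t2 <- (n1 * n2) / (n1 + n2) * drop(diff %*% Sinv %*% diff)
    df2 <- n1 + n2 - d - 1
    fstat <- t2 * df2 / (d * (n1 + n2 - 2))
    method <- "Two-sample Hotelling's T-squared test"
    dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  } else {
    n1 <- nrow(x)
    if (n1 <= d) stop("sample size must exceed dimension for the F test")
    mu <- rep_len(mu, d)
    S <- stats::cov(x)
    diff <- colMeans(x) - mu
    Sinv <- tryCatch(solve(S), error = function(e)
      stop("sample covariance is singular; drop collinear or constant ",
           "objective components", call. = FALSE))
    t2 <- n1 * drop(diff %*% Sinv %*% diff)
    df2 <- n1 - d
    fstat <- t2 * df2 / (d * (n1 - 1))
    method <- "One-sample Hotelling's T-squared test"
    dname <- deparse1(substitute(x))
  }
  pval <- stats::pf(fstat, d, df2, lower.tail = FALSE)
  structure(list(
    statistic = c(T2 = t2, F = fstat),
    parameter = c(df1 = d, df2 = df2),
    p.value = pval, method = method, data.name = dname,
    estimate = if (is.null(y)) colMeans(x) else diff,
    alternative = "true mean difference is not zero"),
    class = "htest")
}
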