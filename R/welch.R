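#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test with the Welch–Satterthwaite degrees of
#' freedom. Degenerate case: when both groups have zero variance, p is 1 if
#' the means are equal and 0 otherwise (the data are then deterministic).
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 finite values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    eq <- mean(a) == mean(b)
    return(list(t = if (eq) 0 else Inf, df = na + nb - 2,
                p_value = if (eq) 1 else 0))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Row-wise Welch tests for two matrices
#'
#' Vectorized version of [welch_test()] used by the simulation suites and
#' per-column expression testing: row i of `A` is compared with row i of
#' `B`.
#'
#' @param A,B Numeric matrices with equal row counts; columns are samples.
#' @return Data frame with one row per feature: `t`, `df`, `p_value`,
#'   `delta` (rowMeans(A) - rowMeans(B)).
#' @export
welch_test_rows <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == nrow(B))
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 columns", call. = FALSE)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  delta <- ma - mb
  tstat <- ifelse(se2 > 0, delta / sqrt(se2), ifelse(delta == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df),
              ifelse(delta == 0, 1, 0))
  data.frame(t = tstat, df = df, p_value = p, delta = delta)
}

#' Letter significance tier for a p-value
#'
#' Tiers follow the atlas figure convention, with strict inequalities:
#' a: p < 0.05, b: p < 0.01, c: p < 0.001, d: p < 0.0001. The most
#' stringent applicable tier is returned; p exactly 0.05 is `"none"`.
#'
#' @param p Numeric p-value(s) in \[0, 1\].
#' @return Character vector over `{"none","a","b","c","d"}`.
#' @examples
#' significance_tier(c(0.03, 0.0005, 0.05))  # "a" "c" "none"
#' @export
significance_tier <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 1e-4, "d",
  ifelse(p < 1e-3, "c",
  ifelse(p < 1e-2, "b",
  ifelse(p < 5e-2, "a", "none"))))
}
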