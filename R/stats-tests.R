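# Nonparametric tests with exact small-sample null distributions.

#' Wilcoxon signed-rank test against zero
#'
#' For `n <= exact_max` non-zero values the null distribution of the
#' positive-rank sum V is computed exactly over all 2^n sign assignments
#' via a generating-function convolution on the (doubled, hence integer)
#' average ranks, so ties among |values| are handled exactly as well. For
#' larger n a normal approximation with tie-corrected variance and
#' continuity correction is used. Zeros are dropped beforehand.
#'
#' @param values numeric vector; at least one non-zero entry.
#' @param alternative `"greater"` (default; values stochastically above
#'   zero), `"less"` or `"two.sided"`.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with `statistic` (V), `p.value`, `n` (non-zero values) and
#'   `exact`.
#' @export
#' @examples
#' wilcoxon_vs_zero(c(1, 2, 3, 4, 5))$p.value # 1/32
wilcoxon_vs_zero <- function(values,
                             alternative = c("greater", "less", "two.sided"),
                             exact_max = 25L) {
  alternative <- match.arg(alternative)
  v <- values[values != 0]
  n <- length(v)
  if (!n) stop_data("all values are zero")
  r <- rank(abs(v))
  V <- sum(r[v > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r)) # average ranks doubled -> integers
    tot <- sum(r2)
    cnt <- numeric(tot + 1L) # cnt[s + 1] = #sign patterns with 2V = s
    cnt[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), cnt[seq_len(tot + 1L - ri)])
      cnt <- cnt + shifted
    }
    s <- 0:tot
    tot_patterns <- 2^n
    p_ge <- sum(cnt[s >= round(2 * V) - 1e-9]) / tot_patterns
    p_le <- sum(cnt[s <= round(2 * V) + 1e-9]) / tot_patterns
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sg2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    p_ge <- pnorm((V - mu - 0.5) / sqrt(sg2), lower.tail = FALSE)
    p_le <- pnorm((V - mu + 0.5) / sqrt(sg2))
    exact <- FALSE
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = V, p.value = p, n = n, exact = exact)
}

# All permutations of 1..n as an integer matrix (n! rows); recursive
# insertion construction, intended for small n.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  Psub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(Psub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- seq_len(nrow(Psub)) + row
    if (pos > 1L) out[blk, seq_len(pos - 1L)] <- Psub[, seq_len(pos - 1L)]
    out[blk, pos] <- n
    if (pos < n) out[blk, seq(pos + 1L, n)] <- Psub[, seq(pos, n - 1L)]
    row <- row + nrow(Psub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Correlation of ranks (average ranks under ties). For `n <= exact_max`
#' the p-value is exact, computed by enumerating all n! permutations of one
#' rank vector (conditional on the observed tie pattern); beyond that, the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom is used.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exact_max largest n for which the permutation null is enumerated
#'   (capped at 10).
#' @return list with `rho`, `p.value`, `n` and `exact`.
#' @export
spearman_test <- function(x, y,
                          alternative = c("greater", "less", "two.sided"),
                          exact_max = 8L) {
  alternative <- match.arg(alternative)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_data("need >= 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop_data("constant ranks; rho undefined")
  rho <- cor(rx, ry)
  if (n <= min(exact_max, 10L)) {
    Pm <- perm_matrix(n)
    # rho is a fixed increasing function of T = sum(rx[perm] * ry)
    Tnull <- as.vector(matrix(rx[Pm], nrow(Pm), n) %*% ry)
    Tobs <- sum(rx * ry)
    eps <- 1e-9
    p_ge <- mean(Tnull >= Tobs - eps)
    p_le <- mean(Tnull <= Tobs + eps)
    exact <- TRUE
  } else {
    r <- max(-1 + 1e-12, min(1 - 1e-12, rho))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p_ge <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    p_le <- stats::pt(tstat, df = n - 2)
    exact <- FALSE
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(rho = rho, p.value = p, n = n, exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; a thin, order-preserving
#' wrapper around [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_data("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}
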