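#' One-sample t test
#'
#' Two-sided t test of `mean(x) == mu0` with `t = (mean - mu0) /
#' (sd / sqrt(n))` on `n - 1` degrees of freedom. A zero-variance sample
#' is degenerate: the statistic is returned as missing with
#' `degenerate = TRUE`, never a silent NaN.
#'
#' @param x Numeric sample, `n >= 2`.
#' @param mu0 Null mean (default 0).
#' @return List with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort_domain("one_sample_t needs at least 2 observations.")
  if (sd(x) == 0) {
    return(list(statistic = NA_real_, df = n - 1, p_value = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = mu0, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Cohen's d for two independent samples
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled variance `((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b -
#' 2)`. Conventional magnitudes: ~0.2 small, ~0.5 medium, ~0.8 large.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @return List with `d`, `pooled_sd`, `degenerate` (TRUE when the pooled
#'   SD is zero).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) abort_domain("cohens_d needs n >= 2 in each sample.")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    return(list(d = NA_real_, pooled_sd = 0, degenerate = TRUE))
  }
  list(d = (mean(a) - mean(b)) / sqrt(sp2), pooled_sd = sqrt(sp2),
       degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. `U` is the number of
#' (a, b) pairs with `a > b` (ties count one half). `Z` comes from the
#' normal approximation with the tie correction always applied and a 0.5
#' continuity correction. For combined `n <= 20` with no ties an exact
#' two-sided p value is computed by enumerating all labelings
#' (`2 * min(P(U <= u), P(U >= u))`, capped at 1) and is the reported
#' `p_value`; otherwise the approximation is reported. Both p values are
#' returned.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `U`, `Z`, `p_value`, `p_exact` (NA when not
#'   computed), `p_approx`, `degenerate` (TRUE when every value in the two
#'   samples is identical).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) abort_domain("Both samples must be non-empty.")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(list(U = na * nb / 2, Z = NA_real_, p_value = NA_real_,
                p_exact = NA_real_, p_approx = NA_real_, degenerate = TRUE))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  N <- na + nb
  mu <- na * nb / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  sigma <- sqrt(sigma2)
  cc <- if (U != mu) 0.5 * sign(U - mu) else 0
  Z <- if (sigma > 0) (U - mu - cc) / sigma else NA_real_
  p_approx <- if (is.na(Z)) NA_real_ else 2 * pnorm(-abs(Z))
  has_ties <- any(ties > 1)
  p_exact <- NA_real_
  if (N <= 20 && !has_ties) {
    idx <- combn(N, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p_exact <- min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
  }
  list(U = U, Z = Z,
       p_value = if (!is.na(p_exact)) p_exact else p_approx,
       p_exact = p_exact, p_approx = min(1, p_approx), degenerate = FALSE)
}

#' Wilcoxon signed-rank test
#'
#' One-sample (against `mu0`) or paired signed-rank test. Differences of
#' exactly zero are dropped by the Wilcoxon convention; `W` is the sum of
#' ranks of positive differences. `Z` uses the normal approximation with
#' tie correction and a 0.5 continuity correction. For `n <= 12` nonzero
#' differences with untied magnitudes, an exact two-sided p value is
#' computed by enumerating all sign patterns and is the reported
#' `p_value`.
#'
#' @param x Numeric sample.
#' @param mu0 Null location for the one-sample form (default 0).
#' @param paired_with Optional second sample; differences are
#'   `x - paired_with`.
#' @return List with `W`, `Z`, `p_value`, `p_exact`, `p_approx`,
#'   `n_nonzero`, `degenerate` (TRUE when all differences are zero).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # W = 6, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, mu0 = 0, paired_with = NULL) {
  d <- if (is.null(paired_with)) {
    x - mu0
  } else {
    if (length(x) != length(paired_with)) {
      abort_domain("Paired samples must have the same length.")
    }
    x - paired_with
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(W = NA_real_, Z = NA_real_, p_value = NA_real_,
                p_exact = NA_real_, p_approx = NA_real_, n_nonzero = 0L,
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  cc <- if (W != mu) 0.5 * sign(W - mu) else 0
  Z <- if (sigma > 0) (W - mu - cc) / sigma else NA_real_
  p_approx <- if (is.na(Z)) NA_real_ else min(1, 2 * pnorm(-abs(Z)))
  has_ties <- any(ties > 1)
  p_exact <- NA_real_
  if (n <= 12 && !has_ties) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_exact <- min(1, 2 * min(mean(w_all <= W), mean(w_all >= W)))
  }
  list(W = W, Z = Z,
       p_value = if (!is.na(p_exact)) p_exact else p_approx,
       p_exact = p_exact, p_approx = p_approx, n_nonzero = n,
       degenerate = FALSE)
}
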