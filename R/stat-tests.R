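# Exact nonparametric tests that remain exact under ties.
#
# stats::wilcox.test falls back to a normal approximation whenever ties are
# present (and cannot handle the all-zero-difference case), so the exact
# permutation distributions are computed here by a generating-function
# "shift" algorithm over doubled midranks (doubling makes tied midranks
# integer). Two-sided p-values use the distance-from-mean convention
# p = P(|T - E[T]| >= |t_obs - E[T]|), which reduces to the usual doubled
# tail for symmetric (tie-free) distributions.

EPS_RANK <- 1e-9

# distribution of the size-n subset sum of integer weights w (counts vector
# indexed by sum 0..sum(w)); classic two-dimensional shift algorithm
subset_sum_counts <- function(w, n) {
  S <- sum(w)
  cnt <- matrix(0, nrow = n + 1L, ncol = S + 1L)
  cnt[1L, 1L] <- 1
  for (r in w) {
    kmax <- n  # shift rows top-down so each weight is used at most once
    for (k in kmax:1L) {
      if (r + 1L <= S + 1L)
        cnt[k + 1L, (r + 1L):(S + 1L)] <-
          cnt[k + 1L, (r + 1L):(S + 1L)] + cnt[k, 1L:(S - r + 1L)]
    }
  }
  cnt[n + 1L, ]
}

# distribution of the signed-rank sum over all 2^n sign assignments
# (weights = doubled midranks); one-dimensional convolution
sign_flip_counts <- function(w) {
  S <- sum(w)
  cnt <- numeric(S + 1L)
  cnt[1L] <- 1
  for (r in w) {
    shifted <- c(numeric(r), cnt[1L:(S - r + 1L)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Two-sided Mann-Whitney U test (exact under ties for small samples)
#'
#' Exact permutation p-value over all `choose(n+m, n)` group assignments for
#' combined sample size `n + m <= exact_max` (ties handled by midranks);
#' otherwise a normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined sample size for which the exact
#'   distribution is enumerated (default 20).
#' @return List with `statistic` (U of `x`), `p_value`, `exact` (logical)
#'   and `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y); N <- n + m
  if (n == 0L || m == 0L)
    ks_abort("degenerate_group", "both samples must be non-empty")
  r <- rank(c(x, y))
  Tx <- sum(r[seq_len(n)])
  U <- Tx - n * (n + 1) / 2
  if (N <= exact_max) {
    w <- as.integer(round(2 * r))
    cnt <- subset_sum_counts(w, n)
    t2 <- 2 * Tx
    mu2 <- n * sum(w) / N
    s <- seq_along(cnt) - 1
    p <- sum(cnt[abs(s - mu2) >= abs(t2 - mu2) - EPS_RANK]) / choose(N, n)
    return(list(statistic = U, p_value = min(1, p), exact = TRUE,
                method = "Mann-Whitney U, exact permutation"))
  }
  ties <- table(r)
  sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- U - n * m / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = U, p_value = p, exact = FALSE,
       method = "Mann-Whitney U, normal approximation with tie correction")
}

#' Two-sided Wilcoxon signed-rank test (exact under ties for small samples)
#'
#' Zero differences are dropped (Wilcoxon convention); if all differences
#' are zero the p-value is 1. Exact over all `2^n` sign assignments for
#' `n <= exact_max` non-zero differences, else normal approximation with
#' tie and continuity corrections.
#'
#' @param x Differences, or the first sample if `y` is given.
#' @param y Optional second sample (paired with `x`).
#' @param exact_max Largest number of non-zero differences for which the
#'   exact distribution is computed (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `centered`
#'   (`V - E[V]`, sign-flips when samples are swapped), `p_value`,
#'   `n_nonzero`, `exact` and `method`.
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, centered = 0, p_value = 1, n_nonzero = 0L,
                exact = TRUE,
                method = "Wilcoxon signed rank (all differences zero)"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    w <- as.integer(round(2 * r))
    cnt <- sign_flip_counts(w)
    s <- seq_along(cnt) - 1
    v2 <- 2 * V; mu2 <- sum(w) / 2
    p <- sum(cnt[abs(s - mu2) >= abs(v2 - mu2) - EPS_RANK]) / 2^n
    return(list(statistic = V, centered = V - mu, p_value = min(1, p),
                n_nonzero = n, exact = TRUE,
                method = "Wilcoxon signed rank, exact permutation"))
  }
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, centered = V - mu, p_value = p, n_nonzero = n,
       exact = FALSE,
       method = "Wilcoxon signed rank, normal approximation with tie correction")
}

#' Likelihood-ratio (G) test of independence on a contingency table
#'
#' `G = 2 * sum(obs * log(obs / exp))` over non-zero cells; zero-margin rows
#' and columns are dropped before computing degrees of freedom. G is
#' non-negative and zero iff observed equals expected.
#'
#' @param tab Matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab)))
    ks_abort("invalid_params", "counts must be finite and non-negative")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = 0, df = 0L, p_value = 1))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  nz <- tab > 0
  G <- 2 * sum(tab[nz] * log(tab[nz] / expd[nz]))
  G <- max(0, G)  # guard tiny negative rounding
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = G, df = df,
       p_value = stats::pchisq(G, df, lower.tail = FALSE))
}
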