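#' Pooled-variance two-sample t statistic, group versus rest
#'
#' Classical (Student) two-sample t with pooled variance and a two-tailed p
#' from the t distribution on n1 + n2 - 2 degrees of freedom. The sign is
#' positive when the group mean exceeds the rest mean. A Welch option is
#' provided for unequal variances.
#'
#' @param group_values,rest_values numeric vectors; missing values dropped.
#'   Each needs at least 2 non-missing values.
#' @param welch if TRUE use the Welch unequal-variance statistic.
#' @return list with `t`, `p`, `df`, `mean_group`, `mean_rest`.
#' @export
group_t_statistic <- function(group_values, rest_values, welch = FALSE) {
  x <- group_values[!is.na(group_values)]
  y <- rest_values[!is.na(rest_values)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_group = NA_real_, mean_rest = NA_real_))
  }
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- (m1 - m2) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tt <- if (se == 0) 0 else (m1 - m2) / se
  }
  p <- if (is.nan(tt)) NA_real_ else 2 * stats::pt(-abs(tt), df)
  list(t = tt, p = p, df = df, mean_group = m1, mean_rest = m2)
}

#' Wilcoxon rank-sum statistic with exact small-sample p
#'
#' Mid-ranks are used for ties. When both groups have at most `exact_max`
#' observations the two-tailed p-value is exact: it is computed from the full
#' permutation distribution of the group rank sum (all choose(n1+n2, n1)
#' assignments, evaluated by dynamic programming over rank sums, which is
#' identical to literal enumeration). Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_values,rest_values numeric vectors; missing values dropped.
#' @param exact_max per-group size at or below which the exact distribution is
#'   used (default 20).
#' @return list with `W` (rank sum of the group), `p` (two-tailed), `exact`.
#' @export
ranksum_statistic <- function(group_values, rest_values, exact_max = 20L) {
  x <- group_values[!is.na(group_values)]
  y <- rest_values[!is.na(rest_values)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(list(W = NA_real_, p = NA_real_, exact = NA))
  r <- rank(c(x, y))                      # mid-ranks for ties
  W <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- ranksum_exact_p(r, n1, W)
    return(list(W = W, p = p, exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(W = W, p = 1, exact = FALSE))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)   # continuity correction
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

# Exact two-tailed p for the rank-sum: distribution of the sum of n1 ranks
# drawn without replacement from the (mid-)rank multiset. Ranks are doubled so
# .5 mid-ranks become integers; f[k+1, s+1] counts k-subsets with doubled-rank
# sum s. Two-tailed p doubles the smaller tail (capped at 1), the convention
# matching tail-mass doubling for asymmetric discrete nulls.
ranksum_exact_p <- function(r, n1, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      cols <- which(f[k, ] > 0)
      if (length(cols)) {
        tgt <- cols + v
        ok <- tgt <= smax + 1L
        f[k + 1L, tgt[ok]] <- f[k + 1L, tgt[ok]] + f[k, cols[ok]]
      }
    }
  }
  counts <- f[n1 + 1L, ]
  tot <- sum(counts)
  w2 <- as.integer(round(2 * W))
  sums <- seq_len(smax + 1L) - 1L
  lower <- sum(counts[sums <= w2]) / tot
  upper <- sum(counts[sums >= w2]) / tot
  min(1, 2 * min(lower, upper))
}

#' Signed -log10 p-values
#'
#' Returns -log10(p) with the sign of the effect direction (positive when the
#' group mean exceeds the rest mean), the quantity heat maps display.
#'
#' @param p matrix (or vector) of p-values in (0, 1].
#' @param direction matrix of effect directions (sign of t or of mean
#'   difference), same shape as `p`.
#' @return signed -log10 p matrix.
#' @export
signed_log10_p <- function(p, direction) {
  s <- sign(direction)
  s[s == 0] <- 1
  -log10(p) * s
}
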