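#' Percentile with mid-point probability positions
#'
#' Linear interpolation between order statistics placed at probability
#' points `(k - 0.5) / n`, clamped to the extremes (R's `quantile`
#' type 5) — the convention that reproduces the published quartile ranges
#' of the accuracy tables.
#'
#' @param values Nonempty numeric vector.
#' @param q Percentile in `[0, 100]`.
#' @return Scalar.
#' @export
percentile <- function(values, q) {
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  unname(quantile(values, q / 100, type = 5))
}

#' Exact two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped, tied absolute differences receive average
#' ranks, and for `n <= exact_limit` retained pairs the null distribution
#' of the positive-rank sum is computed exactly by convolution over sign
#' assignments (average ranks are doubled so all rank sums are integers),
#' so ties do not force a normal approximation. Beyond `exact_limit` a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Equal-length numeric vectors (paired observations).
#' @param exact_limit Largest n for the exact null distribution
#'   (default 25).
#' @return List with `statistic` (positive-rank sum `V`), `p_value`
#'   (two-sided), `n` (pairs retained after dropping zero differences) and
#'   `method`.
#' @export
wilcoxon_paired <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))  # average ranks are multiples of 1/2
    # distribution of sum of a random subset of r2: polynomial product
    dist <- c(1, rep(0, sum(r2)))
    for (w in r2) {
      shifted <- c(rep(0, w), head(dist, length(dist) - w))
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p_ge <- sum(dist[(v2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = v, p_value = p, n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = v, p_value = p, n = n, method = "normal")
}

#' Wolpaw information transfer rate
#'
#' Bits per selection
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`
#' scaled to bits per minute by the selection time. The limits `P = 0` and
#' `P = 1` are handled by continuity. At the four-choice chance level
#' `P = 1/N` the rate is zero; at `P = 1` with one selection per 10 s
#' block (four flashes at 2.5 s ISI) it reaches the paradigm's 12 bit/min
#' ceiling.
#'
#' @param accuracy_p Probability of a correct selection, in `[0, 1]`.
#' @param n_choices Number of selectable commands (>= 2), default 4.
#' @param seconds_per_selection Time per selection in seconds, default
#'   `4 * 2.5 = 10`.
#' @return Information transfer rate in bit/min.
#' @export
wolpaw_bitrate <- function(accuracy_p, n_choices = 4, seconds_per_selection = 10) {
  stopifnot(all(accuracy_p >= 0), all(accuracy_p <= 1), n_choices >= 2)
  p <- accuracy_p
  term_p <- ifelse(p > 0, p * log2(p), 0)
  term_q <- ifelse(p < 1, (1 - p) * log2((1 - p) / (n_choices - 1)), 0)
  bits <- log2(n_choices) + term_p + term_q
  bits * 60 / seconds_per_selection
}
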