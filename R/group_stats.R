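# Rank-based group statistics: tie-corrected Kruskal-Wallis omnibus test,
# Dunn's pairwise post hoc z tests with multiplicity adjustment, and
# distribution-free (order-statistic) median confidence intervals.
#
# These are implemented from the defining formulas rather than wrapped from
# stats:: so the tie handling and the Dunn pooled-variance term are explicit
# and testable; base-R implementations serve as independent oracles in the
# test suite.

#' Grouped measurements
#'
#' @param groups Named list of numeric vectors, `>= 2` groups, each non-empty.
#' @return A `group_data` object.
#' @export
group_data <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  for (g in groups) {
    if (length(g) == 0) stop("every group must be non-empty")
    if (anyNA(g) || any(!is.finite(g))) stop("measurements must be finite")
  }
  structure(groups, class = "group_data")
}

.rank_setup <- function(data) {
  groups <- unclass(data)
  pooled <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(pooled)
  r <- rank(pooled)  # mid-ranks for ties
  idx <- rep(seq_along(groups), n)
  rbar <- tapply(r, idx, mean)
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts)
  list(groups = groups, n = n, N = N, rbar = as.numeric(rbar),
       tie_term = tie_term)
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' `H = (12 / (N(N+1))) * sum n_i (Rbar_i - (N+1)/2)^2`, divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)`; p-value from the chi-square
#' distribution with `k - 1` degrees of freedom. Recommended group sizes
#' `>= 3` for the chi-square approximation.
#'
#' @param data A [group_data] (or plain named list of numeric vectors).
#' @return A `kw_result`: list with `H`, `df`, `p_value`,
#'   `tie_correction_factor`.
#' @export
kruskal_wallis <- function(data) {
  if (!inherits(data, "group_data")) data <- group_data(data)
  s <- .rank_setup(data)
  if (s$N < 3) stop("need total N >= 3")
  C <- 1 - s$tie_term / (s$N^3 - s$N)
  if (C <= 0) stop("degenerate data: all pooled values identical")
  H0 <- 12 / (s$N * (s$N + 1)) * sum(s$n * (s$rbar - (s$N + 1) / 2)^2)
  H <- H0 / C
  df <- length(s$groups) - 1L
  structure(list(H = H, df = df,
                 p_value = stats::pchisq(H, df, lower.tail = FALSE),
                 tie_correction_factor = C),
            class = "kw_result")
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each group pair,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3-t)/(12(N-1))) (1/n_i + 1/n_j))`
#' with two-sided p from the standard normal; adjusted over all
#' `k(k-1)/2` pairs by the chosen method, capped at 1.
#'
#' @param data A [group_data] (or plain named list).
#' @param adjust `"bonferroni"` (default, mirroring the GraphPad convention),
#'   `"holm"`, or `"none"`.
#' @return A `dunn_result`: data.frame with columns `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`, plus attribute `adjust`.
#' @export
dunn_posthoc <- function(data, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (!inherits(data, "group_data")) data <- group_data(data)
  s <- .rank_setup(data)
  C <- 1 - s$tie_term / (s$N^3 - s$N)
  if (C <= 0) stop("degenerate data: all pooled values identical")
  k <- length(s$groups)
  var_term <- s$N * (s$N + 1) / 12 - s$tie_term / (12 * (s$N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (q in seq_len(m)) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(var_term * (1 / s$n[i] + 1 / s$n[j]))
    z[q] <- (s$rbar[i] - s$rbar[j]) / se
    p_raw[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  p_adjusted <- .adjust_p(p_raw, adjust)
  out <- data.frame(group1 = names(s$groups)[pairs[1, ]],
                    group2 = names(s$groups)[pairs[2, ]],
                    z = z, p_raw = p_raw, p_adjusted = p_adjusted,
                    stringsAsFactors = FALSE)
  structure(out, adjust = adjust, class = c("dunn_result", "data.frame"))
}

.adjust_p <- function(p, method) {
  m <- length(p)
  switch(method,
    none = p,
    bonferroni = pmin(1, p * m),
    holm = {
      o <- order(p)
      adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
      adj <- cummax(adj)  # enforce monotonicity
      out <- numeric(m); out[o] <- adj
      out
    })
}

#' Distribution-free confidence interval for the median
#'
#' The median is the middle order statistic (mean of the two central values
#' for even n). The CI endpoints are symmetric order statistics
#' `(x_(l), x_(n+1-l))` with `l` the largest index for which the
#' binomial(n, 1/2) tail gives coverage at least `level`. When even the full
#' sample range cannot attain the level (n <= 5 for 0.95), the range is
#' returned and `achieved_coverage` reports the actual (sub-nominal)
#' coverage.
#'
#' @param sample Numeric vector, `n >= 1`.
#' @param level Nominal coverage (default 0.95).
#' @return A `median_ci`: list with `median`, `lower`, `upper`, `level`,
#'   `achieved_coverage`.
#' @export
median_ci <- function(sample, level = 0.95) {
  if (length(sample) == 0) stop("empty sample")
  if (anyNA(sample)) stop("sample must not contain NA")
  n <- length(sample)
  xs <- sort(sample)
  med <- stats::median(xs)
  alpha <- 1 - level
  if (n == 1) {
    return(structure(list(median = med, lower = xs[1], upper = xs[1],
                          level = level, achieved_coverage = 0),
                     class = "median_ci"))
  }
  # coverage of (x_(l), x_(n+1-l)) is 1 - 2 * P(Binom(n, 1/2) <= l - 1)
  cand <- seq_len(floor(n / 2))
  cov <- 1 - 2 * stats::pbinom(cand - 1, n, 0.5)
  ok <- which(cov >= level)
  l <- if (length(ok) > 0) max(ok) else 1L
  structure(list(median = med, lower = xs[l], upper = xs[n + 1 - l],
                 level = level, achieved_coverage = cov[l]),
            class = "median_ci")
}

#' Significance stars at the published thresholds
#'
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  vapply(p, function(v) {
    if (is.na(v)) NA_character_
    else if (v < 1e-4) "****"
    else if (v < 1e-3) "***"
    else if (v < 1e-2) "**"
    else if (v < 0.05) "*"
    else "ns"
  }, character(1))
}
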