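# core Mann-Whitney-type count: #(x < y) + 0.5 #(x = y)
mw_count <- function(x, y) {
  sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
}

# tie-corrected null mean and variance of the Jonckheere-Terpstra statistic
# (Hollander & Wolfe form; reduces to the classical no-tie expressions when
# every pooled value is distinct)
jt_null_moments <- function(groups) {
  n <- lengths(groups)
  N <- sum(n)
  ties <- as.numeric(table(unlist(groups, use.names = FALSE)))
  mean_jt <- (N^2 - sum(n^2)) / 4
  a <- N * (N - 1) * (2 * N + 5) -
    sum(n * (n - 1) * (2 * n + 5)) -
    sum(ties * (ties - 1) * (2 * ties + 5))
  b <- sum(n * (n - 1) * (n - 2)) * sum(ties * (ties - 1) * (ties - 2))
  cc <- sum(n * (n - 1)) * sum(ties * (ties - 1))
  var_jt <- a / 72 +
    b / (36 * N * (N - 1) * (N - 2)) +
    cc / (8 * N * (N - 1))
  list(mean = mean_jt, var = var_jt)
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests the null of identical distributions against an ordered alternative.
#' The statistic sums, over every ordered pair of groups (i < j in the stated
#' order), the Mann-Whitney count `#(x in group i, y in group j : x < y)` plus
#' half the number of ties. Significance uses the asymptotic normal
#' approximation with tie-corrected null variance (the large-sample form
#' standard statistical software reports).
#'
#' @param groups list of numeric vectors in the hypothesized order; at least
#'   two non-empty groups.
#' @param alternative `"two.sided"` (default), `"increasing"` (values tend to
#'   grow along the group order) or `"decreasing"`.
#' @return An object of class `htest` with the JT `statistic`, its null
#'   `mean` and `variance`, the standardized statistic `z`, and `p.value`.
#' @examples
#' jonckheere_terpstra(list(a = c(1, 2), b = c(3, 4), c = 5))
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("two.sided", "increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  if (!is.list(groups)) stop("`groups` must be a list of numeric vectors", call. = FALSE)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least two non-empty groups", call. = FALSE)
  lapply(groups, assert_finite_numeric, name = "groups")
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) jt <- jt + mw_count(groups[[i]], groups[[j]])
  }
  mom <- jt_null_moments(groups)
  z <- (jt - mom$mean) / sqrt(mom$var)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              increasing = stats::pnorm(z, lower.tail = FALSE),
              decreasing = stats::pnorm(z))
  structure(list(
    statistic = c(JT = jt),
    parameter = c(mean = mom$mean, variance = mom$var),
    z = z,
    p.value = p,
    alternative = alternative,
    method = "Jonckheere-Terpstra test (normal approximation, tie-corrected)",
    data.name = paste(names(groups) %||% paste0("group", seq_len(k)), collapse = ", ")
  ), class = "htest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni adjustment of p-values
#'
#' `min(1, p * n_comparisons)`, the correction applied to the pairwise
#' post-hoc significance values.
#'
#' @param p raw p-value(s).
#' @param n_comparisons number of simultaneous comparisons.
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni_adjust <- function(p, n_comparisons) {
  pmin(1, p * n_comparisons)
}

#' Pairwise post-hoc comparisons between groups
#'
#' For every pair of groups, computes the two-sample rank statistic
#' (Mann-Whitney count with the tie-half convention), its tie-corrected
#' standard error under the null, the standardized statistic, the two-sided
#' significance and the Bonferroni-adjusted significance over all pairs —
#' the columns a pairwise trend-test table reports.
#'
#' @param groups named list of numeric score vectors (the order fixes which
#'   group is "sample 1" in each pair).
#' @return A data frame with columns `sample1`, `sample2`, `statistic`,
#'   `std_error`, `std_statistic`, `p_value`, `p_adjusted`; for k groups,
#'   `choose(k, 2)` rows.
#' @export
pairwise_posthoc <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least two non-empty groups", call. = FALSE)
  nm <- names(groups) %||% paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(c) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    g2 <- groups[c(i, j)]
    u <- mw_count(g2[[1L]], g2[[2L]])
    mom <- jt_null_moments(g2)
    se <- sqrt(mom$var)
    z <- (u - mom$mean) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(sample1 = nm[i], sample2 = nm[j], statistic = u,
               std_error = se, std_statistic = z, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value, n_comp)
  out
}
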