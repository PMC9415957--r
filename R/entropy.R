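#' Shift a series to nonnegative values
#'
#' Subtracts the series minimum so that every Poincare-plot coordinate falls
#' in the first quadrant. The subtracted minimum is kept so the transform is
#' invertible.
#'
#' @param series numeric vector, length >= 2, all values finite.
#' @return A list with `values` (nonnegative series, minimum exactly 0) and
#'   `offset` (the subtracted minimum of the input).
#' @examples
#' to_positive_series(c(-2, 0, 3))
#' @export
to_positive_series <- function(series) {
  assert_finite_numeric(series, "series")
  if (length(series) < 2L) stop("`series` must have at least 2 samples", call. = FALSE)
  s_min <- min(series)
  list(values = series - s_min, offset = s_min)
}

#' Build Poincare plot points
#'
#' Pairs each sample with its `delay`-lagged successor: point j is
#' `(x[j], x[j + delay])`. Delay 1 gives the standard form, the scatter of
#' adjacent samples.
#'
#' @param x nonnegative numeric vector (output of [to_positive_series()]).
#' @param delay positive integer lag between abscissa and ordinate.
#' @return A two-column matrix (`x`, `y`) with `length(x) - delay` rows.
#' @export
poincare_points <- function(x, delay = 1L) {
  assert_finite_numeric(x, "x")
  delay <- assert_count(delay, "delay")
  n <- length(x)
  if (n <= delay) stop("series length must exceed `delay`", call. = FALSE)
  idx <- seq_len(n - delay)
  cbind(x = x[idx], y = x[idx + delay])
}

#' Partition Poincare points into equal-width sector rings
#'
#' Draws `rings` concentric circles about the origin, the outermost through
#' the farthest point (radius `l_max`), and counts points per annulus. Ring k
#' is the half-open annulus `[l_{k-1}, l_k)`; the outer ring is closed so the
#' farthest point is always counted. A point's radial distance is the
#' Euclidean norm of its coordinate pair.
#'
#' If every point sits at the origin (`l_max = 0`, a constant series) the
#' partition is flagged degenerate with all mass in ring 1.
#'
#' @param points two-column matrix from [poincare_points()].
#' @param rings number of sector rings W (>= 1).
#' @return An object of class `ring_partition`: a list with `rings`, `l_max`,
#'   `dl` (ring width), `radii` (outer radius of each ring), `counts`,
#'   `p` (occupancy probabilities, summing to 1), `n_points`, `degenerate`.
#' @export
ring_partition <- function(points, rings) {
  rings <- assert_count(rings, "rings")
  if (!is.matrix(points) || ncol(points) != 2L || nrow(points) < 1L) {
    stop("`points` must be a two-column matrix with at least one row", call. = FALSE)
  }
  d <- sqrt(points[, 1L]^2 + points[, 2L]^2)
  l_max <- max(d)
  n <- length(d)
  if (l_max == 0) {
    counts <- c(n, rep(0L, rings - 1L))
    part <- list(rings = rings, l_max = 0, dl = 0,
                 radii = rep(0, rings), counts = counts, p = counts / n,
                 n_points = n, degenerate = TRUE)
    class(part) <- "ring_partition"
    return(part)
  }
  dl <- l_max / rings
  k <- pmin(floor(d / dl) + 1L, rings) # half-open rings, outer ring closed
  counts <- tabulate(k, nbins = rings)
  part <- list(rings = rings, l_max = l_max, dl = dl,
               radii = dl * seq_len(rings), counts = counts, p = counts / n,
               n_points = n, degenerate = FALSE)
  class(part) <- "ring_partition"
  part
}

#' @export
print.ring_partition <- function(x, ...) {
  cat(sprintf("Poincare sector-ring partition: %d rings, %d points, l_max = %.6g%s\n",
              x$rings, x$n_points, x$l_max,
              if (x$degenerate) " (degenerate)" else ""))
  cat("counts:", x$counts, "\n")
  invisible(x)
}

#' Distribution entropy of a ring partition
#'
#' Shannon entropy (natural log) of the ring-occupancy probabilities,
#' `-sum(p_k log p_k)` with `0 log 0 := 0`. Bounded by `log(rings)`, attained
#' for a uniform occupancy; 0 when all points fall in one ring. A degenerate
#' partition (all points at the origin) scores 0.
#'
#' @param partition a `ring_partition`.
#' @return Nonnegative entropy in nats.
#' @export
distribution_entropy <- function(partition) {
  stopifnot(inherits(partition, "ring_partition"))
  if (partition$degenerate) return(0)
  shannon_entropy(partition$p)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Tsallis nonextensive entropy
#'
#' `S_q = (1 - sum(p^q)) / (q - 1)` for a single nonextensive parameter `q`.
#' The q -> 1 limit is Shannon entropy; use [distribution_entropy()] for that
#' case, this function requires `q != 1`.
#'
#' @param p probability vector summing to 1.
#' @param q nonextensive parameter, not equal to 1.
#' @return The Tsallis entropy.
#' @export
tsallis_entropy <- function(p, q) {
  assert_finite_numeric(p, "p")
  if (length(q) != 1L || !is.finite(q) || q == 1) {
    stop("`q` must be a single finite value != 1 (the q = 1 limit is Shannon entropy)",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("`p` must be nonnegative and sum to 1", call. = FALSE)
  }
  (1 - sum(p^q)) / (q - 1)
}

#' Distance-derived nonextensive parameter set
#'
#' Assigns each ring a nonextensive parameter from the reverse-subtracted
#' distance of its center to the origin:
#' `q_k = 1 + l_max - (k - 1) dl - dl/2`. The innermost ring gets the largest
#' q (hence the smallest weight in the entropy), the outermost the smallest
#' (`1 + dl/2`), so high-amplitude excursions dominate. All `q_k > 1`; the
#' values carry the amplitude units of the input series by construction.
#'
#' @param partition a non-degenerate `ring_partition`.
#' @return Numeric vector of length `rings`, strictly decreasing, all > 1.
#' @export
nonextensive_params <- function(partition) {
  stopifnot(inherits(partition, "ring_partition"))
  if (partition$degenerate || partition$dl == 0) {
    stop("degenerate partition (l_max = 0): nonextensive parameters are undefined; ",
         "the entropy of a constant series is 0", call. = FALSE)
  }
  k <- seq_len(partition$rings)
  1 + partition$l_max - (k - 1) * partition$dl - partition$dl / 2
}

#' Nonextensive entropy with a per-unit parameter set
#'
#' Generalizes Tsallis entropy to one nonextensive parameter per probability:
#' `S = sum_k (p_k - p_k^{q_k}) / (q_k - 1)`. Empty cells (`p_k = 0`) and
#' concentrated cells (`p_k = 1`) contribute exactly 0. Any `q_k` within
#' 1e-8 of 1 is evaluated by its continuous limit `-p_k log p_k`, so the
#' whole-set q -> 1 limit recovers Shannon entropy.
#'
#' @param p probability vector summing to 1.
#' @param q vector of nonextensive parameters, same length as `p`, all >= 1
#'   (values below 1 are rejected).
#' @return Nonnegative entropy value.
#' @export
nne <- function(p, q) {
  assert_finite_numeric(p, "p")
  assert_finite_numeric(q, "q")
  if (length(p) != length(q)) stop("`p` and `q` must have equal length", call. = FALSE)
  if (any(q < 1)) stop("all nonextensive parameters must be >= 1", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("`p` must be nonnegative and sum to 1", call. = FALSE)
  }
  terms <- numeric(length(p))
  lim <- abs(q - 1) < 1e-8
  pos <- p > 0
  i <- pos & lim
  terms[i] <- -p[i] * log(p[i])
  i <- pos & !lim
  terms[i] <- (p[i] - p[i]^q[i]) / (q[i] - 1)
  sum(terms)
}

#' Poincare plot nonextensive distribution entropy (NDE)
#'
#' The full pipeline: shift the series to nonnegative values, build the
#' delay-1 Poincare plot, partition it into `rings` equal-width sector rings,
#' derive per-ring nonextensive parameters from ring-center distance, and
#' combine occupancy probabilities and parameters in nonextensive-entropy
#' form. Unlike distribution entropy, the result is sensitive to how far from
#' the origin the occupied rings lie, i.e. to signal amplitude.
#'
#' A constant series (all points at the origin) scores 0. The value is exactly
#' invariant to adding a constant to the series, but not to rescaling it: the
#' nonextensive parameters are computed in the series' native amplitude units.
#' `rescale` divides the positive series by its own maximum first, giving a
#' unit-amplitude variant; it is off by default.
#'
#' @param series numeric vector, length >= 2.
#' @param rings number of sector rings W (default 50, the value at which the
#'   measure stabilizes on fractional Brownian motion).
#' @param delay Poincare plot lag (default 1, the standard form).
#' @param rescale if `TRUE`, divide the min-subtracted series by its maximum
#'   before analysis.
#' @param details if `TRUE`, return a one-row data frame
#'   (`method`, `rings`, `delay`, `value`, `offset`, `l_max`) instead of a
#'   bare value.
#' @return The NDE value (nonnegative), or a one-row data frame.
#' @examples
#' set.seed(1)
#' poincare_nde(cumsum(rnorm(500)), rings = 50)
#' @export
poincare_nde <- function(series, rings = 50L, delay = 1L, rescale = FALSE,
                         details = FALSE) {
  ps <- to_positive_series(series)
  x <- ps$values
  if (rescale && max(x) > 0) x <- x / max(x)
  pts <- poincare_points(x, delay)
  part <- ring_partition(pts, rings)
  value <- if (part$degenerate) 0 else nne(part$p, nonextensive_params(part))
  if (!details) return(value)
  data.frame(method = "NDE", rings = part$rings, delay = as.integer(delay),
             value = value, offset = ps$offset, l_max = part$l_max)
}

#' Poincare plot distribution entropy (DE)
#'
#' Shannon entropy of the sector-ring occupancy probabilities of the Poincare
#' plot. Depends only on the occupancy histogram, not on which rings are
#' occupied, hence is invariant to rescaling the series and blind to
#' amplitude; see [poincare_nde()] for the amplitude-aware variant.
#'
#' @inheritParams poincare_nde
#' @param rings number of sector rings (default 40).
#' @return The DE value in nats, in `[0, log(rings)]`, or a one-row data
#'   frame when `details = TRUE`.
#' @export
poincare_de <- function(series, rings = 40L, delay = 1L, details = FALSE) {
  ps <- to_positive_series(series)
  pts <- poincare_points(ps$values, delay)
  part <- ring_partition(pts, rings)
  value <- distribution_entropy(part)
  if (!details) return(value)
  data.frame(method = "DE", rings = part$rings, delay = as.integer(delay),
             value = value, offset = ps$offset, l_max = part$l_max)
}
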