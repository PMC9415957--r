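#' Autocovariance of fractional Gaussian noise
#'
#' Autocovariance at integer lag k of the unit-variance increment process of
#' fractional Brownian motion with Hurst index H:
#' `gamma(k) = 0.5 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`.
#' `gamma(0) = 1`; for H = 0.5 increments are uncorrelated; H > 0.5 gives
#' persistent (positive) and H < 0.5 anti-persistent (negative) lag-1
#' correlation.
#'
#' @param H Hurst index in (0, 1).
#' @param lag nonnegative integer lag(s); vectorized.
#' @return Autocovariance value(s).
#' @export
fgn_autocovariance <- function(H, lag) {
  if (length(H) != 1L || !is.finite(H) || H <= 0 || H >= 1) {
    stop("`H` must be in (0, 1); H = 1 is handled by generate_fbm directly",
         call. = FALSE)
  }
  if (any(lag < 0) || any(lag != floor(lag))) {
    stop("`lag` must contain nonnegative integers", call. = FALSE)
  }
  k <- as.numeric(lag)
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Davies-Harte / circulant-embedding sampler for fractional Gaussian noise.
# Embeds the n-term covariance in a circulant of size m = 2^ceil(log2(2n));
# for fGn the circulant eigenvalues are nonnegative for all H in (0,1), but a
# Cholesky fallback on the Toeplitz covariance guards against numerical
# failure at extreme H.
fgn_sample <- function(n, H) {
  m <- 2^ceiling(log2(2 * n))
  gamma <- fgn_autocovariance(H, 0:(m / 2))
  first_row <- c(gamma, rev(gamma[2:(m / 2)]))
  lambda <- Re(stats::fft(first_row))
  if (any(lambda < -1e-8 * max(lambda))) {
    return(fgn_sample_cholesky(n, H))
  }
  lambda[lambda < 0] <- 0
  half <- m / 2
  v <- complex(length.out = m)
  v[1] <- stats::rnorm(1)
  v[half + 1] <- stats::rnorm(1)
  re <- stats::rnorm(half - 1)
  im <- stats::rnorm(half - 1)
  v[2:half] <- complex(real = re, imaginary = im) / sqrt(2)
  v[m:(half + 2)] <- Conj(v[2:half])
  z <- Re(stats::fft(sqrt(lambda / m) * v))
  z[seq_len(n)]
}

fgn_sample_cholesky <- function(n, H) {
  gamma <- fgn_autocovariance(H, 0:(n - 1))
  sigma <- stats::toeplitz(gamma)
  cf <- chol(sigma)
  as.numeric(crossprod(cf, stats::rnorm(n)))
}

#' Generate fractional Brownian motion
#'
#' Samples an fBm path with exact increment covariance: the increments are
#' stationary Gaussian with the fractional-Gaussian-noise autocovariance
#' implied by `E[B_t B_s] = (t^(2H) + s^(2H) - |t - s|^(2H)) / 2`, drawn by
#' circulant embedding (Davies-Harte), with a Cholesky factorization of the
#' Toeplitz covariance as fallback. The path starts at exactly 0 and
#' `Var(B_t) = t^(2H)` with t counted in samples. The degenerate H = 1 case
#' returns the perfectly correlated path `B_t = t * Z` with Z standard normal.
#'
#' @param H Hurst index in (0, 1].
#' @param n series length in samples (>= 2).
#' @param seed optional integer; if given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of length `n`, first element 0.
#' @examples
#' b <- generate_fbm(0.7, 1000, seed = 42)
#' @export
generate_fbm <- function(H, n, seed = NULL) {
  if (length(H) != 1L || !is.finite(H) || H <= 0 || H > 1) {
    stop("`H` must be in (0, 1]", call. = FALSE)
  }
  n <- assert_count(n, "n", min = 2L)
  with_seed(seed, {
    if (H == 1) {
      (0:(n - 1)) * stats::rnorm(1)
    } else {
      cumsum(c(0, fgn_sample(n - 1L, H)))
    }
  })
}
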