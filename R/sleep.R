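#' Remove the slow trend of a signal by singular-spectrum analysis
#'
#' Embeds the series in a Hankel trajectory matrix of `embedding_dim` rows,
#' eigen-decomposes its lag-covariance, reconstructs the component carried by
#' the leading `trend_rank` singular directions by diagonal averaging, and
#' subtracts it. The leading singular components of an EEG trace capture the
#' baseline drift and slow trend; the residual keeps the oscillatory content.
#'
#' @param series numeric vector, longer than `embedding_dim`.
#' @param embedding_dim trajectory-matrix window length in samples
#'   (default 200, i.e. 2 s at 100 Hz).
#' @param trend_rank number of leading components treated as trend
#'   (default 1; a linear ramp needs at most 2).
#' @return Detrended series, same length as the input.
#' @export
svd_detrend <- function(series, embedding_dim = 200L, trend_rank = 1L) {
  assert_finite_numeric(series, "series")
  embedding_dim <- assert_count(embedding_dim, "embedding_dim", min = 2L)
  trend_rank <- assert_count(trend_rank, "trend_rank")
  if (trend_rank >= embedding_dim) {
    stop("`trend_rank` must be smaller than `embedding_dim`", call. = FALSE)
  }
  n <- length(series)
  if (n <= embedding_dim) {
    stop("series must be longer than `embedding_dim`", call. = FALSE)
  }
  series - ssa_reconstruct(series, embedding_dim, trend_rank)
}

# full linear convolution, zero-padded to a 2-3-5-smooth FFT length so cost
# stays n log n for any input length
conv_full <- function(a, b) {
  n_out <- length(a) + length(b) - 1L
  m <- stats::nextn(n_out, c(2L, 3L, 5L))
  fa <- stats::fft(c(a, numeric(m - length(a))))
  fb <- stats::fft(c(b, numeric(m - length(b))))
  Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n_out)] / m
}

# Rank-r SSA reconstruction. The Gram matrix S = X X^T of the L x K Hankel
# trajectory matrix is built from its first row by the sliding-product
# recursion S[i+1, j+1] = S[i, j] - x_i x_j + x_{K+i} x_{K+j}, so X is never
# materialized; eigenvectors of S are the left singular vectors of X.
ssa_reconstruct <- function(x, L, r) {
  n <- length(x)
  K <- n - L + 1L
  S <- matrix(0, L, L)
  head_k <- x[seq_len(K)]
  for (j in seq_len(L)) S[1L, j] <- sum(head_k * x[j:(j + K - 1L)])
  S[, 1L] <- S[1L, ]
  for (i in seq_len(L - 1L)) {
    j <- (i + 1L):L
    S[i + 1L, j] <- S[i, j - 1L] - x[i] * x[j - 1L] + x[K + i] * x[K + j - 1L]
    S[j, i + 1L] <- S[i + 1L, j]
  }
  u <- eigen(S, symmetric = TRUE)$vectors[, seq_len(r), drop = FALSE]
  recon <- numeric(n)
  weights <- pmin(seq_len(n), L, K, n - seq_len(n) + 1L)
  for (m in seq_len(r)) {
    um <- u[, m]
    ym <- conv_full(rev(um), x)[L:(L + K - 1L)] # u_m^T X, length K
    recon <- recon + conv_full(um, ym)          # anti-diagonal sums of u_m y_m^T
  }
  recon / weights
}

#' Zero-phase 1-32 Hz band-pass filter
#'
#' Default realization is a 4th-order Butterworth band-pass applied
#' forward-backward (`signal::filtfilt`), giving zero phase distortion.
#' `method = "fft"` instead zeroes all Fourier components outside 1-32 Hz —
#' an ideal band-limiter, equivalent to harmonic-wavelet (boxcar-in-frequency)
#' filtering. Both retain a 10 Hz component essentially unchanged and
#' attenuate DC/drift and components above 32 Hz.
#'
#' @param series numeric vector.
#' @param fs sampling rate in Hz; must exceed 64 Hz so the 32 Hz band edge is
#'   below Nyquist.
#' @param method `"butterworth"` (default) or `"fft"`.
#' @param band passband edges in Hz (default `c(1, 32)`).
#' @return Filtered series, same length, zero phase shift in the passband.
#' @export
bandpass_1_32 <- function(series, fs = 100, method = c("butterworth", "fft"),
                          band = c(1, 32)) {
  assert_finite_numeric(series, "series")
  method <- match.arg(method)
  if (fs <= 2 * band[2]) {
    stop(sprintf("`fs` must exceed %g Hz for a %g Hz band edge", 2 * band[2], band[2]),
         call. = FALSE)
  }
  if (method == "butterworth") {
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, series))
  } else {
    n <- length(series)
    freq <- (seq_len(n) - 1L) / n * fs
    freq <- pmin(freq, fs - freq) # two-sided frequency axis
    keep <- freq >= band[1] & freq <= band[2]
    Re(stats::fft(stats::fft(series) * keep, inverse = TRUE)) / n
  }
}

#' Score 30-second epochs by sliding-window NDE
#'
#' Segments a (preprocessed) signal into fixed-length epochs and scores each
#' epoch by the mean Poincare-plot NDE over overlapping sliding windows within
#' the epoch. With the defaults (30 s epochs at 100 Hz, window 1000 samples,
#' step 10) each epoch is summarized by 201 windows.
#'
#' @param signal numeric vector, the preprocessed recording.
#' @param hypnogram optional integer stage code per epoch
#'   (0 AWAKE, 1-4 NREM, 5 REM, 6 movement, 9 unscored); recycled checking is
#'   strict — its length must equal the epoch count.
#' @param rings number of sector rings (default 50).
#' @param fs sampling rate in Hz (default 100).
#' @param epoch_s epoch length in seconds (default 30).
#' @param width,step sliding-window width and hop within an epoch (samples).
#' @return A data frame with columns `epoch`, `stage` (NA if no hypnogram),
#'   `nde`. Trailing samples not filling an epoch are dropped with a warning.
#' @export
score_epochs <- function(signal, hypnogram = NULL, rings = 50L, fs = 100,
                         epoch_s = 30, width = 1000L, step = 10L) {
  assert_finite_numeric(signal, "signal")
  epoch_len <- as.integer(round(fs * epoch_s))
  n_epochs <- length(signal) %/% epoch_len
  if (n_epochs < 1L) stop("signal shorter than one epoch", call. = FALSE)
  if (length(signal) %% epoch_len != 0L) {
    warning(sprintf("dropping %d trailing samples that do not fill an epoch",
                    length(signal) %% epoch_len))
  }
  if (!is.null(hypnogram) && length(hypnogram) != n_epochs) {
    stop("`hypnogram` length must equal the epoch count", call. = FALSE)
  }
  nde <- vapply(seq_len(n_epochs), function(e) {
    seg <- signal[((e - 1L) * epoch_len + 1L):(e * epoch_len)]
    windowed_entropy(seg, width = width, step = step, rings = rings, method = "NDE")
  }, numeric(1))
  data.frame(epoch = seq_len(n_epochs),
             stage = if (is.null(hypnogram)) NA_integer_ else as.integer(hypnogram),
             nde = nde)
}

#' Group per-epoch scores by sleep stage
#'
#' Collects epoch scores into one sample per stage, in a stated order of
#' expected decreasing complexity, for ordered-trend testing. NREM stage 1 is
#' excluded by default (few epochs in typical recordings), as are movement
#' (6) and unscored (9) epochs.
#'
#' @param scores data frame from [score_epochs()] with a `stage` column.
#' @param order stage codes in the hypothesized order of decreasing score;
#'   default AWAKE (0), REM (5), stage 2, stage 3, stage 4.
#' @param include_n1 if `TRUE`, keep NREM-1 epochs (code 1) appended after
#'   AWAKE in the ordering; default drops them.
#' @return Named list of numeric score vectors, one per stage present, in the
#'   requested order; empty stages are dropped.
#' @export
group_stage_scores <- function(scores, order = c(0L, 5L, 2L, 3L, 4L),
                               include_n1 = FALSE) {
  stopifnot(is.data.frame(scores), all(c("stage", "nde") %in% names(scores)))
  if (include_n1 && !1L %in% order) order <- append(order, 1L, after = 1L)
  labels <- c(`0` = "AWAKE", `1` = "N1", `2` = "stage2", `3` = "stage3",
              `4` = "stage4", `5` = "REM")
  groups <- lapply(order, function(code) scores$nde[scores$stage == code])
  names(groups) <- labels[as.character(order)]
  groups[lengths(groups) > 0L]
}

# per-stage generator parameters: spectral slope beta of the 1/f^beta noise
# and RMS amplitude (arbitrary microvolt-like units). Deeper NREM has a
# steeper spectrum and larger slow-wave amplitude; wake and REM are flatter
# and lower amplitude, so NDE is designed to fall AWAKE > REM > s2 > s3 > s4.
stage_params <- function() {
  data.frame(code = c(0L, 1L, 2L, 3L, 4L, 5L),
             beta = c(0.8, 1.2, 1.6, 2.0, 2.2, 1.0),
             amp = c(10, 15, 25, 45, 60, 12))
}

# Band-limited 1/f^beta Gaussian noise of length n, unit variance. The
# spectrum is shaped only inside `band` (Hz) and zero outside: scalp-EEG
# stage amplitudes are conventionally quoted on the 0.5-35 Hz rhythms, so the
# generator's amplitude parameter is in-band RMS and survives the 1-32 Hz
# preprocessing filter the way real slow-wave amplitude does.
colored_noise <- function(n, beta, fs = 100, band = c(0.5, 35)) {
  half <- n %/% 2
  f <- seq_len(half) / n * fs
  mag <- ifelse(f >= band[1] & f <= band[2], f^(-beta / 2), 0)
  coef <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * mag
  spec <- complex(length.out = n)
  spec[2:(half + 1)] <- coef
  spec[n:(n - half + 2)] <- Conj(coef[seq_len(half - 1L)])
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

#' Synthesize a stage-labelled sleep-like EEG record
#'
#' Generates per-epoch colored Gaussian noise whose spectral slope and
#' amplitude depend on the sleep stage: deeper NREM stages get a steeper
#' 1/f^beta spectrum and larger slow-wave amplitude, wake and REM a flatter
#' spectrum and smaller amplitude. The epochs are concatenated in hypnogram
#' order. This emulates the stage-dependent character real sleep EEG shows to
#' the Poincare-plot NDE, so the full scoring-and-trend-testing pipeline can
#' run without any recording; it does not emulate spindles, K-complexes,
#' artifacts or stage-transition dynamics.
#'
#' @param stages integer stage code per epoch (0 AWAKE, 1-4 NREM, 5 REM).
#' @param fs sampling rate in Hz (default 100).
#' @param epoch_s epoch length in seconds (default 30).
#' @param seed optional integer for a reproducible record.
#' @return A list of class `sleep_record` with `signal` (length
#'   `fs * epoch_s * length(stages)`), `hypnogram`, `fs`, `epoch_s`.
#' @examples
#' rec <- synth_sleep_record(rep(c(0L, 2L, 3L), each = 2), seed = 7)
#' @export
synth_sleep_record <- function(stages, fs = 100, epoch_s = 30, seed = NULL) {
  pars <- stage_params()
  stages <- as.integer(stages)
  if (!all(stages %in% pars$code)) {
    stop("unknown stage code: generator supports codes 0-5", call. = FALSE)
  }
  epoch_len <- as.integer(round(fs * epoch_s))
  signal <- with_seed(seed, {
    unlist(lapply(stages, function(code) {
      row <- pars[pars$code == code, ]
      row$amp * colored_noise(epoch_len, row$beta, fs = fs)
    }), use.names = FALSE)
  })
  structure(list(signal = signal, hypnogram = stages, fs = fs, epoch_s = epoch_s),
            class = "sleep_record")
}

#' @export
print.sleep_record <- function(x, ...) {
  cat(sprintf("sleep_record: %d epochs of %gs at %g Hz (%d samples)\n",
              length(x$hypnogram), x$epoch_s, x$fs, length(x$signal)))
  print(table(stage = x$hypnogram))
  invisible(x)
}

#' End-to-end sleep staging analysis
#'
#' Runs the full pipeline on a record: singular-spectrum detrending,
#' zero-phase 1-32 Hz band-pass, per-epoch sliding-window NDE scoring, stage
#' grouping, Jonckheere-Terpstra ordered-trend test and Bonferroni-adjusted
#' pairwise comparisons.
#'
#' @param record a `sleep_record` (or any list with `signal`, `hypnogram`,
#'   `fs`, `epoch_s`).
#' @param rings number of sector rings for the NDE (default 50).
#' @param order stage codes in hypothesized order of decreasing NDE.
#' @param width,step sliding-window parameters within each epoch.
#' @param detrend,bandpass logical switches for the two preprocessing steps.
#' @return A list with `scores` (per-epoch data frame), `groups`, `trend`
#'   (the Jonckheere-Terpstra `htest`), and `pairwise` (post-hoc table).
#' @export
sleep_analysis <- function(record, rings = 50L, order = c(0L, 5L, 2L, 3L, 4L),
                           width = 1000L, step = 10L,
                           detrend = TRUE, bandpass = TRUE) {
  x <- record$signal
  if (detrend) x <- svd_detrend(x)
  if (bandpass) x <- bandpass_1_32(x, fs = record$fs)
  scores <- score_epochs(x, record$hypnogram, rings = rings, fs = record$fs,
                         epoch_s = record$epoch_s, width = width, step = step)
  groups <- group_stage_scores(scores, order = order)
  trend <- jonckheere_terpstra(groups)
  pairwise <- pairwise_posthoc(groups)
  list(scores = scores, groups = groups, trend = trend, pairwise = pairwise)
}
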