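#' Default run configuration
#'
#' The recommended operating point: 50 sector rings, delay 1, sliding window
#' width 2500 with step 500 (for fractional-Brownian-motion-scale series),
#' width 1000 / step 10 within 30 s sleep epochs, 20 replicates, stage order
#' AWAKE, REM, stage 2, stage 3, stage 4.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    rings = 50L,
    delay = 1L,
    width = 2500L,
    step = 500L,
    epoch_width = 1000L,
    epoch_step = 10L,
    hurst_grid = seq(0.05, 1, by = 0.05),
    length = 20000L,
    replicates = 20L,
    seed = 1L,
    stage_order = c(0L, 5L, 2L, 3L, 4L),
    filter_method = "butterworth",
    detrend = TRUE,
    bandpass = TRUE
  )
}

#' Load and merge a run configuration
#'
#' Merge order: package defaults, then a YAML config file, then explicit
#' overrides (e.g. command-line flags) — later sources win. Unknown keys are
#' rejected, and merged values are validated against the module preconditions
#' (positive ring count, delay, window sizes, Hurst grid in (0, 1], ...).
#'
#' @param path optional YAML file; `NULL` or a missing/empty file means pure
#'   defaults.
#' @param overrides named list of values that take precedence over the file.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    from_file <- yaml::read_yaml(path)
    if (length(from_file)) cfg <- merge_config(cfg, from_file, "config file")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  validate_run_config(cfg)
}

merge_config <- function(cfg, new, src) {
  new <- new[!vapply(new, is.null, logical(1))]
  unknown <- setdiff(names(new), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s) in %s: %s", src,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(new)] <- new
  cfg
}

validate_run_config <- function(cfg) {
  cfg$rings <- assert_count(cfg$rings, "rings")
  cfg$delay <- assert_count(cfg$delay, "delay")
  cfg$width <- assert_count(cfg$width, "width")
  cfg$step <- assert_count(cfg$step, "step")
  cfg$epoch_width <- assert_count(cfg$epoch_width, "epoch_width")
  cfg$epoch_step <- assert_count(cfg$epoch_step, "epoch_step")
  cfg$length <- assert_count(cfg$length, "length", min = 2L)
  cfg$replicates <- assert_count(cfg$replicates, "replicates")
  cfg$seed <- assert_count(cfg$seed, "seed", min = 0L)
  if (any(cfg$hurst_grid <= 0 | cfg$hurst_grid > 1)) {
    stop("`hurst_grid` values must be in (0, 1]", call. = FALSE)
  }
  if (!cfg$filter_method %in% c("butterworth", "fft")) {
    stop("`filter_method` must be \"butterworth\" or \"fft\"", call. = FALSE)
  }
  cfg
}

#' Write a results table to CSV at full precision
#'
#' Deterministic column order (as given), no row names, 17 significant digits
#' for doubles so that write -> read -> write round-trips byte-identically.
#'
#' @param rows data frame of results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a single-column numeric series
#'
#' Accepts a plain numeric text file (one value per line) or a CSV with a
#' header, in which case `column` selects the series.
#'
#' @param path input file.
#' @param column column name or index for CSV input (default 1).
#' @return Numeric vector.
#' @export
read_series <- function(path, column = 1L) {
  first <- readLines(path, n = 1L)
  if (suppressWarnings(is.na(as.numeric(first)))) {
    df <- utils::read.csv(path)
    as.numeric(df[[column]])
  } else {
    as.numeric(scan(path, quiet = TRUE))
  }
}

#' Read one signal from an EDF file
#'
#' Minimal reader for continuous European Data Format recordings: parses the
#' fixed-width ASCII header, extracts one signal across all data records and
#' maps digital values to physical units by the per-signal calibration.
#' Supports plain EDF (16-bit integer samples); annotation channels and EDF+
#' discontinuous files are out of scope.
#'
#' @param path EDF file.
#' @param signal signal index (1-based) or label substring.
#' @return A list with `signal` (numeric, physical units), `fs` (Hz),
#'   `label`, and `n_records`.
#' @export
read_edf <- function(path, signal = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  version <- hdr(8)
  if (version != "0") stop("not an EDF file (version field != 0)", call. = FALSE)
  hdr(80); hdr(80); hdr(8); hdr(8) # patient, recording, date, time
  header_bytes <- as.integer(hdr(8))
  hdr(44)
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(nchars) vapply(seq_len(ns), function(i) hdr(nchars), character(1))
  labels <- field(16)
  field(80) # transducer
  field(8)  # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80) # prefiltering
  spr <- as.integer(field(8)) # samples per record
  field(32) # reserved
  seek(con, header_bytes)
  idx <- if (is.character(signal)) {
    hit <- grep(signal, labels, fixed = TRUE)
    if (!length(hit)) stop("no signal label matching \"", signal, "\"", call. = FALSE)
    hit[1L]
  } else as.integer(signal)
  if (idx < 1L || idx > ns) stop("signal index out of range", call. = FALSE)
  gain <- (phys_max[idx] - phys_min[idx]) / (dig_max[idx] - dig_min[idx])
  offset <- phys_min[idx] - gain * dig_min[idx]
  rec_len <- sum(spr)
  out <- numeric(n_records * spr[idx])
  pre <- if (idx > 1L) sum(spr[seq_len(idx - 1L)]) else 0L
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = rec_len, size = 2L, signed = TRUE,
                   endian = "little")
    out[((r - 1L) * spr[idx] + 1L):(r * spr[idx])] <- rec[(pre + 1L):(pre + spr[idx])]
  }
  list(signal = gain * out + offset, fs = spr[idx] / record_dur,
       label = labels[idx], n_records = n_records)
}

#' Read a plain-text hypnogram
#'
#' One integer stage code per line (or whitespace-separated), using the
#' Rechtschaffen-Kales convention: 0 AWAKE, 1-4 NREM stages, 5 REM,
#' 6 movement time, 9 unscored.
#'
#' @param path text file.
#' @return Integer vector of per-epoch stage codes.
#' @export
read_hypnogram <- function(path) {
  codes <- as.integer(scan(path, quiet = TRUE))
  bad <- setdiff(unique(codes), c(0:6, 9L))
  if (length(bad)) stop("invalid stage code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  codes
}
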