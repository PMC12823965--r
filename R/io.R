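#' Single-channel EEG signal
#'
#' Lightweight container for one electrode's samples. Everything downstream
#' (filtering, decomposition, entropy features) consumes this unit.
#'
#' @param samples numeric vector of samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel electrode label in 10-20 nomenclature (e.g. "FZ").
#' @return an object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, channel = "X1") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate fs must be a positive scalar")
  structure(list(samples = samples, fs = fs,
                 channel = normalize_labels(channel)),
            class = "eeg_signal")
}

#' Multichannel EEG recording
#'
#' @param data numeric matrix, samples in rows, one column per channel.
#' @param fs sampling rate in Hz shared by all channels.
#' @param labels electrode labels, one per column.
#' @param condition class label, `"task"` or `"rest"`.
#' @param subject_id subject identifier.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, condition = c("rest", "task"),
                          subject_id = "S01") {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  labels <- normalize_labels(labels)
  if (length(labels) != ncol(data))
    stop(sprintf("%d labels supplied for %d channels",
                 length(labels), ncol(data)))
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    stop("duplicate channel labels: ", paste(dup, collapse = ", "))
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (fs <= 0) stop("sampling rate fs must be positive")
  colnames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 condition = condition, subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat(sprintf("  subject %s, condition %s\n", x$subject_id, x$condition))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

# 10-20 nomenclature normalization.  Old temporal names (T3/T4/T5/T6) map
# to modern ones only through the explicit alias table, never silently.
.t1020_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Normalize electrode labels
#'
#' Upper-cases labels and strips whitespace. Legacy temporal labels
#' (T3/T4/T5/T6) are translated to their modern equivalents (T7/T8/P7/P8)
#' only when `apply_aliases = TRUE`.
#'
#' @param labels character vector of electrode labels.
#' @param apply_aliases translate legacy temporal labels.
#' @return normalized character vector.
#' @export
normalize_labels <- function(labels, apply_aliases = FALSE) {
  out <- toupper(trimws(as.character(labels)))
  if (apply_aliases) {
    hit <- out %in% names(.t1020_aliases)
    out[hit] <- unname(.t1020_aliases[out[hit]])
  }
  out
}

# ---------------------------------------------------------------------------
# EDF reading

read_edf_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a recording from an EDF file
#'
#' Minimal reader for continuous European Data Format files with one
#' uniform sampling rate across all data channels. Digital values are
#' rescaled to physical units using the per-signal calibration fields.
#'
#' @param path path to the EDF file.
#' @param condition,subject_id metadata attached to the recording (EDF
#'   carries neither a class label nor a normalized subject field).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, condition = "rest", subject_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_ascii(con, 8L)
  if (version != "0") stop("malformed EDF header in ", path,
                           " (unsupported version field: '", version, "')")
  patient <- read_edf_ascii(con, 80L)
  read_edf_ascii(con, 80L)   # recording id
  read_edf_ascii(con, 8L)    # start date
  read_edf_ascii(con, 8L)    # start time
  header_bytes <- as.integer(read_edf_ascii(con, 8L))
  read_edf_ascii(con, 44L)   # reserved
  n_records <- as.integer(read_edf_ascii(con, 8L))
  record_dur <- as.numeric(read_edf_ascii(con, 8L))
  ns <- as.integer(read_edf_ascii(con, 4L))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L ||
      is.na(record_dur) || record_dur <= 0)
    stop("malformed EDF header in ", path)
  field <- function(w) vapply(seq_len(ns), function(i) read_edf_ascii(con, w),
                              character(1))
  labels   <- field(16L)
  field(80L)                 # transducer
  field(8L)                  # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min  <- as.numeric(field(8L))
  dig_max  <- as.numeric(field(8L))
  field(80L)                 # prefiltering
  nsamp    <- as.integer(field(8L))
  field(32L)                 # reserved
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF file contains no data channels: ", path)
  if (length(unique(nsamp[keep])) != 1L)
    stop("channels with unequal sampling rates in ", path, ": ",
         paste(sprintf("%s=%d", labels[keep], nsamp[keep]), collapse = ", "))
  fs <- nsamp[keep][1] / record_dur
  seek(con, header_bytes)
  per_rec <- sum(nsamp)
  raw <- readBin(con, "integer", n = per_rec * n_records, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < per_rec * n_records)
    stop("truncated EDF data section in ", path)
  offsets <- cumsum(c(0L, nsamp[-ns]))
  data <- matrix(0, nrow = nsamp[keep][1] * n_records, ncol = sum(keep))
  col <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    col <- col + 1L
    idx <- as.vector(outer(seq_len(nsamp[i]), (seq_len(n_records) - 1L) * per_rec + offsets[i], `+`))
    dig <- raw[idx]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[, col] <- (dig - dig_min[i]) * gain + phys_min[i]
  }
  lab <- normalize_labels(labels[keep])
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    stop("duplicate channel labels in ", path, ": ", paste(dup, collapse = ", "))
  if (is.null(subject_id)) subject_id <- if (nzchar(patient)) patient else "S01"
  eeg_recording(data, fs = fs, labels = lab, condition = condition,
                subject_id = subject_id)
}

# ---------------------------------------------------------------------------
# Delimited text I/O (one column per channel, sidecar JSON metadata)

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a recording from delimited text
#'
#' Expects one column per channel. `fs` and `labels` may be given
#' explicitly or read from the sidecar metadata file written by
#' [write_delimited()] (`<path>.meta.json`). A header row of labels is
#' used when `labels` is not supplied otherwise.
#'
#' @param path delimited text file (separator inferred: `,` for `.csv`,
#'   tab otherwise).
#' @param fs sampling rate in Hz.
#' @param labels electrode labels, one per column.
#' @param condition,subject_id metadata; sidecar values take precedence
#'   over these defaults when present.
#' @return an [eeg_recording()].
#' @export
read_delimited <- function(path, fs = NULL, labels = NULL,
                           condition = "rest", subject_id = "S01") {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  fs <- fs %||% meta$fs
  labels <- labels %||% meta$labels
  condition <- meta$condition %||% condition
  subject_id <- meta$subject_id %||% subject_id
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty file: ", path)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]]))))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "numeric")
  if (nrow(tab) == 0L) stop("empty file: ", path)
  if (is.null(labels)) {
    if (!has_header) stop("no labels supplied and file has no header row: ", path)
    labels <- colnames(tab)
  }
  if (length(labels) != ncol(tab))
    stop(sprintf("%d labels supplied for %d data columns in %s",
                 length(labels), ncol(tab), path))
  if (is.null(fs)) stop("sampling rate fs not supplied and no sidecar found for ", path)
  eeg_recording(as.matrix(tab), fs = fs, labels = labels,
                condition = condition, subject_id = subject_id)
}

#' Write a recording as delimited text plus sidecar metadata
#'
#' @param rec an [eeg_recording()].
#' @param path output file; `.csv` gets comma separation, anything else tab.
#' @param digits significant digits retained.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(rec, path, digits = 12) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(signif(rec$data, digits))
  colnames(df) <- rec$labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, labels = rec$labels,
                            condition = rec$condition,
                            subject_id = rec$subject_id),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Filtering

# Steady-state initial filter state for a step of unit height, so that
# filtering a constant yields its steady-state response from sample one.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  if (nf == 1L) return(numeric(0))
  # companion matrix of a (monic), transposed
  comp_t <- cbind(-a[-1], rbind(diag(1, nf - 2L), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(1, nf - 1L) - comp_t, B)
}

# Zero-phase forward-backward IIR filtering with odd-symmetric edge
# padding and steady-state initial conditions, so edge transients do not
# leak into the retained samples (and a constant maps exactly to its
# steady-state gain).
filtfilt_padded <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  # generous padding: EEG band edges sit well below 1% of the sampling
  # rate, so their poles ring for hundreds of samples
  npad <- min(max(3L * max(length(a), length(b)), 1024L), length(x) - 1L)
  pre  <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad)]
  y <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[seq(npad + 1L, npad + length(x))]
}

#' Zero-phase Butterworth band-limiting filter
#'
#' Applies a Butterworth filter forward and backward (zero phase, squared
#' magnitude response). With both cutoffs a band-pass is used; with
#' `high = NULL` a high-pass at `low`; with `low = 0` a low-pass at `high`.
#'
#' @param sig an [eeg_signal()].
#' @param low lower cutoff in Hz (0 for pure low-pass).
#' @param high upper cutoff in Hz, or `NULL` for high-pass only.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return a filtered [eeg_signal()] of the same length and rate.
#' @export
bandpass <- function(sig, low, high = NULL, order = 4L) {
  stopifnot(inherits(sig, "eeg_signal"))
  nyq <- sig$fs / 2
  if (low < 0) stop("low cutoff must be >= 0")
  if (!is.null(high)) {
    if (high <= low) stop("high cutoff must exceed low cutoff")
    if (high >= nyq) stop("high cutoff must be below the Nyquist rate ", nyq, " Hz")
  } else if (low <= 0) {
    stop("high-pass mode requires low > 0")
  }
  if (low >= nyq) stop("low cutoff must be below the Nyquist rate ", nyq, " Hz")
  flt <- if (is.null(high)) {
    signal::butter(order, low / nyq, type = "high")
  } else if (low == 0) {
    signal::butter(order, high / nyq, type = "low")
  } else {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  y <- filtfilt_padded(flt$b, flt$a, sig$samples)
  eeg_signal(y, sig$fs, sig$channel)
}

#' Butterworth filter magnitude response of the zero-phase filter
#'
#' Squared one-pass magnitude at the requested frequencies, i.e. the gain
#' actually applied by [bandpass()]. Exposed so attenuation claims can be
#' checked against the designed response.
#'
#' @inheritParams bandpass
#' @param fs sampling rate in Hz.
#' @param freqs frequencies (Hz) at which to evaluate the gain.
#' @return numeric vector of linear gains.
#' @export
bandpass_gain <- function(freqs, fs, low, high = NULL, order = 4L) {
  nyq <- fs / 2
  flt <- if (is.null(high)) signal::butter(order, low / nyq, type = "high")
  else if (low == 0) signal::butter(order, high / nyq, type = "low")
  else signal::butter(order, c(low, high) / nyq, type = "pass")
  w <- pi * freqs / nyq
  z <- exp(1i * w)
  num <- outer(z, 0:(length(flt$b) - 1L), function(zz, k) zz^(-k)) %*% flt$b
  den <- outer(z, 0:(length(flt$a) - 1L), function(zz, k) zz^(-k)) %*% flt$a
  Mod(num / den)^2
}

#' Preprocess a recording with a dataset preset
#'
#' `"mat"`: 0.5-45 Hz zero-phase band-pass (the mental-arithmetic preset).
#' `"stew"`: 1 Hz zero-phase high-pass plus re-referencing (common average
#' by default). An optional 50 Hz notch handles mains interference.
#'
#' @param rec an [eeg_recording()].
#' @param preset `"mat"`, `"stew"` or `"custom"`.
#' @param low,high,order filter settings used when `preset = "custom"`.
#' @param reref re-referencing: `"none"`, `"car"` (common average reference,
#'   per-sample mean across channels subtracted) or `"channel_mean"`
#'   (per-channel mean subtracted).
#' @param notch_50hz apply a 48-52 Hz band-stop before the main filter.
#' @return the preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec,
                                 preset = c("mat", "stew", "custom"),
                                 low = 0.5, high = 45, order = 4L,
                                 reref = c("none", "car", "channel_mean"),
                                 notch_50hz = FALSE) {
  preset <- match.arg(preset)
  reref <- if (missing(reref) && preset == "stew") "car" else match.arg(reref)
  if (preset == "mat") { low <- 0.5; high <- 45 }
  if (preset == "stew") { low <- 1; high <- NULL }
  data <- rec$data
  if (notch_50hz) {
    nyq <- rec$fs / 2
    flt <- signal::butter(2L, c(48, 52) / nyq, type = "stop")
    for (j in seq_len(ncol(data)))
      data[, j] <- filtfilt_padded(flt$b, flt$a, data[, j])
  }
  for (j in seq_len(ncol(data))) {
    s <- eeg_signal(data[, j], rec$fs, rec$labels[j])
    data[, j] <- bandpass(s, low, high, order)$samples
  }
  if (reref == "car") data <- data - rowMeans(data)
  if (reref == "channel_mean") data <- sweep(data, 2L, colMeans(data))
  eeg_recording(data, rec$fs, rec$labels, rec$condition, rec$subject_id)
}

# ---------------------------------------------------------------------------
# Segmentation

#' Slice a recording into fixed-length labeled segments
#'
#' Windows of `window_s` seconds advance with stride
#' `window_s - overlap_s`; a trailing partial window is discarded. Each
#' segment inherits the recording's condition, subject and channel labels.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default the 4-s analysis
#'   window).
#' @param overlap_s overlap between consecutive windows in seconds.
#' @return list of `eeg_segment` objects (possibly empty, with a warning,
#'   when the recording is shorter than one window).
#' @export
segment_record <- function(rec, window_s = 4, overlap_s = 0) {
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s)
  n <- nrow(rec$data)
  wlen <- round(window_s * rec$fs)
  stride <- round((window_s - overlap_s) * rec$fs)
  if (n < wlen) {
    warning(sprintf("recording (%.2f s) shorter than one %g-s window; no segments",
                    n / rec$fs, window_s))
    return(list())
  }
  starts <- seq(1L, n - wlen + 1L, by = stride)
  lapply(seq_along(starts), function(i) {
    structure(list(data = rec$data[starts[i]:(starts[i] + wlen - 1L), , drop = FALSE],
                   fs = rec$fs, labels = rec$labels,
                   condition = rec$condition, subject_id = rec$subject_id,
                   window = i),
              class = "eeg_segment")
  })
}
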