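#' Fourier magnitude spectrum of a segment
#'
#' Computes the DFT and retains the non-negative-frequency half of the
#' magnitude spectrum together with the full complex spectrum (needed later
#' for mode extraction). Bin `k` (0-based) sits at normalized frequency
#' `omega = 2*pi*k / n_fft`, so the half spectrum covers `[0, pi]`.
#'
#' @param x numeric samples or an [eeg_signal()].
#' @param n_fft transform length, at least `length(x)`; defaults to the
#'   signal length (no zero padding).
#' @return list with `magnitude` (length `floor(n_fft/2) + 1`), `full`
#'   (complex spectrum), `n_fft`, `fs` (may be `NA`).
#' @export
forward_spectrum <- function(x, n_fft = NULL) {
  fs <- NA_real_
  if (inherits(x, "eeg_signal")) { fs <- x$fs; x <- x$samples }
  x <- as.numeric(x)
  if (length(x) < 1L) stop("empty input")
  n_fft <- n_fft %||% length(x)
  if (n_fft < length(x)) stop("n_fft must be >= length(x)")
  if (n_fft > length(x)) x <- c(x, numeric(n_fft - length(x)))
  full <- stats::fft(x)
  half <- Mod(full[seq_len(n_fft %/% 2L + 1L)])
  list(magnitude = half, full = full, n_fft = n_fft, fs = fs)
}

# Strict local maxima of a magnitude vector (0-based bin indices).
# Plateaus are represented by their left-most bin.
strict_local_maxima <- function(m) {
  n <- length(m)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (m[i] > m[i - 1L]) {
      j <- i
      while (j < n && m[j + 1L] == m[j]) j <- j + 1L  # walk plateau
      if (j < n && m[j + 1L] < m[i]) idx <- c(idx, i - 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

#' Adaptive spectral segmentation (improved lowest-minima rule)
#'
#' Finds the boundaries that partition `[0, pi]` into one band per mode.
#' Candidate peaks are the magnitudes at `omega = 0`, at the Nyquist bin,
#' and every strict local maximum. The `N` largest candidates (ties broken
#' toward lower frequency) become the band centres; each interior boundary
#' is placed at the minimum magnitude strictly between two consecutive
#' centres. When fewer than `N` candidates exist, `N` is clamped with a
#' warning so batch decomposition of narrowband segments never aborts.
#'
#' @param spec output of [forward_spectrum()].
#' @param N requested number of modes (`>= 1`).
#' @return list of class `emfd_segmentation`: `peak_bins`, `boundary_bins`
#'   (0-based, length `N + 1`, first 0 and last the Nyquist bin),
#'   `boundaries_omega` (radians), `N`, `n_bins`, `n_fft`, `fs`.
#' @export
locate_boundaries <- function(spec, N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("N must be a positive integer")
  N <- as.integer(N)
  m <- spec$magnitude
  nb <- length(m)
  nyq <- nb - 1L
  cand <- sort(unique(c(0L, nyq, strict_local_maxima(m))))
  # order by magnitude descending, ties toward lower frequency
  ord <- cand[order(-m[cand + 1L], cand)]
  if (length(ord) < N) {
    warning(sprintf("only %d spectral peak candidates available; clamping N from %d",
                    length(ord), N))
    N <- length(ord)
  }
  peaks <- sort(ord[seq_len(N)])
  bounds <- 0L
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      lo <- peaks[i]; hi <- peaks[i + 1L]
      if (hi - lo <= 1L) {
        bounds <- c(bounds, hi)  # empty interior: collapse onto the later peak
      } else {
        inner <- (lo + 1L):(hi - 1L)
        bounds <- c(bounds, inner[which.min(m[inner + 1L])])
      }
    }
  }
  bounds <- c(bounds, nyq)
  bounds <- unique(bounds)
  if (length(bounds) < 2L) bounds <- c(0L, nyq)
  structure(list(peak_bins = peaks, boundary_bins = bounds,
                 boundaries_omega = 2 * pi * bounds / spec$n_fft,
                 N = length(bounds) - 1L, n_bins = nb,
                 n_fft = spec$n_fft, fs = spec$fs),
            class = "emfd_segmentation")
}

#' Zero-phase filter bank from a spectral segmentation
#'
#' Builds one binary indicator mask per band over the non-negative
#' frequency bins. Band `n` takes bins in `[omega_{n-1}, omega_n)`; the
#' last band is closed at `pi`. The masks are pairwise disjoint and sum to
#' the all-ones vector, which is what makes reconstruction exact.
#'
#' @param seg an `emfd_segmentation` from [locate_boundaries()].
#' @param n_bins half-spectrum length the masks must cover.
#' @return logical matrix, one row per band.
#' @export
build_filter_bank <- function(seg, n_bins = seg$n_bins) {
  b <- seg$boundary_bins
  if (n_bins != seg$n_bins)
    stop("mask length does not match the segmentation's spectrum")
  N <- length(b) - 1L
  masks <- matrix(FALSE, nrow = N, ncol = n_bins)
  bins <- 0:(n_bins - 1L)
  for (n in seq_len(N)) {
    if (n < N) masks[n, ] <- bins >= b[n] & bins < b[n + 1L]
    else masks[n, ] <- bins >= b[n] & bins <= b[n + 1L]
  }
  masks
}

#' Extract modes through the zero-phase filter bank
#'
#' Each mask is mirrored onto the negative-frequency bins (preserving
#' conjugate symmetry, hence real output) and applied to the retained
#' complex spectrum; the inverse DFT of each masked spectrum is one mode.
#'
#' @param spec output of [forward_spectrum()] for the same samples.
#' @param bank mask matrix from [build_filter_bank()].
#' @return list `modes` (matrix, one column per mode, `n_fft` rows) and
#'   `max_imag` (largest imaginary residue discarded; diagnostic).
#' @export
extract_modes <- function(spec, bank) {
  n <- spec$n_fft
  nb <- n %/% 2L + 1L
  if (ncol(bank) != nb)
    stop("filter bank length ", ncol(bank), " does not match spectrum bins ", nb)
  modes <- matrix(0, nrow = n, ncol = nrow(bank))
  max_imag <- 0
  for (k in seq_len(nrow(bank))) {
    fullmask <- logical(n)
    half <- which(bank[k, ]) - 1L            # 0-based bins
    fullmask[half + 1L] <- TRUE
    mirror <- half[half > 0L & half < (n - half)]  # skip DC and self-mirrored Nyquist
    fullmask[n - mirror + 1L] <- TRUE
    y <- stats::fft(spec$full * fullmask, inverse = TRUE) / n
    max_imag <- max(max_imag, max(abs(Im(y))))
    modes[, k] <- Re(y)
  }
  list(modes = modes, max_imag = max_imag)
}

#' Empirical Fourier decomposition
#'
#' Decomposes a single-channel segment into `N` band-limited intrinsic
#' modes: the magnitude spectrum is adaptively partitioned
#' ([locate_boundaries()]) and each band extracted with a zero-phase
#' indicator-mask filter ([build_filter_bank()], [extract_modes()]). The
#' modes are spectrally disjoint and sum exactly to the input. Entirely
#' deterministic.
#'
#' @param x numeric samples or an [eeg_signal()].
#' @param N number of modes requested (default 10; clamped with a warning
#'   when the spectrum offers fewer peak candidates).
#' @param fs sampling rate in Hz, used only to report boundaries in Hz
#'   (taken from `x` when it is an `eeg_signal`).
#' @return object of class `emfd`: `modes` (matrix, one column per mode),
#'   `segmentation`, `x` (input samples), `fs`, `boundaries_hz` (when `fs`
#'   known), `max_imag`.
#' @examples
#' fs <- 500
#' t <- seq(0, 4 - 1 / fs, by = 1 / fs)
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
#' d <- emfd(x, N = 2, fs = fs)
#' max(abs(x - rowSums(d$modes)))   # exact reconstruction
#' @export
emfd <- function(x, N = 10L, fs = NULL) {
  if (inherits(x, "eeg_signal")) { fs <- fs %||% x$fs; x <- x$samples }
  x <- as.numeric(x)
  if (length(x) < 2 * N)
    stop("input too short for ", N, " modes (need length >= ", 2 * N, ")")
  spec <- forward_spectrum(x)
  if (!is.null(fs)) spec$fs <- fs
  seg <- locate_boundaries(spec, N)
  bank <- build_filter_bank(seg)
  ex <- extract_modes(spec, bank)
  colnames(ex$modes) <- paste0("imf", seq_len(ncol(ex$modes)))
  structure(list(modes = ex$modes, segmentation = seg, x = x,
                 fs = spec$fs,
                 boundaries_hz = if (!is.na(spec$fs))
                   seg$boundaries_omega * spec$fs / (2 * pi) else NULL,
                 max_imag = ex$max_imag),
            class = "emfd")
}

#' @export
print.emfd <- function(x, ...) {
  cat(sprintf("Empirical Fourier decomposition: %d modes, %d samples\n",
              ncol(x$modes), nrow(x$modes)))
  if (!is.null(x$boundaries_hz))
    cat("  band edges (Hz):",
        paste(sprintf("%.2f", x$boundaries_hz), collapse = " "), "\n")
  err <- max(abs(x$x - rowSums(x$modes))) / max(abs(x$x), .Machine$double.eps)
  cat(sprintf("  relative reconstruction error: %.2e\n", err))
  invisible(x)
}

#' @export
plot.emfd <- function(x, ...) {
  N <- ncol(x$modes)
  op <- graphics::par(mfrow = c(N + 1L, 1L), mar = c(1.5, 4, 0.5, 1))
  on.exit(graphics::par(op))
  tt <- if (!is.na(x$fs)) seq_along(x$x) / x$fs else seq_along(x$x)
  graphics::plot(tt, x$x, type = "l", ylab = "x", xlab = "", ...)
  for (k in seq_len(N))
    graphics::plot(tt, x$modes[, k], type = "l",
                   ylab = paste0("imf", k), xlab = "", ...)
  invisible(x)
}

#' Reconstruct the input from an EMFD object
#'
#' @param object an [emfd()] decomposition.
#' @param ... unused.
#' @return numeric vector, the sum of all modes.
#' @export
reconstruct <- function(object, ...) UseMethod("reconstruct")

#' @export
reconstruct.emfd <- function(object, ...) rowSums(object$modes)
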