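#' Entropy feature parameters
#'
#' Bundles the tunable parameters of the five entropy measures. Defaults
#' follow the standard choices for short biomedical series: embedding
#' dimension 2 and tolerance 0.2 x sample SD for the template entropies,
#' fuzzy exponent 2, Silverman's rule for the Renyi kernel width, and for
#' fractal-dimension entropy a Higuchi estimator (kmax 10) over 0.5-s
#' sub-windows with 50% overlap, histogrammed into 10 bins spanning the interval from 1 to 2.
#'
#' @param embed_m embedding dimension for approximate and fuzzy entropy.
#' @param r_coeff tolerance as a fraction of the sample SD.
#' @param fuzzy_exponent membership steepness of fuzzy entropy.
#' @param renyi_sigma kernel width in signal units, or `NULL` for
#'   Silverman's rule (`1.06 * sd * n^(-1/5)`).
#' @param fd_subwindow_s sub-window length in seconds for the fractal
#'   dimension sweep.
#' @param fd_overlap fractional overlap between consecutive sub-windows.
#' @param fd_kmax largest Higuchi scale.
#' @param hist_bins_M histogram bin count over the fractal-dimension range.
#' @param var_floor variance floor used when differential entropy meets a
#'   (near-)constant mode during batch extraction; set `NULL` to error
#'   instead.
#' @return list of class `entropy_params`.
#' @export
entropy_params <- function(embed_m = 2L, r_coeff = 0.2, fuzzy_exponent = 2,
                           renyi_sigma = NULL, fd_subwindow_s = 0.5,
                           fd_overlap = 0.5, fd_kmax = 10L,
                           hist_bins_M = 10L, var_floor = 1e-15) {
  stopifnot(embed_m >= 1, r_coeff > 0, fuzzy_exponent > 0, hist_bins_M >= 2,
            fd_overlap >= 0, fd_overlap < 1, fd_subwindow_s > 0, fd_kmax >= 2)
  structure(list(embed_m = as.integer(embed_m), r_coeff = r_coeff,
                 fuzzy_exponent = fuzzy_exponent, renyi_sigma = renyi_sigma,
                 fd_subwindow_s = fd_subwindow_s, fd_overlap = fd_overlap,
                 fd_kmax = as.integer(fd_kmax),
                 hist_bins_M = as.integer(hist_bins_M),
                 var_floor = var_floor),
            class = "entropy_params")
}

#' Approximate entropy
#'
#' Regularity statistic `Phi_m(r) - Phi_{m+1}(r)` over embedded templates
#' with Chebyshev distance and self-match-inclusive counting (the classical
#' definition), in nats.
#'
#' @param x numeric samples.
#' @param m embedding dimension.
#' @param r tolerance in signal units (absolute, not a fraction of SD).
#' @return scalar entropy in nats.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("approximate entropy needs length(x) > m + 1")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  apen_cpp(x, as.integer(m), r)
}

#' Fuzzy entropy
#'
#' Like approximate entropy but with baseline-removed templates and a
#' smooth membership `exp(-(d/r)^nexp)` in place of the hard threshold,
#' self-matches excluded, in nats. Invariant to constant offsets.
#'
#' @inheritParams approximate_entropy
#' @param nexp membership steepness exponent.
#' @return scalar entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x), nexp = 2) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("fuzzy entropy needs length(x) > m + 1")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  if (nexp <= 0) stop("fuzzy exponent must be positive")
  fuzzyen_cpp(x, as.integer(m), r, nexp)
}

#' Differential entropy under a Gaussian model
#'
#' Closed form `0.5 * log(2*pi*e*sigma^2)` with `sigma` the sample
#' standard deviation, in nats. Valid as an entropy only under the Gaussian
#' assumption; used here as a log-power-like feature.
#'
#' @param x numeric samples (length >= 2).
#' @param var_floor optional lower bound substituted for the sample
#'   variance; with the default `NULL` a (near-)zero variance is an error
#'   since the entropy diverges to `-Inf`.
#' @return scalar entropy in nats.
#' @export
differential_entropy <- function(x, var_floor = NULL) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("differential entropy needs at least 2 samples")
  v <- stats::var(x)
  if (!is.null(var_floor)) v <- max(v, var_floor)
  if (v <= 0) stop("zero variance: differential entropy diverges; supply var_floor")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Quadratic Renyi entropy via the information potential
#'
#' The information potential is the mean pairwise Gaussian-kernel
#' similarity `IP = (1/P^2) * sum_jk B_sigma(y_k - y_j)`; the quadratic
#' Renyi entropy is `h2 = -log(IP)` (nats). The kernel is the normalized
#' Gaussian density, so `P` identical samples give `IP = B_sigma(0)`.
#'
#' @param x numeric samples.
#' @param sigma kernel width; `NULL` applies Silverman's rule
#'   (`1.06 * sd * n^(-1/5)`, floored at `1e-12`).
#' @return list with `ip` (information potential) and `h2` (nats).
#' @export
renyi_entropy <- function(x, sigma = NULL) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 samples")
  if (is.null(sigma))
    sigma <- max(1.06 * stats::sd(x) * length(x)^(-1 / 5), 1e-12)
  if (!is.finite(sigma) || sigma <= 0) stop("kernel width sigma must be positive")
  ip <- renyi_ip_cpp(x, sigma)
  list(ip = ip, h2 = -log(ip))
}

#' Higuchi fractal dimension
#'
#' Least-squares slope of `log L(k)` against `log(1/k)` over scales
#' `k = 1..kmax`. A straight line has dimension close to 1; white noise
#' approaches 2.
#'
#' @param x numeric samples.
#' @param kmax largest scale.
#' @return scalar fractal dimension.
#' @export
higuchi_fd <- function(x, kmax = 10L) higuchi_fd_cpp(as.numeric(x), as.integer(kmax))

#' Fractal-dimension entropy
#'
#' Computes the Higuchi fractal dimension on sliding sub-windows, bins the
#' resulting dimensions into `hist_bins_M` equal bins spanning `[1, 2]`
#' (values outside clamped to the range), and returns the Shannon entropy
#' (base 2) of the normalized bin occupancy over non-empty bins. Zero when
#' all sub-windows land in one bin; `log2(M)` for equal occupancy.
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz (fixes the sub-window length in samples).
#' @param params an [entropy_params()].
#' @return scalar entropy in bits.
#' @export
fractal_dimension_entropy <- function(x, fs, params = entropy_params()) {
  x <- as.numeric(x)
  wlen <- max(round(params$fd_subwindow_s * fs), params$fd_kmax + 1L)
  stride <- max(1L, round(wlen * (1 - params$fd_overlap)))
  if (length(x) < wlen + stride)
    stop("too few samples for two fractal-dimension sub-windows")
  starts <- seq(1L, length(x) - wlen + 1L, by = stride)
  fds <- vapply(starts, function(s)
    higuchi_fd_cpp(x[s:(s + wlen - 1L)], params$fd_kmax), numeric(1))
  fd_shannon(fds, params$hist_bins_M)
}

# Shannon entropy (bits) of fractal-dimension values binned over [1, 2].
fd_shannon <- function(fds, M) {
  fds <- pmin(pmax(fds, 1), 2)
  br <- seq(1, 2, length.out = M + 1L)
  cnt <- tabulate(pmin(findInterval(fds, br, rightmost.closed = TRUE), M), M)
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}

.entropy_names <- c("apen", "fuzzyen", "diffen", "renyi", "fde")

# All five entropies for one mode. r is tied to the mode's own SD; a
# (near-)constant mode gets the degenerate values the definitions imply
# (0 for the template entropies) rather than NaN, so batch extraction
# stays finite.
mode_entropies <- function(x, fs, params) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    de <- if (!is.null(params$var_floor))
      0.5 * log(2 * pi * exp(1) * params$var_floor) else
        stop("constant mode and no var_floor set")
    return(c(apen = 0, fuzzyen = 0, diffen = de,
             renyi = -log(renyi_ip_cpp(x, 1e-12)), fde = 0))
  }
  r <- params$r_coeff * s
  sigma <- params$renyi_sigma %||%
    max(1.06 * s * length(x)^(-1 / 5), 1e-12)
  de <- if (!is.null(params$var_floor))
    0.5 * log(2 * pi * exp(1) * max(stats::var(x), params$var_floor))
  else differential_entropy(x)
  c(apen = apen_cpp(x, params$embed_m, r),
    fuzzyen = fuzzyen_cpp(x, params$embed_m, r, params$fuzzy_exponent),
    diffen = de,
    renyi = -log(renyi_ip_cpp(x, sigma)),
    fde = fractal_dimension_entropy(x, fs, params))
}

#' One feature row from a segment's per-channel decompositions
#'
#' Computes the five entropies on every mode of every channel and lays
#' them out in deterministic column order: channel, then mode, then
#' entropy name (`<channel>__imf<k>__<entropy>`).
#'
#' @param modesets named list (one entry per channel) of [emfd()] objects
#'   decomposed with the same number of modes.
#' @param fs sampling rate in Hz.
#' @param params an [entropy_params()].
#' @return named numeric vector of length `channels x modes x 5`.
#' @export
features_from_modes <- function(modesets, fs, params = entropy_params()) {
  ks <- vapply(modesets, function(m) ncol(m$modes), integer(1))
  if (length(unique(ks)) != 1L)
    stop("inconsistent mode counts across channels: ",
         paste(unique(ks), collapse = ", "))
  out <- lapply(names(modesets), function(ch) {
    md <- modesets[[ch]]$modes
    v <- unlist(lapply(seq_len(ncol(md)), function(k)
      mode_entropies(md[, k], fs, params)))
    names(v) <- as.vector(t(outer(paste0(ch, "__imf", seq_len(ncol(md))),
                                  .entropy_names, paste, sep = "__")))
    v
  })
  unlist(out)
}

#' Entropy feature matrix from labeled segments
#'
#' Runs EMFD on every channel of every segment and assembles the feature
#' matrix: one row per segment, columns `<channel>__imf<k>__<entropy>`,
#' plus `condition` and `subject_id` metadata columns.
#'
#' @param segments list of `eeg_segment` objects (see [segment_record()]).
#' @param n_modes modes per channel (clamping warnings from narrowband
#'   segments are suppressed here; the realized count must still agree
#'   across channels of one segment).
#' @param params an [entropy_params()].
#' @param verbose print progress every 50 segments.
#' @return `data.frame` of class `eeg_features`.
#' @export
extract_features <- function(segments, n_modes = 10L,
                             params = entropy_params(), verbose = FALSE) {
  if (!length(segments)) stop("no segments supplied")
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    modesets <- lapply(seq_along(seg$labels), function(j)
      suppressWarnings(emfd(seg$data[, j], N = n_modes, fs = seg$fs)))
    names(modesets) <- seg$labels
    rows[[i]] <- features_from_modes(modesets, seg$fs, params)
    if (verbose && i %% 50L == 0L)
      message("  features: segment ", i, "/", length(segments))
  }
  nm <- names(rows[[1]])
  if (!all(vapply(rows, function(r) identical(names(r), nm), logical(1))))
    stop("feature columns differ across segments (unequal realized mode counts)")
  df <- as.data.frame(do.call(rbind, rows))
  df$condition <- factor(vapply(segments, `[[`, character(1), "condition"),
                         levels = c("rest", "task"))
  df$subject_id <- vapply(segments, `[[`, character(1), "subject_id")
  class(df) <- c("eeg_features", "data.frame")
  df
}

#' Metadata column names of a feature matrix
#' @param x an `eeg_features` data frame.
#' @return character vector of non-feature column names present.
#' @export
meta_cols <- function(x) intersect(c("condition", "subject_id"), colnames(x))

feature_cols <- function(x) setdiff(colnames(x), meta_cols(x))

#' Min-max scaling fitted on training rows only
#'
#' Per-column `(x - min) / (max - min)` with statistics taken from `train`
#' alone; a constant training column maps everything to 0.5 and
#' out-of-range values in `apply_to` are not clipped, so no information
#' from held-out rows leaks into the scaling.
#'
#' @param train feature matrix providing the min/max statistics.
#' @param apply_to feature matrix to scale (its columns must all appear in
#'   `train`); defaults to `train`.
#' @return scaled copy of `apply_to`.
#' @export
fit_apply_minmax <- function(train, apply_to = train) {
  fc <- feature_cols(apply_to)
  if (!all(fc %in% colnames(train)))
    stop("apply_to has columns missing from train")
  out <- apply_to
  for (cn in fc) {
    lo <- min(train[[cn]]); hi <- max(train[[cn]])
    out[[cn]] <- if (hi > lo) (apply_to[[cn]] - lo) / (hi - lo)
    else rep(0.5, nrow(apply_to))
  }
  out
}

#' Variance / correlation feature reduction
#'
#' Drops feature columns with variance at or below `variance_floor`, then
#' greedily drops the later column of any pair with absolute Pearson
#' correlation at or above `corr_cap`. Never drops every column; the names
#' removed are recorded in the `"dropped"` attribute. Idempotent.
#'
#' @param x an `eeg_features` data frame.
#' @param variance_floor variance threshold (>= 0).
#' @param corr_cap absolute-correlation threshold in (0, 1].
#' @return reduced feature matrix with attribute `"dropped"`.
#' @export
reduce_features <- function(x, variance_floor = 1e-12, corr_cap = 0.98) {
  stopifnot(variance_floor >= 0, corr_cap > 0, corr_cap <= 1)
  fc <- feature_cols(x)
  v <- vapply(x[fc], stats::var, numeric(1))
  drop_var <- fc[v <= variance_floor]
  keep <- setdiff(fc, drop_var)
  if (!length(keep)) keep <- fc[which.max(v)]  # never drop all columns
  drop_cor <- character(0)
  if (length(keep) > 1L) {
    cm <- abs(suppressWarnings(stats::cor(as.matrix(x[keep]))))
    cm[!is.finite(cm)] <- 0
    for (j in 2:length(keep)) {
      if (any(cm[seq_len(j - 1L), j] >= corr_cap &
              !(keep[seq_len(j - 1L)] %in% drop_cor)))
        drop_cor <- c(drop_cor, keep[j])
    }
  }
  keep <- setdiff(keep, drop_cor)
  out <- x[, c(keep, meta_cols(x)), drop = FALSE]
  class(out) <- class(x)
  attr(out, "dropped") <- c(drop_var, drop_cor)
  out
}
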