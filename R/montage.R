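.montage_presets <- list(
  mat19 = list(
    frontal   = c("FP1", "FP2", "F3", "F4", "F7", "F8", "FZ"),
    central   = c("C3", "C4", "CZ"),
    temporal  = c("T3", "T4", "T5", "T6"),
    parietal  = c("P3", "P4", "PZ"),
    occipital = c("O1", "O2")
  ),
  stew14 = list(
    frontal   = c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6"),
    temporal  = c("T7", "T8"),
    parietal  = c("P7", "P8"),
    occipital = c("O1", "O2")
  )
)

#' Electrode-to-lobe montage
#'
#' Maps 10-20 electrode labels to cortical lobes. Two presets are built
#' in: `mat19` (19 channels at 500 Hz, five lobes) and `stew14`
#' (14 channels at 128 Hz, four lobes -- it has no central-line
#' electrodes, and the fronto-central FC5/FC6 pair is assigned to the
#' frontal lobe). A custom mapping is validated for disjointness and,
#' when `channels` is given, for full coverage of the channel set.
#'
#' @param montage_id `"mat19"`, `"stew14"` or `"custom"`.
#' @param mapping named list of electrode-label vectors (lobe -> labels),
#'   required for `"custom"`.
#' @param channels full channel set a custom mapping must cover.
#' @return object of class `lobe_montage`: `mapping`, `montage_id`,
#'   `channels`.
#' @export
build_montage <- function(montage_id = c("mat19", "stew14", "custom"),
                          mapping = NULL, channels = NULL) {
  montage_id <- match.arg(montage_id)
  if (montage_id != "custom") {
    mapping <- .montage_presets[[montage_id]]
  } else if (is.null(mapping) || is.null(names(mapping))) {
    stop("custom montage requires a named lobe -> labels mapping")
  }
  mapping <- lapply(mapping, normalize_labels)
  all_lab <- unlist(mapping, use.names = FALSE)
  dup <- unique(all_lab[duplicated(all_lab)])
  if (length(dup))
    stop("electrodes assigned to more than one lobe: ", paste(dup, collapse = ", "))
  if (any(!lengths(mapping)))
    stop("empty lobe in montage: ",
         paste(names(mapping)[!lengths(mapping)], collapse = ", "))
  if (!is.null(channels)) {
    channels <- normalize_labels(channels)
    missing <- setdiff(channels, all_lab)
    if (length(missing))
      stop("montage omits channel(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(all_lab, channels)
    if (length(extra))
      stop("montage lists unknown channel(s): ", paste(extra, collapse = ", "))
  }
  structure(list(mapping = mapping, montage_id = montage_id,
                 channels = all_lab),
            class = "lobe_montage")
}

#' @export
print.lobe_montage <- function(x, ...) {
  cat(sprintf("Lobe montage '%s' (%d channels, %d lobes)\n",
              x$montage_id, length(x$channels), length(x$mapping)))
  for (lb in names(x$mapping))
    cat(sprintf("  %-9s %s\n", lb, paste(x$mapping[[lb]], collapse = " ")))
  invisible(x)
}

#' Restrict a feature matrix to one lobe's electrodes
#'
#' Keeps the feature columns whose channel prefix belongs to the requested
#' lobe; metadata columns are preserved.
#'
#' @param x an `eeg_features` data frame whose columns are named
#'   `<channel>__imf<k>__<entropy>`.
#' @param montage a [build_montage()] object.
#' @param lobe lobe name present in the montage.
#' @return the column-subset feature matrix.
#' @export
select_lobe_features <- function(x, montage, lobe) {
  if (!lobe %in% names(montage$mapping))
    stop("lobe '", lobe, "' not present in montage '", montage$montage_id,
         "' (has: ", paste(names(montage$mapping), collapse = ", "), ")")
  fc <- feature_cols(x)
  ch <- sub("__.*$", "", fc)
  keep <- fc[ch %in% montage$mapping[[lobe]]]
  out <- x[, c(keep, meta_cols(x)), drop = FALSE]
  class(out) <- class(x)
  out
}
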