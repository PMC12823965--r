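make_modesets <- function(labels, n_modes, len = 256, fs = 128, seed = 1) {
  set.seed(seed)
  ms <- lapply(labels, function(ch)
    suppressWarnings(emfd(rnorm(len), N = n_modes, fs = fs)))
  names(ms) <- labels
  ms
}

test_that("feature rows have the documented width and deterministic order", {
  labs19 <- c("FP1", "FP2", "FZ", "F3", "F4", "F7", "F8", "T3", "T4", "T5",
              "T6", "P3", "P4", "PZ", "O1", "O2", "C3", "C4", "CZ")
  ms <- make_modesets(labs19, 10, len = 512)
  row <- features_from_modes(ms, fs = 128)
  expect_length(row, 19 * 10 * 5)
  expect_identical(names(row)[1:5],
                   paste0("FP1__imf1__", c("apen", "fuzzyen", "diffen",
                                           "renyi", "fde")))
  expect_identical(names(row)[6], "FP1__imf2__apen")

  labs14 <- paste0("E", 1:14)
  ms14 <- make_modesets(labs14, 10, len = 512)
  expect_length(features_from_modes(ms14, fs = 128), 14 * 10 * 5)

  # identical inputs give identical rows
  ms_b <- make_modesets(labs14, 10, len = 512)
  expect_identical(features_from_modes(ms14, fs = 128),
                   features_from_modes(ms_b, fs = 128))

  # inconsistent mode counts across channels are rejected
  bad <- c(make_modesets("A1", 3), make_modesets("A2", 4))
  expect_error(features_from_modes(bad, fs = 128), "inconsistent")
})

test_that("extract_features produces a finite labeled matrix", {
  cfg <- synth_config(n_subjects = 1, rest_duration_s = 8, task_duration_s = 8,
                      seed = 3)
  segs <- generate_dataset(cfg)
  fm <- extract_features(segs, n_modes = 3)
  expect_s3_class(fm, "eeg_features")
  expect_identical(nrow(fm), length(segs))
  expect_length(feature_cols(fm), 14 * 3 * 5)
  expect_false(anyNA(fm))
  expect_true(all(is.finite(as.matrix(fm[feature_cols(fm)]))))
  expect_setequal(levels(fm$condition), c("rest", "task"))
})

test_that("min-max scaling uses training statistics only", {
  tr <- data.frame(A__imf1__apen = c(3, 7, 5),
                   B__imf1__apen = c(2, 2, 2),
                   condition = factor(rep("rest", 3),
                                      levels = c("rest", "task")))
  class(tr) <- c("eeg_features", "data.frame")
  te <- tr[1, ]
  te$A__imf1__apen <- 9
  out <- fit_apply_minmax(tr, te)
  expect_equal(out$A__imf1__apen, 1.5)           # out of range, unclipped
  expect_equal(out$B__imf1__apen, 0.5)           # constant training column
  expect_equal(fit_apply_minmax(tr)$A__imf1__apen, c(0, 1, 0.5))
  te_bad <- te
  te_bad$C__imf1__apen <- 1
  expect_error(fit_apply_minmax(tr, te_bad), "missing")
})

test_that("feature reduction drops constants and duplicates, never everything", {
  set.seed(12)
  df <- as.data.frame(matrix(rnorm(40 * 4), 40))
  colnames(df) <- paste0("C", 1:4, "__imf1__apen")
  df$C5__imf1__apen <- df$C1__imf1__apen          # exact duplicate
  df$C6__imf1__apen <- 1                          # constant
  df$condition <- factor(rep(c("rest", "task"), 20))
  class(df) <- c("eeg_features", "data.frame")
  red <- reduce_features(df)
  expect_setequal(attr(red, "dropped"),
                  c("C5__imf1__apen", "C6__imf1__apen"))
  expect_true("C1__imf1__apen" %in% colnames(red))
  # idempotent
  red2 <- reduce_features(red)
  expect_identical(feature_cols(red2), feature_cols(red))
  # near-orthogonal matrix is unchanged
  expect_length(attr(reduce_features(df[, c(1:4, 7)]), "dropped"), 0)
  # all-constant matrix keeps one column
  cc <- df
  for (cn in feature_cols(cc)) cc[[cn]] <- 2
  expect_length(feature_cols(reduce_features(cc)), 1)
})
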