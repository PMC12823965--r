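test_that("generation is bitwise reproducible and respects the protocol", {
  cfg <- synth_config(n_subjects = 1, rest_duration_s = 12,
                      task_duration_s = 8, seed = 5)
  a <- generate_record(cfg, "S01", "task")
  b <- generate_record(cfg, "S01", "task")
  expect_identical(a$data, b$data)
  expect_identical(ncol(a$data), 14L)
  expect_identical(nrow(a$data), 8L * 128L)
  expect_identical(nrow(generate_record(cfg, "S01", "rest")$data), 12L * 128L)
  # different subjects/conditions differ
  expect_false(identical(a$data, generate_record(cfg, "S02", "task")$data))
  expect_error(generate_record(cfg, "S01", "sleep"), "arg")
})

test_that("segment counts follow the recording durations", {
  cfg <- synth_config(n_subjects = 10, rest_duration_s = 60,
                      task_duration_s = 60, seed = 2)
  segs <- generate_dataset(cfg, preprocess = FALSE)
  expect_length(segs, 10 * (15 + 15))
  expect_setequal(unique(vapply(segs, `[[`, character(1), "subject_id")),
                  sprintf("S%02d", 1:10))

  mat <- synth_config("mat19", n_subjects = 1, rest_duration_s = 180,
                      task_duration_s = 60, seed = 2)
  msegs <- generate_dataset(mat, preprocess = FALSE)
  conds <- vapply(msegs, `[[`, character(1), "condition")
  expect_identical(sum(conds == "rest"), 45L)
  expect_identical(sum(conds == "task"), 15L)
})

test_that("frontal theta gain shows up in band power where it should", {
  cfg <- synth_config(n_subjects = 20, rest_duration_s = 8, task_duration_s = 8,
                      frontal_theta_gain = 2.0, seed = 9)
  ratios_frontal <- ratios_occipital <- numeric(20)
  for (s in 1:20) {
    sid <- sprintf("S%02d", s)
    rest <- generate_record(cfg, sid, "rest")
    task <- generate_record(cfg, sid, "task")
    th <- function(rec, ch) band_power(rec$data[, ch], cfg$fs, 4, 7)
    ratios_frontal[s] <- th(task, "F3") / th(rest, "F3")
    ratios_occipital[s] <- th(task, "O1") / th(rest, "O1")
  }
  expect_gt(mean(ratios_frontal), 1.5)
  # theta effect is frontal-specific
  expect_lt(mean(ratios_occipital), 1.5)
})

test_that("the null generator carries no frontal theta effect", {
  insignificant <- 0
  for (rep_i in 1:50) {
    cfg <- synth_config(n_subjects = 1, rest_duration_s = 8,
                        task_duration_s = 8, seed = 1000 + rep_i)
    rest <- generate_record(cfg, "S01", "rest")
    task <- generate_record(cfg, "S01", "task")
    frontal <- build_montage("stew14")$mapping$frontal
    p_rest <- vapply(frontal, function(ch)
      band_power(rest$data[, ch], cfg$fs, 4, 7), numeric(1))
    p_task <- vapply(frontal, function(ch)
      band_power(task$data[, ch], cfg$fs, 4, 7), numeric(1))
    p <- t.test(log(p_task), log(p_rest))$p.value
    if (p > 0.01) insignificant <- insignificant + 1
  }
  expect_gte(insignificant, 45)
})

test_that("a strong frontal effect separates conditions in the features", {
  cfg <- synth_config(n_subjects = 10, rest_duration_s = 40, task_duration_s = 40,
                      frontal_theta_gain = 2.5, alpha_suppression = 0.7,
                      irregularity_delta = 0.1, seed = 4)
  segs <- generate_dataset(cfg)
  expect_length(segs, 200)
  fm <- extract_features(segs, n_modes = 5)
  frontal_cols <- grep("^(AF3|AF4|F3|F4|F7|F8|FC5|FC6)__",
                       feature_cols(fm), value = TRUE)
  d <- vapply(frontal_cols, function(cn) {
    a <- fm[[cn]][fm$condition == "task"]
    b <- fm[[cn]][fm$condition == "rest"]
    (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_gt(max(abs(d)), 0.8)   # at least one frontal feature separates
})
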