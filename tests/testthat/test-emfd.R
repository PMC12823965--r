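test_that("forward spectrum has the expected symmetry and peak locations", {
  set.seed(1)
  x <- rnorm(400)
  sp <- forward_spectrum(x)
  n <- sp$n_fft
  asym <- max(abs(sp$full[2:n] - Conj(sp$full[n:2]))) / max(Mod(sp$full))
  expect_lt(asym, 1e-12)

  imp <- forward_spectrum(c(1, rep(0, 255)))
  expect_lt(diff(range(imp$magnitude)), 1e-12)

  tn <- make_tones(10, fs = 500, dur = 4)
  sp10 <- forward_spectrum(tn$x)
  expect_identical(which.max(sp10$magnitude) - 1L, 40L)  # 10 * 2000 / 500
  expect_error(forward_spectrum(numeric(0)), "empty")
})

test_that("boundary location matches the argmin oracle and handles edge cases", {
  tn <- make_tones(c(5, 40), fs = 500, dur = 4)
  sp <- forward_spectrum(tn$x)
  seg <- locate_boundaries(sp, 2)
  inner <- 21:159                       # strictly between bins 20 and 160
  want <- inner[which.min(sp$magnitude[inner + 1L])]
  expect_identical(seg$boundary_bins, c(0L, want, 1000L))

  seg1 <- locate_boundaries(sp, 1)
  expect_identical(seg1$boundary_bins, c(0L, 1000L))
  expect_equal(seg1$boundaries_omega, c(0, pi))

  # noiseless constructed spectrum: ends plus two maxima = 4 candidates
  sparse <- list(magnitude = c(0, 3, 0, 0, 5, 0, 0), n_fft = 12)
  expect_warning(segc <- locate_boundaries(sparse, 5), "clamping")
  expect_identical(segc$N, 4L)   # clamped to the 4 available candidates
  expect_error(locate_boundaries(sp, 0), "positive")
})

test_that("boundary location agrees with the brute-force oracle on random spectra", {
  set.seed(11)
  for (i in 1:30) {
    mag <- abs(rnorm(sample(40:200, 1)))
    sp <- list(magnitude = mag, n_fft = 2 * (length(mag) - 1))
    N <- sample(1:6, 1)
    got <- suppressWarnings(locate_boundaries(sp, N))$boundary_bins
    want <- boundaries_oracle(mag, N)
    expect_identical(got, as.integer(want))
  }
})

test_that("filter bank masks partition the half spectrum", {
  tn <- make_tones(c(5, 40, 80), fs = 500, dur = 4)
  sp <- forward_spectrum(tn$x)
  seg <- locate_boundaries(sp, 3)
  bank <- build_filter_bank(seg)
  expect_identical(colSums(bank), rep(1, ncol(bank)))  # disjoint cover
  seg1 <- locate_boundaries(sp, 1)
  expect_true(all(build_filter_bank(seg1)[1, ]))       # all-pass
})

test_that("mode extraction reconstructs exactly and separates tones", {
  tn <- make_tones(c(5, 40), fs = 500, dur = 4)
  d <- emfd(tn$x, N = 2, fs = 500)
  expect_lt(max(abs(tn$x - rowSums(d$modes))) / max(abs(tn$x)), 1e-10)
  expect_gt(cor(d$modes[, 1], tn$tones[[1]]), 0.999)
  expect_gt(cor(d$modes[, 2], tn$tones[[2]]), 0.999)
  expect_lt(d$max_imag, 1e-12)
  expect_identical(emfd(tn$x, 2)$modes, d$modes)  # deterministic

  # single mode: identity
  set.seed(5)
  x <- rnorm(300)
  d1 <- emfd(x, 1)
  expect_lt(max(abs(d1$modes[, 1] - x)) / max(abs(x)), 1e-10)
})

test_that("decomposition conserves energy and keeps modes spectrally disjoint", {
  set.seed(21)
  for (len in c(64, 257, 1024)) {
    x <- rnorm(len)
    d <- suppressWarnings(emfd(x, 6))
    expect_lt(abs(sum(d$modes^2) - sum(x^2)) / sum(x^2), 1e-9)
    specs <- apply(d$modes, 2, function(m)
      Mod(fft(m))[seq_len(len %/% 2 + 1)])
    specs[specs < 1e-9 * max(specs)] <- 0   # numerical zeros from the ifft
    for (a in seq_len(ncol(specs) - 1))
      for (b in (a + 1):ncol(specs))
        expect_identical(sum(specs[, a] * specs[, b]), 0)
  }
})

test_that("well-separated tones are each recovered by one mode", {
  fs <- 500
  for (freqs in list(c(8, 60), c(6, 35, 90), c(5, 30, 70, 120))) {
    tn <- make_tones(freqs, fs = fs, dur = 2)
    d <- emfd(tn$x, N = length(freqs), fs = fs)
    expect_identical(ncol(d$modes), length(freqs))
    for (k in seq_along(freqs))
      expect_gt(cor(d$modes[, k], tn$tones[[k]]), 0.99)
  }
})

test_that("default decomposition of broadband noise yields ten modes", {
  set.seed(8)
  x <- rnorm(2000)
  d <- emfd(x, N = 10)
  expect_identical(ncol(d$modes), 10L)
  expect_error(emfd(rnorm(10), 10), "too short")
})
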