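test_that("approximate entropy matches the brute-force oracle and its limits", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(25:40, 1))
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.5) * sd(x)
    expect_equal(approximate_entropy(x, m, r), apen_oracle(x, m, r),
                 tolerance = 1e-12)
  }
  expect_identical(approximate_entropy(rep(2, 30), 2, 0.5), 0)
  expect_error(approximate_entropy(rnorm(3), 2), "length")
  expect_error(approximate_entropy(rnorm(30), 2, r = -1), "positive")
})

test_that("white noise is less regular than a sine by approximate entropy", {
  set.seed(17)
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 10 * t)
  ae_sine <- approximate_entropy(sine, 2, 0.2 * sd(sine))
  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    w <- rnorm(2000)
    if (approximate_entropy(w, 2, 0.2 * sd(w)) > ae_sine) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("fuzzy entropy matches its oracle, is offset-invariant, zero for constants", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(sample(25:40, 1))
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.5) * sd(x)
    nexp <- sample(c(1, 2, 3), 1)
    expect_equal(fuzzy_entropy(x, m, r, nexp), fuzzyen_oracle(x, m, r, nexp),
                 tolerance = 1e-12)
  }
  expect_identical(fuzzy_entropy(rep(1.5, 30), 2, 0.3), 0)
  x <- rnorm(40)
  r <- 0.2 * sd(x)
  expect_equal(fuzzy_entropy(x + 17.3, 2, r), fuzzy_entropy(x, 2, r),
               tolerance = 1e-12)
})

test_that("differential entropy follows the Gaussian closed form and scaling law", {
  set.seed(33)
  n <- 4000
  x <- rnorm(n)
  # SE of the entropy ~ SE of log(sd) ~ 1/sqrt(2 (n-1))
  se <- 1 / sqrt(2 * (n - 1))
  expect_lt(abs(differential_entropy(x) - 0.5 * log(2 * pi * exp(1))), 3 * se)
  a <- 3.7
  expect_equal(differential_entropy(a * x) - differential_entropy(x), log(a),
               tolerance = 1e-12)
  expect_error(differential_entropy(rep(1, 10)), "variance")
  expect_equal(differential_entropy(rep(1, 10), var_floor = 1),
               0.5 * log(2 * pi * exp(1)))
})

test_that("Renyi information potential matches its oracle and kernel limits", {
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(sample(30:50, 1))
    sigma <- runif(1, 0.3, 2)
    got <- renyi_entropy(x, sigma)
    expect_equal(got$ip, renyi_ip_oracle(x, sigma), tolerance = 1e-12)
    expect_equal(got$h2, -log(got$ip), tolerance = 1e-12)
  }
  # identical samples: IP equals the kernel at zero
  sigma <- 0.8
  b0 <- 1 / (sqrt(2 * pi) * sigma)
  same <- renyi_entropy(rep(4, 25), sigma)
  expect_equal(same$ip, b0, tolerance = 1e-12)
  expect_equal(same$h2, -log(b0), tolerance = 1e-12)
  # two-point IP strictly decreases with separation
  ips <- vapply(seq(0, 3, by = 0.25), function(d)
    renyi_entropy(c(-d / 2, d / 2), sigma)$ip, numeric(1))
  expect_true(all(diff(ips) < 0))
  expect_error(renyi_entropy(rnorm(10), sigma = -1), "positive")
})

test_that("fractal-dimension entropy hits its limits and Higuchi calibrates", {
  expect_lt(abs(higuchi_fd(seq(0, 1, length.out = 500), 10) - 1), 0.05)
  set.seed(35)
  expect_gt(higuchi_fd(rnorm(2000), 10), 1.8)  # white noise approaches 2

  # degenerate: every sub-window in one bin -> zero entropy
  t <- seq(0, 4, length.out = 512)
  expect_identical(fractal_dimension_entropy(t, fs = 128), 0)
  # equal occupancy of all M bins -> log2(M), via the histogram step
  M <- 10
  fds <- seq(1.05, 1.95, length.out = M)   # one value per bin
  expect_equal(emfdeeg:::fd_shannon(fds, M), log2(M))
  expect_identical(emfdeeg:::fd_shannon(rep(1.5, 8), M), 0)
})

test_that("entropies transform predictably under offset and scale", {
  set.seed(36)
  x <- rnorm(64)
  p <- entropy_params()
  # offset invariance with r tied to SD
  for (f in list(
    function(z) approximate_entropy(z, 2, 0.2 * sd(z)),
    function(z) fuzzy_entropy(z, 2, 0.2 * sd(z)),
    function(z) fractal_dimension_entropy(z, fs = 16, params = p)
  )) expect_equal(f(x + 5), f(x), tolerance = 1e-10)
  # Renyi IP with fixed sigma is offset-invariant
  expect_equal(renyi_entropy(x + 5, 1)$ip, renyi_entropy(x, 1)$ip,
               tolerance = 1e-12)
})
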