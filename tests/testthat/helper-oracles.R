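# Independent brute-force oracles, written directly from the definitions.
# They deliberately share no code with the package implementations.

apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    tmpl <- matrix(0, nt, mm)
    for (i in seq_len(nt)) tmpl[i, ] <- x[i:(i + mm - 1)]
    s <- 0
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(tmpl[i, ] - tmpl[j, ])) <= r) cnt <- cnt + 1  # incl. self
      }
      s <- s + log(cnt / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1)
}

fuzzyen_oracle <- function(x, m, r, nexp) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - m  # same template count for both lengths
    tmpl <- matrix(0, nt, mm)
    for (i in seq_len(nt)) {
      v <- x[i:(i + mm - 1)]
      tmpl[i, ] <- v - mean(v)
    }
    s <- 0
    for (i in seq_len(nt)) {
      row <- 0
      for (j in seq_len(nt)) {
        if (j == i) next
        d <- max(abs(tmpl[i, ] - tmpl[j, ]))
        row <- row + exp(-(d / r)^nexp)
      }
      s <- s + row / (nt - 1)
    }
    s / nt
  }
  log(phi(m)) - log(phi(m + 1))
}

renyi_ip_oracle <- function(x, sigma) {
  P <- length(x)
  s <- 0
  for (j in seq_len(P)) {
    for (k in seq_len(P)) {
      u <- x[k] - x[j]
      s <- s + exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
    }
  }
  s / P^2
}

# Boundary-placement oracle: sort all candidate peaks (spectrum ends plus
# strict local maxima) by magnitude, take the N largest, and place each
# interior boundary with an explicit argmin scan.
boundaries_oracle <- function(mag, N) {
  nb <- length(mag)
  cand <- c(1L, nb)
  for (i in 2:(nb - 1L)) {
    if (mag[i] > mag[i - 1L] && mag[i] > mag[i + 1L]) cand <- c(cand, i)
  }
  cand <- sort(unique(cand))
  ord <- cand[order(-mag[cand], cand)]
  N <- min(N, length(ord))
  peaks <- sort(ord[seq_len(N)])
  bounds <- 1L
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      lo <- peaks[i]; hi <- peaks[i + 1L]
      if (hi - lo <= 1L) bounds <- c(bounds, hi)
      else {
        inner <- (lo + 1L):(hi - 1L)
        bounds <- c(bounds, inner[which.min(mag[inner])])
      }
    }
  }
  unique(c(bounds, nb)) - 1L   # 0-based bins
}

# AUC oracle: probability a positive outscores a negative, ties half.
auc_oracle <- function(scores, y) {
  pos <- scores[y == "task"]; neg <- scores[y == "rest"]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

confusion_oracle <- function(pred, truth) {
  tp <- sum(pred == "task" & truth == "task")
  fn <- sum(pred == "rest" & truth == "task")
  tn <- sum(pred == "rest" & truth == "rest")
  fp <- sum(pred == "task" & truth == "rest")
  c(tp = tp, fn = fn, tn = tn, fp = fp)
}

# Small labeled feature table with a separable effect of given size
# (difference in means, units of SD) on the first column.
make_feature_df <- function(n = 60, p = 5, effect = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  y <- rep(c("rest", "task"), length.out = n)
  X[y == "task", 1] <- X[y == "task", 1] + effect
  df <- as.data.frame(X)
  colnames(df) <- paste0("CH", seq_len(p), "__imf1__apen")
  df$condition <- factor(y, levels = c("rest", "task"))
  df$subject_id <- sprintf("S%02d", rep(seq_len(max(2, n %/% 6)),
                                        length.out = n))
  class(df) <- c("eeg_features", "data.frame")
  df
}

# Sum of pure tones, unit amplitudes, 4 s at fs.
make_tones <- function(freqs, fs = 500, dur = 4) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  list(t = t, x = Reduce(`+`, lapply(freqs, function(f) sin(2 * pi * f * t))),
       tones = lapply(freqs, function(f) sin(2 * pi * f * t)))
}

# Welch-style band power oracle (periodogram averaged over 2-s halves).
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  half <- floor(n / 2)
  pw <- function(seg) {
    X <- Mod(fft(seg))^2 / length(seg)
    f <- (seq_along(seg) - 1) * fs / length(seg)
    sum(X[f >= lo & f <= hi])
  }
  (pw(x[1:half]) + pw(x[(half + 1):(2 * half)])) / 2
}
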