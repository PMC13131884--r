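# Shared fixtures, all generated in code.

# a tiny valid recording with arbitrary forces
make_recording <- function(n = 50, fs = 100, bw = 700, seed = 1,
                           speed = 1.2, incline = 5) {
  withr::with_seed(seed, {
    grf_recording(time_s = (seq_len(n) - 1) / fs,
                  heel_n = runif(n, 0, 100),
                  midfoot_n = runif(n, 0, 50),
                  forefoot_n = runif(n, 0, 120),
                  subject_id = "T01", body_weight_n = bw,
                  speed_mps = speed, incline_deg = incline,
                  sampling_rate_hz = fs)
  })
}

# deterministic (noise-free, jitter-free) simulator parameters
clean_params <- function(...) {
  gait_params(noise_sd_n = 0, period_jitter_cv = 0, amp_jitter_cv = 0, ...)
}

# small planted-signal feature matrix: `n_signal` informative columns
# (class-dependent means), `n_noise` pure-noise columns, plus duplicates of
# the first signal column
planted_features <- function(n_per_class = 40, n_classes = 3, n_signal = 3,
                             n_noise = 50, n_dup = 10, effect = 1.5,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * n_classes
    y <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    sig <- sapply(seq_len(n_signal), function(j) {
      rnorm(n, mean = effect * (y + 1) * j / n_signal, sd = 1)
    })
    colnames(sig) <- sprintf("signal_%02d", seq_len(n_signal))
    noise <- matrix(rnorm(n * n_noise), n, n_noise)
    colnames(noise) <- sprintf("noise_%02d", seq_len(n_noise))
    dup <- sig[, rep(1, n_dup), drop = FALSE]
    colnames(dup) <- sprintf("dup_%02d", seq_len(n_dup))
    list(X = cbind(sig, noise, dup), y = y)
  })
}

# display rounding: half-up at d decimals (how the reference table prints)
round_half_up <- function(x, d) floor(x * 10^d + 0.5 + 1e-9) / 10^d

# brute-force oracle for sign-reversal crossings: explicit scan carrying
# the last nonzero sign
oracle_crossings <- function(a, b) {
  d <- a - b
  last <- 0
  out <- integer(0)
  for (i in seq_along(d)) {
    s <- sign(d[i])
    if (s != 0) {
      if (last != 0 && s != last) out <- c(out, i)
      last <- s
    }
  }
  out
}

# brute-force oracle for peak detection: enumerate local maxima (plateaus
# at their first sample) then greedy highest-first pruning
oracle_peaks <- function(x, min_height, min_separation_ms, fs) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && x[j + 1] < x[i] && x[i] > min_height) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  sep <- min_separation_ms / 1000 * fs
  kept <- integer(0)
  for (i in cand[order(-x[cand], cand)]) {
    if (!length(kept) || min(abs(kept - i)) >= sep) kept <- c(kept, i)
  }
  sort(kept)
}
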