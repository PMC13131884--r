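test_that("noise floor zeroes sub-threshold samples only", {
  expect_equal(apply_noise_floor(c(0.1, 2.0, 1.4), 1.5), c(0, 2.0, 0))
  expect_equal(apply_noise_floor(c(2, 3, 4), 1.5), c(2, 3, 4))
  expect_equal(apply_noise_floor(numeric(3), 1.5), numeric(3))
})

test_that("sign-reversal crossings report the first sample on the new side", {
  expect_identical(signed_difference_crossings(c(0, 1, 2, 3), c(3, 2, 1, 0)),
                   3L)
  # equal signals never cross
  x <- c(1, 2, 3, 2)
  expect_identical(signed_difference_crossings(x, x), integer(0))
  # a difference touching zero without crossing is not an event
  expect_identical(signed_difference_crossings(c(-1, 0, -1), c(0, 0, 0)),
                   integer(0))
  # ...but zero inherits the previous sign, so the crossing lands on the
  # first nonzero sample on the new side
  expect_identical(signed_difference_crossings(c(-1, 0, 1), c(0, 0, 0)), 3L)
  expect_error(signed_difference_crossings(1:3, 1:4), "equal length")
})

test_that("crossings agree with a brute-force scan on random signal pairs", {
  withr::with_seed(42, {
    for (rep in 1:1000) {
      n <- sample(5:40, 1)
      a <- round(rnorm(n), 1)       # rounding creates exact zeros/ties
      b <- round(rnorm(n), 1)
      expect_identical(signed_difference_crossings(a, b),
                       oracle_crossings(a, b))
    }
  })
})

test_that("zero-amplitude refinement keeps crossings near a silent signal", {
  a <- c(5, 5, 5, 0.2)
  b <- c(6, 4, 5.5, 3)
  cr <- c(2L, 3L, 4L)
  expect_identical(refine_zero_amplitude(cr, a, b, eps = 0.5), 4L)
  expect_identical(refine_zero_amplitude(cr, a, b, eps = Inf), cr)
  expect_identical(refine_zero_amplitude(integer(0), a, b, 0.5), integer(0))
})

test_that("peak detection keeps the higher of two close candidates", {
  x <- c(0, 2, 8, 3, 9, 1, 0)
  expect_identical(detect_force_peaks(x, 7, 80, 100), 5L)
  expect_identical(detect_force_peaks(c(1, 2, 3), 7, 80, 100), integer(0))
  expect_identical(detect_force_peaks(rep(0, 10), 7, 80, 100), integer(0))
  # a two-sample plateau strictly above its flanks counts once, first sample
  expect_identical(detect_force_peaks(c(0, 5, 9, 9, 4, 0), 7, 10, 100), 3L)
})

test_that("peak detection matches the brute-force oracle on random signals", {
  withr::with_seed(7, {
    for (rep in 1:1000) {
      n <- sample(20:80, 1)
      x <- round(pmax(0, rnorm(n, 3, 4)), 1)
      sep <- sample(c(20, 50, 80), 1)
      expect_identical(detect_force_peaks(x, 3.5, sep, 100),
                       oracle_peaks(x, 3.5, sep, 100))
    }
  })
})

test_that("heel strike is the nearest upward threshold crossing before the peak", {
  expect_identical(find_heel_strike(c(0, 0.5, 1.5, 3, 5), 5, 1), 3L)
  # signal above threshold from the first sample: rejected
  expect_identical(find_heel_strike(c(2, 3, 5, 8), 4, 1), NA_integer_)
  # nearest crossing wins when the signal dips twice
  expect_identical(find_heel_strike(c(0, 2, 0.5, 3, 9), 5, 1), 4L)
})

test_that("toe-off is the first downward threshold crossing after the peak", {
  ff <- c(0, 2, 6, 4, 2, 0.5, 0)
  expect_identical(find_toe_off(ff, 3, 1), 6L)
  # plateau to the end of the recording: truncated
  expect_identical(find_toe_off(c(0, 2, 6, 3, 3, 3), 3, 1), NA_integer_)
})

test_that("event finders recover exact truth samples on noise-free steps", {
  p <- clean_params()
  for (inc in c(0, 15, 25)) {
    st <- simulate_step(p, 1.2, inc)
    # a lone step needs one swing sample ahead of the strike, as in a session
    heel <- c(0, st$heel)
    ff <- c(0, st$forefoot)
    hp <- detect_force_peaks(heel, 3.5, 80, 100)
    fp <- detect_force_peaks(ff, 7, 80, 100)
    expect_length(hp, 1)
    expect_length(fp, 1)
    expect_identical(find_heel_strike(heel, hp, 1), st$hs_idx + 1L)
    expect_identical(find_toe_off(ff, fp, 1), st$to_idx + 1L)
  }
})

test_that("segmentation recovers every noise-free truth step exactly", {
  p <- clean_params()
  sess <- simulate_session(p, condition_grid(c(0, 25), c(0.8, 1.6)),
                           collect_s = 20, seed = 8)
  fs <- 100
  for (ci in seq_along(sess$recordings)) {
    steps <- segment_steps(sess$recordings[[ci]])
    tr <- sess$truth[sess$truth$condition_index == ci, ]
    expect_equal(nrow(steps), nrow(tr))
    expect_identical(steps$start_idx,
                     as.integer(round(tr$heel_strike_s * fs)) + 1L)
    expect_identical(steps$end_idx,
                     as.integer(round(tr$toe_off_s * fs)) + 1L)
    expect_identical(steps$step_id, seq_len(nrow(steps)))
  }
})

test_that("segments are ordered, disjoint, and deterministically reproduced", {
  sess <- simulate_session(gait_params(), condition_grid(10, 1.2),
                           collect_s = 20, seed = 19)
  steps <- segment_steps(sess$recordings[[1]])
  expect_true(all(diff(steps$start_idx) > 0))
  expect_true(all(steps$start_idx < steps$end_idx))
  expect_true(all(steps$start_idx[-1] >= steps$end_idx[-nrow(steps)]))
  steps2 <- segment_steps(sess$recordings[[1]])
  expect_identical(as.data.frame(steps[1:10]), as.data.frame(steps2[1:10]))
})

test_that("noisy default simulation recovers >= 95% of steps within 30 ms", {
  sess <- simulate_session(gait_params(), condition_grid(c(0, 10, 25),
                                                         c(0.8, 1.2, 1.6)),
                           collect_s = 20, seed = 123)
  fs <- 100
  tot <- 0L
  hit <- 0L
  for (ci in seq_along(sess$recordings)) {
    steps <- segment_steps(sess$recordings[[ci]])
    tr <- sess$truth[sess$truth$condition_index == ci, ]
    tot <- tot + nrow(tr)
    for (i in seq_len(nrow(tr))) {
      hs <- round(tr$heel_strike_s[i] * fs) + 1
      to <- round(tr$toe_off_s[i] * fs) + 1
      hit <- hit + any(abs(steps$start_idx - hs) <= 3 &
                         abs(steps$end_idx - to) <= 3)
    }
  }
  expect_gte(hit / tot, 0.95)
})

test_that("empty and all-zero recordings yield empty step tables", {
  rec <- grf_recording(time_s = (0:99) / 100, heel_n = numeric(100),
                       midfoot_n = numeric(100), forefoot_n = numeric(100))
  steps <- segment_steps(rec)
  expect_equal(nrow(steps), 0)
  expect_s3_class(steps, "grf_steps")
})

test_that("midstance intersections are annotated inside clean segments", {
  p <- clean_params()
  sess <- simulate_session(p, condition_grid(0, 1.2), collect_s = 20,
                           seed = 4)
  steps <- segment_steps(sess$recordings[[1]])
  # forefoot rises above heel mid-stance in every step of this waveform
  expect_true(all(!is.na(steps$ms_idx)))
  expect_true(all(steps$ms_idx > steps$start_idx &
                    steps$ms_idx < steps$end_idx))
})

test_that("parsing diagnostics account for every candidate", {
  sess <- simulate_session(gait_params(), condition_grid(5, 1.2),
                           collect_s = 20, seed = 31)
  steps <- segment_steps(sess$recordings[[1]])
  v <- validate_steps(steps)
  counts <- setNames(v$count, v$metric)
  expect_equal(counts[["candidates_accounted"]],
               counts[["heel_peak_candidates"]])
  expect_equal(counts[["emitted"]], nrow(steps))
  # clean simulation: nothing rejected
  expect_equal(counts[["rejected_no_onset"]] + counts[["overlap_discarded"]],
               0)
})

test_that("a recording that ends mid-stance reports a truncation", {
  p <- clean_params()
  sess <- simulate_session(p, condition_grid(0, 1.2), collect_s = 20,
                           seed = 6)
  rec <- sess$recordings[[1]]
  tr <- sess$truth
  # cut inside the last step's stance, after its heel peak
  cut <- round(tr$toe_off_s[nrow(tr)] * 100) - 20
  cut_rec <- grf_recording(rec$time_s[1:cut], rec$heel_n[1:cut],
                           rec$midfoot_n[1:cut], rec$forefoot_n[1:cut],
                           body_weight_n = 700, sampling_rate_hz = 100)
  v <- validate_steps(segment_steps(cut_rec))
  expect_equal(v$count[v$metric == "truncated"], 1)
  expect_equal(v$count[v$metric == "emitted"], nrow(tr) - 1)
})
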