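test_that("recording constructor enforces channel and time invariants", {
  t <- c(0, 0.01, 0.02)
  expect_s3_class(grf_recording(t, 1:3, 1:3, 1:3), "grf_recording")
  expect_error(grf_recording(t, 1:2, 1:3, 1:3), "same length")
  expect_error(grf_recording(t, c(1, -1, 2), 1:3, 1:3), "negative")
  expect_error(grf_recording(t, c(1, NA, 2), 1:3, 1:3), "non-finite")
  expect_error(grf_recording(c(0, 0.02, 0.01), 1:3, 1:3, 1:3),
               "strictly increasing")
  expect_error(grf_recording(c(0, 0.01, 0.5), 1:3, 1:3, 1:3), "uniform")
  expect_error(grf_recording(t, 1:3, 1:3, 1:3, body_weight_n = 0), "positive")
})

test_that("read/write round-trips samples and metadata exactly", {
  rec <- make_recording(n = 37, bw = 712.5, speed = 0.8, incline = 15)
  f <- withr::local_tempfile(fileext = ".csv")
  write_grf_recording(rec, f)
  back <- read_grf_recording(f)
  expect_identical(back$time_s, rec$time_s)
  expect_identical(back$heel_n, rec$heel_n)
  expect_identical(back$midfoot_n, rec$midfoot_n)
  expect_identical(back$forefoot_n, rec$forefoot_n)
  expect_equal(recording_meta(back), recording_meta(rec))
  # second write is byte-identical (stable dialect)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_grf_recording(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed recording files produce parse errors naming the fault", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# subject_id=X", "# body_weight_n=700",
               "time_s,heel_n,midfoot_n,forefoot_n",
               "0,1,1,1", "0.01,2,2,2", "0.01,3,3,3"), f)
  expect_error(read_grf_recording(f), "repeated time")
  writeLines(c("# subject_id=X", "time_s,heel_n,midfoot_n,forefoot_n",
               "0,1,1,1", "0.01,oops,2,2"), f)
  expect_error(read_grf_recording(f), "non-numeric.*heel_n.*row 2")
  writeLines(c("# subject_id=X", "time_s,heel_n,forefoot_n",
               "0,1,1", "0.01,2,2"), f)
  expect_error(read_grf_recording(f), "missing column.*midfoot_n")
  expect_error(read_grf_recording(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("total force is the exact channel sum at every sample", {
  rec <- grf_recording(c(0, 0.01), c(1, 0), c(2, 0), c(3, 0))
  expect_identical(total_force(rec), c(6, 0))
  rec2 <- make_recording(n = 200, seed = 9)
  expect_identical(total_force(rec2),
                   rec2$heel_n + rec2$midfoot_n + rec2$forefoot_n)
})

test_that("body-weight normalization rescales once and only once", {
  rec <- grf_recording(c(0, 0.01), c(700, 0), c(350, 0), c(0, 0),
                       body_weight_n = 700)
  norm <- normalize_by_body_weight(rec)
  expect_equal(norm$heel_n, c(1, 0))
  expect_equal(norm$midfoot_n, c(0.5, 0))
  expect_true(attr(norm, "normalized"))
  expect_error(normalize_by_body_weight(norm), "already")
})

test_that("protocol trimming keeps the collection window", {
  rec <- make_recording(n = 3000)          # 30 s at 100 Hz
  trimmed <- trim_protocol(rec)
  expect_equal(nrow(trimmed), 2000)
  expect_equal(trimmed$time_s[1], 10, tolerance = 1e-9)
  expect_identical(trimmed$heel_n, rec$heel_n[1001:3000])
  expect_identical(recording_meta(trimmed)$body_weight_n,
                   recording_meta(rec)$body_weight_n)
  # identity when the window is the whole recording
  id <- trim_protocol(rec, adjust_s = 0, collect_s = 30)
  expect_identical(id$heel_n, rec$heel_n)
  # too-short recording errors
  expect_error(trim_protocol(make_recording(n = 2500)), "shorter")
})

test_that("condition grid enumerates incline-major with bijective codes", {
  grid <- condition_grid()
  expect_equal(nrow(grid), 18)
  expect_identical(grid$code, 0:17)
  expect_equal(grid$incline_deg[1:3], c(0, 0, 0))
  expect_equal(grid$speed_mps[1:3], c(0.8, 1.2, 1.6))
  expect_equal(anyDuplicated(paste(grid$incline_deg, grid$speed_mps)), 0L)
  one <- condition_grid(10, 1.2)
  expect_equal(nrow(one), 1)
  expect_identical(one$code, 0L)
  expect_error(condition_grid(c(0, 0, 5), c(0.8)), "duplicate")
})

test_that("label encoding is order-independent and round-trips", {
  grid <- condition_grid()
  enc <- condition_encoder(grid)
  codes <- encode_conditions(grid, enc)
  expect_identical(codes, grid$code)
  back <- decode_conditions(codes, enc)
  expect_equal(back$speed_mps, grid$speed_mps)
  expect_equal(back$incline_deg, grid$incline_deg)
  # shuffled input yields the identical mapping
  shuffled <- grid[withr::with_seed(3, sample(nrow(grid))), ]
  enc2 <- condition_encoder(shuffled)
  expect_equal(as.data.frame(enc2), as.data.frame(enc))
  expect_error(decode_conditions(99L, enc), "not in the encoder")
  expect_error(encode_conditions(data.frame(speed_mps = 9, incline_deg = 0), enc),
               "not in the encoder")
})
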