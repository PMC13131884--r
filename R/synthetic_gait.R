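# Synthetic insole GRF generator with exported ground-truth gait events.
#
# The waveform model is deliberately simple: each stance phase is built from
# half-sine force bumps (heel early, forefoot late, midfoot low in between),
# with walking speed driving cadence and overall amplitude and treadmill
# incline shifting load from heel to forefoot. Analytic construction makes
# the true heel-strike/toe-off samples known exactly, so the parser and the
# whole downstream pipeline can be validated without real sensor data.

#' Parameters of the synthetic gait generator
#'
#' @param base_step_period_s Step period in seconds at the 1.2 m/s reference
#'   speed (default 1.1).
#' @param period_speed_exponent Period scales as `speed^-exponent` relative
#'   to the reference speed (default 0.5): faster walking, shorter steps.
#' @param stance_fraction Fraction of the step period spent in stance
#'   (default 0.62).
#' @param heel_peak_bw Peak heel force in body weights at 0 degrees incline
#'   (default 0.9).
#' @param forefoot_peak_bw Peak forefoot force in BW at 0 degrees
#'   (default 1.0).
#' @param midfoot_peak_bw Peak midfoot force in BW (default 0.25).
#' @param incline_shift_per_deg BW per degree of incline transferred from
#'   heel to forefoot (default 0.012): uphill walking loads the forefoot.
#' @param speed_amp_gain BW of extra peak force per m/s above 0.8 m/s
#'   (default 0.15).
#' @param period_jitter_cv Coefficient of variation of the step-to-step
#'   period (default 0.03).
#' @param amp_jitter_cv Coefficient of variation of step-to-step peak
#'   amplitudes (default 0.05); gives adjacent incline conditions the
#'   overlapping force signatures seen in real gait.
#' @param noise_sd_n Standard deviation (Newtons) of the additive zero-mean
#'   Gaussian sensor noise at the transducer's oversampled rate
#'   (default 2.0).
#' @param noise_oversample Number of transducer draws averaged per emitted
#'   100 Hz sample (default 10), modeling the acquisition chain's
#'   decimation; the in-band RMS noise is `noise_sd_n / sqrt(noise_oversample)`.
#' @param body_weight_n Subject body weight in Newtons (default 700).
#' @param sampling_rate_hz Output sampling rate (default 100).
#'
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(base_step_period_s = 1.1,
                        period_speed_exponent = 0.5,
                        stance_fraction = 0.62,
                        heel_peak_bw = 0.9,
                        forefoot_peak_bw = 1.0,
                        midfoot_peak_bw = 0.25,
                        incline_shift_per_deg = 0.012,
                        speed_amp_gain = 0.15,
                        period_jitter_cv = 0.03,
                        amp_jitter_cv = 0.05,
                        noise_sd_n = 2.0,
                        noise_oversample = 10,
                        body_weight_n = 700,
                        sampling_rate_hz = 100) {
  p <- list(base_step_period_s = base_step_period_s,
            period_speed_exponent = period_speed_exponent,
            stance_fraction = stance_fraction,
            heel_peak_bw = heel_peak_bw,
            forefoot_peak_bw = forefoot_peak_bw,
            midfoot_peak_bw = midfoot_peak_bw,
            incline_shift_per_deg = incline_shift_per_deg,
            speed_amp_gain = speed_amp_gain,
            period_jitter_cv = period_jitter_cv,
            amp_jitter_cv = amp_jitter_cv,
            noise_sd_n = noise_sd_n,
            noise_oversample = noise_oversample,
            body_weight_n = body_weight_n,
            sampling_rate_hz = sampling_rate_hz)
  stopifnot(p$base_step_period_s > 0,
            p$stance_fraction > 0, p$stance_fraction < 1,
            p$heel_peak_bw > 0, p$forefoot_peak_bw > 0, p$midfoot_peak_bw > 0,
            p$period_jitter_cv >= 0, p$amp_jitter_cv >= 0,
            p$noise_sd_n >= 0, p$noise_oversample >= 1,
            p$body_weight_n > 0, p$sampling_rate_hz > 0)
  class(p) <- "gait_params"
  p
}

#' Nominal step period at a given walking speed
#'
#' @param params A [gait_params()].
#' @param speed_mps Walking speed in m/s.
#' @return Step period in seconds.
#' @export
step_period <- function(params, speed_mps) {
  params$base_step_period_s * (speed_mps / 1.2)^(-params$period_speed_exponent)
}

# one multiplicative jitter draw, floored so the factor stays positive
.jitter <- function(cv) max(0.2, 1 + stats::rnorm(1, 0, cv))

# band-limited sensor noise: mean of `over` white draws per output sample
.sensor_noise <- function(n, sd, over) {
  if (sd <= 0) return(numeric(n))
  stats::rnorm(n, 0, sd / sqrt(over))
}

#' Simulate one gait cycle
#'
#' Generates one full step period (stance + swing) of heel/midfoot/forefoot
#' force at the configured sampling rate, plus the ground-truth event
#' samples. The heel bump occupies the first half of stance (peaking at
#' ~25% of stance), the forefoot bump the second half (peaking at ~75%),
#' and the midfoot a low bump in mid-stance. Peak amplitudes follow the
#' condition: incline shifts load heel-to-forefoot at
#' `incline_shift_per_deg` BW/degree (heel floored at 0.1 BW) and speed adds
#' `speed_amp_gain` BW per m/s above 0.8. Draws period/amplitude jitter and
#' sensor noise from the current RNG state; seed the RNG for
#' reproducibility.
#'
#' @param params A [gait_params()].
#' @param speed_mps,incline_deg The loading condition.
#' @return A list with numeric vectors `heel`, `midfoot`, `forefoot`
#'   (Newtons, one step period long), and 1-based sample indices
#'   `hs_idx` (truth heel strike: first sample of stance, already above the
#'   1 N event threshold when noise-free) and `to_idx` (truth toe-off:
#'   first sample at which the forefoot has returned to zero).
#' @export
simulate_step <- function(params, speed_mps, incline_deg) {
  fs <- params$sampling_rate_hz
  period <- step_period(params, speed_mps) * .jitter(params$period_jitter_cv)
  n_step <- max(4L, as.integer(round(period * fs)))
  n_stance <- max(3L, as.integer(round(params$stance_fraction * n_step)))

  speed_gain <- params$speed_amp_gain * (speed_mps - 0.8)
  heel_amp <- max(params$heel_peak_bw - params$incline_shift_per_deg * incline_deg
                  + speed_gain, 0.1)
  ff_amp <- params$forefoot_peak_bw + params$incline_shift_per_deg * incline_deg +
    speed_gain
  mid_amp <- params$midfoot_peak_bw
  bw <- params$body_weight_n
  heel_amp <- heel_amp * .jitter(params$amp_jitter_cv) * bw
  ff_amp <- ff_amp * .jitter(params$amp_jitter_cv) * bw
  mid_amp <- mid_amp * .jitter(params$amp_jitter_cv) * bw

  heel <- numeric(n_step)
  mid <- numeric(n_step)
  ff <- numeric(n_step)

  # heel: half-sine on the first half of stance; sampled with a one-sample
  # phase lead so the stance-onset sample is already on the rise (the truth
  # heel strike is then the first sample exceeding the 1 N event threshold)
  n_h <- max(2L, as.integer(round(0.5 * n_stance)))
  k <- seq_len(n_h)
  heel[k] <- heel_amp * sin(pi * k / (n_h + 1))

  # forefoot: half-sine on the second half of stance, exactly zero at the
  # stance end sample (the truth toe-off)
  n_f <- max(2L, as.integer(round(0.5 * n_stance)))
  kf <- (n_stance - n_f + 1L):n_stance
  ff[kf] <- ff_amp * sin(pi * (n_stance + 1L - kf) / (n_f + 1))

  # midfoot: low bump across mid-stance
  a <- max(1L, as.integer(round(0.2 * n_stance)))
  b <- as.integer(round(0.8 * n_stance))
  km <- a:b
  mid[km] <- mid_amp * sin(pi * (km - a + 1) / (b - a + 2))

  noisy <- function(x) {
    pmax(x + .sensor_noise(n_step, params$noise_sd_n, params$noise_oversample), 0)
  }
  list(heel = noisy(heel), midfoot = noisy(mid), forefoot = noisy(ff),
       hs_idx = 1L, to_idx = n_stance + 1L, n = n_step)
}

#' Simulate one recording session across conditions
#'
#' For each condition, concatenates whole simulated steps until the next
#' step would exceed the collection window, then pads the remainder with
#' noise-only swing samples, producing one [grf_recording()] of exactly
#' `collect_s` seconds per condition plus a ground-truth event table.
#'
#' @param params A [gait_params()].
#' @param conditions A condition table as from [condition_grid()].
#' @param collect_s Seconds of data per condition (default 20).
#' @param seed Integer seed for all jitter and noise; `NULL` uses the
#'   current RNG state.
#' @param subject_id Subject identifier attached to the recordings.
#' @param lead_in_s Seconds of swing (zero force) before the first step of
#'   each recording (default 0.05), so the first heel strike has a
#'   sub-threshold sample before it.
#' @return A list with `recordings` (list of [grf_recording()], one per
#'   condition, in condition order) and `truth` (tibble: `condition_index`,
#'   `step_index`, `heel_strike_s`, `toe_off_s`, `speed_mps`,
#'   `incline_deg`; times relative to each recording's start).
#' @export
simulate_session <- function(params, conditions = condition_grid(),
                             collect_s = 20, seed = NULL,
                             subject_id = "SIM01", lead_in_s = 0.05) {
  stopifnot(is.data.frame(conditions),
            all(c("speed_mps", "incline_deg") %in% names(conditions)))
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  fs <- params$sampling_rate_hz
  n_total <- as.integer(round(collect_s * fs))
  recordings <- vector("list", nrow(conditions))
  truth <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    sp <- conditions$speed_mps[ci]
    inc <- conditions$incline_deg[ci]
    if (collect_s <= 2 * step_period(params, sp)) {
      rlang::abort("`collect_s` must exceed two step periods")
    }
    heel <- numeric(n_total); mid <- numeric(n_total); ff <- numeric(n_total)
    pos <- as.integer(round(lead_in_s * fs))
    if (pos > 0L) {
      lead <- seq_len(pos)
      heel[lead] <- pmax(.sensor_noise(pos, params$noise_sd_n, params$noise_oversample), 0)
      mid[lead] <- pmax(.sensor_noise(pos, params$noise_sd_n, params$noise_oversample), 0)
      ff[lead] <- pmax(.sensor_noise(pos, params$noise_sd_n, params$noise_oversample), 0)
    }
    rows <- list()
    step_index <- 0L
    repeat {
      st <- simulate_step(params, sp, inc)
      if (pos + st$n > n_total) break
      idx <- (pos + 1L):(pos + st$n)
      heel[idx] <- st$heel; mid[idx] <- st$midfoot; ff[idx] <- st$forefoot
      step_index <- step_index + 1L
      rows[[step_index]] <- tibble::tibble(
        condition_index = ci, step_index = step_index,
        heel_strike_s = (pos + st$hs_idx - 1L) / fs,
        toe_off_s = (pos + st$to_idx - 1L) / fs,
        speed_mps = sp, incline_deg = inc)
      pos <- pos + st$n
    }
    if (pos < n_total) {
      tail_idx <- (pos + 1L):n_total
      nt <- length(tail_idx)
      heel[tail_idx] <- pmax(.sensor_noise(nt, params$noise_sd_n, params$noise_oversample), 0)
      mid[tail_idx] <- pmax(.sensor_noise(nt, params$noise_sd_n, params$noise_oversample), 0)
      ff[tail_idx] <- pmax(.sensor_noise(nt, params$noise_sd_n, params$noise_oversample), 0)
    }
    recordings[[ci]] <- grf_recording(
      time_s = (seq_len(n_total) - 1L) / fs,
      heel_n = heel, midfoot_n = mid, forefoot_n = ff,
      subject_id = subject_id, body_weight_n = params$body_weight_n,
      speed_mps = sp, incline_deg = inc, sampling_rate_hz = fs)
    truth[[ci]] <- dplyr::bind_rows(rows)
  }
  list(recordings = recordings, truth = dplyr::bind_rows(truth))
}

#' Simulate a cohort of subjects
#'
#' Draws subject-level parameters (body weight uniform on 500-1000 N;
#' amplitude parameters uniform within +/-15% of their defaults) and
#' simulates one session per subject. Per-subject seeds are derived
#' deterministically from `seed`, so adding a subject never perturbs the
#' others.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param conditions Condition table (default the 18-condition grid).
#' @param collect_s Seconds of data per condition (default 20).
#' @param seed Master integer seed.
#' @param params_fn Optional function `(subject_index, base_params)` ->
#'   [gait_params()], replacing the default subject-level draws.
#' @return A tibble of class `grf_cohort`: one row per subject with columns
#'   `subject_id`, `seed`, and list-columns `params`, `recordings`, `truth`.
#' @export
simulate_cohort <- function(n_subjects = 14, conditions = condition_grid(),
                            collect_s = 20, seed = 1, params_fn = NULL) {
  stopifnot(n_subjects >= 1)
  rows <- purrr::map(seq_len(n_subjects), function(s) {
    subject_seed <- (as.integer(seed) + 7919L * s) %% 2147483647L
    set.seed(subject_seed)
    if (is.null(params_fn)) {
      jig <- function(x) x * stats::runif(1, 0.85, 1.15)
      params <- gait_params(
        body_weight_n = stats::runif(1, 500, 1000),
        heel_peak_bw = jig(0.9),
        forefoot_peak_bw = jig(1.0),
        midfoot_peak_bw = jig(0.25),
        incline_shift_per_deg = 0.012,
        speed_amp_gain = 0.15)
    } else {
      params <- params_fn(s, gait_params())
    }
    subject_id <- sprintf("SIM%02d", s)
    sess <- simulate_session(params, conditions, collect_s,
                             seed = subject_seed, subject_id = subject_id)
    tibble::tibble(subject_id = subject_id, seed = subject_seed,
                   params = list(params), recordings = list(sess$recordings),
                   truth = list(sess$truth))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grf_cohort", class(out))
  out
}

#' Write a simulated session to disk in the recording CSV dialect
#'
#' Writes one recording CSV per condition plus a `truth.csv` with the
#' ground-truth events.
#'
#' @param session A list as returned by [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(session$recordings)) {
    rec <- session$recordings[[i]]
    m <- recording_meta(rec)
    fn <- sprintf("%s_speed%.1f_incline%02d.csv", m$subject_id, m$speed_mps,
                  as.integer(m$incline_deg))
    write_grf_recording(rec, file.path(dir, fn))
  }
  utils::write.csv(session$truth[, c("step_index", "heel_strike_s",
                                     "toe_off_s", "speed_mps", "incline_deg")],
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
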