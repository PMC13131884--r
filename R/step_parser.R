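# Gait-cycle segmentation from regional GRF signals.
#
# Steps are delimited by threshold-crossing logic anchored to detected force
# peaks: a heel strike is the last upward 1 N crossing of the heel signal
# before a heel peak, a toe-off the first downward 1 N crossing of the
# forefoot signal after the following forefoot peak. Signal-intersection
# events (heel = total, forefoot = heel, forefoot = total), computed on
# body-weight-normalized noise-floored copies, annotate the stance phases.

#' Step-parser configuration
#'
#' Detection thresholds for gait-event parsing. Peak and event thresholds
#' apply to the raw signals in Newtons; the noise floor applies to the
#' body-weight-normalized copies used for intersection analysis (as
#' `noise_floor_n / body_weight`).
#'
#' @param ff_peak_min_n Minimum forefoot peak height in N (default 7).
#' @param heel_peak_min_n Minimum heel peak height in N (default 3.5).
#' @param peak_min_separation_ms Minimum separation between retained peaks
#'   in milliseconds (default 80).
#' @param event_threshold_n Heel-strike / toe-off crossing threshold in N
#'   (default 1).
#' @param zero_amplitude_eps_n Intersections are kept only when one signal
#'   is within this many Newtons of zero at the crossing (default 0.5).
#' @param noise_floor_n Values below this force (N), after body-weight
#'   normalization as `noise_floor_n / body_weight`, are zeroed on the
#'   intersection-analysis copies (default 1.5).
#' @return A list of class `parser_config`.
#' @export
parser_config <- function(ff_peak_min_n = 7, heel_peak_min_n = 3.5,
                          peak_min_separation_ms = 80, event_threshold_n = 1,
                          zero_amplitude_eps_n = 0.5, noise_floor_n = 1.5) {
  cfg <- list(ff_peak_min_n = ff_peak_min_n,
              heel_peak_min_n = heel_peak_min_n,
              peak_min_separation_ms = peak_min_separation_ms,
              event_threshold_n = event_threshold_n,
              zero_amplitude_eps_n = zero_amplitude_eps_n,
              noise_floor_n = noise_floor_n)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, logical(1))))
  class(cfg) <- "parser_config"
  cfg
}

#' Zero out sub-threshold samples
#'
#' Samples with value strictly below `floor` are set to 0; all others are
#' unchanged. Used to suppress noise on the normalized copies fed to
#' intersection analysis.
#'
#' @param x Numeric force series.
#' @param floor Noise-floor threshold, in the same units as `x`.
#' @return The floored series.
#' @export
apply_noise_floor <- function(x, floor) {
  x[x < floor] <- 0
  x
}

#' Sign-reversal crossings of two signals
#'
#' Returns each (1-based) index `i >= 2` at which the sign of the pointwise
#' difference `a - b` reverses between consecutive samples. Exact-zero
#' differences inherit the previous nonzero sign, so a difference that
#' touches zero without crossing is not an event. The reported index is the
#' later sample of the reversing pair (the first sample on the new side).
#'
#' @param a,b Numeric series of equal length (>= 2).
#' @return Integer vector of crossing indices.
#' @export
signed_difference_crossings <- function(a, b) {
  n <- length(a)
  if (length(b) != n) rlang::abort("`a` and `b` must have equal length")
  if (n < 2) return(integer(0))
  s <- sign(a - b)
  nz <- s != 0
  # carry the last nonzero sign forward; samples before any nonzero keep 0
  idx <- cumsum(nz)
  filled <- ifelse(idx > 0, s[nz][pmax(idx, 1L)], 0)
  which(filled[-1] * filled[-n] < 0) + 1L
}

#' Keep only crossings where one signal approaches zero
#'
#' @param crossings Crossing indices from [signed_difference_crossings()].
#' @param a,b The two series the crossings came from.
#' @param eps Zero-amplitude tolerance (same units as the signals).
#' @return The subset of `crossings` at which `min(a[i], b[i]) <= eps`.
#' @export
refine_zero_amplitude <- function(crossings, a, b, eps) {
  crossings[pmin(a[crossings], b[crossings]) <= eps]
}

#' Detect force peaks
#'
#' Local maxima above `min_height` — samples strictly greater than both
#' neighbours, with a flat run (plateau) strictly above its flanks counting
#' once, at its first sample — pruned greedily so retained peaks are
#' separated by at least `min_separation_ms`: candidates are visited from
#' highest to lowest (ties broken toward the earlier index) and kept only
#' if no already-kept peak lies closer than the separation.
#'
#' @param x Numeric force series.
#' @param min_height Minimum peak height (same units as `x`).
#' @param min_separation_ms Minimum peak separation in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Sorted integer vector of peak indices (1-based).
#' @export
detect_force_peaks <- function(x, min_height, min_separation_ms, fs) {
  stopifnot(fs > 0)
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  nr <- length(r$values)
  cand <- integer(0)
  if (nr >= 3) {
    mid <- 2:(nr - 1)
    is_peak <- r$values[mid] > r$values[mid - 1] &
      r$values[mid] > r$values[mid + 1] & r$values[mid] > min_height
    cand <- run_start[mid][is_peak]
  }
  if (!length(cand)) return(integer(0))
  sep <- min_separation_ms / 1000 * fs
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || min(abs(kept - i)) >= sep) kept <- c(kept, i)
  }
  sort(kept)
}

#' Locate the heel strike for a heel peak
#'
#' Scans backward from the heel peak for the nearest upward crossing of the
#' event threshold: the first index `j` (counting back from the peak) with
#' `heel[j - 1] <= threshold < heel[j]`. This is the onset of the rise that
#' produces the peak.
#'
#' @param heel Heel force series (N).
#' @param heel_peak Peak index; `heel[heel_peak]` must exceed `threshold`.
#' @param threshold Event threshold in N (default 1).
#' @return The heel-strike index, or `NA_integer_` if the signal is above
#'   threshold all the way back to the first sample (event rejected).
#' @export
find_heel_strike <- function(heel, heel_peak, threshold = 1) {
  stopifnot(heel_peak >= 1, heel_peak <= length(heel),
            heel[heel_peak] > threshold)
  if (heel_peak < 2) return(NA_integer_)
  j <- 2:heel_peak
  cross <- j[heel[j - 1] <= threshold & heel[j] > threshold]
  if (!length(cross)) NA_integer_ else max(cross)
}

#' Locate the toe-off for a forefoot peak
#'
#' Scans forward from the forefoot peak for the first downward crossing of
#' the event threshold: the first index `j` with
#' `forefoot[j - 1] > threshold >= forefoot[j]`.
#'
#' @param forefoot Forefoot force series (N).
#' @param ff_peak Peak index; `forefoot[ff_peak]` must exceed `threshold`.
#' @param threshold Event threshold in N (default 1).
#' @return The toe-off index, or `NA_integer_` if no crossing occurs before
#'   the end of the recording (step truncated).
#' @export
find_toe_off <- function(forefoot, ff_peak, threshold = 1) {
  n <- length(forefoot)
  stopifnot(ff_peak >= 1, ff_peak <= n, forefoot[ff_peak] > threshold)
  if (ff_peak >= n) return(NA_integer_)
  j <- (ff_peak + 1L):n
  cross <- j[forefoot[j - 1] > threshold & forefoot[j] <= threshold]
  if (!length(cross)) NA_integer_ else min(cross)
}

#' Segment a recording into gait cycles
#'
#' For each detected heel peak in time order: locate its heel strike, pair
#' it with the first forefoot peak after the heel peak and that peak's
#' toe-off, and emit a step segment spanning the half-open sample interval
#' `[heel_strike, toe_off)` (the stance phase) if the boundaries are
#' ordered and the segment does not overlap the previously emitted one
#' (overlaps discard the later candidate). Refined signal intersections
#' falling inside a segment are attached as phase annotations: initial
#' contact (heel = total), midstance (forefoot = heel) and toe-off
#' (forefoot = total), computed on body-weight-normalized copies with the
#' noise floor applied.
#'
#' @param rec A [grf_recording()] (raw Newtons; a normalized recording is
#'   converted back to Newtons internally so the thresholds apply).
#' @param cfg A [parser_config()].
#' @return A tibble of class `grf_steps`, one row per step: `step_id`,
#'   `start_idx`/`end_idx` (1-based, half-open), `start_s`/`end_s`,
#'   `ms_idx`/`ms_s` (first midstance intersection inside the segment, or
#'   `NA`), `heel_peak_idx`, `ff_peak_idx`, `n` (samples), list-columns
#'   `heel`/`midfoot`/`forefoot` (raw-N channel slices), `events`
#'   (per-step event tibble), and the recording's `subject_id`,
#'   `speed_mps`, `incline_deg`. Parsing diagnostics (counts of detected,
#'   emitted, rejected, truncated and overlap-discarded candidates) are in
#'   attribute `"diagnostics"`; see [validate_steps()].
#' @export
segment_steps <- function(rec, cfg = parser_config()) {
  stopifnot(inherits(rec, "grf_recording"), inherits(cfg, "parser_config"))
  m <- recording_meta(rec)
  fs <- m$sampling_rate_hz
  scale <- if (m$normalized) m$body_weight_n else 1
  heel <- rec$heel_n * scale
  mid <- rec$midfoot_n * scale
  ff <- rec$forefoot_n * scale
  time_s <- rec$time_s
  n <- length(heel)

  empty <- tibble::tibble(step_id = integer(0), start_idx = integer(0),
                          end_idx = integer(0), start_s = numeric(0),
                          end_s = numeric(0), ms_idx = integer(0),
                          ms_s = numeric(0), heel_peak_idx = integer(0),
                          ff_peak_idx = integer(0), n = integer(0),
                          heel = list(), midfoot = list(), forefoot = list(),
                          events = list(), subject_id = character(0),
                          speed_mps = numeric(0), incline_deg = numeric(0))

  heel_peaks <- detect_force_peaks(heel, cfg$heel_peak_min_n,
                                   cfg$peak_min_separation_ms, fs)
  ff_peaks <- detect_force_peaks(ff, cfg$ff_peak_min_n,
                                 cfg$peak_min_separation_ms, fs)

  # intersection analysis on normalized, noise-floored copies
  bw <- m$body_weight_n
  floor_bw <- cfg$noise_floor_n / bw
  eps_bw <- cfg$zero_amplitude_eps_n / bw
  nh <- apply_noise_floor(heel / bw, floor_bw)
  nm <- apply_noise_floor(mid / bw, floor_bw)
  nf <- apply_noise_floor(ff / bw, floor_bw)
  nt <- nh + nm + nf
  ix_hc <- refine_zero_amplitude(signed_difference_crossings(nh, nt), nh, nt, eps_bw)
  ix_ms <- refine_zero_amplitude(signed_difference_crossings(nf, nh), nf, nh, eps_bw)
  # the midstance annotation is the crossing where the forefoot overtakes
  # the heel (difference turns positive); the opposite-direction crossing
  # near initial contact stays in the event list but is not midstance
  ix_ms_pos <- ix_ms[nf[ix_ms] > nh[ix_ms]]
  ix_to <- refine_zero_amplitude(signed_difference_crossings(nf, nt), nf, nt, eps_bw)

  diag <- c(heel_peaks = length(heel_peaks), ff_peaks = length(ff_peaks),
            emitted = 0L, rejected_no_onset = 0L, truncated = 0L,
            overlap_discarded = 0L)
  out <- list()
  prev_end <- -Inf
  thr <- cfg$event_threshold_n
  for (p in heel_peaks) {
    hs <- find_heel_strike(heel, p, thr)
    if (is.na(hs)) { diag["rejected_no_onset"] <- diag["rejected_no_onset"] + 1L; next }
    fp <- ff_peaks[ff_peaks > p]
    if (!length(fp)) { diag["truncated"] <- diag["truncated"] + 1L; next }
    fp <- fp[1]
    to <- find_toe_off(ff, fp, thr)
    if (is.na(to)) { diag["truncated"] <- diag["truncated"] + 1L; next }
    if (!(hs < to)) { diag["rejected_no_onset"] <- diag["rejected_no_onset"] + 1L; next }
    if (hs < prev_end) { diag["overlap_discarded"] <- diag["overlap_discarded"] + 1L; next }
    sl <- hs:(to - 1L)
    ms_in <- ix_ms[ix_ms >= hs & ix_ms < to]
    ms_pos_in <- ix_ms_pos[ix_ms_pos >= hs & ix_ms_pos < to]
    ms_idx <- if (length(ms_pos_in)) ms_pos_in[1] else NA_integer_
    ev <- tibble::tibble(
      kind = c("heel_strike", "toe_off", "heel_peak", "ff_peak",
               rep("intersection_HC", sum(ix_hc >= hs & ix_hc < to)),
               rep("intersection_MS", length(ms_in)),
               rep("intersection_TO", sum(ix_to >= hs & ix_to < to))),
      sample_index = c(hs, to, p, fp,
                       ix_hc[ix_hc >= hs & ix_hc < to], ms_in,
                       ix_to[ix_to >= hs & ix_to < to]))
    ev$time_s <- time_s[ev$sample_index]
    diag["emitted"] <- diag["emitted"] + 1L
    out[[length(out) + 1L]] <- tibble::tibble(
      step_id = diag[["emitted"]], start_idx = hs, end_idx = to,
      start_s = time_s[hs], end_s = time_s[to],
      ms_idx = ms_idx, ms_s = if (is.na(ms_idx)) NA_real_ else time_s[ms_idx],
      heel_peak_idx = p, ff_peak_idx = fp, n = length(sl),
      heel = list(heel[sl]), midfoot = list(mid[sl]), forefoot = list(ff[sl]),
      events = list(ev), subject_id = m$subject_id,
      speed_mps = m$speed_mps, incline_deg = m$incline_deg)
    prev_end <- to
  }
  res <- if (length(out)) dplyr::bind_rows(out) else empty
  attr(res, "diagnostics") <- diag
  class(res) <- c("grf_steps", class(res))
  res
}

#' Summarize parsing diagnostics
#'
#' Automated stand-in for visual inspection of the parsed events: reports
#' how many heel-peak candidates were emitted as steps, rejected for lack
#' of a threshold onset, truncated at the recording end, or discarded for
#' overlapping an earlier step, and checks the bookkeeping identity
#' candidates = emitted + rejected + truncated + overlap-discarded.
#'
#' @param steps A `grf_steps` tibble from [segment_steps()].
#' @return A tibble with columns `metric` and `count`.
#' @export
validate_steps <- function(steps) {
  d <- attr(steps, "diagnostics")
  if (is.null(d)) rlang::abort("`steps` carries no parsing diagnostics")
  accounted <- d[["emitted"]] + d[["rejected_no_onset"]] + d[["truncated"]] +
    d[["overlap_discarded"]]
  tibble::tibble(
    metric = c("heel_peak_candidates", "forefoot_peaks", "emitted",
               "rejected_no_onset", "truncated", "overlap_discarded",
               "candidates_accounted"),
    count = c(d[["heel_peaks"]], d[["ff_peaks"]], d[["emitted"]],
              d[["rejected_no_onset"]], d[["truncated"]],
              d[["overlap_discarded"]], accounted))
}

#' Parse every recording of a session into one step table
#'
#' @param recordings A list of [grf_recording()]s.
#' @param cfg A [parser_config()].
#' @return A combined `grf_steps` tibble with globally renumbered
#'   `step_id`s; per-recording diagnostics are summed in the
#'   `"diagnostics"` attribute.
#' @export
segment_session <- function(recordings, cfg = parser_config()) {
  parsed <- purrr::map(recordings, segment_steps, cfg = cfg)
  diags <- purrr::map(parsed, attr, "diagnostics")
  res <- dplyr::bind_rows(parsed)
  if (nrow(res)) res$step_id <- seq_len(nrow(res))
  attr(res, "diagnostics") <- Reduce(`+`, diags)
  class(res) <- unique(c("grf_steps", class(res)))
  res
}
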