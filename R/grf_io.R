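#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom dplyr arrange distinct left_join mutate bind_rows
NULL

# ---------------------------------------------------------------------------
# Recording container
# ---------------------------------------------------------------------------

#' Construct an insole ground-reaction-force recording
#'
#' A `grf_recording` is a tibble with one row per sample and columns
#' `time_s`, `heel_n`, `midfoot_n`, `forefoot_n`, carrying recording-level
#' metadata (subject, body weight, loading condition, sampling rate) as
#' attributes. Forces are regional vertical ground reaction forces in
#' Newtons from a pressure-sensing insole (heel, midfoot and forefoot
#' zones); after [normalize_by_body_weight()] they are in units of body
#' weight (BW) and the `normalized` flag is set.
#'
#' @param time_s Sample times in seconds; strictly increasing and uniform.
#' @param heel_n,midfoot_n,forefoot_n Regional forces per sample. Newtons
#'   (or BW if `normalized = TRUE`); must be finite and non-negative.
#' @param subject_id Subject identifier string.
#' @param body_weight_n Subject body weight in Newtons; must be positive.
#' @param speed_mps Treadmill speed of the recording condition (m/s), or
#'   `NA` if unknown.
#' @param incline_deg Treadmill incline of the condition (degrees), or `NA`.
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param normalized Logical; `TRUE` once forces have been divided by body
#'   weight.
#'
#' @return A tibble of class `grf_recording`.
#' @seealso [read_grf_recording()], [total_force()], [trim_protocol()]
#' @export
grf_recording <- function(time_s, heel_n, midfoot_n, forefoot_n,
                          subject_id = "S01", body_weight_n = 700,
                          speed_mps = NA_real_, incline_deg = NA_real_,
                          sampling_rate_hz = 100, normalized = FALSE) {
  n <- length(time_s)
  if (length(heel_n) != n || length(midfoot_n) != n || length(forefoot_n) != n) {
    abort("all force channels must have the same length as `time_s`")
  }
  if (n < 1) abort("a recording needs at least one sample")
  if (!all(is.finite(time_s))) abort("`time_s` contains non-finite values")
  for (ch in c("heel_n", "midfoot_n", "forefoot_n")) {
    x <- switch(ch, heel_n = heel_n, midfoot_n = midfoot_n, forefoot_n = forefoot_n)
    if (!all(is.finite(x))) {
      abort(sprintf("channel `%s` contains non-finite values (first at row %d)",
                    ch, which(!is.finite(x))[1]))
    }
    if (any(x < 0)) {
      abort(sprintf("channel `%s` contains negative forces (first at row %d)",
                    ch, which(x < 0)[1]))
    }
  }
  if (n > 1) {
    dt <- diff(time_s)
    if (any(dt <= 0)) {
      abort(sprintf("`time_s` must be strictly increasing (violated at row %d)",
                    which(dt <= 0)[1] + 1L))
    }
    if (max(dt) - min(dt) > 1e-6) {
      abort("`time_s` must be uniformly sampled")
    }
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive")
  }
  if (!is.numeric(body_weight_n) || body_weight_n <= 0) {
    abort("`body_weight_n` must be positive")
  }
  out <- tibble(time_s = as.numeric(time_s), heel_n = as.numeric(heel_n),
                midfoot_n = as.numeric(midfoot_n),
                forefoot_n = as.numeric(forefoot_n))
  structure(out,
            subject_id = as.character(subject_id),
            body_weight_n = as.numeric(body_weight_n),
            speed_mps = as.numeric(speed_mps),
            incline_deg = as.numeric(incline_deg),
            sampling_rate_hz = as.numeric(sampling_rate_hz),
            normalized = isTRUE(normalized),
            class = c("grf_recording", class(out)))
}

#' Recording metadata
#'
#' @param rec A [grf_recording()].
#' @return A one-row tibble of recording metadata.
#' @export
recording_meta <- function(rec) {
  stopifnot(inherits(rec, "grf_recording"))
  tibble(subject_id = attr(rec, "subject_id"),
         body_weight_n = attr(rec, "body_weight_n"),
         speed_mps = attr(rec, "speed_mps"),
         incline_deg = attr(rec, "incline_deg"),
         sampling_rate_hz = attr(rec, "sampling_rate_hz"),
         normalized = attr(rec, "normalized"),
         n_samples = nrow(rec))
}

#' @export
print.grf_recording <- function(x, ...) {
  m <- recording_meta(x)
  cat(sprintf("<grf_recording> subject %s | %.3g s at %g Hz | %s | speed %s m/s, incline %s deg\n",
              m$subject_id, nrow(x) / m$sampling_rate_hz, m$sampling_rate_hz,
              if (m$normalized) "normalized (BW)" else "raw (N)",
              format(m$speed_mps), format(m$incline_deg)))
  NextMethod()
}

# ---------------------------------------------------------------------------
# CSV dialect
# ---------------------------------------------------------------------------

.header_keys <- c("subject_id", "body_weight_n", "speed_mps", "incline_deg",
                  "sampling_rate_hz")

#' Read a recording from the self-describing CSV dialect
#'
#' The dialect is a plain CSV with a `#`-prefixed `key=value` header block
#' (`subject_id`, `body_weight_n`, `speed_mps`, `incline_deg`,
#' `sampling_rate_hz`, optionally `normalized`) followed by the columns
#' `time_s,heel_n,midfoot_n,forefoot_n`, one row per sample.
#'
#' @param path Path to a recording CSV file.
#' @return A [grf_recording()].
#' @export
read_grf_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
    }
  }
  body <- lines[!hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) abort(sprintf("no data rows in %s", path))
  df <- utils::read.csv(text = body, colClasses = "character",
                        check.names = FALSE)
  need <- c("time_s", "heel_n", "midfoot_n", "forefoot_n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s) in %s: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  num <- lapply(need, function(cn) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(x))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column `%s` at data row %d of %s",
                    cn, bad[1], path))
    }
    x
  })
  names(num) <- need
  if (anyDuplicated(num$time_s)) {
    abort(sprintf("repeated time value at data row %d of %s",
                  anyDuplicated(num$time_s), path))
  }
  as_num <- function(key, default = NA_real_) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  grf_recording(num$time_s, num$heel_n, num$midfoot_n, num$forefoot_n,
                subject_id = if (is.null(meta$subject_id)) "unknown" else meta$subject_id,
                body_weight_n = as_num("body_weight_n", 700),
                speed_mps = as_num("speed_mps"),
                incline_deg = as_num("incline_deg"),
                sampling_rate_hz = as_num("sampling_rate_hz", 100),
                normalized = identical(tolower(meta$normalized %||% "false"), "true"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording in the self-describing CSV dialect
#'
#' Emits the identical dialect that [read_grf_recording()] parses, with
#' full (round-trippable) float precision and a fixed column order.
#'
#' @param rec A [grf_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grf_recording <- function(rec, path) {
  stopifnot(inherits(rec, "grf_recording"))
  m <- recording_meta(rec)
  hdr <- c(sprintf("# subject_id=%s", m$subject_id),
           sprintf("# body_weight_n=%.17g", m$body_weight_n),
           sprintf("# speed_mps=%.17g", m$speed_mps),
           sprintf("# incline_deg=%.17g", m$incline_deg),
           sprintf("# sampling_rate_hz=%.17g", m$sampling_rate_hz))
  if (m$normalized) hdr <- c(hdr, "# normalized=true")
  rows <- sprintf("%.17g,%.17g,%.17g,%.17g",
                  rec$time_s, rec$heel_n, rec$midfoot_n, rec$forefoot_n)
  writeLines(c(hdr, "time_s,heel_n,midfoot_n,forefoot_n", rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Derived signals and preprocessing
# ---------------------------------------------------------------------------

#' Total-foot force
#'
#' The total-foot signal is the sum of the three regional channels at every
#' sample, i.e. the insole's regional decomposition reassembled.
#'
#' @param rec A [grf_recording()].
#' @return Numeric vector of total force per sample.
#' @export
total_force <- function(rec) {
  stopifnot(inherits(rec, "grf_recording"))
  rec$heel_n + rec$midfoot_n + rec$forefoot_n
}

#' Normalize a recording by body weight
#'
#' Divides every force channel by the subject's body weight, making the
#' signals dimensionless (units of BW) and comparable across subjects.
#' Applying it twice is an error.
#'
#' @param rec A raw (unnormalized) [grf_recording()].
#' @return The normalized recording with the `normalized` flag set.
#' @export
normalize_by_body_weight <- function(rec) {
  stopifnot(inherits(rec, "grf_recording"))
  if (attr(rec, "normalized")) {
    abort("recording is already body-weight normalized")
  }
  bw <- attr(rec, "body_weight_n")
  out <- rec
  out$heel_n <- rec$heel_n / bw
  out$midfoot_n <- rec$midfoot_n / bw
  out$forefoot_n <- rec$forefoot_n / bw
  attr(out, "normalized") <- TRUE
  out
}

#' Trim a recording to the data-collection window
#'
#' Drops the adjustment (warm-up) period and anything after the collection
#' window, keeping the half-open interval
#' `[adjust_s, adjust_s + collect_s)` relative to the recording start. The
#' defaults match a 30 s trial protocol: 20 s of data collection following
#' a 10 s adjustment period.
#'
#' @param rec A [grf_recording()].
#' @param adjust_s Seconds of adjustment period to discard (default 10).
#' @param collect_s Seconds of data collection to keep (default 20).
#' @return The trimmed [grf_recording()].
#' @export
trim_protocol <- function(rec, adjust_s = 10, collect_s = 20) {
  stopifnot(inherits(rec, "grf_recording"))
  fs <- attr(rec, "sampling_rate_hz")
  duration <- nrow(rec) / fs
  if (duration < adjust_s + collect_s - 1e-9) {
    abort(sprintf("recording of %.2f s is shorter than adjust_s + collect_s = %.2f s",
                  duration, adjust_s + collect_s))
  }
  t0 <- rec$time_s[1]
  keep <- rec$time_s >= t0 + adjust_s - 1e-9 &
    rec$time_s < t0 + adjust_s + collect_s - 1e-9
  out <- rec[keep, ]
  # subsetting a tibble keeps extra attributes only partially; restore class
  attrs <- attributes(rec)
  for (a in c("subject_id", "body_weight_n", "speed_mps", "incline_deg",
              "sampling_rate_hz", "normalized")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(rec)
  out
}

# ---------------------------------------------------------------------------
# Condition labels
# ---------------------------------------------------------------------------

#' Enumerate a speed-by-incline condition grid
#'
#' Builds the Cartesian product of inclines and speeds in a deterministic
#' order (incline-major, speed ascending within incline) and assigns
#' integer codes `0..N-1` in that order. The defaults are the 18-condition
#' grid of 6 inclines (0, 5, 10, 15, 20, 25 degrees) by 3 speeds (0.8,
#' 1.2, 1.6 m/s).
#'
#' @param inclines_deg Unique incline values in degrees.
#' @param speeds_mps Unique speed values in m/s.
#' @return A tibble with columns `incline_deg`, `speed_mps`, `code`.
#' @export
condition_grid <- function(inclines_deg = c(0, 5, 10, 15, 20, 25),
                           speeds_mps = c(0.8, 1.2, 1.6)) {
  if (length(inclines_deg) == 0 || length(speeds_mps) == 0) {
    abort("incline and speed lists must be non-empty")
  }
  if (anyDuplicated(inclines_deg)) abort("duplicate incline values")
  if (anyDuplicated(speeds_mps)) abort("duplicate speed values")
  grid <- tidyr::expand_grid(incline_deg = sort(as.numeric(inclines_deg)),
                             speed_mps = sort(as.numeric(speeds_mps)))
  grid$code <- seq_len(nrow(grid)) - 1L
  grid
}

#' Build a stable label encoding for condition pairs
#'
#' Maps each distinct (speed, incline) pair to an integer class code. Codes
#' are assigned after sorting by (incline, speed), so the mapping is
#' independent of the order in which labels are supplied.
#'
#' @param labels A data frame with columns `speed_mps` and `incline_deg`.
#' @return A tibble of class `condition_encoder` with columns
#'   `incline_deg`, `speed_mps`, `code`.
#' @export
condition_encoder <- function(labels) {
  stopifnot(is.data.frame(labels),
            all(c("speed_mps", "incline_deg") %in% names(labels)))
  map <- labels |>
    distinct(.data$incline_deg, .data$speed_mps) |>
    arrange(.data$incline_deg, .data$speed_mps)
  map$code <- seq_len(nrow(map)) - 1L
  class(map) <- c("condition_encoder", class(map))
  map
}

#' Encode condition labels as integer class codes
#'
#' @param labels A data frame with `speed_mps` and `incline_deg` columns.
#' @param encoder A [condition_encoder()].
#' @return Integer vector of class codes.
#' @export
encode_conditions <- function(labels, encoder) {
  stopifnot(inherits(encoder, "condition_encoder"))
  key <- paste(labels$incline_deg, labels$speed_mps)
  idx <- match(key, paste(encoder$incline_deg, encoder$speed_mps))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("label (speed %s m/s, incline %s deg) is not in the encoder",
                  format(labels$speed_mps[bad]), format(labels$incline_deg[bad])))
  }
  encoder$code[idx]
}

#' Decode integer class codes back to condition labels
#'
#' @param codes Integer class codes.
#' @param encoder A [condition_encoder()].
#' @return A tibble with `incline_deg` and `speed_mps` per code.
#' @export
decode_conditions <- function(codes, encoder) {
  stopifnot(inherits(encoder, "condition_encoder"))
  idx <- match(codes, encoder$code)
  if (anyNA(idx)) {
    abort(sprintf("code %s is not in the encoder", format(codes[which(is.na(idx))[1]])))
  }
  tibble(incline_deg = encoder$incline_deg[idx],
         speed_mps = encoder$speed_mps[idx])
}
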