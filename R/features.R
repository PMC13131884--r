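# Step-level preprocessing (zero padding, [0,1] scaling) and a large
# parameterised time-series feature bank (statistical, temporal and
# frequency-domain summaries per channel).

# ---------------------------------------------------------------------------
# Padding and scaling
# ---------------------------------------------------------------------------

#' Zero-pad parsed steps to a common length
#'
#' Appends trailing zeros to every channel of every step so all steps match
#' the longest one; original samples are untouched.
#'
#' @param steps A `grf_steps` tibble from [segment_steps()].
#' @return A list of class `padded_steps` with `step_id`, `n_orig` (original
#'   lengths) and numeric matrices `heel`, `midfoot`, `forefoot` of
#'   dimension steps x max length.
#' @export
pad_steps <- function(steps) {
  stopifnot(is.data.frame(steps), nrow(steps) >= 1)
  lens <- lengths(steps$heel)
  L <- max(lens)
  pad_one <- function(x) c(x, numeric(L - length(x)))
  to_mat <- function(col) do.call(rbind, lapply(col, pad_one))
  out <- list(step_id = steps$step_id, n_orig = lens,
              heel = to_mat(steps$heel), midfoot = to_mat(steps$midfoot),
              forefoot = to_mat(steps$forefoot))
  class(out) <- "padded_steps"
  out
}

#' Fit a per-channel min-max scaler on training steps
#'
#' Computes per-channel global minimum and maximum over the training rows
#' only, so scaling of held-out steps cannot leak test information. Values
#' scale to `[0, 1]` on the training data; test values outside the training
#' range map outside `[0, 1]` (no clipping). A constant channel maps to 0.
#'
#' @param padded A [pad_steps()] result.
#' @param train Logical vector (or integer indices) selecting training rows.
#' @return A scaler object of class `minmax_scaler`.
#' @export
fit_minmax <- function(padded, train) {
  stopifnot(inherits(padded, "padded_steps"))
  rng <- lapply(padded[c("heel", "midfoot", "forefoot")], function(m) {
    tr <- m[train, , drop = FALSE]
    c(min = min(tr), max = max(tr))
  })
  structure(list(range = rng), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A [fit_minmax()] scaler.
#' @param padded A [pad_steps()] result.
#' @return The padded steps with each channel rescaled by the training
#'   min/max.
#' @export
apply_minmax <- function(scaler, padded) {
  stopifnot(inherits(scaler, "minmax_scaler"), inherits(padded, "padded_steps"))
  out <- padded
  for (ch in c("heel", "midfoot", "forefoot")) {
    r <- scaler$range[[ch]]
    span <- r["max"] - r["min"]
    out[[ch]] <- if (span <= 0) {
      matrix(0, nrow(padded[[ch]]), ncol(padded[[ch]]))
    } else {
      (padded[[ch]] - r["min"]) / span
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Feature bank
# ---------------------------------------------------------------------------

#' Feature-bank configuration
#'
#' Controls the parameterised families of per-channel summary features.
#' Defaults give roughly 800 named candidate features per channel
#' (statistical moments, quantiles, run/crossing counts, autocorrelation
#' and partial autocorrelation, nonlinearity statistics, change-quantile
#' corridors, chunked aggregates, an FFT coefficient grid and spectral
#' moments). Candidate names are data-independent: features that cannot be
#' computed for a given series length (e.g. FFT bins beyond the Nyquist
#' index) are emitted as `NA` and removed later by
#' [drop_invalid_features()].
#'
#' @param n_fft Number of FFT coefficient bins emitted per attribute
#'   (default 150).
#' @param acf_lags Autocorrelation / partial-autocorrelation lags
#'   (default 10).
#' @param n_chunks Number of chunks for chunked aggregates and energy
#'   ratios (default 10).
#' @return A list of class `feature_bank`.
#' @export
feature_bank <- function(n_fft = 150, acf_lags = 10, n_chunks = 10) {
  structure(list(n_fft = n_fft, acf_lags = acf_lags, n_chunks = n_chunks,
                 quantiles = seq(0.1, 0.9, by = 0.1),
                 peak_supports = c(1L, 3L, 5L, 10L),
                 r_sigmas = c(0.5, 1, 1.5, 2, 2.5, 3),
                 cq_pairs = {
                   ql <- c(0, 0.2, 0.4, 0.6)
                   do.call(rbind, lapply(ql, function(l) {
                     qh <- seq(l + 0.2, 1, by = 0.2)
                     cbind(ql = l, qh = round(qh, 1))
                   }))
                 }),
            class = "feature_bank")
}

# quantile (type 7) from a pre-sorted vector
.q_sorted <- function(xs, p) {
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[pmin(lo + 1, n)] - xs[lo])
}

# feature names for one channel, data-independent
.series_feature_names <- function(bank) {
  c("mean", "variance", "sd", "skewness", "kurtosis", "minimum", "maximum",
    "median", "sum_values", "abs_energy", "mean_abs_change", "mean_change",
    "root_mean_square", "abs_maximum", "variation_coefficient",
    "mean_second_derivative",
    sprintf("quantile_q%.1f", bank$quantiles),
    "mean_crossings", "median_crossings", "longest_strike_above_mean",
    "longest_strike_below_mean", "count_above_mean", "count_below_mean",
    "first_location_of_maximum", "last_location_of_maximum",
    "first_location_of_minimum", "last_location_of_minimum",
    sprintf("autocorrelation_lag%d", seq_len(bank$acf_lags)),
    sprintf("partial_autocorrelation_lag%d", seq_len(bank$acf_lags)),
    sprintf("c3_lag%d", 1:3),
    sprintf("time_reversal_asymmetry_lag%d", 1:3),
    "cid_ce_raw", "cid_ce_normalized",
    sprintf("number_peaks_support%d", bank$peak_supports),
    sprintf("ratio_beyond_sigma_r%.1f", bank$r_sigmas),
    sprintf("binned_entropy_bins%d", c(5L, 10L)),
    sprintf("index_mass_quantile_q%.1f", bank$quantiles),
    sprintf("energy_ratio_chunk%d", seq_len(bank$n_chunks)),
    sprintf("chunk%d_%s", rep(seq_len(bank$n_chunks), each = 4),
            rep(c("mean", "sd", "min", "max"), bank$n_chunks)),
    sprintf("change_quantiles_l%.1f_h%.1f_%s_%s",
            rep(bank$cq_pairs[, "ql"], each = 4),
            rep(bank$cq_pairs[, "qh"], each = 4),
            rep(c("abs", "abs", "raw", "raw"), nrow(bank$cq_pairs)),
            rep(c("mean", "sd", "mean", "sd"), nrow(bank$cq_pairs))),
    sprintf("linear_trend_%s", c("slope", "intercept", "r2", "pvalue", "stderr")),
    "spectral_centroid", "spectral_variance", "spectral_skewness",
    "spectral_kurtosis", "dominant_frequency", "dominant_power",
    sprintf("fft_%s_bin%d", rep(c("abs", "real", "imag", "angle"),
                                each = bank$n_fft),
            rep(seq_len(bank$n_fft) - 1L, 4)))
}

#' Candidate feature names of a bank
#'
#' Enumerates the full, data-independent candidate-name set of the bank for
#' the given channels.
#'
#' @param bank A [feature_bank()].
#' @param channels Channel name prefixes.
#' @return Character vector of `channel__feature` names.
#' @export
bank_feature_names <- function(bank = feature_bank(),
                               channels = c("heel", "midfoot", "forefoot")) {
  base <- .series_feature_names(bank)
  as.vector(t(outer(channels, base, paste, sep = "__")))
}

# all features for one numeric series; returns named numeric vector with the
# exact name set of .series_feature_names(bank)
.series_features <- function(x, bank) {
  n <- length(x)
  if (!all(is.finite(x))) rlang::abort("feature extraction requires finite input")
  xs <- sort(x)
  mu <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  dx <- diff(x)
  out <- c(
    mean = mu, variance = v, sd = s,
    skewness = suppressWarnings(e1071::skewness(x)),
    kurtosis = suppressWarnings(e1071::kurtosis(x)),
    minimum = xs[1], maximum = xs[n], median = .q_sorted(xs, 0.5),
    sum_values = sum(x), abs_energy = sum(x^2),
    mean_abs_change = mean(abs(dx)), mean_change = mean(dx),
    root_mean_square = sqrt(mean(x^2)), abs_maximum = max(abs(x)),
    variation_coefficient = if (mu == 0) NA_real_ else s / mu,
    mean_second_derivative =
      if (n < 3) NA_real_ else mean((x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / 2)
  )
  q <- .q_sorted(xs, bank$quantiles)
  names(q) <- sprintf("quantile_q%.1f", bank$quantiles)
  out <- c(out, q)

  above <- x > mu
  r <- rle(above)
  med <- .q_sorted(xs, 0.5)
  out <- c(out,
           mean_crossings = sum(above[-1] != above[-n]),
           median_crossings = {am <- x > med; sum(am[-1] != am[-n])},
           longest_strike_above_mean = max(c(0, r$lengths[r$values])),
           longest_strike_below_mean = max(c(0, r$lengths[!r$values])),
           count_above_mean = sum(above), count_below_mean = sum(!above),
           first_location_of_maximum = (which.max(x) - 1) / n,
           last_location_of_maximum = (n - which.max(rev(x)) ) / n,
           first_location_of_minimum = (which.min(x) - 1) / n,
           last_location_of_minimum = (n - which.min(rev(x))) / n)

  lags <- seq_len(bank$acf_lags)
  if (v > 0 && n > bank$acf_lags + 1) {
    ac <- as.vector(stats::acf(x, lag.max = bank$acf_lags, plot = FALSE,
                               demean = TRUE)$acf)[-1]
    pac <- tryCatch(as.vector(stats::pacf(x, lag.max = bank$acf_lags,
                                          plot = FALSE)$acf),
                    error = function(e) rep(NA_real_, bank$acf_lags))
  } else {
    ac <- pac <- rep(NA_real_, bank$acf_lags)
  }
  names(ac) <- sprintf("autocorrelation_lag%d", lags)
  names(pac) <- sprintf("partial_autocorrelation_lag%d", lags)
  out <- c(out, ac, pac)

  c3 <- vapply(1:3, function(l) {
    if (n <= 2 * l) return(NA_real_)
    idx <- seq_len(n - 2 * l)
    mean(x[idx] * x[idx + l] * x[idx + 2 * l])
  }, numeric(1))
  names(c3) <- sprintf("c3_lag%d", 1:3)
  tra <- vapply(1:3, function(l) {
    if (n <= 2 * l) return(NA_real_)
    idx <- seq_len(n - 2 * l)
    mean(x[idx + 2 * l]^2 * x[idx + l] - x[idx + l] * x[idx]^2)
  }, numeric(1))
  names(tra) <- sprintf("time_reversal_asymmetry_lag%d", 1:3)
  cid <- sqrt(sum(dx^2))
  out <- c(out, c3, tra,
           cid_ce_raw = cid,
           cid_ce_normalized = if (s == 0) NA_real_ else {
             z <- (x - mu) / s
             sqrt(sum(diff(z)^2))
           })

  np <- vapply(bank$peak_supports, function(supp) {
    if (n < 2 * supp + 1) return(NA_real_)
    cnt <- 0L
    for (i in (supp + 1):(n - supp)) {
      w <- x[(i - supp):(i + supp)]
      if (x[i] == max(w) && sum(w == x[i]) == 1L) cnt <- cnt + 1L
    }
    as.numeric(cnt)
  }, numeric(1))
  names(np) <- sprintf("number_peaks_support%d", bank$peak_supports)
  out <- c(out, np)

  dev <- abs(x - mu)
  rb <- vapply(bank$r_sigmas, function(rr) mean(dev > rr * s), numeric(1))
  names(rb) <- sprintf("ratio_beyond_sigma_r%.1f", bank$r_sigmas)
  out <- c(out, rb)

  be <- vapply(c(5L, 10L), function(nb) {
    rngx <- xs[n] - xs[1]
    if (rngx == 0) return(0)
    cuts <- xs[1] + rngx * (0:nb) / nb
    h <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE), nb), nb)
    p <- h[h > 0] / n
    -sum(p * log(p))
  }, numeric(1))
  names(be) <- sprintf("binned_entropy_bins%d", c(5L, 10L))
  out <- c(out, be)

  absx <- abs(x)
  tot <- sum(absx)
  cs <- cumsum(absx)
  imq <- vapply(bank$quantiles, function(p) {
    if (tot == 0) return(NA_real_)
    (which(cs >= p * tot)[1]) / n
  }, numeric(1))
  names(imq) <- sprintf("index_mass_quantile_q%.1f", bank$quantiles)
  out <- c(out, imq)

  nc <- bank$n_chunks
  bounds <- floor(n * (0:nc) / nc)
  en_tot <- sum(x^2)
  chunk_stats <- numeric(0)
  erb <- numeric(nc)
  for (ci in seq_len(nc)) {
    seg <- x[(bounds[ci] + 1):bounds[ci + 1]]
    erb[ci] <- if (en_tot == 0) NA_real_ else sum(seg^2) / en_tot
    chunk_stats <- c(chunk_stats, mean(seg),
                     if (length(seg) > 1) stats::sd(seg) else NA_real_,
                     min(seg), max(seg))
  }
  names(erb) <- sprintf("energy_ratio_chunk%d", seq_len(nc))
  names(chunk_stats) <- sprintf("chunk%d_%s", rep(seq_len(nc), each = 4),
                                rep(c("mean", "sd", "min", "max"), nc))
  out <- c(out, erb, chunk_stats)

  cq <- numeric(0)
  for (pi in seq_len(nrow(bank$cq_pairs))) {
    ql <- bank$cq_pairs[pi, "ql"]; qh <- bank$cq_pairs[pi, "qh"]
    lo <- .q_sorted(xs, ql); hi <- .q_sorted(xs, qh)
    inside <- x >= lo & x <= hi
    ok <- inside[-n] & inside[-1]
    d <- dx[ok]
    vals <- if (length(d) == 0) c(0, 0, 0, 0) else
      c(mean(abs(d)), if (length(d) > 1) stats::sd(abs(d)) else 0,
        mean(d), if (length(d) > 1) stats::sd(d) else 0)
    names(vals) <- sprintf("change_quantiles_l%.1f_h%.1f_%s_%s", ql, qh,
                           c("abs", "abs", "raw", "raw"),
                           c("mean", "sd", "mean", "sd"))
    cq <- c(cq, vals)
  }
  out <- c(out, cq)

  tt <- seq_len(n) - 1
  vt <- stats::var(tt)
  slope <- if (vt == 0) NA_real_ else stats::cov(tt, x) / vt
  intercept <- mu - slope * mean(tt)
  res <- x - (intercept + slope * tt)
  sse <- sum(res^2)
  sst <- v * (n - 1)
  r2 <- if (sst == 0) NA_real_ else 1 - sse / sst
  se_slope <- if (n > 2) sqrt(sse / (n - 2) / (vt * (n - 1))) else NA_real_
  tstat <- if (!is.na(se_slope) && se_slope > 0) slope / se_slope else NA_real_
  pval <- if (is.na(tstat)) NA_real_ else 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- c(out, linear_trend_slope = slope, linear_trend_intercept = intercept,
           linear_trend_r2 = r2, linear_trend_pvalue = pval,
           linear_trend_stderr = se_slope)

  z <- stats::fft(x)
  nb_avail <- floor(n / 2) + 1L
  mag <- Mod(z[seq_len(nb_avail)])
  fr <- (seq_len(nb_avail) - 1) / n      # cycles per sample
  pw <- mag[-1]^2                         # spectrum without the DC bin
  fw <- fr[-1]
  if (sum(pw) > 0) {
    pm <- pw / sum(pw)
    sc <- sum(fw * pm)
    sv <- sum((fw - sc)^2 * pm)
    ssk <- if (sv > 0) sum((fw - sc)^3 * pm) / sv^1.5 else NA_real_
    sku <- if (sv > 0) sum((fw - sc)^4 * pm) / sv^2 else NA_real_
    dfreq <- fw[which.max(pw)]
    dpow <- max(pw)
  } else {
    sc <- sv <- ssk <- sku <- dfreq <- dpow <- NA_real_
  }
  out <- c(out, spectral_centroid = sc, spectral_variance = sv,
           spectral_skewness = ssk, spectral_kurtosis = sku,
           dominant_frequency = dfreq, dominant_power = dpow)

  nf <- bank$n_fft
  take <- seq_len(min(nf, nb_avail))
  pad_na <- function(vals) c(vals, rep(NA_real_, nf - length(vals)))
  fftf <- c(pad_na(mag[take]), pad_na(Re(z[take])), pad_na(Im(z[take])),
            pad_na(Arg(z[take])))
  names(fftf) <- sprintf("fft_%s_bin%d", rep(c("abs", "real", "imag", "angle"),
                                             each = nf),
                         rep(seq_len(nf) - 1L, 4))
  c(out, fftf)
}

#' Extract the feature bank from padded (and scaled) steps
#'
#' Applies the per-series feature bank to every channel of every step,
#' producing one named feature vector per step. Extraction is a pure
#' function of its input: the same padded steps give bitwise-identical
#' features, and names are stable across runs.
#'
#' @param padded A [pad_steps()] result (typically after [apply_minmax()]).
#' @param bank A [feature_bank()].
#' @param channels Channels to featurize.
#' @param include_total Also featurize the summed total-foot channel
#'   (default `FALSE`).
#' @return A tibble with `step_id` and one column per candidate feature
#'   (`channel__feature`); entries may be `NA`/`NaN` where a feature is
#'   undefined, to be pruned by [drop_invalid_features()].
#' @export
extract_features <- function(padded, bank = feature_bank(),
                             channels = c("heel", "midfoot", "forefoot"),
                             include_total = FALSE) {
  stopifnot(inherits(padded, "padded_steps"))
  mats <- padded[channels]
  if (include_total) {
    mats$total <- padded$heel + padded$midfoot + padded$forefoot
    channels <- c(channels, "total")
  }
  n_steps <- nrow(mats[[1]])
  base_names <- .series_feature_names(bank)
  blocks <- lapply(channels, function(ch) {
    m <- mats[[ch]]
    block <- t(vapply(seq_len(n_steps),
                      function(i) unname(.series_features(m[i, ], bank)),
                      numeric(length(base_names))))
    colnames(block) <- paste(ch, base_names, sep = "__")
    block
  })
  out <- tibble::as_tibble(as.data.frame(do.call(cbind, blocks),
                                         check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(step_id = padded$step_id), out)
  out
}

#' Remove invalid feature columns
#'
#' Drops every feature column containing a non-finite value and every
#' zero-variance (constant) column, judged on the given rows (by default
#' all rows; pass the training mask to keep the decision independent of
#' held-out data). Row count is unchanged.
#'
#' @param features A feature tibble from [extract_features()] (may carry
#'   `step_id` and other non-feature columns, preserved as-is).
#' @param rows Logical vector or indices of rows used to judge validity
#'   (default all rows).
#' @param keep_cols Non-feature columns to pass through untouched.
#' @return The feature tibble with invalid feature columns removed.
#' @export
drop_invalid_features <- function(features, rows = NULL,
                                  keep_cols = c("step_id", "label", "partition")) {
  keep_cols <- intersect(keep_cols, names(features))
  feat_cols <- setdiff(names(features), keep_cols)
  sub <- if (is.null(rows)) features[feat_cols] else features[rows, feat_cols]
  ok <- vapply(sub, function(x) {
    all(is.finite(x)) && max(x) > min(x)
  }, logical(1))
  if (!any(ok)) rlang::abort("all feature columns are invalid; nothing to select")
  features[c(keep_cols, feat_cols[ok])]
}
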