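## live-imaging periodicity analysis: QC -> Gaussian detrend -> Lomb-Scargle

#' Quality-control filter for fluorescence traces
#'
#' Excludes traces shorter than `min_duration_h` (strict `<`; a trace of
#' exactly 25 h is kept) and traces whose intensity variance is an outlier
#' within the cohort: variance greater than `mean(variances) + 5 *
#' SD(variances)` over all input traces. Both exclusion reasons are
#' recorded; a trace failing both gets both, separated by `";"`.
#'
#' @param traces data.frame with columns `time_h`, `intensity`, `trace_id`
#'   (extra columns such as `condition`/`channel` are preserved).
#' @param min_duration_h minimum trace duration in hours.
#' @param var_sd_mult variance-outlier multiplier (SDs above the cohort mean).
#' @return List with `kept` (data.frame of surviving rows) and `excluded`
#'   (data.frame with `trace_id`, `reason`).
#' @export
qc_filter_traces <- function(traces, min_duration_h = 25, var_sd_mult = 5) {
  if (is.null(traces) || nrow(traces) == 0) {
    return(list(kept = traces,
                excluded = data.frame(trace_id = character(0),
                                      reason = character(0))))
  }
  check_that(all(c("time_h", "intensity", "trace_id") %in% names(traces)),
             "traces must have columns time_h, intensity, trace_id")
  ids <- unique(traces$trace_id)
  dur <- vapply(ids, function(id) {
    t <- traces$time_h[traces$trace_id == id]
    max(t) - min(t)
  }, numeric(1))
  v <- vapply(ids, function(id) {
    stats::var(traces$intensity[traces$trace_id == id])
  }, numeric(1))
  var_limit <- if (length(ids) >= 2 && is.finite(stats::sd(v)))
    mean(v) + var_sd_mult * stats::sd(v) else Inf
  reasons <- vapply(seq_along(ids), function(i) {
    r <- character(0)
    if (dur[i] < min_duration_h) r <- c(r, "duration")
    if (v[i] > var_limit) r <- c(r, "variance")
    paste(r, collapse = ";")
  }, character(1))
  bad <- nzchar(reasons)
  list(kept = traces[traces$trace_id %in% ids[!bad], , drop = FALSE],
       excluded = data.frame(trace_id = ids[bad], reason = reasons[bad],
                             stringsAsFactors = FALSE))
}

#' Gaussian-weighted moving-average detrending
#'
#' Estimates the slow trend of a trace by a Gaussian-weighted average with a
#' moving window: the trend at time `t_k` is
#' `sum_j w_kj * y_j / sum_j w_kj` with
#' `w_kj = exp(-(t_j - t_k)^2 / (2 * sigma^2))`, `sigma = window_h / 5`,
#' and weights truncated to `|t_j - t_k| <= window_h / 2`. Subtracting the
#' trend leaves the fluctuations faster than the window (by default, shorter
#' than 24 h periodicity). Trend plus detrended reconstructs the input
#' exactly.
#'
#' @param time_h strictly increasing sample times (hours).
#' @param intensity intensity values (a.u.), same length.
#' @param window_h moving-window width in hours (> 0; default 24).
#' @return List of class `detrend_result` with `time_h`, `trend`,
#'   `detrended` (`intensity - trend`).
#' @export
gaussian_detrend <- function(time_h, intensity, window_h = 24) {
  check_that(is_number(window_h) && window_h > 0, "window_h must be > 0")
  check_that(length(time_h) == length(intensity) && length(time_h) >= 3,
             "need >= 3 samples with matching times and intensities")
  check_that(all(diff(time_h) > 0), "time_h must be strictly increasing")
  sigma <- window_h / 5
  half <- window_h / 2
  n <- length(time_h)
  trend <- vapply(seq_len(n), function(k) {
    dt <- time_h - time_h[k]
    inside <- abs(dt) <= half
    w <- exp(-dt[inside]^2 / (2 * sigma^2))
    sum(w * intensity[inside]) / sum(w)
  }, numeric(1))
  structure(list(time_h = time_h, trend = trend,
                 detrended = intensity - trend),
            class = "detrend_result")
}

#' Lomb-Scargle power spectral density of an unevenly sampled series
#'
#' Classical variance-normalized Lomb-Scargle periodogram, the spectral
#' estimate of choice for unevenly sampled data: for angular frequency
#' `w = 2*pi*f` and the time shift `tau` defined by
#' `tan(2*w*tau) = sum(sin(2*w*t)) / sum(cos(2*w*t))`,
#' `P(f) = 1/(2*s^2) * ((sum(yc * cos(w*(t - tau)))^2 / sum(cos^2)) +
#'                      (sum(yc * sin(w*(t - tau)))^2 / sum(sin^2)))`
#' with `yc` the mean-centered series and `s^2` its sample variance. The
#' frequency grid spans the requested period band at the natural resolution
#' `1 / duration` refined by the oversampling factor.
#'
#' @param detrended numeric series (normally the `detrended` component of
#'   [gaussian_detrend()]).
#' @param time_h sample times in hours, strictly increasing, length >= 3.
#' @param band period search band in hours, `c(min_period, max_period)`;
#'   default 2-24 h (ultradian focus; the detrend window removes slower
#'   components).
#' @param oversample oversampling factor applied to the natural frequency
#'   resolution `1 / duration`.
#' @return Object of class `periodogram`: list with `frequency` (cycles per
#'   hour, increasing), `power` (PSD, >= 0), `dominant_power` (max power),
#'   `dominant_period_h` (1 / argmax frequency), `normalization`
#'   (`"variance"`).
#' @examples
#' t <- seq(0, 68, by = 1 / 3)
#' pg <- lomb_scargle_psd(sin(2 * pi * t / 17), t)
#' pg$dominant_period_h
#' @export
lomb_scargle_psd <- function(detrended, time_h, band = c(2, 24),
                             oversample = 4) {
  check_that(length(detrended) == length(time_h) && length(time_h) >= 3,
             "need >= 3 points with matching times")
  check_that(all(diff(time_h) > 0), "time_h must be strictly increasing")
  check_that(is.numeric(band) && length(band) == 2 && all(band > 0) &&
               band[1] < band[2],
             "band must be c(min_period_h, max_period_h) with 0 < min < max")
  check_that(is_number(oversample) && oversample >= 1,
             "oversample must be >= 1")
  duration <- max(time_h) - min(time_h)
  check_that(duration >= band[1],
             sprintf("trace duration %.2f h is shorter than the minimum period %.2f h",
                     duration, band[1]))
  ## shortest resolvable period: twice the median sampling interval (Nyquist)
  nyq_period <- 2 * stats::median(diff(time_h))
  check_that(band[1] >= nyq_period,
             sprintf(paste("band minimum period %.2f h is below the Nyquist",
                           "limit %.2f h for this sampling"),
                     band[1], nyq_period))
  f_min <- 1 / band[2]
  f_max <- 1 / band[1]
  df <- 1 / (oversample * duration)
  freq <- seq(f_min, f_max, by = df)
  yc <- detrended - mean(detrended)
  s2 <- stats::var(detrended)
  if (s2 == 0) {
    power <- rep(0, length(freq))
  } else {
    power <- vapply(freq, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * time_h)), sum(cos(2 * w * time_h))) / (2 * w)
      ct <- cos(w * (time_h - tau))
      st <- sin(w * (time_h - tau))
      (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * s2)
    }, numeric(1))
  }
  imax <- which.max(power)
  structure(list(frequency = freq, power = power,
                 dominant_power = power[imax],
                 dominant_period_h = 1 / freq[imax],
                 normalization = "variance"),
            class = "periodogram")
}

#' @export
#' @method print periodogram
print.periodogram <- function(x, ...) {
  cat(sprintf("periodogram: %d frequencies in [%.4f, %.4f] /h; dominant period %.2f h (power %.2f)\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$dominant_period_h, x$dominant_power))
  invisible(x)
}

#' Average periodograms on a common frequency grid
#'
#' Linearly interpolates every periodogram onto the intersection of the
#' input frequency bands, sampled at the finest input resolution, and takes
#' the pointwise mean. Used to build the mean PSD of a condition's traces.
#'
#' @param periodograms non-empty list of [lomb_scargle_psd()] results.
#' @return List with `frequency`, `mean_psd`, `n` (number of periodograms).
#' @export
common_grid_average <- function(periodograms) {
  check_that(is.list(periodograms) && length(periodograms) >= 1 &&
               all(vapply(periodograms, inherits, logical(1), "periodogram")),
             "need a non-empty list of periodogram objects")
  f_lo <- max(vapply(periodograms, function(p) min(p$frequency), numeric(1)))
  f_hi <- min(vapply(periodograms, function(p) max(p$frequency), numeric(1)))
  check_that(f_lo <= f_hi, "periodogram frequency bands are disjoint")
  res <- min(vapply(periodograms,
                    function(p) stats::median(diff(p$frequency)), numeric(1)))
  grid <- seq(f_lo, f_hi, by = res)
  psd <- vapply(periodograms, function(p) {
    stats::approx(p$frequency, p$power, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  psd <- matrix(psd, nrow = length(grid))
  list(frequency = grid, mean_psd = rowMeans(psd), n = length(periodograms))
}

#' Summarize the periodicity of one condition's traces
#'
#' Runs the full imaging pipeline for the traces of one condition: QC
#' filtering, Gaussian-weighted detrending, Lomb-Scargle PSD per trace,
#' dominant power/period extraction, and the mean PSD on a common frequency
#' grid. Per-trace mean raw intensity is also reported (expression-level
#' comparisons use the raw, not detrended, signal).
#'
#' @param traces data.frame with columns `time_h`, `intensity`, `trace_id`
#'   and optionally `condition`/`channel`.
#' @param condition condition label to select (ignored when the column is
#'   absent).
#' @param channel optional channel label to select.
#' @param window_h detrend window (hours).
#' @param min_duration_h QC duration threshold (hours).
#' @param band period band for the periodogram (hours).
#' @param oversample frequency oversampling factor.
#' @return Object of class `condition_summary`: list with `condition`,
#'   `per_trace` (data.frame: `trace_id`, `duration_h`, `variance`,
#'   `dominant_power`, `dominant_period_h`, `mean_intensity`), `mean_psd`
#'   (from [common_grid_average()], or NULL), `n`, `n_excluded`, `excluded`.
#' @export
summarize_condition <- function(traces, condition = NULL, channel = NULL,
                                window_h = 24, min_duration_h = 25,
                                band = c(2, 24), oversample = 4) {
  if (!is.null(condition) && "condition" %in% names(traces))
    traces <- traces[traces$condition == condition, , drop = FALSE]
  if (!is.null(channel) && "channel" %in% names(traces))
    traces <- traces[traces$channel == channel, , drop = FALSE]
  qc <- qc_filter_traces(traces, min_duration_h = min_duration_h)
  kept_ids <- unique(qc$kept$trace_id)
  if (length(kept_ids) == 0) {
    warning("no trace passed QC; returning an empty summary")
    return(structure(list(condition = condition,
                          per_trace = data.frame(),
                          mean_psd = NULL, n = 0L,
                          n_excluded = nrow(qc$excluded),
                          excluded = qc$excluded),
                     class = "condition_summary"))
  }
  pgs <- list()
  rows <- list()
  for (id in kept_ids) {
    tr <- qc$kept[qc$kept$trace_id == id, , drop = FALSE]
    tr <- tr[order(tr$time_h), , drop = FALSE]
    det <- gaussian_detrend(tr$time_h, tr$intensity, window_h = window_h)
    pg <- lomb_scargle_psd(det$detrended, tr$time_h, band = band,
                           oversample = oversample)
    pgs[[id]] <- pg
    rows[[id]] <- data.frame(trace_id = id,
                             duration_h = max(tr$time_h) - min(tr$time_h),
                             variance = stats::var(tr$intensity),
                             dominant_power = pg$dominant_power,
                             dominant_period_h = pg$dominant_period_h,
                             mean_intensity = mean(tr$intensity),
                             stringsAsFactors = FALSE)
  }
  structure(list(condition = condition,
                 per_trace = do.call(rbind, rows),
                 mean_psd = common_grid_average(pgs),
                 n = length(kept_ids),
                 n_excluded = nrow(qc$excluded),
                 excluded = qc$excluded),
            class = "condition_summary")
}

#' @export
#' @method print condition_summary
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition_summary '%s': %d traces kept, %d excluded\n",
              if (is.null(x$condition)) "(all)" else x$condition,
              x$n, x$n_excluded))
  if (x$n > 0)
    cat(sprintf("  mean dominant period %.2f h, mean dominant power %.2f\n",
                mean(x$per_trace$dominant_period_h),
                mean(x$per_trace$dominant_power)))
  invisible(x)
}
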