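mk_trace <- function(id, duration, dt = 1 / 3, f = function(t) rep(0, length(t)),
                     condition = "cond", channel = "signal") {
  t <- seq(0, duration, by = dt)
  data.frame(time_h = t, intensity = f(t), trace_id = id,
             condition = condition, channel = channel,
             stringsAsFactors = FALSE)
}

test_that("QC excludes short traces with a strict 25 h boundary", {
  traces <- rbind(mk_trace("short", 24, f = function(t) sin(t)),
                  mk_trace("exact", 25, f = function(t) sin(t)),
                  mk_trace("long", 40, f = function(t) sin(t)))
  qc <- qc_filter_traces(traces)
  expect_setequal(unique(qc$kept$trace_id), c("exact", "long"))
  expect_identical(qc$excluded$trace_id, "short")
  expect_identical(qc$excluded$reason, "duration")
})

test_that("QC variance rule is a cohort-level outlier test", {
  ## equal-variance cohort: SD of variances is 0 but no trace exceeds
  ## mean + 5*0, so none is excluded for variance
  same <- do.call(rbind, lapply(1:4, function(i) {
    mk_trace(paste0("t", i), 40, f = function(t) sin(2 * pi * t / 10))
  }))
  qc <- qc_filter_traces(same)
  expect_equal(nrow(qc$excluded), 0)

  ## one wildly variable trace among many calm ones is excluded (the rule
  ## needs a large cohort: the outlier itself inflates the variance SD)
  cohort <- do.call(rbind, c(
    lapply(1:40, function(i) {
      set.seed(i)
      mk_trace(paste0("calm", i), 40,
               f = function(t) sin(2 * pi * t / 10) + 0.05 * rnorm(length(t)))
    }),
    list(mk_trace("wild", 40, f = function(t) 100 * sin(2 * pi * t / 5)))))
  qc <- qc_filter_traces(cohort)
  expect_true("wild" %in% qc$excluded$trace_id)
  expect_match(qc$excluded$reason[qc$excluded$trace_id == "wild"], "variance")

  empty <- qc_filter_traces(data.frame(time_h = numeric(0),
                                       intensity = numeric(0),
                                       trace_id = character(0)))
  expect_equal(nrow(empty$excluded), 0)
})

test_that("detrending reconstructs the input and zeroes a constant trace", {
  t <- seq(0, 40, by = 0.5)
  y <- rep(3.7, length(t))
  d <- gaussian_detrend(t, y)
  expect_equal(d$trend, y, tolerance = 1e-12)
  expect_true(all(abs(d$detrended) < 1e-12))

  set.seed(12)
  y2 <- 5 + sin(t) + rnorm(length(t))
  d2 <- gaussian_detrend(t, y2)
  expect_equal(d2$trend + d2$detrended, y2, tolerance = 1e-12)
  expect_error(gaussian_detrend(t, y2, window_h = 0), "window")
})

test_that("a linear ramp passes through the Gaussian filter untouched inside", {
  t <- seq(0, 70, by = 1 / 3)
  ramp <- 2 + 0.3 * t
  d <- gaussian_detrend(t, ramp, window_h = 24)
  interior <- t >= 12 & t <= 70 - 12
  expect_lt(max(abs(d$trend[interior] - ramp[interior]) / ramp[interior]),
            1e-9)
})

test_that("detrending separates a 17 h sinusoid from a linear trend", {
  t <- seq(0, 70, by = 1 / 3)
  sine <- sin(2 * pi * t / 17)
  y <- 10 + 0.2 * t + sine
  d <- gaussian_detrend(t, y, window_h = 24)
  interior <- t >= 12 & t <= 70 - 12
  expect_gt(cor(d$detrended[interior], sine[interior]), 0.95)
})

test_that("the 24 h window removes slow components and keeps fast ones", {
  t <- seq(0, 200, by = 1 / 3)
  interior <- t >= 12 & t <= 200 - 12
  slow <- sin(2 * pi * t / 48)
  d_slow <- gaussian_detrend(t, slow)
  expect_lt(var(d_slow$detrended[interior]) / var(slow[interior]), 0.10)
  fast <- sin(2 * pi * t / 12)
  d_fast <- gaussian_detrend(t, fast)
  expect_gt(var(d_fast$detrended[interior]) / var(fast[interior]), 0.50)
})

test_that("Lomb-Scargle matches a least-squares sinusoid-fit oracle", {
  set.seed(91)
  t <- sort(runif(90, 0, 60))
  y <- sin(2 * pi * t / 13) + 0.4 * rnorm(90)
  pg <- lomb_scargle_psd(y, t)
  expect_equal(pg$power, lsq_periodogram(y, t, pg$frequency),
               tolerance = 1e-10)
  expect_equal(pg$dominant_power, max(pg$power))
  expect_equal(pg$dominant_period_h,
               1 / pg$frequency[which.max(pg$power)])
})

test_that("a pure 17 h tone is recovered within one frequency-grid bin", {
  t <- seq(0, 68, by = 1 / 3)
  pg <- lomb_scargle_psd(sin(2 * pi * t / 17), t)
  bin <- median(diff(pg$frequency))
  expect_lt(abs(1 / pg$dominant_period_h - 1 / 17), bin + 1e-12)

  ## white noise of the same sampling has a far weaker peak
  set.seed(14)
  pg_noise <- lomb_scargle_psd(rnorm(length(t)), t)
  expect_gt(pg$dominant_power / pg_noise$dominant_power, 10)
})

test_that("uneven sampling does not break period recovery", {
  set.seed(15)
  t_full <- seq(0, 68, by = 1 / 3)
  keep <- sort(sample(length(t_full), round(0.7 * length(t_full))))
  t <- t_full[keep]
  pg <- lomb_scargle_psd(sin(2 * pi * t / 17), t)
  bin <- median(diff(pg$frequency))
  expect_lt(abs(1 / pg$dominant_period_h - 1 / 17), bin + 1e-12)
})

test_that("normalized PSD is invariant to intensity scaling", {
  set.seed(16)
  t <- seq(0, 50, by = 0.5)
  y <- sin(2 * pi * t / 9) + 0.2 * rnorm(length(t))
  p1 <- lomb_scargle_psd(y, t)
  p2 <- lomb_scargle_psd(7.7 * y, t)
  expect_equal(p1$power, p2$power, tolerance = 1e-12)
})

test_that("infeasible bands are rejected with the limit named", {
  t <- seq(0, 68, by = 2)  # Nyquist period 4 h
  expect_error(lomb_scargle_psd(sin(t), t, band = c(2, 24)), "Nyquist")
  t2 <- seq(0, 10, by = 1 / 3)
  expect_error(lomb_scargle_psd(sin(t2), t2, band = c(12, 24)), "duration")
})

test_that("common_grid_average preserves identical inputs and common peaks", {
  t <- seq(0, 68, by = 1 / 3)
  pg <- lomb_scargle_psd(sin(2 * pi * t / 17), t)
  avg2 <- common_grid_average(list(pg, pg))
  expect_equal(avg2$mean_psd, pg$power, tolerance = 1e-12)
  avg1 <- common_grid_average(list(pg))
  expect_equal(avg1$mean_psd, pg$power, tolerance = 1e-12)

  set.seed(17)
  pgb <- lomb_scargle_psd(sin(2 * pi * t / 17) + 0.1 * rnorm(length(t)), t)
  avg <- common_grid_average(list(pg, pgb))
  expect_equal(avg$frequency[which.max(avg$mean_psd)],
               pg$frequency[which.max(pg$power)])
})

test_that("condition summaries recover the planted period and rank powers", {
  periodic <- do.call(rbind, lapply(1:6, function(i) {
    generate_trace(trace_spec(period_h = 17, duration_h = 80, noise_sd = 0.3,
                              trend_type = "linear", trend_slope = 0.03,
                              seed = 100 + i),
                   trace_id = sprintf("sig%d", i), condition = "periodic")
  }))
  flat <- do.call(rbind, lapply(1:6, function(i) {
    generate_trace(trace_spec(period_h = 17, duration_h = 80, amplitude = 0,
                              noise_sd = 0.3, seed = 200 + i),
                   trace_id = sprintf("ctrl%d", i), condition = "flat")
  }))
  s_per <- summarize_condition(rbind(periodic, flat), condition = "periodic")
  s_flat <- summarize_condition(rbind(periodic, flat), condition = "flat")
  expect_equal(s_per$n, 6)
  expect_lt(abs(mean(s_per$per_trace$dominant_period_h) - 17), 1)
  expect_gt(mean(s_per$per_trace$dominant_power),
            mean(s_flat$per_trace$dominant_power))

  expect_warning(empty <- summarize_condition(periodic, condition = "nope"),
                 "no trace")
  expect_equal(empty$n, 0L)
})
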