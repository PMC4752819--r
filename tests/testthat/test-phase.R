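test_that("moving-average detrending removes constants, ramps and drift", {
  tt <- seq(0, 1440, by = 10)
  # constant trace -> zero
  d1 <- detrend_trace(rep(3.5, length(tt)), window = 150, dt = 10)
  expect_true(all(abs(d1$signal) < 1e-12))
  # linear ramp -> zero in the interior (moving average of a line is the line)
  d2 <- detrend_trace(0.02 * tt, window = 150, dt = 10)
  interior <- tt >= 80 & tt <= 1360
  expect_true(all(abs(d2$signal[interior]) < 1e-9))
  # cosine on a slow drift: carrier recovered with < 5% amplitude error
  x <- cos(2 * pi * tt / 150) + 0.01 * tt
  d3 <- detrend_trace(data.frame(time_min = tt, intensity = x), window = 150)
  ref <- cos(2 * pi * tt / 150)
  expect_lt(max(abs(d3$signal[interior] - ref[interior])), 0.05)
  # guards
  expect_error(detrend_trace(x, window = 15, dt = 10), "two sample")
  expect_error(detrend_trace(x, window = 1e5, dt = 10), "longer than")
})

test_that("Hilbert phase, amplitude and period recover a pure cosine", {
  tt <- seq(0, 1430, by = 10)
  at <- analytic_phase(2 * cos(2 * pi * tt / 150), dt = 10)
  ok <- at$valid
  # interior phase slope within 1% of 2*pi/150 (finite records carry a
  # small edge-leakage ripple, so the slope is read off a linear fit)
  slope <- coef(lm(at$phase_rad[ok] ~ at$time_min[ok]))[2L]
  expect_lt(abs(slope - 2 * pi / 150), 0.01 * 2 * pi / 150)
  expect_true(all(abs(at$amplitude[ok] - 2) < 0.06))
  expect_true(all(abs(at$period_min[ok] - 150) < 5))
  expect_lt(abs(median(at$period_min[ok]) - 150), 1)
})

test_that("Hilbert period recovery spans the physiological band", {
  tt <- seq(0, 1430, by = 10)
  for (T0 in c(120, 135, 150, 165, 180)) {
    at <- analytic_phase(cos(2 * pi * tt / T0), dt = 10)
    est <- median(at$period_min[at$valid], na.rm = TRUE)
    expect_lt(abs(est - T0), 2)
  }
})

test_that("a chirp yields a monotone instantaneous period", {
  # linear frequency sweep between the gradient endpoints
  tt <- seq(0, 1430, by = 10)
  f0 <- 1 / 130; f1 <- 1 / 170
  finst <- f0 + (f1 - f0) * tt / max(tt)
  phase <- 2 * pi * cumsum(finst) * 10
  at <- analytic_phase(cos(phase), dt = 10)
  ok <- at$valid
  per <- at$period_min[ok]
  truth <- 1 / finst[ok]
  # the recovered period sweep tracks the constructed one: same rate of
  # increase (within 25%) and small typical error; edge-leakage ripple makes
  # pointwise extremes noisier
  fit <- coef(lm(per ~ truth))[2L]
  expect_gt(fit, 0.75)
  expect_lt(fit, 1.25)
  expect_lt(median(abs(per - truth), na.rm = TRUE), 3)
})

test_that("non-uniform sampling is rejected", {
  expect_error(
    analytic_phase(data.frame(time_min = c(0, 10, 25, 30),
                              signal = rnorm(4))),
    "uniformly sampled")
})

test_that("collective amplitude tracks synchrony, not single-cell activity", {
  tt <- seq(0, 1430, by = 10)
  # identical in-phase unit cosines -> collective amplitude ~ 1
  sync <- sapply(1:20, function(i) cos(2 * pi * tt / 150))
  ca <- collective_amplitude(sync, times = tt)
  expect_lt(max(abs(ca$amplitude[ca$valid] - 1)), 0.1)

  # control vs uncoupled simulation from the same gradient ensemble
  ens <- build_mixture("PSM", n = 100, seed = 131)
  mk <- function(K) {
    trj <- simulate_oscillators(ens, coupling_config(K = K, "mean-field"),
                                slowing = NULL, t_end = 1440, dt = 0.5)
    tr <- trajectory_traces(trj)
    collective_amplitude(tr$intensity, times = tr$times)
  }
  ctrl <- mk(0.1); dapt <- mk(0)
  plateau <- function(ca) mean(ca$amplitude[ca$valid & ca$time_min >= 960])
  expect_lt(plateau(dapt), 0.2 * plateau(ctrl))
  # at a coupling strength that synchronizes over ~5-6 h, the collective
  # amplitude visibly rises across the first six hours
  slow <- mk(0.03)
  first6 <- slow$amplitude[slow$valid & slow$time_min <= 360]
  expect_gt(tail(first6, 1), head(first6, 1))
  expect_gt(cor(seq_along(first6), first6), 0.8)
})

test_that("collective amplitude approximates R times the mean amplitude", {
  tt <- seq(0, 1430, by = 10)
  set.seed(141)
  for (spread in c(0.5, 1.5, 3)) {
    offs <- runif(40, -spread, spread)
    R <- unname(order_parameter(offs)["R"])
    traces <- sapply(offs, function(o) cos(2 * pi * tt / 150 + o))
    ca <- collective_amplitude(traces, times = tt)
    plateau <- mean(ca$amplitude[ca$valid])
    expect_lt(abs(plateau - R) / max(R, 1e-9), 0.05)
  }
})

test_that("Fourier dominant period is found within one padded bin", {
  tt <- seq(0, 1430, by = 10)
  for (T0 in c(120, 135, 150, 170)) {
    fp <- fourier_period(cos(2 * pi * tt / T0), dt = 10)
    bin <- T0^2 / (8 * length(tt) * 10)  # period resolution at T0
    expect_lt(abs(fp$period_min - T0), bin)
    expect_gt(fp$confidence, 0.5)
  }
  expect_error(fourier_period(cos(2 * pi * (0:20) * 10 / 150), dt = 10),
               "two cycles")
})

test_that("Fourier and Hilbert estimators agree on stationary traces", {
  tt <- seq(0, 1430, by = 10)
  set.seed(151)
  for (T0 in c(125, 140, 160, 175)) {
    x <- cos(2 * pi * tt / T0) + rnorm(length(tt), sd = 0.05)
    f_est <- fourier_period(x, dt = 10)$period_min
    h_est <- median(analytic_phase(x, dt = 10)$period_min, na.rm = TRUE)
    expect_lt(abs(f_est - h_est), 3)
  }
})

test_that("white noise gets low spectral confidence and is flagged", {
  set.seed(161)
  confs <- replicate(300, {
    fourier_period(rnorm(144), dt = 10)$confidence
  })
  # the default period-map flagging threshold clears the noise null
  expect_gt(0.2, quantile(confs, 0.99))
  # while a clean oscillation scores far above it
  tt <- seq(0, 1430, by = 10)
  expect_gt(fourier_period(cos(2 * pi * tt / 150), dt = 10)$confidence, 0.5)
})

test_that("period maps flag empty pixels and resolve planted periods", {
  set.seed(171)
  f <- function(x, y, t) {
    if (x < 100) 0.5 + 0.5 * cos(2 * pi * t / 130) else 0
  }
  mv <- synthetic_movie(function(x, y, t) {
    (x < 100) * (0.5 + 0.5 * cos(2 * pi * t / 130))
  }, extent = c(0, 200, 0, 200))
  # add noise everywhere
  mv$frames <- mv$frames + array(rnorm(length(mv$frames), sd = 0.03),
                                 dim = dim(mv$frames))
  pm <- period_map(mv)
  xs <- mv$extent[1L] + (seq_len(dim(mv$frames)[2L]) - 0.5) * mv$pixel_size
  left <- xs < 100
  expect_true(all(abs(pm$period[, left] - 130) < 3, na.rm = TRUE))
  expect_gt(mean(!is.na(pm$period[, left])), 0.95)
  expect_lt(mean(!is.na(pm$period[, !left])), 0.05)
})

test_that("kymographs turn waves into oblique stripes of the right period", {
  # static movie: every column of the kymograph is constant over time
  static <- synthetic_movie(function(x, y, t) x / 200 + y / 400)
  ky <- kymograph(static, rbind(c(10, 10), c(190, 190)))
  expect_true(all(apply(ky, 1L, function(v) diff(range(v))) < 1e-9))
  # row count = arc length / pixel size
  expect_equal(nrow(ky), length(seq(0, sqrt(2) * 180, by = 4)))

  # target wave emanating from the center: stripes with the source period
  ctr <- c(100, 100)
  wave <- synthetic_movie(function(x, y, t) {
    r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    0.5 + 0.5 * cos(2 * pi * (t / 150 - r / 120))
  })
  kw <- kymograph(wave, rbind(c(100, 100), c(100, 190)))
  # every point along the line oscillates at the collective period
  mid <- kw[nrow(kw) %/% 2, ]
  fp <- fourier_period(data.frame(time_min = wave$times, intensity = mid))
  expect_lt(abs(fp$period_min - 150), 3)
  # phase lags increase along the line: stripes are oblique
  ph1 <- analytic_phase(detrend_trace(
    data.frame(time_min = wave$times, intensity = kw[5, ]), window = 150))
  ph2 <- analytic_phase(detrend_trace(
    data.frame(time_min = wave$times, intensity = kw[15, ]), window = 150))
  lag <- phase_difference(ph1, ph2)
  expect_gt(mean(lag$diff_rad[lag$valid]), 0.5)

  expect_error(kymograph(static, rbind(c(10, 10), c(10, 10))), "degenerate")
})

test_that("phase differences are circular, antisymmetric and exact", {
  tt <- seq(0, 1430, by = 10)
  a <- analytic_phase(cos(2 * pi * tt / 150), dt = 10)
  b <- analytic_phase(cos(2 * pi * (tt - 75) / 150), dt = 10)  # half period
  d_ab <- phase_difference(a, b)
  expect_true(all(abs(d_ab$diff_rad[d_ab$valid]) > pi - 0.1))
  d_aa <- phase_difference(a, a)
  expect_true(all(d_aa$diff_rad == 0))
  # antisymmetry (mod 2*pi), exactly
  d_ba <- phase_difference(b, a)
  expect_true(all(abs((d_ab$diff_rad + d_ba$diff_rad) %% (2 * pi)) < 1e-12 |
                    abs((d_ab$diff_rad + d_ba$diff_rad) %% (2 * pi) - 2 * pi) < 1e-12))
  expect_error(phase_difference(a, a[1:10, ]), "time base")
})
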