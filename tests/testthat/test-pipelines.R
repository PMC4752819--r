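test_that("predicted collective periods are composition-weighted means", {
  expect_equal(predict_collective_period(
    list(list(region = "P/2", fraction = 1))), 140)
  expect_equal(predict_collective_period(
    list(list(region = "P/2", fraction = 0.5),
         list(region = "A/2", fraction = 0.5))), 150)
  expect_equal(predict_collective_period(
    list(list(region = "A/2", fraction = 1))), 160)
  expect_error(predict_collective_period(
    list(list(region = "P/2", fraction = 0.7),
         list(region = "A/2", fraction = 0.7))), "sum to 1")
})

test_that("configurations round-trip through YAML and hash stably", {
  cfg <- experiment_config(coupling = list(K = 0.25),
                           foci = list(density = 10))
  expect_equal(cfg$coupling$K, 0.25)
  expect_equal(cfg$foci$r_min, 100)  # untouched default
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  write_experiment_config(cfg, p)
  back <- read_experiment_config(p)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  expect_false(identical(epsm:::config_hash(cfg),
                         epsm:::config_hash(experiment_config())))
  expect_error(experiment_config(nonsense = list(a = 1)), "unknown config")
})

test_that("titration mixes lock onto the arithmetic-mean period", {
  rep <- run_titration(fractions = c(1, 0.8, 0.5, 0.2), n = 200,
                       n_seeds = 3, seed = 1)
  tab <- rep$measurements$titration
  expect_true(all(tab$locked))
  expect_true(all(abs(tab$measured_min - tab$predicted_min) < 3))
  # more posterior (fast) cells -> faster collective rhythm
  expect_true(all(diff(tab$measured_min) > 0))  # fractions are decreasing
  expect_length(rep$flags, 0)
})

test_that("the collective-frequency law holds across random compositions", {
  set.seed(221)
  errs <- sapply(1:20, function(i) {
    fp <- runif(1, 0.05, 0.95)
    rep <- run_titration(fractions = fp, n = 200, n_seeds = 1, seed = 300 + i)
    tab <- rep$measurements$titration
    abs(tab$measured_min - tab$predicted_min)
  })
  expect_lt(max(errs), 3)
})

test_that("sorted populations keep their anti-phase offset for 12 hours", {
  rep <- run_sorted_phase_experiment(n = 200, t_end = 720, seed = 1)
  expect_lt(abs(rep$measurements$phase_diff_abs - pi), 0.3)
  expect_lt(abs(rep$measurements$phase_diff_drift), 0.3)
  expect_warning(run_sorted_phase_experiment(n = 20, window_width = 2.5,
                                             t_end = 300, seed = 2),
                 "overlap")
})

test_that("aggregates from one pool stay in phase when separated", {
  # the shared pool draw keeps separately simulated collective rhythms
  # aligned (with noiseless dynamics, exactly)
  rep <- run_separated_aggregates(n_aggregates = 3, n = 150, t_end = 720,
                                  seed = 3)
  expect_lt(rep$measurements$max_abs_diff, 0.3)
  # a phase-sorted (high-resultant) pool keeps them aligned even when each
  # aggregate experiences its own dynamics noise
  cfg <- experiment_config(simulate = list(phase_noise = 5e-4))
  model <- period_gradient_model()
  ens <- build_mixture("PSM", n = 150, phase_window = c(0, pi / 2),
                       model = model, seed = 33)
  ats <- lapply(1:3, function(a) {
    trj <- simulate_oscillators(ens, coupling_config(K = 0.1, "mean-field"),
                                slowing = NULL, t_end = 720, dt = 0.5,
                                phase_noise = 5e-4, seed = 100 + a)
    tr <- trajectory_traces(trj)
    analytic_phase(detrend_trace(
      data.frame(time_min = tr$times, intensity = rowMeans(tr$intensity)),
      window = 150), edge = 110)
  })
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    pd <- phase_difference(ats[[pr[1]]], ats[[pr[2]]])
    expect_lt(abs(epsm:::circular_mean(pd$diff_rad[pd$valid])), 0.3)
  }
})

test_that("a mean-frequency offset makes the phase difference drift at 2*pi*delta", {
  cfg <- experiment_config()
  model <- period_gradient_model()
  pool <- build_mixture("PSM", n = 200, seed = 31)
  delta <- 1 / 3000  # cycles per minute
  ens_a <- pool
  ens_b <- pool
  ens_b$period_min <- 1 / (1 / pool$period_min + delta)  # B faster by delta
  sim <- function(e) simulate_oscillators(
    e, coupling_config(K = 0.1, "mean-field"), slowing = NULL,
    t_end = 720, dt = 0.5)
  hp <- function(trj) {
    tr <- trajectory_traces(trj)
    analytic_phase(detrend_trace(
      data.frame(time_min = tr$times, intensity = rowMeans(tr$intensity)),
      window = 150), edge = 110)
  }
  a <- hp(sim(ens_a)); b <- hp(sim(ens_b))
  ok <- a$valid & b$valid
  d_unwrapped <- b$phase_rad[ok] - a$phase_rad[ok]
  slope <- coef(lm(d_unwrapped ~ a$time_min[ok]))[2L]
  expect_lt(abs(slope - 2 * pi * delta) / (2 * pi * delta), 0.1)
})

test_that("tracked sub-populations converge on a common period", {
  rep <- run_tracking_experiment(label_fraction = 1 / 8, n = 200, seed = 4)
  pops <- rep$measurements$populations
  lab <- pops[pops$population == "labeled", ]
  blk <- pops[pops$population == "bulk", ]
  # inputs reflect the sampled regions (anterior half vs tail bud)
  expect_lt(abs(lab$input_min - 160), 4)
  expect_lt(abs(blk$input_min - 133), 1)
  # after locking: common period, slow cells sped up, fast cells slowed down
  expect_lt(rep$measurements$common_period_gap_min, 3)
  expect_equal(lab$change, "accelerated")
  expect_equal(blk$change, "slowed")
  expect_length(rep$flags, 0)
})

test_that("blocking coupling abolishes synchrony but not single-cell rhythms", {
  rep <- run_dapt_experiment(n = 200, seed = 5)
  m <- rep$measurements
  expect_lt(m$plateau_ratio, 0.2)
  amp <- m$single_cell_amplitude
  expect_lt(abs(amp["inhibited"] - amp["control"]) / amp["control"], 0.1)
  # both layouts individually reject spatial randomness
  expect_lt(m$spacing$control$ks_p, 0.05)
  expect_lt(m$spacing$inhibited$ks_p, 0.05)
})

test_that("foci spacing is indistinguishable between coupling conditions", {
  # paired hard-core layouts (coupling-on vs coupling-off conditions) are
  # draws from the same spatial process: the between-condition KS test
  # should reject only at chance level
  rejections <- sum(sapply(1:20, function(s) {
    a <- place_foci(16.5, c(2000, 2000), 100, seed = 2 * s)
    b <- place_foci(16.5, c(2000, 2000), 100, seed = 2 * s + 1)
    ks_nonrandomness_test(nn_distances(a), nn_distances(b))$p_value < 0.05
  }))
  expect_lte(rejections, 4)
})

test_that("identical configuration and seed give identical reports", {
  a <- run_titration(fractions = 0.5, n = 80, n_seeds = 2, seed = 9)
  b <- run_titration(fractions = 0.5, n = 80, n_seeds = 2, seed = 9)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$config_hash, b$config_hash)
  dir <- withr::local_tempdir()
  p <- write_report(a, dir)
  expect_true(file.exists(p))
  expect_true(file.exists(sub("json$", "md", p)))
})

test_that("the randomization pipeline self-organizes wave-emitting foci", {
  rep <- run_randomization_experiment(composition = "PSM", seed = 1)
  m <- rep$measurements

  # several foci detected, spaced at least the hard-core scale apart
  expect_gte(m$n_detected, 5)
  expect_gte(m$spacing$min, 90)
  # the spacing report carries the calibrated KS comparison (at ~10 foci per
  # field the per-run test has little power; the rejection property is
  # established on full-size layouts in the spatial/acceptance suites)
  expect_true(m$spacing$ks_p >= 0 && m$spacing$ks_p <= 1)

  # period map: radially increasing from focus center to periphery
  rp <- m$radial_period_min$period_min
  expect_gt(rp[length(rp)], rp[1L] + 5)
  expect_true(all(diff(rp) > -1))

  # stable center vs slowing periphery over the culture
  expect_lt(diff(range(m$center_period$period_min)), 10)
  pp <- m$periphery_period$period_min
  expect_true(all(diff(pp) > -2))
  expect_gt(pp[length(pp)] - pp[1L], 10)

  # kymograph through two foci shows oscillations at the collective period
  ky <- m$kymograph
  expect_s3_class(ky, "kymograph")
  mid <- ky[3, ]
  fp <- fourier_period(data.frame(time_min = attr(ky, "times"),
                                  intensity = mid), detrend_window = 150)
  expect_gt(fp$confidence, 0.2)
  expect_true(fp$period_min > 140 && fp$period_min < 190)

  # tail-bud-only re-aggregation reproduces the same foci density
  rep_tb <- run_randomization_experiment(composition = "tailbud", seed = 2)
  expect_lt(abs(rep_tb$measurements$density_mm2 - m$density_mm2), 3.8)
})
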