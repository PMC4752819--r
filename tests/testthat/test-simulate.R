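test_that("an uncoupled oscillator advances at its intrinsic rate", {
  ens <- build_mixture("PSM", n = 1, seed = 1)
  ens$period_min <- 150
  trj <- simulate_oscillators(ens, coupling_config(K = 0, "mean-field"),
                              slowing = NULL, t_end = 150, dt = 0.5)
  advance <- trj$phases[nrow(trj$phases), 1] - trj$phases[1, 1]
  expect_equal(advance, 2 * pi, tolerance = 1e-9)
})

test_that("two-oscillator locking follows the closed-form criterion", {
  # omega_i = 2*pi/T_i; with mean-field normalization by n the phase
  # difference obeys d(delta)/dt = dw - K*sin(delta): locking iff K >= |dw|
  ens <- build_mixture("PSM", n = 2, seed = 2)
  ens$period_min <- c(137, 156)
  dw <- abs(2 * pi / 137 - 2 * pi / 156)

  lock_K <- 2 * dw
  trj <- simulate_oscillators(ens, coupling_config(K = lock_K, "mean-field"),
                              slowing = NULL, t_end = 2880, dt = 0.25)
  i1 <- which(trj$times >= 2000)[1L]
  i2 <- nrow(trj$phases)
  # locked common frequency equals the mean intrinsic frequency
  f_obs <- (trj$phases[i2, ] - trj$phases[i1, ]) /
    (trj$times[i2] - trj$times[i1])
  f_mean <- mean(2 * pi / c(137, 156))
  expect_equal(unname(f_obs[1L]), f_mean, tolerance = 1e-3)
  expect_equal(unname(f_obs[2L]), f_mean, tolerance = 1e-3)
  # phase difference bounded
  dphi <- trj$phases[, 1] - trj$phases[, 2]
  expect_lt(diff(range(dphi[trj$times >= 1000])), 0.05)

  # against an independently written brute-force integrator
  oracle <- brute_force_kuramoto(ens$phase_rad, 2 * pi / c(137, 156),
                                 K = lock_K, t_end = 720, dt = 0.05)
  i720 <- which.min(abs(trj$times - 720))
  expect_equal(unname(trj$phases[i720, ]), unname(oracle[nrow(oracle), ]),
               tolerance = 0.05)

  # below threshold: no lock, monotone drift of the phase difference
  weak_K <- 0.5 * dw
  trj2 <- simulate_oscillators(ens, coupling_config(K = weak_K, "mean-field"),
                               slowing = NULL, t_end = 2880, dt = 0.25)
  d2 <- trj2$phases[, 1] - trj2$phases[, 2]
  expect_true(all(diff(d2) > 0))
  expect_gt(d2[length(d2)] - d2[1L], 2 * pi)
})

test_that("order parameter matches its definition and uniform-phase scale", {
  expect_equal(unname(order_parameter(rep(1.3, 50))["R"]), 1)
  expect_equal(unname(order_parameter(c(0, pi))["R"]), 0, tolerance = 1e-12)
  expect_error(order_parameter(numeric(0)), "non-empty")
  # E[R] for n uniform phases ~ sqrt(pi/(4n)) (brute-force Monte Carlo)
  set.seed(61)
  n <- 1000
  Rbar <- mean(replicate(300, order_parameter(runif(n, 0, 2 * pi))["R"]))
  expect_equal(Rbar, sqrt(pi / (4 * n)), tolerance = 0.05)
})

test_that("symmetric mean-field coupling conserves the mean frequency", {
  ens <- build_mixture("PSM", n = 100, seed = 71)
  trj <- simulate_oscillators(ens, coupling_config(K = 0.1, "mean-field"),
                              slowing = NULL, t_end = 720, dt = 0.5)
  omega_bar <- mean(2 * pi / ens$period_min)
  inst <- diff(rowMeans(trj$phases)) / trj$dt
  expect_true(all(abs(inst - omega_bar) < 1e-6))
})

test_that("halving the step barely changes a day-long trajectory", {
  ens <- build_mixture("PSM", n = 100, seed = 81)
  a <- simulate_oscillators(ens, coupling_config(K = 0.1, "mean-field"),
                            slowing = NULL, t_end = 1440, dt = 0.5)
  b <- simulate_oscillators(ens, coupling_config(K = 0.1, "mean-field"),
                            slowing = NULL, t_end = 1440, dt = 0.25)
  expect_lt(max(abs(a$phases[nrow(a$phases), ] - b$phases[nrow(b$phases), ])),
            1e-2)
})

test_that("coupled gradient ensembles synchronize within six hours", {
  for (seed in 1:3) {
    ens <- build_mixture(list(list(region = "P/2", fraction = 0.5),
                              list(region = "A/2", fraction = 0.5)),
                         n = 200, seed = seed)
    trj <- simulate_oscillators(ens, coupling_config(K = 0.1, "mean-field"),
                                slowing = NULL, t_end = 360, dt = 0.5)
    oc <- order_parameter_course(trj, every = 20)
    expect_gt(oc$R[nrow(oc)], 0.95)
    # R eventually non-decreasing: no late collapse
    late <- oc$R[oc$time_min >= 240]
    expect_true(all(diff(late) > -0.01))
  }
})

test_that("without coupling an ensemble decays to the incoherent floor", {
  ens <- build_mixture("PSM", n = 200, phase_window = c(0, 0), seed = 91)
  trj <- simulate_oscillators(ens, coupling_config(K = 0, "mean-field"),
                              slowing = NULL, t_end = 1440, dt = 0.5)
  oc <- order_parameter_course(trj, every = 40)
  expect_equal(oc$R[1L], 1)
  expect_lt(oc$R[nrow(oc)], 0.2)
})

test_that("intrinsic periods slow linearly with radius and time", {
  sl <- slowing_profile(s_max = 0.05, r_focus = 60)
  expect_equal(intrinsic_period_at(150, r = 0, t = 600, sl), 150)
  expect_equal(intrinsic_period_at(150, r = 60, t = 600, sl), 180)
  expect_equal(intrinsic_period_at(150, r = 30, t = 600, sl), 165)
  # no slowing: no gradient ever forms
  expect_equal(intrinsic_period_at(150, r = 60, t = 600, NULL), 150)
  # decoupling weight: 1 before onset, 0 beyond full
  sl2 <- slowing_profile(decouple_onset = 5, decouple_full = 15)
  expect_equal(sl2$w(0), 1)
  expect_equal(sl2$w(5), 1)
  expect_equal(sl2$w(10), 0.5)
  expect_equal(sl2$w(20), 0)
})

test_that("slowing cells arrest at the period ceiling and freeze", {
  ens <- build_mixture("PSM", n = 20, seed = 101)
  foci <- foci_set(50, 50, area = c(100, 100))
  ens <- assign_positions(ens, foci, r_focus = 60, seed = 102)
  ens$radius_um <- seq(0, 60, length.out = 20)  # controlled radii
  sl <- slowing_profile(s_max = 0.1, r_focus = 60, arrest_period = 200)
  trj <- simulate_oscillators(ens, coupling_config(K = 0, "mean-field"),
                              slowing = sl, t_end = 1440, dt = 0.5)
  rim <- 20  # fastest-slowing cell
  expect_false(is.na(trj$arrest_time[rim]))
  # phase frozen after arrest
  after <- trj$times >= trj$arrest_time[rim] + 1
  expect_equal(diff(range(trj$phases[after, rim])), 0)
  # center cell never arrests
  expect_true(is.na(trj$arrest_time[1L]))
  # stored intrinsic periods capped at the ceiling
  expect_lte(max(trj$periods), 200)
})

test_that("unstable steps and missing positions are caught", {
  ens <- build_mixture("PSM", n = 5, seed = 111)
  expect_error(
    simulate_oscillators(ens, coupling_config(K = 10, "mean-field"),
                         t_end = 10, dt = 1),
    "unstable|pi")
  expect_error(
    simulate_oscillators(ens, coupling_config(K = 0.1, "radius", radius = 20),
                         t_end = 10),
    "positions")
  expect_error(
    simulate_oscillators(ens, coupling_config(K = 0, "mean-field"),
                         slowing = slowing_profile(), t_end = 10),
    "positions")
  expect_error(
    simulate_oscillators(ens, coupling_config(K = 0, "mean-field"), dt = 2),
    "dt")
})

test_that("noisy dynamics are reproducible under a fixed seed", {
  ens <- build_mixture("PSM", n = 20, seed = 121)
  a <- simulate_oscillators(ens, coupling_config(K = 0.05, "mean-field"),
                            t_end = 120, phase_noise = 0.01, seed = 5)
  b <- simulate_oscillators(ens, coupling_config(K = 0.05, "mean-field"),
                            t_end = 120, phase_noise = 0.01, seed = 5)
  expect_identical(a$phases, b$phases)
})
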