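# Kuramoto-type phase dynamics for ensembles of genetic oscillators.
#
# Each cell i advances as
#   dphi_i/dt = 2*pi / T_i(t) + (K / |N_i|) * sum_{j in N_i} sin(phi_j - phi_i)
# integrated with explicit Euler (Euler-Maruyama when phase noise is on).
# T_i(t) is the intrinsic period, which may increase with time for cells far
# from their focus center (peripheral slowing); once it exceeds a ceiling the
# cell arrests (differentiation), its phase freezes and it stops contributing
# to its neighbors' coupling.

#' Coupling configuration
#'
#' @param K coupling strength, rad/min, `>= 0`. `K = 0` models Notch
#'   inhibition (DAPT): oscillators run free and never synchronize.
#' @param topology `"mean-field"` (all-to-all) or `"radius"` (cells within
#'   `radius` micrometers are neighbors). The coupling sum is normalized by
#'   the neighbor count so `K` is comparable across topologies.
#' @param radius interaction radius in micrometers (used when
#'   `topology = "radius"`).
#' @return a `coupling_config` list.
#' @export
coupling_config <- function(K = 0.1, topology = c("radius", "mean-field"),
                            radius = 30) {
  topology <- match.arg(topology)
  stopifnot(K >= 0)
  if (topology == "radius" && !(radius > 0)) stop("`radius` must be > 0")
  structure(list(K = K, topology = topology, radius = radius),
            class = "coupling_config")
}

#' Peripheral slowing profile
#'
#' Cells at the periphery of a focus progressively slow their oscillations
#' while cells at the center keep a stable period. The intrinsic period of a
#' cell at radial distance `r` from its focus center evolves as
#' `T(t) = T0 + s(r) * t` with slope `s(r) = s_max * r / r_focus`
#' (dimensionless: minutes of period gained per minute of elapsed time), so
#' `s(0) = 0` (stable center). The default `s_max` takes a 150-min cell at the
#' focus rim to about 180 min after 12 h of culture.
#'
#' @param s_max slope at the focus rim (`r = r_focus`); dimensionless.
#' @param r_focus focus radius, micrometers.
#' @param arrest_period period ceiling in minutes: a cell whose intrinsic
#'   period exceeds it is marked arrested (stops oscillating and coupling;
#'   its rendered amplitude decays).
#' @param decouple_onset,decouple_full differentiation-driven decoupling, in
#'   minutes of *accumulated* slowing `s(r) * t`: a cell's coupling weight is
#'   1 until its period has risen by `decouple_onset`, fades linearly, and
#'   reaches 0 once the rise exceeds `decouple_full`. Slowing and decoupling
#'   are two faces of the same differentiation program: as a peripheral cell
#'   commits, it stops exchanging phase information and expresses its own
#'   progressively slower rhythm instead of being entrained by (or dragging)
#'   the focus center — so the entrained core shrinks toward the center over
#'   time, as in the shrinking wave-swept area. Cells that never slow keep
#'   weight 1.
#' @return a `slowing_profile` with a callable slope `s(r)` and coupling
#'   weight `w(delta_T)` of the accumulated period rise.
#' @export
slowing_profile <- function(s_max = 30 / 720, r_focus = 60,
                            arrest_period = 200, decouple_onset = 5,
                            decouple_full = 15) {
  stopifnot(s_max >= 0, r_focus > 0, arrest_period > 0,
            decouple_onset >= 0, decouple_full > decouple_onset)
  structure(list(
    s = function(r) s_max * pmax(r, 0) / r_focus,
    w = function(delta_T) pmin(pmax((decouple_full - delta_T) /
                                      (decouple_full - decouple_onset), 0), 1),
    s_max = s_max, r_focus = r_focus, arrest_period = arrest_period,
    decouple_onset = decouple_onset, decouple_full = decouple_full
  ), class = "slowing_profile")
}

#' Intrinsic period of a slowing cell
#'
#' @param T0 initial intrinsic period, minutes.
#' @param r radial distance from the focus center, micrometers.
#' @param t elapsed time, minutes (`>= 0`).
#' @param slowing a [slowing_profile()], or `NULL` for no slowing.
#' @return `T0 + s(r) * t`, minutes.
#' @examples
#' intrinsic_period_at(150, r = 0, t = 600)  # stable center: 150
#' @export
intrinsic_period_at <- function(T0, r, t, slowing = slowing_profile()) {
  stopifnot(all(t >= 0))
  if (is.null(slowing)) return(T0 + 0 * r + 0 * t)
  T0 + slowing$s(r) * t
}

#' Kuramoto order parameter
#'
#' Modulus `R` and argument `Psi` of the complex mean of unit phasors:
#' `R * exp(1i * Psi) = mean(exp(1i * phases))`. `R = 1` for perfect phase
#' synchrony; for `n` independent uniform phases `R` is of order
#' `1 / sqrt(n)` (expectation `sqrt(pi / (4n))`).
#'
#' @param phases numeric vector of phases, radians (any wrapping).
#' @return named numeric `c(R =, psi =)`.
#' @export
order_parameter <- function(phases) {
  if (length(phases) < 1L) stop("`phases` must be non-empty")
  z <- mean(exp(1i * phases))
  c(R = Mod(z), psi = Arg(z))
}

#' Simulate coupled phase oscillators
#'
#' Integrates the ensemble's phase equations with explicit Euler at step `dt`
#' (Euler-Maruyama when `phase_noise > 0`). With `K = 0` and no slowing each
#' oscillator advances at its own intrinsic rate. Peripheral slowing requires
#' positions (see [assign_positions()]); cells whose intrinsic period crosses
#' the arrest ceiling freeze and stop coupling.
#'
#' @param ensemble an [build_mixture()] ensemble.
#' @param coupling a [coupling_config()].
#' @param slowing a [slowing_profile()] or `NULL` (no slowing).
#' @param t_end total simulated time, minutes.
#' @param dt Euler step, minutes (`<= 1` enforced for stability).
#' @param phase_noise phase diffusion coefficient, rad^2/min; per-step
#'   increments have standard deviation `sqrt(2 * phase_noise * dt)`.
#' @param seed integer seed for the noise stream (optional).
#' @return a `phase_trajectory`: list with `times` (minutes), `phases`
#'   (time x cell matrix, unwrapped radians), `periods` (time x cell intrinsic
#'   periods), `arrest_time` (per cell, `NA` if never arrested), `ensemble`,
#'   `coupling`, `slowing`, `dt`.
#' @examples
#' ens <- build_mixture("P/2", n = 10, seed = 1)
#' tr <- simulate_oscillators(ens, coupling_config(K = 0.1, "mean-field"),
#'                            slowing = NULL, t_end = 720)
#' order_parameter(tr$phases[nrow(tr$phases), ])["R"]
#' @export
simulate_oscillators <- function(ensemble, coupling = coupling_config(),
                                 slowing = NULL, t_end = 1440, dt = 0.5,
                                 phase_noise = 0, seed = NULL) {
  stopifnot(inherits(ensemble, "oscillator_ensemble"),
            inherits(coupling, "coupling_config"))
  if (dt > 1) stop("`dt` must be <= 1 min for stability")
  if (t_end < dt) stop("`t_end` must be at least one step")
  n <- nrow(ensemble)

  r <- rep(0, n)
  if (!is.null(slowing)) {
    stopifnot(inherits(slowing, "slowing_profile"))
    if (is.null(ensemble$radius_um)) {
      stop("peripheral slowing requires positions; run assign_positions() first")
    }
    r <- ensemble$radius_um
  }

  adj <- NULL
  deg <- rep(n - 1, n)
  if (coupling$topology == "radius" && coupling$K > 0) {
    if (all(is.na(ensemble$pos_x_um))) {
      stop("radius coupling requires positions; run assign_positions() first")
    }
    pos <- cbind(ensemble$pos_x_um, ensemble$pos_y_um)
    d <- cross_dist(pos, pos)
    adj <- (d <= coupling$radius)
    diag(adj) <- FALSE
    storage.mode(adj) <- "double"
    deg <- rowSums(adj)
  }

  if (!is.null(seed)) set.seed(substream_seed(seed, "dynamics"))

  steps <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = steps + 1L)
  phases <- matrix(NA_real_, steps + 1L, n)
  periods <- matrix(NA_real_, steps + 1L, n)
  phi <- ensemble$phase_rad
  T0 <- ensemble$period_min
  slope <- if (is.null(slowing)) rep(0, n) else slowing$s(r)
  ceiling_T <- if (is.null(slowing)) Inf else slowing$arrest_period
  arrest_time <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  noise_sd <- sqrt(2 * phase_noise * dt)

  phases[1L, ] <- phi
  periods[1L, ] <- T0

  for (s in seq_len(steps)) {
    t_now <- times[s]
    T_now <- T0 + slope * t_now
    newly_arrested <- active & (T_now > ceiling_T)
    if (any(newly_arrested)) {
      arrest_time[newly_arrested] <- t_now
      active[newly_arrested] <- FALSE
    }
    omega <- 2 * pi / T_now

    if (coupling$K > 0) {
      # differentiation fades a cell out of the coupling graph: weight w in
      # [0,1] applies both to the input it exerts and its own susceptibility
      w <- if (is.null(slowing)) as.double(active) else
        slowing$w(slope * t_now) * as.double(active)
      if (is.null(adj)) {
        wsum <- sum(w)
        if (wsum > 0) {
          zs <- sum(sin(phi) * w); zc <- sum(cos(phi) * w)
          coup <- w * coupling$K / wsum * (cos(phi) * zs - sin(phi) * zc)
        } else coup <- rep(0, n)
      } else {
        sv <- as.vector(adj %*% (sin(phi) * w))
        cv <- as.vector(adj %*% (cos(phi) * w))
        wdeg <- as.vector(adj %*% w)
        coup <- ifelse(wdeg > 0,
                       w * coupling$K / pmax(wdeg, 1e-12) *
                         (cos(phi) * sv - sin(phi) * cv),
                       0)
      }
    } else coup <- rep(0, n)

    dphi <- (omega + coup) * dt
    if (noise_sd > 0) dphi <- dphi + rnorm(n, sd = noise_sd)
    dphi[!active] <- 0
    if (max(abs(dphi)) > pi) {
      stop("unstable step: |phase increment| > pi; reduce dt or K")
    }
    phi <- phi + dphi
    phases[s + 1L, ] <- phi
    periods[s + 1L, ] <- pmin(T0 + slope * times[s + 1L], ceiling_T)
  }

  structure(list(
    times = times, phases = phases, periods = periods,
    arrest_time = arrest_time, ensemble = ensemble,
    coupling = coupling, slowing = slowing, dt = dt
  ), class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  Rf <- order_parameter(x$phases[nrow(x$phases), ])["R"]
  cat(sprintf("Phase trajectory: %d cells, %.0f min at dt = %g min (%s coupling, K = %g)\n",
              ncol(x$phases), max(x$times), x$dt,
              x$coupling$topology, x$coupling$K))
  cat(sprintf("  final order parameter R = %.3f; %d arrested cells\n",
              Rf, sum(!is.na(x$arrest_time))))
  invisible(x)
}

#' Order-parameter time course of a trajectory
#'
#' @param trajectory a [simulate_oscillators()] result.
#' @param every compute `R` every `every`-th stored step (default all).
#' @return data frame with `time_min`, `R`, `psi`.
#' @export
order_parameter_course <- function(trajectory, every = 1L) {
  idx <- seq(1L, nrow(trajectory$phases), by = every)
  z <- rowMeans(exp(1i * trajectory$phases[idx, , drop = FALSE]))
  data.frame(time_min = trajectory$times[idx], R = Mod(z), psi = Arg(z))
}

#' Reporter intensity traces from a phase trajectory
#'
#' Converts per-cell phases into the cosine reporter model used by the
#' imaging layer, `I_i(t) = A_i * (1 + cos phi_i(t)) / 2`, sampled at the
#' imaging frame interval; arrested cells decay exponentially with time
#' constant `arrest_tau`. This gives per-cell traces without spatial binning
#' (the movie renderer adds the pixel grid and noise).
#'
#' @param trajectory a [simulate_oscillators()] result.
#' @param frame_interval sampling interval, minutes (must be a multiple of
#'   the trajectory `dt`).
#' @param amplitude scalar or per-cell amplitude.
#' @param arrest_tau amplitude decay time constant after arrest, minutes.
#' @return list with `times` and `intensity` (time x cell matrix).
#' @export
trajectory_traces <- function(trajectory, frame_interval = 10, amplitude = 1,
                              arrest_tau = 60) {
  stride <- frame_interval / trajectory$dt
  if (abs(stride - round(stride)) > 1e-9) {
    stop("`frame_interval` must be a multiple of the trajectory dt")
  }
  idx <- seq(1L, nrow(trajectory$phases), by = round(stride))
  times <- trajectory$times[idx]
  ph <- trajectory$phases[idx, , drop = FALSE]
  n <- ncol(ph)
  A <- matrix(rep(amplitude, length.out = n), nrow = length(idx), ncol = n,
              byrow = TRUE)
  at <- trajectory$arrest_time
  for (j in which(!is.na(at))) {
    dtpost <- pmax(times - at[j], 0)
    A[, j] <- A[, j] * exp(-dtpost / arrest_tau)
  }
  list(times = times, intensity = A * (1 + cos(ph)) / 2)
}

#' Write a phase trajectory to CSV + JSON metadata
#'
#' Phases and intrinsic periods are written as wide CSV (one row per time
#' point, one column per cell) beside a JSON file with the run metadata.
#'
#' @param trajectory a [simulate_oscillators()] result.
#' @param prefix path prefix; writes `<prefix>_phases.csv`,
#'   `<prefix>_periods.csv` and `<prefix>_meta.json`.
#' @return `prefix`, invisibly.
#' @export
write_trajectory <- function(trajectory, prefix) {
  ph <- data.frame(time_min = trajectory$times, trajectory$phases)
  names(ph) <- c("time_min", paste0("cell_", seq_len(ncol(trajectory$phases))))
  write.csv(ph, paste0(prefix, "_phases.csv"), row.names = FALSE)
  pd <- data.frame(time_min = trajectory$times, trajectory$periods)
  names(pd) <- names(ph)
  write.csv(pd, paste0(prefix, "_periods.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_cells = ncol(trajectory$phases), dt = trajectory$dt,
         t_end = max(trajectory$times),
         coupling = unclass(trajectory$coupling),
         arrested = sum(!is.na(trajectory$arrest_time))),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
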