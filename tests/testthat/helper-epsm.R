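# Shared fixtures and independent oracles for the test suite.

# Plain-loop Euler integrator for a handful of coupled phase oscillators,
# written independently of the package's vectorized simulator so the two can
# be cross-checked. dphi_i/dt = omega_i + (K/n) * sum_j sin(phi_j - phi_i).
brute_force_kuramoto <- function(phi0, omega, K, t_end, dt = 0.1) {
  n <- length(phi0)
  steps <- round(t_end / dt)
  phi <- phi0
  out <- matrix(NA_real_, steps + 1L, n)
  out[1L, ] <- phi
  for (s in seq_len(steps)) {
    dphi <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + sin(phi[j] - phi[i])
      dphi[i] <- omega[i] + K / n * acc
    }
    phi <- phi + dphi * dt
    out[s + 1L, ] <- phi
  }
  out
}

# Sampled cosine trace with the package's 10-min default frame interval.
cosine_trace <- function(T_min, t_end = 1440, dt = 10, amplitude = 1,
                         phase0 = 0) {
  tt <- seq(0, t_end, by = dt)
  data.frame(time_min = tt,
             intensity = amplitude * cos(2 * pi * tt / T_min + phase0))
}

# Synthetic intensity_movie built directly from a pixel-value function
# f(x_um, y_um, t_min), bypassing the renderer.
synthetic_movie <- function(f, extent = c(0, 200, 0, 200), pixel_size = 4,
                            frame_interval = 10, t_end = 1440) {
  nx <- ceiling((extent[2L] - extent[1L]) / pixel_size)
  ny <- ceiling((extent[4L] - extent[3L]) / pixel_size)
  nt <- ceiling(t_end / frame_interval)
  times <- seq(0, by = frame_interval, length.out = nt)
  xs <- extent[1L] + (seq_len(nx) - 0.5) * pixel_size
  ys <- extent[3L] + (seq_len(ny) - 0.5) * pixel_size
  frames <- array(0, dim = c(ny, nx, nt))
  for (k in seq_len(nt)) {
    frames[, , k] <- outer(ys, xs, function(y, x) 0 * x + f(x, y, times[k]))
  }
  structure(list(frames = frames, times = times, pixel_size = pixel_size,
                 frame_interval = frame_interval, extent = extent),
            class = "intensity_movie")
}

# Nearest-neighbor distances by explicit double loop (oracle for the
# package's vectorized version and for null-distribution checks).
brute_force_nn <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}
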