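# Quantification stack for oscillatory reporter signals: moving-average
# detrending, Hilbert-transform instantaneous phase/amplitude/period,
# collective amplitude, Fourier dominant periods and per-pixel period maps,
# kymographs, and circular phase differences.

trace_parts <- function(trace, dt = NULL) {
  # accept roi_trace / data.frame(time_min, intensity) / numeric + dt
  if (is.data.frame(trace)) {
    times <- trace$time_min %||% trace$time
    x <- trace$intensity %||% trace$signal
    if (is.null(times) || is.null(x)) {
      stop("data-frame traces need columns time_min (or time) and intensity (or signal)")
    }
  } else {
    x <- as.numeric(trace)
    if (is.null(dt)) stop("numeric traces need `dt` (minutes per sample)")
    times <- (seq_along(x) - 1L) * dt
  }
  if (length(times) >= 3L) {
    steps <- diff(times)
    if (any(steps <= 0) || diff(range(steps)) > 1e-6 * mean(steps)) {
      stop("trace must be uniformly sampled with strictly increasing times")
    }
  }
  list(times = times, x = x, dt = if (length(times) > 1L) times[2L] - times[1L] else dt)
}

#' Moving-average detrending
#'
#' Subtracts a background trend line computed as a centered moving average;
#' near the record edges the averaging window shrinks symmetrically. The
#' default window equals one expected period (150 min): averaging over a full
#' cycle cancels the carrier exactly, so the oscillation passes with unit
#' gain while slower drift is removed.
#'
#' @param trace a `roi_trace`, a data frame with `time_min`/`intensity`
#'   columns, or a numeric vector (then supply `dt`).
#' @param window moving-average window, minutes; must be at least two sample
#'   intervals and no longer than the record. A window equal to one expected
#'   period passes the oscillatory carrier with exactly unit gain while
#'   removing slow drift; strongly off-period windows re-scale the carrier.
#' @param dt sample interval in minutes (numeric-vector input only).
#' @return data frame with `time_min` and detrended `signal`.
#' @export
detrend_trace <- function(trace, window = 150, dt = NULL) {
  p <- trace_parts(trace, dt)
  n <- length(p$x)
  if (window < 2 * p$dt) stop("`window` must span at least two sample intervals")
  if (window > (n - 1L) * p$dt + 1e-9) stop("`window` is longer than the trace")
  half <- max(1L, floor(window / p$dt / 2))
  cs <- cumsum(c(0, p$x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  data.frame(time_min = p$times, signal = p$x - trend)
}

# Analytic signal via FFT: zero the negative frequencies, double the
# positive ones. The input is mirror-extended on both sides before the FFT
# so the implicit periodic wrap-around does not inject edge ripple into the
# interior (the extensions are cropped off afterwards).
analytic_signal <- function(x, pad = NULL) {
  n0 <- length(x)
  pad <- min(n0 - 1L, pad %||% ceiling(n0 / 3))
  if (pad > 0L) {
    x <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n0 - pad):(n0 - 1L)]))
  }
  z <- analytic_signal_raw(x)
  z[(pad + 1L):(pad + n0)]
}

analytic_signal_raw <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert-transform instantaneous phase, amplitude and period
#'
#' Computes the analytic signal of a detrended, uniformly sampled trace; its
#' argument gives the instantaneous phase (unwrapped) and its modulus the
#' instantaneous amplitude. The instantaneous period is `2*pi` over the
#' finite-difference phase slope, smoothed with a 3-sample running median to
#' suppress differentiation noise; samples where the phase slope is not
#' positive get `NA`. Hilbert-derived quantities are unreliable near the
#' record edges: samples within `edge` minutes of either end are flagged
#' `valid = FALSE` (they are still reported).
#'
#' @param trace detrended input: a data frame with `time_min`/`signal` (as
#'   returned by [detrend_trace()]), a `roi_trace`, or numeric plus `dt`.
#' @param dt sample interval, minutes (numeric input only).
#' @param edge width of the edge exclusion zone at each end, minutes
#'   (default roughly half of the default detrending window).
#' @return an `analytic_trace`: data frame with `time_min`, `signal`,
#'   `phase_rad` (unwrapped), `amplitude`, `period_min`, `valid`.
#' @examples
#' tr <- analytic_phase(cos(2 * pi * (0:143) * 10 / 150), dt = 10)
#' median(tr$period_min[tr$valid], na.rm = TRUE) # ~150
#' @export
analytic_phase <- function(trace, dt = NULL, edge = 110) {
  p <- trace_parts(trace, dt)
  n <- length(p$x)
  if (n < 4L) stop("trace too short for phase analysis")
  z <- analytic_signal(p$x - mean(p$x))
  phase <- signal::unwrap(Arg(z))
  amp <- Mod(z)
  # centered finite-difference phase slope
  dphi <- c(phase[2L] - phase[1L],
            (phase[3L:n] - phase[1L:(n - 2L)]) / 2,
            phase[n] - phase[n - 1L]) / p$dt
  dphi_s <- stats::runmed(dphi, 3L, endrule = "keep")
  period <- ifelse(dphi_s > 0, 2 * pi / dphi_s, NA_real_)
  valid <- p$times >= p$times[1L] + edge & p$times <= p$times[n] - edge
  structure(
    data.frame(time_min = p$times, signal = p$x, phase_rad = phase,
               amplitude = amp, period_min = period, valid = valid),
    class = c("analytic_trace", "data.frame")
  )
}

#' Collective amplitude of a population of traces
#'
#' Synchronization readout at the population level: each trace is detrended,
#' the population mean trace is formed, and its Hilbert (instantaneous)
#' amplitude is returned. When single cells oscillate coherently the mean
#' trace oscillates with the full single-cell amplitude and the collective
#' amplitude is high; with incoherent phases the mean trace flattens out and
#' the collective amplitude stays near zero, even though every single cell
#' keeps oscillating. For equal-amplitude cosines the collective amplitude
#' approximates the Kuramoto order parameter times the mean single-cell
#' amplitude.
#'
#' @param traces a numeric matrix (time x traces), or a list of
#'   `roi_trace`/data frames on a common time base.
#' @param times time base in minutes (matrix input only).
#' @param window detrending window, minutes.
#' @param edge edge exclusion for the Hilbert step, minutes.
#' @return data frame with `time_min`, `amplitude`, `valid`.
#' @export
collective_amplitude <- function(traces, times = NULL, window = 150,
                                 edge = 110) {
  if (is.list(traces) && !is.data.frame(traces)) {
    parts <- lapply(traces, trace_parts)
    times <- parts[[1L]]$times
    for (pp in parts[-1L]) {
      if (length(pp$times) != length(times) ||
          max(abs(pp$times - times)) > 1e-6) {
        stop("all traces must share a common time base")
      }
    }
    traces <- do.call(cbind, lapply(parts, `[[`, "x"))
  }
  stopifnot(is.matrix(traces), ncol(traces) >= 2L)
  if (is.null(times)) stop("matrix input needs `times`")
  det <- apply(traces, 2L, function(v) {
    detrend_trace(data.frame(time_min = times, intensity = v),
                  window = window)$signal
  })
  at <- analytic_phase(data.frame(time_min = times, signal = rowMeans(det)),
                       edge = edge)
  data.frame(time_min = at$time_min, amplitude = at$amplitude,
             valid = at$valid)
}

#' Dominant oscillation period by Fourier analysis
#'
#' Estimates the dominant period of a trace as the period of maximal spectral
#' power within an analysis band, with the spectrum refined by zero-padding.
#' The reported confidence is the fraction of total (positive-frequency)
#' power carried by the peak bin; white noise spreads power across bins and
#' yields low confidence.
#'
#' @param trace input trace (same forms as [detrend_trace()]); it is mean-
#'   subtracted, and detrended first when `detrend_window` is given.
#' @param dt sample interval, minutes (numeric input only).
#' @param band `c(min_period, max_period)` analysis band, minutes. The
#'   record must cover at least two cycles of the longest band period.
#' @param pad_factor zero-padding factor for spectral refinement.
#' @param detrend_window optional moving-average window, minutes.
#' @return list with `period_min`, `confidence`, and the band spectrum
#'   (`periods`, `power`).
#' @examples
#' fourier_period(cos(2 * pi * (0:143) * 10 / 135), dt = 10)$period_min # ~135
#' @export
fourier_period <- function(trace, dt = NULL, band = c(100, 220),
                           pad_factor = 8, detrend_window = NULL) {
  p <- trace_parts(trace, dt)
  n <- length(p$x)
  if ((n - 1L) * p$dt < 2 * band[2L]) {
    stop("record must span at least two cycles of the longest band period")
  }
  x <- p$x
  if (!is.null(detrend_window)) {
    x <- detrend_trace(data.frame(time_min = p$times, intensity = x),
                       window = detrend_window)$signal
  }
  x <- x - mean(x)
  m <- pad_factor * n
  X <- fft(c(x, numeric(m - n)))
  kmax <- floor(m / 2)
  pw <- Mod(X[2L:(kmax + 1L)])^2
  freq <- (1L:kmax) / (m * p$dt)
  if (!is.null(detrend_window)) {
    # compensate the detrend filter's sloped gain across the band, which
    # would otherwise tilt the spectral peak toward shorter periods
    pw <- pw / detrend_gain(freq, detrend_window, p$dt)^2
  }
  periods <- 1 / freq
  in_band <- periods >= band[1L] & periods <= band[2L]
  if (!any(in_band)) stop("analysis band contains no spectral bins")
  ib <- which(in_band)
  peak <- ib[which.max(pw[ib])]
  # sub-bin refinement: quadratic interpolation of the spectral peak on the
  # (uniform) frequency grid
  f_peak <- freq[peak] + peak_offset(pw, peak) / (m * p$dt)
  list(period_min = 1 / f_peak,
       confidence = peak_power_fraction(pw, peak, pad_factor),
       periods = periods[ib], power = pw[ib])
}

# Fraction of total positive-frequency power within one unpadded resolution
# width (+/- pad_factor padded bins) of the peak. Padding-invariant: a pure
# tone concentrates its mainlobe here, white noise leaves ~2/n.
peak_power_fraction <- function(pw, k, pad_factor) {
  win <- max(1L, k - pad_factor):min(length(pw), k + pad_factor)
  sum(pw[win]) / sum(pw)
}

# Interior amplitude response of the moving-average detrend step
# (1 - Dirichlet kernel of the window), bounded away from 0.
detrend_gain <- function(freq, window, dt) {
  M <- 2L * max(1L, floor(window / dt / 2)) + 1L
  D <- sin(pi * freq * M * dt) / (M * sin(pi * freq * dt))
  pmax(abs(1 - D), 0.2)
}

# Vertex offset (in bins, clamped to [-0.5, 0.5]) of the parabola through a
# power peak and its two neighbors; 0 at the spectrum edges.
peak_offset <- function(pw, k) {
  if (k <= 1L || k >= length(pw)) return(0)
  denom <- pw[k - 1L] - 2 * pw[k] + pw[k + 1L]
  if (denom >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (pw[k - 1L] - pw[k + 1L]) / denom))
}

#' Per-pixel Fourier period map of a movie
#'
#' Applies [fourier_period()] to every pixel trace of an intensity movie,
#' producing a map of dominant periods with a per-pixel spectral confidence.
#' Pixels whose confidence falls below `conf_min` (e.g. noise-only pixels)
#' are flagged by setting their period to `NA`.
#'
#' @param movie an `intensity_movie`.
#' @param band,pad_factor see [fourier_period()].
#' @param detrend_window moving-average window applied per pixel, minutes.
#' @param conf_min confidence threshold below which a pixel is flagged.
#' @return a `period_map`: list with `period` and `confidence` matrices
#'   (movie pixel grid), `pixel_size`, `extent`.
#' @export
period_map <- function(movie, band = c(100, 220), pad_factor = 8,
                       detrend_window = 150, conf_min = 0.2) {
  stopifnot(inherits(movie, "intensity_movie"))
  d <- dim(movie$frames)
  n <- d[3L]
  dt <- movie$frame_interval
  if ((n - 1L) * dt < 2 * band[2L]) {
    stop("movie must span at least two cycles of the longest band period")
  }
  # vectorized over pixels: one padded FFT per pixel column
  X <- matrix(movie$frames, nrow = d[1L] * d[2L], ncol = n)
  half <- max(1L, floor(detrend_window / dt / 2))
  cs <- cbind(0, t(apply(X, 1L, cumsum)))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(X))
  X <- X - trend
  X <- X - rowMeans(X)
  m <- pad_factor * n
  sp <- stats::mvfft(t(cbind(X, matrix(0, nrow(X), m - n))))
  kmax <- floor(m / 2)
  pw <- Mod(sp[2L:(kmax + 1L), , drop = FALSE])^2
  freq_all <- (1L:kmax) / (m * dt)
  pw <- pw / detrend_gain(freq_all, detrend_window, dt)^2
  periods <- 1 / freq_all
  ib <- which(periods >= band[1L] & periods <= band[2L])
  pw_band <- pw[ib, , drop = FALSE]
  peak_in_band <- apply(pw_band, 2L, which.max)
  kpk <- ib[peak_in_band]  # index into the full positive-frequency grid
  off <- vapply(seq_along(kpk),
                function(j) peak_offset(pw[, j], kpk[j]), numeric(1L))
  peak_period <- 1 / ((kpk + off) / (m * dt))
  conf <- vapply(seq_along(kpk),
                 function(j) peak_power_fraction(pw[, j], kpk[j], pad_factor),
                 numeric(1L))
  per <- ifelse(conf >= conf_min, peak_period, NA_real_)
  structure(list(
    period = matrix(per, d[1L], d[2L]),
    confidence = matrix(conf, d[1L], d[2L]),
    pixel_size = movie$pixel_size, extent = movie$extent
  ), class = "period_map")
}

#' Time-averaged oscillation-amplitude map of a movie
#'
#' Per-pixel root-mean-square amplitude of the detrended pixel trace (scaled
#' so a pure cosine of amplitude A maps to A), optionally smoothed with a
#' small Gaussian kernel. Oscillating foci appear as smooth domes against the
#' noise floor, which makes this map the robust substrate for focus-center
#' detection with [detect_foci()].
#'
#' @param movie an `intensity_movie`.
#' @param detrend_window moving-average window per pixel, minutes.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (`0` = off).
#' @param time_range optional `c(from, to)` in minutes restricting the
#'   average to part of the record (e.g. a late window, where only focus
#'   cores still oscillate and the amplitude domes of neighboring foci no
#'   longer overlap).
#' @return numeric matrix (movie pixel grid) with `pixel_size` and `extent`
#'   attributes.
#' @export
amplitude_map <- function(movie, detrend_window = 150, smooth_sigma = 2,
                          time_range = NULL) {
  stopifnot(inherits(movie, "intensity_movie"))
  if (!is.null(time_range)) {
    keep <- movie$times >= time_range[1L] & movie$times <= time_range[2L]
    if (sum(keep) * movie$frame_interval < detrend_window) {
      stop("`time_range` shorter than the detrending window")
    }
    movie$frames <- movie$frames[, , keep, drop = FALSE]
    movie$times <- movie$times[keep]
  }
  d <- dim(movie$frames)
  n <- d[3L]
  dt <- movie$frame_interval
  X <- matrix(movie$frames, nrow = d[1L] * d[2L], ncol = n)
  half <- max(1L, floor(detrend_window / dt / 2))
  cs <- cbind(0, t(apply(X, 1L, cumsum)))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(X))
  X <- X - trend
  amp <- sqrt(2 * rowMeans(X^2))
  m <- matrix(amp, d[1L], d[2L])
  if (smooth_sigma > 0) m <- gaussian_blur(m, smooth_sigma)
  attr(m, "pixel_size") <- movie$pixel_size
  attr(m, "extent") <- movie$extent
  m
}

#' @export
print.period_map <- function(x, ...) {
  ok <- !is.na(x$period)
  cat(sprintf("Period map: %d x %d px, %d confident pixels (%.0f%%), periods %.0f-%.0f min\n",
              ncol(x$period), nrow(x$period), sum(ok),
              100 * mean(ok),
              if (any(ok)) min(x$period[ok]) else NA,
              if (any(ok)) max(x$period[ok]) else NA))
  invisible(x)
}

#' Write a period map as TIFF (period + confidence)
#'
#' @param pm a [period_map()] result.
#' @param path base path; writes `<path>` (period, minutes scaled to `[0,1]`
#'   by the band maximum in the sidecar) and `<path>.confidence.tif`.
#' @param band_max scale used to map periods to `[0,1]` in the TIFF.
#' @return `path` invisibly.
#' @export
write_period_map_tiff <- function(pm, path, band_max = 220) {
  per <- pm$period
  per[is.na(per)] <- 0
  tiff::writeTIFF(per / band_max, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  tiff::writeTIFF(pm$confidence, paste0(path, ".confidence.tif"),
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  jsonlite::write_json(list(scale = band_max, pixel_size = pm$pixel_size,
                            extent = pm$extent),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Kymograph along a polyline
#'
#' Samples a movie along a polyline (arc-length parameterized at one pixel
#' spacing), averaging across `line_width` pixels perpendicular to the line,
#' and stacks the profiles over time. Waves propagating along the line appear
#' as oblique stripes whose temporal spacing equals the oscillation period.
#'
#' @param movie an `intensity_movie`.
#' @param polyline two-column matrix of vertex coordinates, micrometers.
#' @param line_width averaging width in pixels.
#' @return a `kymograph`: matrix (arc-length sample x frame) with attributes
#'   `arc_um` (positions) and `times`.
#' @export
kymograph <- function(movie, polyline, line_width = 1) {
  stopifnot(inherits(movie, "intensity_movie"))
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least two vertices")
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) <= 0) stop("degenerate polyline")
  # resample at pixel_size spacing
  s_total <- sum(seg_len)
  s_at <- seq(0, s_total, by = movie$pixel_size)
  cum <- c(0, cumsum(seg_len))
  pts <- t(vapply(s_at, function(s) {
    k <- max(which(cum <= s + 1e-9)); k <- min(k, nrow(seg))
    f <- (s - cum[k]) / seg_len[k]
    polyline[k, ] + f * seg[k, ]
  }, numeric(2L)))
  d <- dim(movie$frames)
  xs <- movie$extent[1L] + (seq_len(d[2L]) - 0.5) * movie$pixel_size
  ys <- movie$extent[3L] + (seq_len(d[1L]) - 0.5) * movie$pixel_size
  rad <- max(line_width, 1) * movie$pixel_size / 2 + movie$pixel_size / 2
  out <- matrix(NA_real_, nrow(pts), d[3L])
  for (i in seq_len(nrow(pts))) {
    jx <- which(abs(xs - pts[i, 1L]) <= rad)
    jy <- which(abs(ys - pts[i, 2L]) <= rad)
    if (!length(jx) || !length(jy)) next
    out[i, ] <- apply(movie$frames[jy, jx, , drop = FALSE], 3L, mean)
  }
  structure(out, class = "kymograph", arc_um = s_at, times = movie$times)
}

#' Circular phase difference between two analytic traces
#'
#' Wrapped difference `phase(A) - phase(B)` in `(-pi, pi]` per time point.
#'
#' @param a,b `analytic_trace` objects (see [analytic_phase()]) on the same
#'   time base.
#' @return data frame with `time_min`, `diff_rad`, `valid` (both inputs
#'   valid).
#' @export
phase_difference <- function(a, b) {
  stopifnot(inherits(a, "analytic_trace"), inherits(b, "analytic_trace"))
  if (nrow(a) != nrow(b) || max(abs(a$time_min - b$time_min)) > 1e-6) {
    stop("traces must share a common time base")
  }
  data.frame(time_min = a$time_min,
             diff_rad = wrap_angle(a$phase_rad - b$phase_rad),
             valid = a$valid & b$valid)
}

#' Write an analytic trace as CSV
#'
#' @param at an `analytic_trace`.
#' @param path CSV path (columns `time_min`, `signal`, `phase_rad`,
#'   `period_min`, `amplitude`, `valid`).
#' @return `path` invisibly.
#' @export
write_analytic_csv <- function(at, path) {
  write.csv(as.data.frame(at), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.kymograph <- function(x, ...) {
  image(attr(x, "times"), attr(x, "arc_um"), t(unclass(x)),
        col = hcl.colors(64, "viridis"), xlab = "time (min)",
        ylab = "arc length (um)", useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.period_map <- function(x, ...) {
  xs <- x$extent[1L] + (seq_len(ncol(x$period)) - 0.5) * x$pixel_size
  ys <- x$extent[3L] + (seq_len(nrow(x$period)) - 0.5) * x$pixel_size
  image(xs, ys, t(x$period), col = hcl.colors(64, "plasma"),
        xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...)
  invisible(x)
}

#' Write a kymograph as TIFF
#'
#' @param ky a [kymograph()] result.
#' @param path TIFF path; values are scaled to `[0, 1]` by their maximum,
#'   recorded with the axes in a JSON sidecar (`<path>.meta.json`).
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(ky, path) {
  stopifnot(inherits(ky, "kymograph"))
  m <- unclass(ky)
  m[is.na(m)] <- 0
  scale <- max(m, 1e-12)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(scale = scale, arc_um = attr(ky, "arc_um"),
                            times = attr(ky, "times")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
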