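# Synthetic reporter imaging: renders phase trajectories into pixel movies
# emulating dynamic fluorescence time-lapse recordings, so the quantification
# stack can be exercised end-to-end against known ground truth.

#' Render a phase trajectory into a synthetic intensity movie
#'
#' Forward model of the reporter imaging: each cell contributes
#' `A_i(t) * (1 + cos(phi_i(t))) / 2` to the pixel containing it, on top of a
#' constant baseline, with optional additive Gaussian noise; intensities are
#' clipped at zero. Arrested cells decay exponentially with time constant
#' `arrest_tau`. No optics are modeled (no point-spread function, bleaching or
#' drift); an optional Gaussian blur can be applied with `blur_sigma`.
#'
#' @param trajectory a [simulate_oscillators()] result whose ensemble has
#'   positions.
#' @param amplitude scalar or per-cell oscillation amplitude (arbitrary
#'   units).
#' @param baseline constant background intensity.
#' @param noise_sd additive Gaussian noise standard deviation per pixel and
#'   frame.
#' @param pixel_size micrometers per pixel.
#' @param frame_interval minutes per frame (a multiple of the trajectory
#'   `dt`); the movie has `ceiling(t_end / frame_interval)` frames.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in micrometers; default
#'   is the ensemble bounding box padded by `2 * pixel_size`.
#' @param arrest_tau amplitude decay time constant after arrest, minutes.
#' @param blur_sigma optional Gaussian blur sigma in pixels (`0` = off).
#' @param seed integer seed for the noise stream.
#' @return an `intensity_movie`: list with `frames` (array `ny x nx x nt`),
#'   `times` (minutes), `pixel_size`, `frame_interval`, `extent`.
#' @export
render_movie <- function(trajectory, amplitude = 1, baseline = 0.1,
                         noise_sd = 0, pixel_size = 2, frame_interval = 10,
                         extent = NULL, arrest_tau = 60, blur_sigma = 0,
                         seed = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  ens <- trajectory$ensemble
  if (all(is.na(ens$pos_x_um))) {
    stop("trajectory ensemble has no positions; run assign_positions() first")
  }
  if (frame_interval < trajectory$dt) {
    stop("`frame_interval` must be >= the trajectory dt")
  }
  tr <- trajectory_traces(trajectory, frame_interval = frame_interval,
                          amplitude = amplitude, arrest_tau = arrest_tau)
  t_end <- max(trajectory$times)
  nt <- ceiling(t_end / frame_interval)
  times <- tr$times[seq_len(nt)]
  if (is.null(extent)) {
    pad <- 2 * pixel_size
    extent <- c(min(ens$pos_x_um) - pad, max(ens$pos_x_um) + pad,
                min(ens$pos_y_um) - pad, max(ens$pos_y_um) + pad)
  }
  nx <- max(1L, ceiling((extent[2L] - extent[1L]) / pixel_size))
  ny <- max(1L, ceiling((extent[4L] - extent[3L]) / pixel_size))
  px <- floor((ens$pos_x_um - extent[1L]) / pixel_size)
  py <- floor((ens$pos_y_um - extent[3L]) / pixel_size)
  inside <- px >= 0 & px < nx & py >= 0 & py < ny  # crop to the field of view
  lin <- as.integer(py * nx + px + 1L)  # row-major pixel index per cell

  if (!is.null(seed)) set.seed(substream_seed(seed, "imaging"))
  frames <- array(0, dim = c(ny, nx, nt))
  npx <- nx * ny
  for (k in seq_len(nt)) {
    fr <- numeric(npx)
    acc <- tapply(tr$intensity[k, inside], lin[inside], sum)
    fr[as.integer(names(acc))] <- acc
    m <- matrix(fr, nrow = ny, ncol = nx, byrow = TRUE)
    if (blur_sigma > 0) m <- gaussian_blur(m, blur_sigma)  # cell footprint
    m <- m + baseline
    if (noise_sd > 0) m <- m + matrix(rnorm(npx, sd = noise_sd), ny, nx)
    m[m < 0] <- 0
    frames[, , k] <- m
  }
  structure(list(frames = frames, times = times, pixel_size = pixel_size,
                 frame_interval = frame_interval, extent = extent),
            class = "intensity_movie")
}

# Separable Gaussian blur with reflected edges.
gaussian_blur <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -half:half, "+")
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    as.vector(matrix(v[idx], n) %*% k)
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

#' @export
print.intensity_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Intensity movie: %d x %d px (%g um/px), %d frames every %g min\n",
              d[2L], d[1L], x$pixel_size, d[3L], x$frame_interval))
  invisible(x)
}

#' Mean-intensity trace over a circular region of interest
#'
#' @param movie an [render_movie()] result (or one read back with
#'   [read_movie_tiff()]).
#' @param center ROI center `c(x, y)` in micrometers.
#' @param radius ROI radius in micrometers.
#' @return a `roi_trace`: data frame with `time_min`, `intensity`, carrying
#'   the ROI geometry as attributes.
#' @export
extract_roi_trace <- function(movie, center, radius) {
  stopifnot(inherits(movie, "intensity_movie"), length(center) == 2L,
            radius >= 0)
  d <- dim(movie$frames)
  xs <- movie$extent[1L] + (seq_len(d[2L]) - 0.5) * movie$pixel_size
  ys <- movie$extent[3L] + (seq_len(d[1L]) - 0.5) * movie$pixel_size
  inx <- outer(ys, xs, function(y, x) (x - center[1L])^2 + (y - center[2L])^2 <= radius^2)
  if (!any(inx)) stop("ROI does not intersect the movie extent")
  vals <- apply(movie$frames, 3L, function(f) mean(f[inx]))
  structure(data.frame(time_min = movie$times, intensity = vals),
            class = c("roi_trace", "data.frame"),
            center = center, radius = radius)
}

#' Write/read an intensity movie as multi-page TIFF
#'
#' Frames are stored as 32-bit grayscale pages. TIFF stores values in
#' `[0, 1]`, so intensities are scaled by their maximum; the scale and the
#' physical calibration (um/pixel, min/frame, extent) go to a JSON sidecar
#' (`<path>.meta.json`) and the round trip restores original units.
#'
#' @param movie an `intensity_movie`.
#' @param path TIFF file path.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns the reconstructed `intensity_movie`.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "intensity_movie"))
  scale <- max(movie$frames, 1e-12)
  pages <- lapply(seq_len(dim(movie$frames)[3L]),
                  function(k) movie$frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, pixel_size = movie$pixel_size,
         frame_interval = movie$frame_interval, extent = movie$extent,
         times = movie$times),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * meta$scale
  structure(list(frames = frames, times = meta$times,
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval, extent = meta$extent),
            class = "intensity_movie")
}

#' Write/read ROI traces as CSV
#'
#' @param traces a `roi_trace` or list of them.
#' @param path CSV path; columns `time_min`, `intensity`, `roi_id`.
#' @return `path` invisibly / a list of `roi_trace`.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "roi_trace")) traces <- list(traces)
  rows <- do.call(rbind, lapply(seq_along(traces), function(i) {
    cbind(as.data.frame(traces[[i]]), roi_id = i)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$roi_id), function(d) {
    structure(data.frame(time_min = d$time_min, intensity = d$intensity),
              class = c("roi_trace", "data.frame"))
  })
}

#' @export
plot.intensity_movie <- function(x, frame = 1L, ...) {
  xs <- x$extent[1L] + (seq_len(dim(x$frames)[2L]) - 0.5) * x$pixel_size
  ys <- x$extent[3L] + (seq_len(dim(x$frames)[1L]) - 0.5) * x$pixel_size
  image(xs, ys, t(x$frames[, , frame]), col = hcl.colors(64, "viridis"),
        xlab = "x (um)", ylab = "y (um)",
        main = sprintf("t = %g min", x$times[frame]), useRaster = TRUE, ...)
  invisible(x)
}
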