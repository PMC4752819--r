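# Randomized oscillator ensembles and spatial layouts emulating the
# dissociation / re-aggregation experiments: cells drawn from A/P regions of
# the period gradient, with controlled initial phase distributions, placed
# around hard-core-spaced foci.

#' Build a randomized oscillator ensemble from an A/P composition
#'
#' Emulates pooling dissociated PSM cells from one or more regions of the
#' anterior-posterior axis (a "titration mix"): each cell receives an axial
#' origin sampled uniformly within its source region, an intrinsic period from
#' the A/P period gradient at that origin, and an initial phase drawn from a
#' configurable window. Cell-sorter selection by reporter intensity is
#' modeled as a phase window (`"uniform"` reproduces an unsorted randomized
#' pool; a narrow window around 0 emulates peak-sorted cells, around `pi`
#' trough-sorted cells).
#'
#' @param composition list of components, each a `list(region =, fraction =,
#'   label =)`; `region` is a numeric `c(lo, hi)` sub-interval of the
#'   normalized A/P axis or a name understood by [ap_region()], and fractions
#'   must sum to 1. A single region (numeric or name) is accepted as
#'   shorthand for a 100% composition.
#' @param n number of cells.
#' @param phase_window `"uniform"` for phases uniform on the full circle, or
#'   a numeric `c(center, width)` in radians: phases drawn uniformly from
#'   `center +/- width/2` (width 0 gives identical phases).
#' @param model a [period_gradient_model()].
#' @param seed integer seed for reproducibility (optional).
#' @param periods optional numeric vector of length `n` of intrinsic periods,
#'   overriding the gradient draw (used to give physically separated
#'   aggregates an identical frequency distribution).
#' @return an `oscillator_ensemble`: a data frame with columns `cell_id`,
#'   `phase_rad` (in `[0, 2*pi)`), `period_min`, `origin_x`, `pos_x_um`,
#'   `pos_y_um` (NA until [assign_positions()]), `label`, carrying the
#'   gradient model as an attribute.
#' @examples
#' ens <- build_mixture(list(list(region = "P/2", fraction = 0.5),
#'                           list(region = "A/2", fraction = 0.5)),
#'                      n = 100, seed = 1)
#' mean(ens$period_min) # close to 150
#' @export
build_mixture <- function(composition, n, phase_window = "uniform",
                          model = period_gradient_model(), seed = NULL,
                          periods = NULL) {
  stopifnot(n >= 1)
  if (!is.list(composition) || !is.null(composition$region)) {
    composition <- list(list(region = composition, fraction = 1))
  }
  comp <- lapply(composition, function(cc) {
    list(region = ap_region(cc$region),
         fraction = cc$fraction %||% 1,
         label = cc$label %||% region_label(ap_region(cc$region)))
  })
  fr <- vapply(comp, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("composition fractions must sum to 1 (tolerance 1e-9)")
  }
  if (!is.null(seed)) set.seed(substream_seed(seed, "ensemble"))

  # largest-remainder apportionment of n cells to components
  counts <- floor(fr * n)
  rem <- fr * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
  }

  origin <- numeric(0); label <- character(0)
  for (k in seq_along(comp)) {
    if (counts[k] == 0) next
    r <- comp[[k]]$region
    origin <- c(origin, runif(counts[k], r[1L], r[2L]))
    label <- c(label, rep(comp[[k]]$label, counts[k]))
  }

  if (is.null(periods)) {
    periods <- period_gradient(origin, model)
  } else {
    stopifnot(length(periods) == n)
  }

  if (identical(phase_window, "uniform")) {
    phase <- runif(n, 0, 2 * pi)
  } else {
    stopifnot(is.numeric(phase_window), length(phase_window) == 2L,
              phase_window[2L] >= 0)
    phase <- wrap_2pi(phase_window[1L] +
                        runif(n, -phase_window[2L] / 2, phase_window[2L] / 2))
  }

  out <- data.frame(
    cell_id = seq_len(n),
    phase_rad = wrap_2pi(phase),
    period_min = periods,
    origin_x = origin,
    pos_x_um = NA_real_,
    pos_y_um = NA_real_,
    label = label,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("oscillator_ensemble", "data.frame"),
            gradient = model)
}

region_label <- function(region) {
  if (isTRUE(all.equal(region, REGION_P2))) return("P/2")
  if (isTRUE(all.equal(region, REGION_A2))) return("A/2")
  if (isTRUE(all.equal(region, REGION_TAILBUD))) return("tailbud")
  if (isTRUE(all.equal(region, REGION_FULL))) return("PSM")
  sprintf("[%.2f,%.2f]", region[1L], region[2L])
}

#' @export
print.oscillator_ensemble <- function(x, ...) {
  cat(sprintf("Oscillator ensemble: %d cells, periods %.1f-%.1f min (mean %.1f)\n",
              nrow(x), min(x$period_min), max(x$period_min), mean(x$period_min)))
  for (l in unique(x$label)) {
    cat(sprintf("  %-10s %d cells\n", l, sum(x$label == l)))
  }
  if (!all(is.na(x$pos_x_um))) cat("  positions assigned\n")
  invisible(x)
}

#' Hard-core placement of wave-emitting foci
#'
#' Lays out focus centers in a rectangular culture area by random sequential
#' adsorption (RSA): candidate points are drawn uniformly and accepted only if
#' at least `r_min` away from every accepted point. This imposes the
#' phenomenological intrinsic length scale of foci spacing (minimum
#' nearest-neighbor distance around 100 um at a density of ~16.5 foci per
#' square millimeter) without modeling its mechanism.
#'
#' @param density expected foci per square millimeter; the realized count is
#'   `round(density * area)`. Ignored when `n` is given.
#' @param area numeric `c(width, height)` of the culture region in
#'   micrometers.
#' @param r_min hard-core exclusion radius, micrometers (`0` gives a uniform
#'   binomial point pattern).
#' @param n optional explicit number of foci.
#' @param seed integer seed (optional).
#' @param max_tries proposals allowed per point before the packing is deemed
#'   infeasible.
#' @return a `foci_set`: a data frame with columns `focus_id`, `x_um`,
#'   `y_um`, carrying `area` (um), `area_mm2` and `r_min` as attributes.
#' @examples
#' f <- place_foci(density = 16.5, area = c(2000, 2000), r_min = 100, seed = 1)
#' min(nn_distances(f)) >= 100
#' @export
place_foci <- function(density = 16.5, area = c(2000, 2000), r_min = 100,
                       n = NULL, seed = NULL, max_tries = 1e4) {
  stopifnot(length(area) == 2L, all(area > 0), r_min >= 0)
  area_mm2 <- prod(area) / 1e6
  if (is.null(n)) n <- round(density * area_mm2)
  if (n < 0) stop("focus count must be non-negative")
  if (!is.null(seed)) set.seed(substream_seed(seed, "foci"))

  xy <- matrix(NA_real_, nrow = n, ncol = 2L)
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, 0, area[1L]), runif(1, 0, area[2L]))
      if (placed == 0L ||
          min((xy[seq_len(placed), 1L] - p[1L])^2 +
              (xy[seq_len(placed), 2L] - p[2L])^2) >= r_min^2) {
        placed <- placed + 1L
        xy[placed, ] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "hard-core packing infeasible: placed %d of %d foci (r_min = %g um) after %d proposals",
        placed, n, r_min, max_tries))
    }
  }
  foci_set(xy[, 1L], xy[, 2L], area = area, r_min = r_min)
}

#' Construct a foci set from coordinates
#'
#' @param x,y focus center coordinates, micrometers.
#' @param area numeric `c(width, height)` of the region, micrometers.
#' @param r_min exclusion radius used at generation, if any.
#' @return a `foci_set` data frame.
#' @export
foci_set <- function(x, y, area, r_min = NA_real_) {
  stopifnot(length(x) == length(y), length(area) == 2L)
  structure(
    data.frame(focus_id = seq_along(x), x_um = x, y_um = y),
    class = c("foci_set", "data.frame"),
    area = area, area_mm2 = prod(area) / 1e6, r_min = r_min
  )
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("Foci set: %d centers in %.3g x %.3g um (%.3g mm^2), density %.3g / mm^2\n",
              nrow(x), attr(x, "area")[1L], attr(x, "area")[2L],
              attr(x, "area_mm2"), nrow(x) / attr(x, "area_mm2")))
  if (is.finite(attr(x, "r_min"))) {
    cat(sprintf("  hard-core exclusion radius: %g um\n", attr(x, "r_min")))
  }
  invisible(x)
}

#' Place ensemble cells around foci with an optional origin-sorting bias
#'
#' Distributes cells of an ensemble among foci and assigns each a position at
#' a random angle and a radial distance from its focus center. With
#' `sorting_bias = 0` radial placement is independent of axial origin; with
#' increasing bias, cells of more anterior origin are placed at systematically
#' larger radii, emulating the sorting of posterior cells toward focus centers
#' and anterior cells toward the periphery. The bias is phenomenological:
#' radii drawn for a focus are reassigned to its cells in the order of
#' `(1 - bias) * U + bias * rank(origin)` so that `bias = 1` rank-orders radii
#' by origin exactly.
#'
#' @param ensemble an [build_mixture()] ensemble.
#' @param foci a [place_foci()] layout (non-empty).
#' @param sorting_bias number in `[0, 1]`.
#' @param r_focus focus radius, micrometers: cells are placed uniformly over a
#'   disk of this radius (before bias reordering).
#' @param seed integer seed (optional).
#' @return the ensemble with `pos_x_um`, `pos_y_um` filled in and extra
#'   columns `focus_id` and `radius_um` (distance to assigned focus center).
#' @export
assign_positions <- function(ensemble, foci, sorting_bias = 0, r_focus = 60,
                             seed = NULL) {
  stopifnot(inherits(ensemble, "oscillator_ensemble"),
            inherits(foci, "foci_set"), nrow(foci) >= 1L,
            sorting_bias >= 0, sorting_bias <= 1, r_focus > 0)
  if (!is.null(seed)) set.seed(substream_seed(seed, "positions"))
  n <- nrow(ensemble)
  fid <- sample.int(nrow(foci), n, replace = TRUE)
  radius <- numeric(n)
  for (f in unique(fid)) {
    idx <- which(fid == f)
    r <- r_focus * sqrt(runif(length(idx)))  # uniform over the disk
    if (sorting_bias > 0 && length(idx) > 1L) {
      key <- (1 - sorting_bias) * runif(length(idx)) +
        sorting_bias * (rank(ensemble$origin_x[idx], ties.method = "first") /
                          length(idx))
      radius[idx[order(key)]] <- sort(r)
    } else {
      radius[idx] <- r
    }
  }
  theta <- runif(n, 0, 2 * pi)
  ensemble$pos_x_um <- foci$x_um[fid] + radius * cos(theta)
  ensemble$pos_y_um <- foci$y_um[fid] + radius * sin(theta)
  ensemble$focus_id <- fid
  ensemble$radius_um <- radius
  attr(ensemble, "foci") <- foci
  attr(ensemble, "r_focus") <- r_focus
  ensemble
}

#' Read/write ensembles and foci as CSV
#'
#' Ensembles serialize to CSV with columns `cell_id`, `phase_rad`,
#' `period_min`, `origin_x`, `pos_x_um`, `pos_y_um`, `label` (plus
#' `focus_id`/`radius_um` when positions are assigned). Foci serialize to a
#' CSV of `focus_id`, `x_um`, `y_um` with a JSON sidecar
#' (`<path>.meta.json`) holding area and exclusion-radius metadata.
#'
#' @param x object to write.
#' @param path file path.
#' @return `read_*` return the reconstructed object; `write_*` return `path`
#'   invisibly.
#' @export
write_ensemble_csv <- function(x, path) {
  stopifnot(inherits(x, "oscillator_ensemble"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("oscillator_ensemble", "data.frame"))
}

#' @rdname write_ensemble_csv
#' @export
write_foci_csv <- function(x, path) {
  stopifnot(inherits(x, "foci_set"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(
    list(area_um = attr(x, "area"), area_mm2 = attr(x, "area_mm2"),
         r_min = attr(x, "r_min")),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_foci_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    foci_set(df$x_um, df$y_um, area = meta$area_um,
             r_min = meta$r_min %||% NA_real_)
  } else {
    foci_set(df$x_um, df$y_um,
             area = c(max(df$x_um), max(df$y_um)))
  }
}
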