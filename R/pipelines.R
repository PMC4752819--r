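# End-to-end reproductions of the experiment classes: randomization,
# coupling-inhibition (DAPT), phase-sorted (FACS) aggregates, titration
# mixes, and labeled sub-population tracking. All pipelines are driven by a
# nested configuration (YAML-serializable) and a single master seed.

#' Experiment configuration
#'
#' Builds the nested configuration driving the experiment pipelines, merging
#' user overrides into the package defaults. The configuration is plain-list /
#' YAML-serializable and is hashed into every report for provenance.
#'
#' @param ... named overrides of the default sections (`gradient`,
#'   `coupling`, `slowing`, `foci`, `simulate`, `imaging`, `analysis`), each
#'   a list replacing matching fields.
#' @return an `experiment_config` list.
#' @examples
#' cfg <- experiment_config(coupling = list(K = 0.2))
#' cfg$coupling$K
#' @export
experiment_config <- function(...) {
  defaults <- list(
    gradient = list(T_posterior = 130, T_anterior = 170),
    coupling = list(K = 0.1, topology = "mean-field", radius = 30),
    slowing = list(s_max = 30 / 720, r_focus = 60, arrest_period = 200),
    foci = list(density = 16.5, area = c(800, 800), r_min = 100),
    simulate = list(t_end = 1440, dt = 0.5, phase_noise = 0),
    imaging = list(pixel_size = 4, frame_interval = 10, baseline = 0.1,
                   noise_sd = 0.02, amplitude = 1, arrest_tau = 60,
                   blur_sigma = 1.5),
    analysis = list(band = c(100, 220), pad_factor = 8, detrend_window = 150,
                    conf_min = 0.2, measure_fraction = 2 / 3, edge = 110)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  for (sec in names(over)) {
    stopifnot(is.list(over[[sec]]))
    for (f in names(over[[sec]])) defaults[[sec]][[f]] <- over[[sec]][[f]]
  }
  structure(defaults, class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file with (a subset of) the configuration sections.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' @rdname experiment_config
#' @param config an `experiment_config` to write.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

cfg_gradient <- function(config) {
  period_gradient_model(config$gradient$T_posterior, config$gradient$T_anterior)
}
cfg_coupling <- function(config, K = NULL) {
  coupling_config(K = K %||% config$coupling$K,
                  topology = config$coupling$topology,
                  radius = config$coupling$radius)
}
cfg_slowing <- function(config) {
  slowing_profile(config$slowing$s_max, config$slowing$r_focus,
                  config$slowing$arrest_period)
}

new_report <- function(kind, config, seed, measurements, flags = character(0)) {
  structure(list(kind = kind, seed = seed, config_hash = config_hash(config),
                 config = config, measurements = measurements, flags = flags),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %s (seed %s, config %s)\n",
              x$kind, format(x$seed), x$config_hash))
  m <- x$measurements
  for (nm in names(m)) {
    v <- m[[nm]]
    if (is.data.frame(v)) {
      cat(sprintf("  %s:\n", nm)); print(v, row.names = FALSE)
    } else if (is.numeric(v) && length(v) <= 4L) {
      cat(sprintf("  %s: %s\n", nm, paste(signif(v, 4), collapse = ", ")))
    }
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Write an experiment report to JSON (+ Markdown summary)
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed); files are named
#'   `<kind>_<confighash>.json` / `.md`.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(report$kind, "_", report$config_hash))
  out <- report
  out$config <- unclass(out$config)
  jsonlite::write_json(out[c("kind", "seed", "config_hash", "measurements",
                             "flags", "config")],
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  md <- c(sprintf("# %s experiment (seed %s)", report$kind, format(report$seed)),
          sprintf("- config hash: `%s`", report$config_hash),
          vapply(names(report$measurements), function(nm) {
            v <- report$measurements[[nm]]
            if (is.numeric(v) && length(v) <= 6L) {
              sprintf("- %s: %s", nm, paste(signif(v, 5), collapse = ", "))
            } else sprintf("- %s: (%s)", nm, class(v)[1L])
          }, character(1L)))
  writeLines(md, paste0(base, ".md"))
  invisible(paste0(base, ".json"))
}

#' Predicted collective period of a titration composition
#'
#' The collective frequency reached after synchronization is set by the whole
#' ensemble of input oscillators; the predicted collective period is the
#' composition-weighted arithmetic mean of the per-region mean input periods.
#' Under the default linear 130-170 min gradient: 100% posterior-half cells
#' predict 140 min, a balanced mixture 150 min, 100% anterior-half 160 min.
#'
#' @param composition list of `list(region =, fraction =)` with fractions
#'   summing to 1 (region names as in [ap_region()]), or a single region.
#' @param model a [period_gradient_model()].
#' @return predicted collective period, minutes.
#' @examples
#' predict_collective_period(list(list(region = "P/2", fraction = 1))) # 140
#' @export
predict_collective_period <- function(composition,
                                      model = period_gradient_model()) {
  if (!is.list(composition) || !is.null(composition$region)) {
    composition <- list(list(region = composition, fraction = 1))
  }
  fr <- vapply(composition, function(cc) cc$fraction %||% 1, numeric(1L))
  if (abs(sum(fr) - 1) > 1e-9) stop("composition fractions must sum to 1")
  mp <- vapply(composition,
               function(cc) region_mean_period(ap_region(cc$region), model),
               numeric(1L))
  sum(fr * mp)
}

p2_composition <- function(frac_p2) {
  comp <- list()
  if (frac_p2 > 0) comp <- c(comp, list(list(region = "P/2", fraction = frac_p2)))
  if (frac_p2 < 1) comp <- c(comp, list(list(region = "A/2", fraction = 1 - frac_p2)))
  comp
}

# Mean reporter trace of a trajectory (optionally a cell subset), measured on
# the final `fraction` of the record: detrended population-mean intensity,
# dominant Fourier period, and the order-parameter plateau.
measure_collective_period <- function(trajectory, config, cells = NULL) {
  an <- config$analysis
  tr <- trajectory_traces(trajectory,
                          frame_interval = config$imaging$frame_interval,
                          amplitude = config$imaging$amplitude,
                          arrest_tau = config$imaging$arrest_tau)
  keep <- tr$times >= (1 - an$measure_fraction) * max(tr$times)
  cells <- cells %||% seq_len(ncol(tr$intensity))
  mean_trace <- rowMeans(tr$intensity[keep, cells, drop = FALSE])
  fp <- fourier_period(data.frame(time_min = tr$times[keep],
                                  intensity = mean_trace),
                       band = an$band, pad_factor = an$pad_factor,
                       detrend_window = an$detrend_window)
  idx <- trajectory$times >= (1 - an$measure_fraction) * max(trajectory$times)
  Rp <- mean(Mod(rowMeans(exp(1i * trajectory$phases[idx, cells, drop = FALSE]))))
  list(period_min = fp$period_min, confidence = fp$confidence, R_plateau = Rp)
}

#' Titration experiment: collective period vs input composition
#'
#' Builds ensembles containing a given fraction of posterior-half ("P/2",
#' fast) cells topped up with anterior-half ("A/2", slow) cells, simulates
#' them to synchronization, and measures the collective period from the
#' population-mean reporter trace over the final part of the record,
#' comparing it with the arithmetic-mean prediction. Runs that fail to lock
#' (order-parameter plateau below `lock_R`) are flagged.
#'
#' @param fractions P/2 fractions to titrate.
#' @param n cells per ensemble.
#' @param n_seeds replicate simulations per fraction.
#' @param seed master seed.
#' @param config an [experiment_config()].
#' @param lock_R locking threshold on the order-parameter plateau.
#' @return an `experiment_report`; `measurements$titration` has one row per
#'   fraction with `predicted_min`, `measured_min` (mean over seeds),
#'   `measured_sd`, `R_plateau`, `locked`.
#' @export
run_titration <- function(fractions = c(1, 0.8, 0.5, 0.2), n = 200,
                          n_seeds = 10, seed = 1,
                          config = experiment_config(), lock_R = 0.9) {
  model <- cfg_gradient(config)
  rows <- lapply(fractions, function(fp) {
    comp <- p2_composition(fp)
    pred <- predict_collective_period(comp, model)
    per <- numeric(n_seeds); Rp <- numeric(n_seeds)
    for (r in seq_len(n_seeds)) {
      ens <- build_mixture(comp, n = n, model = model,
                           seed = substream_seed(seed, "titration", r * 1000 + round(fp * 100)))
      trj <- simulate_oscillators(ens, cfg_coupling(config), slowing = NULL,
                                  t_end = config$simulate$t_end,
                                  dt = config$simulate$dt,
                                  phase_noise = config$simulate$phase_noise,
                                  seed = substream_seed(seed, "titration-dyn", r))
      m <- measure_collective_period(trj, config)
      per[r] <- m$period_min; Rp[r] <- m$R_plateau
    }
    data.frame(fraction_p2 = fp, predicted_min = pred,
               measured_min = mean(per), measured_sd = sd(per),
               R_plateau = mean(Rp), locked = all(Rp >= lock_R))
  })
  tab <- do.call(rbind, rows)
  flags <- if (all(tab$locked)) character(0) else
    sprintf("unlocked fractions: %s",
            paste(tab$fraction_p2[!tab$locked], collapse = ", "))
  new_report("titration", config, seed,
             list(titration = tab, n = n, n_seeds = n_seeds), flags)
}

#' Phase-sorted (FACS) experiment: anti-phase memory
#'
#' Emulates sorting a randomized cell pool by reporter intensity into peak-
#' and trough-phase populations (phase windows of width `window_width`
#' centered at 0 and `pi`), then running the two populations in physically
#' separate aggregates drawn from the same frequency distribution. Each
#' aggregate synchronizes internally; because the aggregates share the input
#' frequency pool, their collective rhythms keep the initial phase offset:
#' the circular-mean phase difference between the two mean-signal Hilbert
#' phases stays close to `pi`.
#'
#' @param n cells per aggregate.
#' @param window_width phase window width, radians.
#' @param t_end simulated time, minutes (default 12 h).
#' @param seed master seed.
#' @param config an [experiment_config()].
#' @return an `experiment_report` with `measurements$phase_diff_mean`
#'   (circular mean of the wrapped difference over the valid window, rad),
#'   `phase_diff_drift` (difference between last and first valid wrapped
#'   difference), and the difference time series.
#' @export
run_sorted_phase_experiment <- function(n = 200, window_width = pi / 2,
                                        t_end = 720, seed = 1,
                                        config = experiment_config()) {
  if (window_width > pi / 2 + 1e-9) {
    warning("phase windows wider than pi/2 overlap substantially; anti-phase memory degrades")
  }
  model <- cfg_gradient(config)
  # one frequency-pool draw shared by both sorted populations
  pool <- build_mixture("PSM", n = n, model = model,
                        seed = substream_seed(seed, "sorted-pool"))
  mk <- function(center, stream) {
    build_mixture("PSM", n = n, phase_window = c(center, window_width),
                  model = model, seed = substream_seed(seed, stream),
                  periods = pool$period_min)
  }
  peak <- mk(0, "sorted-peak")
  trough <- mk(pi, "sorted-trough")
  sim <- function(ens, stream) {
    simulate_oscillators(ens, cfg_coupling(config), slowing = NULL,
                         t_end = t_end, dt = config$simulate$dt,
                         phase_noise = config$simulate$phase_noise,
                         seed = substream_seed(seed, stream))
  }
  trjA <- sim(peak, "sorted-dynA")
  trjB <- sim(trough, "sorted-dynB")
  an <- config$analysis
  mean_analytic <- function(trj) {
    tr <- trajectory_traces(trj, frame_interval = config$imaging$frame_interval)
    det <- detrend_trace(data.frame(time_min = tr$times,
                                    intensity = rowMeans(tr$intensity)),
                         window = an$detrend_window)
    analytic_phase(det, edge = an$edge)
  }
  pd <- phase_difference(mean_analytic(trjA), mean_analytic(trjB))
  ok <- pd$valid
  diff_mean <- circular_mean(pd$diff_rad[ok])
  drift <- wrap_angle(pd$diff_rad[ok][sum(ok)] - pd$diff_rad[ok][1L])
  new_report("sorted_phase", config, seed, list(
    phase_diff_mean = diff_mean,
    phase_diff_abs = abs(diff_mean),
    phase_diff_drift = drift,
    series = pd
  ))
}

#' Physically separated aggregates from one randomized pool
#'
#' Several aggregates share one random draw of the input phase/frequency
#' pool and are simulated with no inter-aggregate coupling (each with its
#' own dynamics-noise realization). Because the collective rhythm of an
#' aggregate is determined by the statistics of its input pool, aggregates
#' seeded from the same pool draw lock onto the same rhythm and stay
#' pairwise in phase even though they never interact. (Disjoint sub-samples
#' of a phase-uniform pool would not: the collective phase of a large
#' uniform sample is essentially random, so a shared rhythm across separate
#' cultures is only reproducible under a shared pool draw.)
#'
#' @param n_aggregates number of separately simulated aggregates.
#' @param n cells per aggregate.
#' @param t_end simulated time, minutes.
#' @param seed master seed.
#' @param config an [experiment_config()]; `simulate$phase_noise` gives each
#'   aggregate independent stochastic dynamics.
#' @return an `experiment_report` with the pairwise circular-mean phase
#'   differences (`pairwise_diff_rad`) and their maximum absolute value.
#' @export
run_separated_aggregates <- function(n_aggregates = 5, n = 200, t_end = 720,
                                     seed = 1, config = experiment_config()) {
  model <- cfg_gradient(config)
  ens <- build_mixture("PSM", n = n, model = model,
                       seed = substream_seed(seed, "aggregate-pool"))
  an <- config$analysis
  traces <- vector("list", n_aggregates)
  for (a in seq_len(n_aggregates)) {
    trj <- simulate_oscillators(ens, cfg_coupling(config), slowing = NULL,
                                t_end = t_end, dt = config$simulate$dt,
                                phase_noise = config$simulate$phase_noise,
                                seed = substream_seed(seed, "aggregate-dyn", a))
    tr <- trajectory_traces(trj, frame_interval = config$imaging$frame_interval)
    det <- detrend_trace(data.frame(time_min = tr$times,
                                    intensity = rowMeans(tr$intensity)),
                         window = an$detrend_window)
    traces[[a]] <- analytic_phase(det, edge = an$edge)
  }
  pairs <- utils::combn(n_aggregates, 2L)
  diffs <- apply(pairs, 2L, function(pr) {
    pd <- phase_difference(traces[[pr[1L]]], traces[[pr[2L]]])
    circular_mean(pd$diff_rad[pd$valid])
  })
  new_report("separated_aggregates", config, seed, list(
    pairwise_diff_rad = diffs,
    max_abs_diff = max(abs(diffs)),
    n_aggregates = n_aggregates
  ))
}

#' Labeled sub-population tracking experiment
#'
#' A small labeled population from one A/P region (by default anterior-half
#' cells, about one-eighth of the ensemble) is mixed into a bulk population
#' from another region (by default tail-bud cells). Periods of each
#' sub-population are recorded before coupling (intrinsic input means) and
#' measured after locking (Fourier period of each sub-population's mean
#' trace), to show that both converge on a common collective period — the
#' labeled slow cells accelerating and the fast bulk slowing down.
#'
#' @param label_fraction fraction of labeled cells, in (0, 1).
#' @param label_region,bulk_region regions for [ap_region()].
#' @param n total cells.
#' @param seed master seed.
#' @param config an [experiment_config()].
#' @param lock_R locking threshold on the order-parameter plateau.
#' @return an `experiment_report`; `measurements$populations` has per-
#'   population input and measured periods plus the direction of change;
#'   `weighted_mean_input_min` is the cell-number-weighted mean input period.
#' @export
run_tracking_experiment <- function(label_fraction = 1 / 8,
                                    label_region = "A/2",
                                    bulk_region = "tailbud",
                                    n = 200, seed = 1,
                                    config = experiment_config(),
                                    lock_R = 0.9) {
  stopifnot(label_fraction > 0, label_fraction < 1)
  model <- cfg_gradient(config)
  comp <- list(
    list(region = label_region, fraction = label_fraction, label = "labeled"),
    list(region = bulk_region, fraction = 1 - label_fraction, label = "bulk")
  )
  ens <- build_mixture(comp, n = n, model = model,
                       seed = substream_seed(seed, "tracking"))
  trj <- simulate_oscillators(ens, cfg_coupling(config), slowing = NULL,
                              t_end = config$simulate$t_end,
                              dt = config$simulate$dt,
                              seed = substream_seed(seed, "tracking-dyn"))
  lab <- which(ens$label == "labeled"); blk <- which(ens$label == "bulk")
  m_lab <- measure_collective_period(trj, config, cells = lab)
  m_blk <- measure_collective_period(trj, config, cells = blk)
  pops <- data.frame(
    population = c("labeled", "bulk"),
    input_min = c(mean(ens$period_min[lab]), mean(ens$period_min[blk])),
    measured_min = c(m_lab$period_min, m_blk$period_min)
  )
  pops$change <- ifelse(pops$measured_min < pops$input_min,
                        "accelerated", "slowed")
  Rp <- min(m_lab$R_plateau, m_blk$R_plateau)
  flags <- if (Rp < lock_R) "failed to lock" else character(0)
  new_report("tracking", config, seed, list(
    populations = pops,
    common_period_gap_min = abs(diff(pops$measured_min)),
    weighted_mean_input_min = mean(ens$period_min),
    R_plateau = Rp
  ), flags)
}

#' Coupling-inhibition (DAPT) experiment
#'
#' Paired runs from the same randomized ensemble draw: a control with
#' coupling on and a Notch-inhibited condition modeled as zero coupling.
#' Reports the collective-amplitude time courses (low throughout without
#' coupling, rising in the control), the single-cell Hilbert amplitude
#' distributions (preserved under inhibition: cells keep oscillating, only
#' synchrony is lost), and hard-core foci-spacing statistics for both
#' conditions (foci placement is imposed independently of coupling, so the
#' spatial arrangement is unchanged).
#'
#' @param n cells.
#' @param seed master seed.
#' @param config an [experiment_config()].
#' @param spacing_area field size (micrometers) for the foci-spacing
#'   comparison; a full-size field gives the KS tests adequate power
#'   (defaults to 2 x 2 mm, ~66 foci per condition).
#' @return an `experiment_report` with `collective` (time courses for both
#'   conditions), `plateau_ratio` (inhibited / control collective-amplitude
#'   plateau), `single_cell_amplitude` (per-condition medians), and
#'   `spacing` (per-condition spacing stats + KS comparison).
#' @export
run_dapt_experiment <- function(n = 200, seed = 1,
                                config = experiment_config(),
                                spacing_area = c(2000, 2000)) {
  model <- cfg_gradient(config)
  ens <- build_mixture("PSM", n = n, model = model,
                       seed = substream_seed(seed, "dapt"))
  an <- config$analysis
  run_one <- function(K, stream) {
    trj <- simulate_oscillators(ens, cfg_coupling(config, K = K),
                                slowing = NULL,
                                t_end = config$simulate$t_end,
                                dt = config$simulate$dt,
                                phase_noise = config$simulate$phase_noise,
                                seed = substream_seed(seed, stream))
    tr <- trajectory_traces(trj, frame_interval = config$imaging$frame_interval)
    ca <- collective_amplitude(tr$intensity, times = tr$times,
                               window = an$detrend_window, edge = an$edge)
    amps <- apply(tr$intensity, 2L, function(v) {
      at <- analytic_phase(detrend_trace(
        data.frame(time_min = tr$times, intensity = v),
        window = an$detrend_window), edge = an$edge)
      median(at$amplitude[at$valid])
    })
    plateau <- mean(ca$amplitude[ca$valid &
                                   ca$time_min >= 2 / 3 * max(ca$time_min)])
    list(ca = ca, amps = amps, plateau = plateau)
  }
  control <- run_one(config$coupling$K, "dapt-control")
  dapt <- run_one(0, "dapt-inhibited")

  layout_ctrl <- place_foci(config$foci$density, spacing_area,
                            config$foci$r_min,
                            seed = substream_seed(seed, "dapt-foci-ctrl"))
  layout_dapt <- place_foci(config$foci$density, spacing_area,
                            config$foci$r_min,
                            seed = substream_seed(seed, "dapt-foci-dapt"))
  ks_between <- ks_nonrandomness_test(nn_distances(layout_ctrl),
                                      nn_distances(layout_dapt))
  new_report("dapt", config, seed, list(
    collective = data.frame(time_min = control$ca$time_min,
                            control = control$ca$amplitude,
                            inhibited = dapt$ca$amplitude,
                            valid = control$ca$valid),
    plateau_control = control$plateau,
    plateau_inhibited = dapt$plateau,
    plateau_ratio = dapt$plateau / control$plateau,
    single_cell_amplitude = c(control = median(control$amps),
                              inhibited = median(dapt$amps)),
    spacing = list(
      control = spacing_stats(layout_ctrl,
                              seed = substream_seed(seed, "dapt-null-c")),
      inhibited = spacing_stats(layout_dapt,
                                seed = substream_seed(seed, "dapt-null-d")),
      ks_between_D = ks_between$D, ks_between_p = ks_between$p_value
    )
  ))
}

#' Full randomization experiment
#'
#' The complete pipeline emulating dissociation / re-aggregation: build a
#' randomized ensemble, lay out hard-core foci, place cells around them,
#' simulate locally coupled dynamics with peripheral slowing and arrest,
#' render a synthetic reporter movie, compute the per-pixel period map,
#' detect foci on it, compare their spacing against a simulated random null,
#' and quantify center-vs-periphery period time courses plus a kymograph
#' through two foci.
#'
#' @param composition input composition ("PSM" for the whole axis or
#'   "tailbud" for posterior-only re-aggregation; any [ap_region()] input or
#'   composition list).
#' @param n cells.
#' @param seed master seed.
#' @param config an [experiment_config()]; the spatial run uses
#'   radius-topology coupling regardless of the config topology.
#' @param keep_movie keep the rendered movie in the report (large).
#' @return an `experiment_report` with the detected `foci`, `spacing`
#'   statistics (vs random null), `density_mm2`, `center_period` /
#'   `periphery_period` time courses (Hilbert instantaneous period averaged
#'   over foci), a period-map radial summary, and the kymograph.
#' @export
run_randomization_experiment <- function(composition = "PSM", n = 1600,
                                         seed = 1,
                                         config = experiment_config(),
                                         keep_movie = FALSE) {
  model <- cfg_gradient(config)
  ens <- build_mixture(composition, n = n, model = model,
                       seed = substream_seed(seed, "randomization"))
  layout <- place_foci(config$foci$density, config$foci$area,
                       config$foci$r_min,
                       seed = substream_seed(seed, "randomization-foci"))
  ens <- assign_positions(ens, layout, sorting_bias = 0,
                          r_focus = config$slowing$r_focus,
                          seed = substream_seed(seed, "randomization-pos"))
  coup <- coupling_config(K = config$coupling$K, topology = "radius",
                          radius = config$coupling$radius)
  trj <- simulate_oscillators(ens, coup, slowing = cfg_slowing(config),
                              t_end = config$simulate$t_end,
                              dt = config$simulate$dt,
                              phase_noise = config$simulate$phase_noise,
                              seed = substream_seed(seed, "randomization-dyn"))
  img <- config$imaging
  movie <- render_movie(trj, amplitude = img$amplitude,
                        baseline = img$baseline, noise_sd = img$noise_sd,
                        pixel_size = img$pixel_size,
                        frame_interval = img$frame_interval,
                        extent = c(0, config$foci$area[1L],
                                   0, config$foci$area[2L]),
                        arrest_tau = img$arrest_tau,
                        blur_sigma = img$blur_sigma %||% 0,
                        seed = substream_seed(seed, "randomization-img"))
  an <- config$analysis
  pm <- period_map(movie, band = an$band, pad_factor = an$pad_factor,
                   detrend_window = an$detrend_window,
                   conf_min = an$conf_min)
  # foci are extended amplitude domes; detect with a focus-sized disk
  # matched filter and prune at the hard-core exclusion scale
  am <- amplitude_map(movie, detrend_window = an$detrend_window)
  det <- detect_foci(am, min_separation = config$foci$r_min, threshold = 0.35,
                     template_radius = config$slowing$r_focus)
  spacing <- if (nrow(det) >= 2L) {
    spacing_stats(det, seed = substream_seed(seed, "randomization-null"))
  } else NULL

  # center vs periphery period evolution: dominant Fourier period in sliding
  # windows of the ROI traces, averaged across foci
  roi_period_course <- function(offset_um, roi_r, win = 480, step = 240) {
    t_total <- max(movie$times)
    starts <- seq(0, t_total - win, by = step)
    per_focus <- lapply(seq_len(nrow(layout)), function(f) {
      ctr <- c(layout$x_um[f] + offset_um, layout$y_um[f])
      tr <- tryCatch(extract_roi_trace(movie, ctr, roi_r),
                     error = function(e) NULL)
      if (is.null(tr)) return(NULL)
      vapply(starts, function(s0) {
        seg <- tr[tr$time_min >= s0 & tr$time_min < s0 + win, , drop = FALSE]
        fourier_period(seg, band = an$band, pad_factor = an$pad_factor,
                       detrend_window = an$detrend_window)$period_min
      }, numeric(1L))
    })
    per_focus <- Filter(Negate(is.null), per_focus)
    data.frame(t_mid_min = starts + win / 2,
               period_min = rowMeans(do.call(cbind, per_focus)))
  }
  center_period <- roi_period_course(0, 15)
  periphery_period <- roi_period_course(0.85 * config$slowing$r_focus, 10)

  # radial summary of the period map around each focus
  d <- dim(movie$frames)
  xs <- movie$extent[1L] + (seq_len(d[2L]) - 0.5) * movie$pixel_size
  ys <- movie$extent[3L] + (seq_len(d[1L]) - 0.5) * movie$pixel_size
  rad_bins <- seq(0, config$slowing$r_focus, by = 15)
  radial <- vapply(seq_len(length(rad_bins) - 1L), function(b) {
    vals <- unlist(lapply(seq_len(nrow(layout)), function(f) {
      rr <- outer(ys - layout$y_um[f], xs - layout$x_um[f],
                  function(a, b) sqrt(a^2 + b^2))
      sel <- rr >= rad_bins[b] & rr < rad_bins[b + 1L]
      pm$period[sel]
    }))
    mean(vals, na.rm = TRUE)
  }, numeric(1L))

  ky <- if (nrow(layout) >= 2L) {
    kymograph(movie, rbind(c(layout$x_um[1L], layout$y_um[1L]),
                           c(layout$x_um[2L], layout$y_um[2L])),
              line_width = 2)
  } else NULL

  meas <- list(
    foci = det,
    n_detected = nrow(det),
    density_mm2 = foci_density(det, attr(layout, "area_mm2")),
    spacing = spacing,
    center_period = center_period,
    periphery_period = periphery_period,
    radial_period_min = data.frame(r_lo_um = head(rad_bins, -1L),
                                   r_hi_um = tail(rad_bins, -1L),
                                   period_min = radial),
    kymograph = ky
  )
  if (keep_movie) meas$movie <- movie
  new_report("randomization", config, seed, meas)
}
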