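## Run configurations, the end-to-end pipeline, and preset scenario builders.

#' Construct a run configuration
#'
#' A `run_config` is a fully explicit, serializable description of one
#' simulation: grid, intent waveforms, connectivity `G`, the motoneuron pool,
#' mixing matrices `B`/`C`, the noise model, and the master seed. Preset
#' builders ([build_run1()], [build_run2()], [build_run3()], [build_run4()])
#' return ready-made configurations.
#'
#' @param grid list with `sampling_rate` and `duration`.
#' @param intent list of waveform specs (see [generate_intent()]), one per DOF.
#' @param G intent-to-motoneuron gain matrix (m x n).
#' @param pool list of [motoneuron_spec()] (length m).
#' @param B,C electrode mixing matrices (see [electrode_mapping()]).
#' @param noise a [noise_spec()].
#' @param seed integer master seed.
#' @param dof_labels optional DOF names.
#' @param scenario label (`"custom"` for user-built configs).
#' @param levels,level_duration,electrodes used by the steady-level scenarios
#'   (runs 3 and 4): constant intent levels, seconds simulated per level, and
#'   the per-electrode pool description.
#' @return Object of class `run_config`.
#' @export
run_config <- function(grid, intent, G, pool, B, C = NULL,
                       noise = noise_spec("none"), seed = 1,
                       dof_labels = NULL, scenario = "custom",
                       levels = NULL, level_duration = NULL,
                       electrodes = NULL) {
  if (!is.null(G)) {
    G <- as.matrix(G)
    if (length(intent) != ncol(G))
      stop_config("intent DOF count (", length(intent),
                  ") != G column count (", ncol(G), ")")
    if (length(pool) != nrow(G))
      stop_config("pool size (", length(pool), ") != G row count (", nrow(G), ")")
  }
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (!is.null(pool) && ncol(B) != length(pool))
      stop_config("B column count (", ncol(B), ") != pool size (", length(pool), ")")
  }
  if (is.null(dof_labels) && !is.null(intent))
    dof_labels <- paste0("dof", seq_along(intent))
  structure(list(scenario = scenario, grid = grid, intent = intent,
                 dof_labels = dof_labels, G = G, pool = pool, B = B, C = C,
                 noise = noise, seed = as.integer(seed), levels = levels,
                 level_duration = level_duration, electrodes = electrodes),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> scenario %s, seed %d\n", x$scenario, x$seed))
  if (!is.null(x$grid))
    cat(sprintf("  grid: %g Hz x %g s\n", x$grid$sampling_rate, x$grid$duration))
  if (!is.null(x$pool)) cat(sprintf("  pool: %d motoneurons\n", length(x$pool)))
  if (!is.null(x$B)) cat(sprintf("  electrodes: %d\n", nrow(as.matrix(x$B))))
  if (!is.null(x$electrodes))
    cat(sprintf("  electrodes: %d (steady-level sweep, %d levels x %g s)\n",
                length(x$electrodes), length(x$levels), x$level_duration))
  invisible(x)
}

#' Run a full simulation from a configuration
#'
#' Executes intent -> activation -> spike trains -> axon signals ->
#' recording, exposing every intermediate product. Each motoneuron and each
#' electrode noise channel draws from its own seed substream derived from
#' `cfg$seed`, so reruns are bit-identical and adding electrodes never
#' perturbs spike trains.
#'
#' @param cfg a [run_config()] (scenario `"custom"`, `"run1"`, or `"run2"`).
#' @param morphologies morphology registry; defaults to [morphology_library()].
#' @return List with elements `recording`, `axon_signals`, `activation`,
#'   `intent`, `trains`, `templates`, `config`, `manifest`.
#' @export
run_simulation <- function(cfg, morphologies = morphology_library()) {
  grid <- time_grid(cfg$grid$sampling_rate, cfg$grid$duration)
  traj <- lapply(cfg$intent, generate_intent, grid = grid)
  u <- assemble_multi_dof(traj, grid, labels = cfg$dof_labels)
  x <- map_intent_to_activation(u, intent_mapping(cfg$G))
  trains <- lapply(seq_along(cfg$pool), function(i)
    generate_spike_times(cfg$pool[[i]], x$values[i, ], grid,
                         seed = derive_seed(cfg$seed, "mn", i)))
  templates <- lapply(cfg$pool, function(mn) {
    if (is.null(morphologies[[mn$morphology_id]]))
      stop_config("unknown morphology_id: ", mn$morphology_id)
    scale_template(morphologies[[mn$morphology_id]], mn$amplitude,
                   mn$duration, grid, template_id = mn$id)
  })
  axons <- render_pool(trains, templates, grid)
  mapping <- electrode_mapping(cfg$B, cfg$C)
  rec <- record(axons, mapping, cfg$noise, grid, seed = cfg$seed)
  manifest <- list(scenario = cfg$scenario, seed = cfg$seed,
                   config_hash = config_hash(config_to_plain(cfg)),
                   n_motoneurons = length(cfg$pool),
                   n_electrodes = nrow(mapping$H),
                   n_samples = grid$n_samples,
                   total_spikes = sum(vapply(trains, function(tr)
                     length(tr$event_times), integer(1))),
                   package_version = as.character(utils::packageVersion("lifesim")))
  list(recording = rec, axon_signals = axons, activation = x, intent = u,
       trains = trains, templates = templates, config = cfg,
       manifest = manifest)
}

## ---------------------------------------------------------------- presets

# Motoneuron parameter ranges printed for simulation run 1.
run1_ranges <- function(type = c("S", "FF")) {
  type <- match.arg(type)
  if (type == "S")
    list(duration = c(0.004, 0.006), amplitude = c(45, 65),
         f_thr = c(1, 5), f_sat = c(16, 18),
         x_thr = c(0, 0.10), x_sat = c(0.40, 0.50))
  else
    list(duration = c(0.002, 0.004), amplitude = c(95, 105),
         f_thr = c(12, 19), f_sat = c(25, 30),
         x_thr = c(0.35, 0.65), x_sat = c(0.80, 1.00))
}

# Electrode weights "equally spaced over the range from 0.5 to 1".
equally_spaced_weights <- function(k) {
  if (k == 1) return(1)
  seq(0.5, 1, length.out = k)
}

#' Preset: run 1 — fiber-type contrast and superposition
#'
#' One-DOF ramp of motor intent driving 6 S and 6 FF motoneurons whose
#' parameters are drawn uniformly from the published ranges (S: 4-6 ms
#' spikes, amplitude 45-65, rates 1-5 -> 16-18 Hz over intent 0-10% ->
#' 40-50%; FF: 2-4 ms, 95-105, 12-19 -> 25-30 Hz over 35-65% -> 80-100%),
#' Poisson spike timing. Five electrodes record 1 S, 6 S, 1 FF, 6 FF, and
#' 3 S + 3 FF units with contribution weights equally spaced on [0.5, 1],
#' plus additive band-limited Gaussian noise at SNR 3.
#'
#' @param seed integer master seed.
#' @param duration simulated seconds (default 10).
#' @param sampling_rate Hz (default 20000).
#' @return A [run_config()].
#' @export
build_run1 <- function(seed = 1, duration = 10, sampling_rate = 20000) {
  pool_s <- sample_pool(run1_ranges("S"), 6, "S",
                        process = point_process("poisson"),
                        seed = derive_seed(seed, "pool", "S"))
  pool_ff <- sample_pool(run1_ranges("FF"), 6, "FF",
                         process = point_process("poisson"),
                         seed = derive_seed(seed, "pool", "FF"), id_offset = 6)
  pool <- c(pool_s, pool_ff)
  m <- length(pool)
  B <- matrix(0, nrow = 5, ncol = m)
  B[1, 1] <- 1
  B[2, 1:6] <- equally_spaced_weights(6)
  B[3, 7] <- 1
  B[4, 7:12] <- equally_spaced_weights(6)
  B[5, c(1:3, 7:9)] <- equally_spaced_weights(6)
  run_config(grid = list(sampling_rate = sampling_rate, duration = duration),
             intent = list(list(kind = "ramp")),
             G = matrix(1, nrow = m, ncol = 1),
             pool = pool, B = B, C = diag(5),
             noise = noise_spec("gaussian_snr", snr = 3, band = c(100, 7500)),
             seed = seed, scenario = "run1")
}

#' Preset: run 2 — two degrees of freedom and crosstalk
#'
#' Two independent intent signals (a ramp-and-hold, and a series of
#' contraction/relaxation bursts) drive two motor pools of 3 S + 3 FF units
#' each (run-1 mixed-electrode parameters). Electrodes 1 and 2 sit in one
#' pool each; electrode 3 picks up both pools through a crosstalk row of
#' 0.5/0.5 in `C`.
#'
#' @inheritParams build_run1
#' @return A [run_config()].
#' @export
build_run2 <- function(seed = 1, duration = 10, sampling_rate = 20000) {
  mixed_pool <- function(label, offset) {
    c(sample_pool(run1_ranges("S"), 3, "S",
                  seed = derive_seed(seed, "pool", label, "S"),
                  id_offset = offset),
      sample_pool(run1_ranges("FF"), 3, "FF",
                  seed = derive_seed(seed, "pool", label, "FF"),
                  id_offset = offset + 3))
  }
  pool <- c(mixed_pool("p1", 0), mixed_pool("p2", 6))
  G <- cbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)))
  B <- matrix(0, nrow = 3, ncol = 12)
  B[1, 1:6] <- equally_spaced_weights(6)
  B[2, 7:12] <- equally_spaced_weights(6)
  C <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  run_config(grid = list(sampling_rate = sampling_rate, duration = duration),
             intent = list(
               list(kind = "ramp_and_hold", amplitude = 1, t_start = 1,
                    rise_time = 3),
               list(kind = "square", amplitude = 1, period = 2, duty = 0.5,
                    t_start = 1)),
             G = G, pool = pool, B = B, C = C,
             noise = noise_spec("gaussian_snr", snr = 3, band = c(100, 7500)),
             seed = seed, scenario = "run2",
             dof_labels = c("dof1", "dof2"))
}

# Per-electrode pool for the steady-level scenarios: n_axons units split
# between fiber groups, with run-specific curve parameters.
steady_electrode <- function(fiber_group, n_axons, make_s, make_ff, seed) {
  n_s <- switch(fiber_group, S = n_axons, FF = 0L, mixed = n_axons %/% 2L)
  n_ff <- n_axons - n_s
  pool <- c(
    if (n_s > 0) make_s(n_s, seed),
    if (n_ff > 0) make_ff(n_ff, n_s, seed)
  )
  list(fiber_group = fiber_group, n_axons = n_axons, pool = pool,
       weights = equally_spaced_weights(n_axons))
}

#' Preset: run 3 (simulated half) — steady-state intent levels
#'
#' Thirty electrodes (2, 4, 6, 8, or 10 axons; all S, all FF, or an even
#' S/FF mix; two replicates of each combination) are each simulated at three
#' steady intent levels (low/moderate/high). Pool parameters are drawn so
#' that every group modulates across the tested levels: S units recruit near
#' zero and saturate only near maximal intent; FF units recruit at
#' intermediate intent. Noise is band-limited Gaussian whose standard
#' deviation is calibrated once per electrode (SNR 3 against the high-level
#' trace) and held fixed across levels, as a physical electrode's noise floor
#' would be. The spectral analysis pipeline for these recordings is
#' [analyze_steady_levels()] / [run_steady_levels()].
#'
#' @param seed integer master seed.
#' @param level_duration seconds simulated per level (default 10).
#' @param levels named numeric vector of steady intent levels.
#' @param sampling_rate Hz.
#' @return A [run_config()] with scenario `"run3"`.
#' @export
build_run3 <- function(seed = 1, level_duration = 10,
                       levels = c(low = 0.2, moderate = 0.55, high = 0.9),
                       sampling_rate = 20000) {
  s_ranges <- list(duration = c(0.004, 0.006), amplitude = c(45, 65),
                   f_thr = c(1, 5), f_sat = c(16, 18),
                   x_thr = c(0, 0.10), x_sat = c(0.85, 1.00))
  ff_ranges <- list(duration = c(0.002, 0.004), amplitude = c(95, 105),
                    f_thr = c(12, 19), f_sat = c(25, 30),
                    x_thr = c(0.25, 0.40), x_sat = c(0.85, 1.00))
  combos <- expand.grid(n_axons = c(2L, 4L, 6L, 8L, 10L),
                        fiber_group = c("S", "FF", "mixed"),
                        replicate = 1:2, stringsAsFactors = FALSE)
  electrodes <- lapply(seq_len(nrow(combos)), function(e) {
    make_s <- function(n, sd0) sample_pool(s_ranges, n, "S",
      seed = derive_seed(sd0, "run3", e, "S"))
    make_ff <- function(n, off, sd0) sample_pool(ff_ranges, n, "FF",
      seed = derive_seed(sd0, "run3", e, "FF"), id_offset = off)
    el <- steady_electrode(combos$fiber_group[e], combos$n_axons[e],
                           function(n, sd0) make_s(n, sd0),
                           function(n, off, sd0) make_ff(n, off, sd0),
                           seed)
    el$replicate <- combos$replicate[e]
    el
  })
  run_config(grid = list(sampling_rate = sampling_rate,
                         duration = level_duration),
             intent = NULL, G = NULL, pool = NULL, B = NULL, C = NULL,
             noise = noise_spec("gaussian_snr", snr = 3, band = c(100, 7500)),
             seed = seed, scenario = "run3",
             levels = levels, level_duration = level_duration,
             electrodes = electrodes)
}

#' Preset: run 4 — the spike-overlap sweep
#'
#' Fifteen electrodes (all S, all FF, or an even S/FF mix, with 2, 4, 6, 8,
#' or 10 contributing axons) are simulated at ten steady intent levels (10%
#' steps up to 100%). S units have 4 ms spikes and fire 5-18 Hz over the
#' lower half of the intent range; FF units have 2 ms spikes and fire
#' 18-35 Hz over the upper half; spike timing is Poisson. Execute with
#' [run_overlap_sweep()], which reports percent overlap and composite firing
#' rate per electrode and level.
#'
#' @param seed integer master seed.
#' @param level_duration seconds simulated per level (default 10; long enough
#'   that overlap estimates have a standard error below one percentage point
#'   at these firing rates).
#' @param sampling_rate Hz.
#' @return A [run_config()] with scenario `"run4"`.
#' @export
build_run4 <- function(seed = 1, level_duration = 10, sampling_rate = 20000) {
  s_unit <- function(id) motoneuron_spec(
    id = id, fiber_type = "S",
    curve = firing_curve(0, 5, 0.5, 18),
    process = point_process("poisson"),
    morphology_id = "symmetric_1peak", amplitude = 55, duration = 0.004)
  ff_unit <- function(id) motoneuron_spec(
    id = id, fiber_type = "FF",
    curve = firing_curve(0.5, 18, 1, 35),
    process = point_process("poisson"),
    morphology_id = "symmetric_1peak", amplitude = 100, duration = 0.002)
  combos <- expand.grid(n_axons = c(2L, 4L, 6L, 8L, 10L),
                        fiber_group = c("S", "FF", "mixed"),
                        stringsAsFactors = FALSE)
  electrodes <- lapply(seq_len(nrow(combos)), function(e) {
    steady_electrode(combos$fiber_group[e], combos$n_axons[e],
                     function(n, sd0) lapply(seq_len(n), s_unit),
                     function(n, off, sd0) lapply(off + seq_len(n), ff_unit),
                     seed)
  })
  run_config(grid = list(sampling_rate = sampling_rate,
                         duration = level_duration),
             intent = NULL, G = NULL, pool = NULL, B = NULL, C = NULL,
             noise = noise_spec("none"), seed = seed, scenario = "run4",
             levels = seq(0.1, 1, by = 0.1), level_duration = level_duration,
             electrodes = electrodes)
}

#' Execute the overlap sweep of a steady-level configuration
#'
#' For every electrode and steady intent level, generates the spike trains of
#' the contributing axons (each axon/level/seed combination on its own RNG
#' substream) and computes the percent spike overlap and the composite firing
#' rate. Voltage traces are not rendered: the overlap statistic depends only
#' on event times and template durations.
#'
#' @param cfg a [build_run4()]-style `run_config`.
#' @param seeds integer vector of master seeds (default the config seed).
#' @return data.frame with columns `seed`, `electrode`, `fiber_group`,
#'   `n_axons`, `level`, `percent_overlap`, `composite_rate`.
#' @export
run_overlap_sweep <- function(cfg, seeds = cfg$seed) {
  grid <- time_grid(cfg$grid$sampling_rate, cfg$level_duration)
  const <- rep(1, grid$n_samples)
  out <- vector("list", length(seeds) * length(cfg$electrodes) * length(cfg$levels))
  k <- 0L
  for (sd0 in seeds) {
    for (e in seq_along(cfg$electrodes)) {
      el <- cfg$electrodes[[e]]
      for (li in seq_along(cfg$levels)) {
        lev <- cfg$levels[[li]]
        trains <- lapply(seq_along(el$pool), function(a)
          generate_spike_times(el$pool[[a]], const * lev, grid,
                               seed = derive_seed(sd0, "sweep", e, li, a)))
        durations <- vapply(el$pool, function(m) m$duration, numeric(1))
        k <- k + 1L
        out[[k]] <- data.frame(
          seed = sd0, electrode = e, fiber_group = el$fiber_group,
          n_axons = el$n_axons, level = lev,
          percent_overlap = percent_overlap(trains, durations, grid),
          composite_rate = composite_rate(trains, cfg$level_duration))
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Simulate and analyze steady-state intent levels
#'
#' For every electrode of a [build_run3()] configuration and every steady
#' intent level, renders the noise-free composite trace, adds band-limited
#' Gaussian noise (noise floor calibrated once per electrode against its
#' highest level, then held fixed), band-pass filters (4th order, 80 Hz -
#' 4 kHz), and summarizes the Welch spectrum (0.5 s windows, 50% overlap):
#' total power and mean frequency over the analysis band, plus the
#' moving-average decoder's mean output for the level.
#'
#' @param cfg a [build_run3()]-style `run_config`.
#' @param morphologies morphology registry.
#' @param band analysis band in Hz for the spectral summary.
#' @return data.frame with one row per electrode x level: `electrode`,
#'   `fiber_group`, `n_axons`, `level_name`, `level`, `total_power`,
#'   `mean_frequency`, `decoded_intent`, `composite_rate`.
#' @export
run_steady_levels <- function(cfg, morphologies = morphology_library(),
                              band = c(80, 4000)) {
  grid <- time_grid(cfg$grid$sampling_rate, cfg$level_duration)
  levels <- cfg$levels
  level_names <- if (!is.null(names(levels))) names(levels) else
    as.character(seq_along(levels))
  rows <- list()
  for (e in seq_along(cfg$electrodes)) {
    el <- cfg$electrodes[[e]]
    templates <- lapply(el$pool, function(mn)
      scale_template(morphologies[[mn$morphology_id]], mn$amplitude,
                     mn$duration, grid, template_id = mn$id))
    pure <- vector("list", length(levels))
    trains <- vector("list", length(levels))
    for (li in seq_along(levels)) {
      act <- rep(levels[[li]], grid$n_samples)
      trains[[li]] <- lapply(seq_along(el$pool), function(a)
        generate_spike_times(el$pool[[a]], act, grid,
                             seed = derive_seed(cfg$seed, "steady", e, li, a)))
      axons <- render_pool(trains[[li]], templates, grid)
      pure[[li]] <- as.numeric(el$weights %*% axons$values)
    }
    # one noise floor per electrode, set at the most active level
    ref <- pure[[which.max(vapply(pure, sd, numeric(1)))]]
    sigma <- noise_sigma_from_snr(ref, cfg$noise$snr)
    for (li in seq_along(levels)) {
      noise <- generate_gaussian_noise(cfg$noise, pure[[li]], grid,
                                       seed = derive_seed(cfg$seed, "noise", e, li),
                                       sigma = sigma)
      z <- bandpass(pure[[li]] + noise, band[1], band[2],
                    rate = grid$sampling_rate)
      ss <- spectral_summary(z, grid, band = band)
      dec <- moving_average_decode(z, grid$sampling_rate, normalize = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = e, fiber_group = el$fiber_group, n_axons = el$n_axons,
        level_name = level_names[li], level = unname(levels[[li]]),
        total_power = ss$total_power, mean_frequency = ss$mean_frequency,
        decoded_intent = mean(dec),
        composite_rate = composite_rate(trains[[li]], cfg$level_duration))
    }
  }
  do.call(rbind, rows)
}

#' @rdname run_steady_levels
#' @export
analyze_steady_levels <- run_steady_levels

#' Dispatch a scenario configuration to its runner
#'
#' Runs 1 and 2 go through the full [run_simulation()] pipeline; run 4 maps
#' to [run_overlap_sweep()]; run 3 maps to [run_steady_levels()].
#'
#' @param cfg a `run_config`.
#' @param ... passed to the underlying runner.
#' @return The runner's value.
#' @export
run_scenario <- function(cfg, ...) {
  switch(cfg$scenario,
         run4 = run_overlap_sweep(cfg, ...),
         run3 = run_steady_levels(cfg, ...),
         run_simulation(cfg, ...))
}
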