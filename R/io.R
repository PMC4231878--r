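## Reading/writing configurations and sampled-intent files.

mat_to_plain <- function(m) {
  if (is.null(m)) return(NULL)
  m <- as.matrix(m)
  list(nrow = nrow(m), ncol = ncol(m), data = as.numeric(t(m)))
}

plain_to_mat <- function(p) {
  if (is.null(p)) return(NULL)
  matrix(as.numeric(unlist(p$data)), nrow = p$nrow, ncol = p$ncol, byrow = TRUE)
}

mn_to_plain <- function(m) {
  list(id = m$id, fiber_type = m$fiber_type,
       x_thr = m$curve$x_thr, f_thr = m$curve$f_thr,
       x_sat = m$curve$x_sat, f_sat = m$curve$f_sat,
       process = m$process$kind, dispersion = m$process$dispersion,
       width = m$process$width, isi_floor = m$process$isi_floor,
       morphology_id = m$morphology_id,
       amplitude = m$amplitude, duration = m$duration)
}

plain_to_mn <- function(p) {
  motoneuron_spec(
    id = p$id, fiber_type = p$fiber_type,
    curve = firing_curve(p$x_thr, p$f_thr, p$x_sat, p$f_sat),
    process = point_process(p$process, dispersion = p$dispersion,
                            width = p$width, isi_floor = p$isi_floor),
    morphology_id = p$morphology_id,
    amplitude = p$amplitude, duration = p$duration)
}

config_to_plain <- function(cfg) {
  list(
    scenario = cfg$scenario,
    grid = cfg$grid,
    intent = cfg$intent,
    dof_labels = cfg$dof_labels,
    G = mat_to_plain(cfg$G),
    pool = if (is.null(cfg$pool)) NULL else lapply(cfg$pool, mn_to_plain),
    B = mat_to_plain(cfg$B),
    C = mat_to_plain(cfg$C),
    noise = unclass(cfg$noise),
    seed = cfg$seed,
    levels = if (is.null(cfg$levels)) NULL else
      list(names = names(cfg$levels), values = as.numeric(cfg$levels)),
    level_duration = cfg$level_duration,
    electrodes = if (is.null(cfg$electrodes)) NULL else
      lapply(cfg$electrodes, function(el)
        list(fiber_group = el$fiber_group, n_axons = el$n_axons,
             weights = as.numeric(el$weights),
             replicate = el$replicate,
             pool = lapply(el$pool, mn_to_plain)))
  )
}

plain_to_config <- function(p) {
  levels <- NULL
  if (!is.null(p$levels)) {
    levels <- as.numeric(unlist(p$levels$values))
    if (!is.null(p$levels$names)) names(levels) <- unlist(p$levels$names)
  }
  ns <- p$noise
  noise <- noise_spec(ns$model, beta = ns$beta, amplitude = ns$amplitude,
                      snr = ns$snr, band = as.numeric(unlist(ns$band)),
                      shared_across_electrodes = isTRUE(ns$shared_across_electrodes),
                      path = ns$path, rate = ns$rate)
  electrodes <- NULL
  if (!is.null(p$electrodes))
    electrodes <- lapply(p$electrodes, function(el) {
      out <- list(fiber_group = el$fiber_group,
                  n_axons = as.integer(el$n_axons),
                  pool = lapply(el$pool, plain_to_mn),
                  weights = as.numeric(unlist(el$weights)))
      out$replicate <- el$replicate
      out
    })
  run_config(grid = p$grid,
             intent = p$intent,
             G = plain_to_mat(p$G),
             pool = if (is.null(p$pool)) NULL else lapply(p$pool, plain_to_mn),
             B = plain_to_mat(p$B), C = plain_to_mat(p$C),
             noise = noise, seed = p$seed,
             dof_labels = if (is.null(p$dof_labels)) NULL else unlist(p$dof_labels),
             scenario = p$scenario, levels = levels,
             level_duration = p$level_duration, electrodes = electrodes)
}

#' Write a run configuration to structured text (YAML)
#'
#' The serialization is lossless: [read_run_config()] reconstructs an
#' equivalent `run_config` (matrices, pool tables, noise model, seed).
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(config_to_plain(cfg), path, precision = 15)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path input path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  plain_to_config(yaml::read_yaml(path))
}

#' Read sampled motor intent from delimited text
#'
#' Expects a header row of DOF labels and one column per DOF; an optional
#' `time_s` column gives the sample times, otherwise rows are assumed
#' uniformly spaced over the simulation duration when resampled by
#' [generate_intent()] (kind `"file"`).
#'
#' @param path file path (tab- or whitespace-delimited).
#' @return List with `times` (NULL when the file has no `time_s` column),
#'   `values` (matrix, one column per DOF), `labels`.
#' @export
read_intent_file <- function(path) {
  df <- read.table(path, header = TRUE)
  if ("time_s" %in% names(df)) {
    times <- df$time_s
    df <- df[setdiff(names(df), "time_s")]
  } else {
    times <- NULL  # uniform over the target duration, decided at resampling
  }
  if (any(as.matrix(df) < 0 | as.matrix(df) > 1))
    stop_validation("intent samples must lie in [0, 1]")
  list(times = times, values = as.matrix(df), labels = names(df))
}
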