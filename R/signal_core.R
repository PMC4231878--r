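## Time grids, motor-intent waveforms, and the intent -> activation map.

#' Uniform simulation time grid
#'
#' All components of one simulation run share a single uniform grid. The
#' default rate of 20 kHz comfortably satisfies Nyquist for extracellular
#' spike waveforms, whose energy lies between roughly 100 Hz and 10 kHz.
#'
#' @param sampling_rate samples per second.
#' @param duration total duration T in seconds; samples cover `[0, T)`.
#' @return An object of class `time_grid` with fields `sampling_rate`,
#'   `duration`, `n_samples`.
#' @export
time_grid <- function(sampling_rate = 20000, duration = 1) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_validation("sampling_rate must be positive")
  if (!is.numeric(duration) || duration <= 0)
    stop_validation("duration must be positive")
  structure(list(sampling_rate = sampling_rate,
                 duration = duration,
                 n_samples = as.integer(round(sampling_rate * duration))),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %g s @ %g Hz (%d samples)\n",
              x$duration, x$sampling_rate, x$n_samples))
  invisible(x)
}

#' Sample times of a grid
#' @param grid a [time_grid()].
#' @return Numeric vector of length `n_samples`, starting at 0.
#' @export
grid_times <- function(grid) {
  (seq_len(grid$n_samples) - 1) / grid$sampling_rate
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$sampling_rate, b$sampling_rate)) &&
    a$n_samples == b$n_samples
}

#' Generate a single-DOF motor-intent trajectory
#'
#' Motor intent is a normalized (0 = rest, 1 = maximum intended effort)
#' command for one degree of freedom. Supported waveform kinds:
#' \describe{
#'   \item{constant}{`value`.}
#'   \item{ramp}{linear from `from` (default 0) at `t_start` (default 0) to
#'     `to` (default 1) at `t_end` (default T), held outside.}
#'   \item{ramp_and_hold}{rise from 0 to `amplitude` over `rise_time` starting
#'     at `t_start`, hold, then optional linear release over `fall_time`
#'     starting at `t_release`.}
#'   \item{square}{bursts of height `amplitude`, period `period`, duty cycle
#'     `duty` (default 0.5), starting at `t_start`.}
#'   \item{sinusoid}{`offset + amplitude * sin(2*pi*frequency*t + phase)`,
#'     clipped to [0, 1].}
#'   \item{piecewise}{linear interpolation through (`times`, `values`).}
#'   \item{file}{sampled trajectory from delimited text, see
#'     [read_intent_file()]; parameters `path` and `dof` (column name).}
#' }
#'
#' @param waveform_spec a list with element `kind` and the parameters above.
#' @param grid a [time_grid()].
#' @return Numeric vector of length `grid$n_samples`, clipped to [0, 1].
#' @export
generate_intent <- function(waveform_spec, grid) {
  kind <- waveform_spec$kind
  if (is.null(kind)) stop_config("waveform spec has no 'kind'")
  t <- grid_times(grid)
  p <- waveform_spec
  amp_check <- function(a, what) {
    if (is.null(a) || !is.finite(a) || a < 0 || a > 1)
      stop_validation(what, " must lie in [0, 1]")
    a
  }
  v <- switch(kind,
    constant = rep(amp_check(p$value, "value"), length(t)),
    ramp = {
      from <- if (is.null(p$from)) 0 else amp_check(p$from, "from")
      to <- if (is.null(p$to)) 1 else amp_check(p$to, "to")
      t0 <- if (is.null(p$t_start)) 0 else p$t_start
      # default end at the last grid sample so the endpoint value is reached
      t1 <- if (is.null(p$t_end)) max(t) else p$t_end
      if (t1 <= t0) stop_validation("ramp needs t_end > t_start")
      frac <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
      from + frac * (to - from)
    },
    ramp_and_hold = {
      a <- amp_check(p$amplitude, "amplitude")
      t0 <- if (is.null(p$t_start)) 0 else p$t_start
      rise <- if (is.null(p$rise_time)) grid$duration / 5 else p$rise_time
      tr <- if (is.null(p$t_release)) Inf else p$t_release
      fall <- if (is.null(p$fall_time)) 0 else p$fall_time
      up <- pmin(1, pmax(0, (t - t0) / rise))
      down <- if (is.finite(tr)) {
        if (fall > 0) pmin(1, pmax(0, (t - tr) / fall)) else as.numeric(t >= tr)
      } else 0
      a * pmax(0, up - down)
    },
    square = {
      a <- amp_check(p$amplitude, "amplitude")
      per <- p$period
      if (is.null(per) || per <= 0) stop_validation("square needs period > 0")
      duty <- if (is.null(p$duty)) 0.5 else p$duty
      t0 <- if (is.null(p$t_start)) 0 else p$t_start
      phase <- (t - t0) %% per
      ifelse(t >= t0 & phase < duty * per, a, 0)
    },
    sinusoid = {
      a <- amp_check(p$amplitude, "amplitude")
      off <- if (is.null(p$offset)) a else amp_check(p$offset, "offset")
      fr <- p$frequency
      if (is.null(fr) || fr <= 0) stop_validation("sinusoid needs frequency > 0")
      ph <- if (is.null(p$phase)) 0 else p$phase
      off + a * sin(2 * pi * fr * t + ph)
    },
    piecewise = {
      if (is.null(p$times) || is.null(p$values) ||
          length(p$times) != length(p$values))
        stop_validation("piecewise needs matching 'times' and 'values'")
      if (any(p$values < 0 | p$values > 1))
        stop_validation("piecewise values must lie in [0, 1]")
      approx(p$times, p$values, xout = t, rule = 2)$y
    },
    file = {
      tab <- read_intent_file(p$path)
      col <- if (is.null(p$dof)) 1L else p$dof
      src <- tab$values[, col]
      t_src <- if (is.null(tab$times))
        seq(0, max(t), length.out = length(src)) else tab$times
      approx(t_src, src, xout = t, rule = 2)$y
    },
    stop_config("unknown intent waveform kind: ", kind)
  )
  pmin(1, pmax(0, v))
}

#' Assemble single-DOF trajectories into a multi-DOF motor-intent object
#'
#' @param trajectories list of numeric vectors from [generate_intent()], all
#'   on the same grid.
#' @param grid the shared [time_grid()].
#' @param labels character DOF identifiers; defaults to `dof1`, `dof2`, ...
#' @return Object of class `motor_intent`: fields `grid`, `values`
#'   (n_dof x n_samples matrix), `dof_labels`.
#' @export
assemble_multi_dof <- function(trajectories, grid, labels = NULL) {
  if (length(trajectories) < 1) stop_validation("need at least one trajectory")
  lens <- vapply(trajectories, length, integer(1))
  if (any(lens != grid$n_samples))
    stop_validation("trajectories do not share the grid (length mismatch)")
  if (is.null(labels)) labels <- paste0("dof", seq_along(trajectories))
  if (length(labels) != length(trajectories))
    stop_validation("labels length must match trajectory count")
  values <- do.call(rbind, trajectories)
  rownames(values) <- labels
  structure(list(grid = grid, values = values, dof_labels = labels),
            class = "motor_intent")
}

#' Intent-to-motoneuron connectivity matrix
#'
#' Wraps the m x n gain matrix G mapping n intent components to m
#' motoneurons. Uniform values along a row model uniform synaptic drive
#' across a pool; heterogeneous values model unequal drive.
#'
#' @param matrix numeric m x n matrix of non-negative finite gains, m >= n.
#' @return Object of class `intent_mapping`.
#' @export
intent_mapping <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < ncol(matrix))
    stop_validation("G must have at least as many rows (motoneurons) as columns (DOFs)")
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stop_validation("G entries must be finite and >= 0")
  structure(list(matrix = matrix), class = "intent_mapping")
}

#' Map motor intent to motoneuron activation states
#'
#' Computes `x(t) = G u(t)` per time sample. Activation is interpreted on a
#' normalized scale where 1 is maximal activation; values that exceed 1 after
#' the matrix product are clipped to 1 with a warning so the firing-curve
#' domain stays well defined.
#'
#' @param intent a `motor_intent` object.
#' @param mapping an [intent_mapping()] with `ncol(G)` equal to the DOF count.
#' @return Object of class `activation_state`: fields `grid`, `values`
#'   (m x n_samples matrix).
#' @export
map_intent_to_activation <- function(intent, mapping) {
  G <- mapping$matrix
  if (ncol(G) != nrow(intent$values))
    stop_validation("G column count (", ncol(G), ") != intent DOF count (",
                    nrow(intent$values), ")")
  x <- G %*% intent$values
  if (any(x > 1)) {
    warning("activation exceeded 1 after applying G; clipping to 1")
    x <- pmin(x, 1)
  }
  structure(list(grid = intent$grid, values = x), class = "activation_state")
}
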