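## Recruitment/rate curves, point-process ISI models, spike-train generation,
## and uniform sampling of motoneuron pools.

#' Piecewise-linear motoneuron firing-rate curve
#'
#' A motoneuron is silent until its activation exceeds the recruitment
#' threshold `x_thr`, fires at `f_thr` just above threshold, increases
#' linearly with slope `(f_sat - f_thr) / (x_sat - x_thr)`, and saturates at
#' `f_sat` for activation at or above `x_sat`. Recruitment order across a
#' pool (the size principle) is expressed by giving small, slow units low
#' thresholds and large, fast units high thresholds.
#'
#' @param x_thr recruitment threshold, activation above which the unit fires.
#' @param f_thr firing rate (Hz) at recruitment.
#' @param x_sat activation at which the rate saturates; `x_thr < x_sat <= 1`.
#' @param f_sat saturation firing rate (Hz), `>= f_thr`.
#' @return Object of class `firing_curve` with derived field `slope`.
#' @export
firing_curve <- function(x_thr, f_thr, x_sat, f_sat) {
  if (!(x_thr >= 0 && x_thr < x_sat && x_sat <= 1))
    stop_validation("need 0 <= x_thr < x_sat <= 1 (got x_thr=", x_thr,
                    ", x_sat=", x_sat, ")")
  if (!(f_thr > 0 && f_thr <= f_sat))
    stop_validation("need 0 < f_thr <= f_sat")
  structure(list(x_thr = x_thr, f_thr = f_thr, x_sat = x_sat, f_sat = f_sat,
                 slope = (f_sat - f_thr) / (x_sat - x_thr)),
            class = "firing_curve")
}

#' Slope of a firing-rate curve
#'
#' @param curve a [firing_curve()] (or a bare list with the same fields).
#' @return `(f_sat - f_thr) / (x_sat - x_thr)` in Hz per unit activation.
#' @export
rate_slope <- function(curve) {
  if (curve$x_sat == curve$x_thr)
    stop_validation("x_sat must differ from x_thr")
  (curve$f_sat - curve$f_thr) / (curve$x_sat - curve$x_thr)
}

#' Evaluate a firing-rate curve
#'
#' Returns 0 for activation at or below threshold (the threshold is the
#' activation *above which* the unit begins to fire), the linear branch
#' `f_thr + slope * (x - x_thr)` between threshold and saturation, and
#' `f_sat` at or above saturation. Vectorized over `x`.
#'
#' @param curve a [firing_curve()].
#' @param x activation value(s), finite.
#' @return Firing rate(s) in Hz.
#' @export
firing_rate <- function(curve, x) {
  if (any(!is.finite(x))) stop_validation("activation must be finite")
  f <- pmin(curve$f_thr + curve$slope * (x - curve$x_thr), curve$f_sat)
  f[x <= curve$x_thr] <- 0
  f
}

#' Point-process specification for spike timing
#'
#' The mean interspike interval is supplied at draw time as `1/f(x)`; the
#' process controls the variability around it:
#' \describe{
#'   \item{identity}{deterministic, regular train (for testing).}
#'   \item{poisson}{exponential ISI; variability tied to the rate.}
#'   \item{truncated_gaussian}{normal ISI with standard deviation
#'     `dispersion`, truncated below at the ISI floor.}
#'   \item{gamma}{gamma ISI with mean `xi` and standard deviation
#'     `dispersion` (shape `(xi/dispersion)^2`, scale `dispersion^2/xi`).}
#'   \item{uniform}{uniform on `mean +/- width/2`, clipped at the floor.}
#' }
#' For the last three models the ISI variability is set independently of the
#' mean, which is useful for stress-testing decoders at fixed rates.
#'
#' @param kind one of `"identity"`, `"poisson"`, `"truncated_gaussian"`,
#'   `"gamma"`, `"uniform"`.
#' @param dispersion ISI standard deviation in seconds
#'   (truncated_gaussian/gamma).
#' @param width full width in seconds (uniform).
#' @param isi_floor minimum ISI in seconds applied to all stochastic draws;
#'   prevents nonphysical self-overlapping spikes from one axon. The identity
#'   process is exempt.
#' @return Object of class `point_process`.
#' @export
point_process <- function(kind = c("identity", "poisson", "truncated_gaussian",
                                   "gamma", "uniform"),
                          dispersion = NULL, width = NULL, isi_floor = 1e-3) {
  kind <- match.arg(kind)
  if (kind %in% c("truncated_gaussian", "gamma")) {
    if (is.null(dispersion) || dispersion <= 0)
      stop_validation(kind, " requires dispersion > 0")
  }
  if (kind == "uniform") {
    if (is.null(width) || width < 0)
      stop_validation("uniform requires width >= 0")
  }
  if (isi_floor < 0) stop_validation("isi_floor must be >= 0")
  structure(list(kind = kind, dispersion = dispersion, width = width,
                 isi_floor = isi_floor),
            class = "point_process")
}

#' Draw interspike intervals from a point-process model
#'
#' @param spec a [point_process()].
#' @param mean_isi target mean ISI in seconds (`1/f`), positive.
#' @param n number of draws.
#' @return Numeric vector of `n` ISIs, each at least `spec$isi_floor` for
#'   stochastic models.
#' @export
draw_isi <- function(spec, mean_isi, n = 1) {
  if (!is.numeric(mean_isi) || mean_isi <= 0)
    stop_validation("mean_isi must be positive")
  floor_s <- spec$isi_floor
  switch(spec$kind,
    identity = rep(mean_isi, n),
    poisson = pmax(rexp(n, rate = 1 / mean_isi), floor_s),
    truncated_gaussian = {
      x <- rnorm(n, mean_isi, spec$dispersion)
      for (i in seq_len(1000)) {
        bad <- x < floor_s
        if (!any(bad)) break
        x[bad] <- rnorm(sum(bad), mean_isi, spec$dispersion)
      }
      pmax(x, floor_s)
    },
    gamma = {
      shape <- (mean_isi / spec$dispersion)^2
      pmax(rgamma(n, shape = shape, scale = spec$dispersion^2 / mean_isi),
           floor_s)
    },
    uniform = pmax(runif(n, mean_isi - spec$width / 2,
                         mean_isi + spec$width / 2), floor_s)
  )
}

#' Motoneuron specification
#'
#' Bundles everything needed to turn one activation trace into one axon
#' voltage trace: the rate curve, the spike-timing model, and the spike
#' template (morphology id + amplitude + duration).
#'
#' @param id integer or character identifier.
#' @param fiber_type `"S"`, `"FR"`, or `"FF"` (slow fatigue-resistant, fast
#'   fatigue-resistant, fast fatigable).
#' @param curve a [firing_curve()].
#' @param process a [point_process()].
#' @param morphology_id name of a registered spike morphology (see
#'   [morphology_library()]).
#' @param amplitude template peak amplitude, arbitrary recording units.
#' @param duration template duration in seconds.
#' @return Object of class `motoneuron_spec`.
#' @export
motoneuron_spec <- function(id, fiber_type = c("S", "FR", "FF"), curve,
                            process, morphology_id, amplitude, duration) {
  fiber_type <- match.arg(fiber_type)
  if (!inherits(curve, "firing_curve")) stop_validation("curve must be a firing_curve")
  if (!inherits(process, "point_process")) stop_validation("process must be a point_process")
  if (amplitude <= 0) stop_validation("amplitude must be positive")
  if (duration <= 0) stop_validation("duration must be positive")
  structure(list(id = id, fiber_type = fiber_type, curve = curve,
                 process = process, morphology_id = morphology_id,
                 amplitude = amplitude, duration = duration),
            class = "motoneuron_spec")
}

#' Generate spike event times for one motoneuron
#'
#' Sequential-ISI realization of the rate-modulated point process: from the
#' current time, the rate `f(x(t))` is evaluated at the nearest sample; if it
#' is zero the clock advances to the next sample where the unit is recruited,
#' otherwise an ISI with mean `1/f` is drawn and the next event placed one
#' ISI later. The rate is frozen at the time of the previous event, which is
#' adequate for intent signals that vary slowly relative to the ISI. The
#' first event falls one drawn ISI after the first recruited sample; events
#' beyond the grid are discarded.
#'
#' @param mn a [motoneuron_spec()] (only `curve` and `process` are used).
#' @param activation_row numeric activation trace, length `grid$n_samples`.
#' @param grid the [time_grid()].
#' @param seed integer seed for this unit's private substream.
#' @return Object of class `spike_train`: fields `event_times` (strictly
#'   increasing, within `[0, T]`), `motoneuron_id`, `grid`.
#' @export
generate_spike_times <- function(mn, activation_row, grid, seed) {
  if (length(activation_row) != grid$n_samples)
    stop_validation("activation length != grid n_samples")
  f <- firing_rate(mn$curve, activation_row)
  n <- grid$n_samples
  dt <- 1 / grid$sampling_rate
  t_end <- grid$duration
  active_idx <- which(f > 0)
  events <- numeric(0)
  if (length(active_idx)) {
    events <- with_seed(seed, {
      ev <- numeric(512)
      k <- 0L
      t <- (active_idx[1] - 1) * dt
      repeat {
        i <- min(n, floor(t / dt + 1e-9) + 1L)
        if (f[i] <= 0) {
          nxt <- active_idx[active_idx >= i]
          if (!length(nxt)) break
          t <- (nxt[1] - 1) * dt
          i <- nxt[1]
        }
        t <- t + draw_isi(mn$process, 1 / f[i], 1L)
        if (t > t_end) break
        k <- k + 1L
        if (k > length(ev)) ev <- c(ev, numeric(length(ev)))
        ev[k] <- t
      }
      ev[seq_len(k)]
    })
  }
  structure(list(event_times = events, motoneuron_id = mn$id, grid = grid),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d events on [0, %g] s\n",
              format(x$motoneuron_id), length(x$event_times), x$grid$duration))
  invisible(x)
}

#' Sample a motoneuron pool uniformly from parameter ranges
#'
#' Each parameter is drawn independently and uniformly within its
#' `c(low, high)` range. If a draw violates the curve invariants (threshold
#' at or above saturation, or rate at threshold above rate at saturation),
#' the offending pair is redrawn up to 100 times before erroring, which
#' preserves marginal uniformity for valid configurations.
#'
#' @param ranges named list of length-2 numeric ranges: `duration` (s),
#'   `amplitude` (recording units), `f_thr` (Hz), `f_sat` (Hz), `x_thr`,
#'   `x_sat` (activation fractions in [0, 1]).
#' @param count number of motoneurons, >= 1.
#' @param fiber_type fiber class label for all sampled units.
#' @param process a shared [point_process()] (default Poisson).
#' @param morphology_ids candidate morphology names; one is drawn per unit.
#' @param seed integer seed.
#' @param id_offset integer added to unit ids (for assembling several pools).
#' @return List of [motoneuron_spec()] objects.
#' @export
sample_pool <- function(ranges, count, fiber_type = "S",
                        process = point_process("poisson"),
                        morphology_ids = names(morphology_library()),
                        seed = 1, id_offset = 0) {
  if (!is.numeric(count) || count < 1)
    stop_config("count must be >= 1")
  needed <- c("duration", "amplitude", "f_thr", "f_sat", "x_thr", "x_sat")
  missing <- setdiff(needed, names(ranges))
  if (length(missing))
    stop_config("ranges missing: ", paste(missing, collapse = ", "))
  for (nm in needed) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop_config("range for ", nm, " must be c(low, high) with low <= high")
  }
  if (ranges$x_thr[1] >= ranges$x_sat[2])
    stop_config("x_thr/x_sat ranges cannot satisfy x_thr < x_sat")
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      draw <- function(nm) runif(1, ranges[[nm]][1], ranges[[nm]][2])
      x_thr <- draw("x_thr"); x_sat <- draw("x_sat")
      tries <- 0
      while (x_thr >= x_sat) {
        tries <- tries + 1
        if (tries > 100) stop_config("could not draw x_thr < x_sat in 100 tries")
        x_thr <- draw("x_thr"); x_sat <- draw("x_sat")
      }
      f_thr <- draw("f_thr"); f_sat <- draw("f_sat")
      tries <- 0
      while (f_thr > f_sat) {
        tries <- tries + 1
        if (tries > 100) stop_config("could not draw f_thr <= f_sat in 100 tries")
        f_thr <- draw("f_thr"); f_sat <- draw("f_sat")
      }
      motoneuron_spec(
        id = id_offset + i, fiber_type = fiber_type,
        curve = firing_curve(x_thr, f_thr, x_sat, f_sat),
        process = process,
        morphology_id = if (length(morphology_ids) == 1) morphology_ids else
          sample(morphology_ids, 1),
        amplitude = draw("amplitude"),
        duration = draw("duration"))
    })
  })
}

#' Export a motoneuron pool as a delimited table
#'
#' One row per motoneuron with all curve, process, and template fields;
#' readable back with [read_pool_table()].
#'
#' @param pool list of [motoneuron_spec()].
#' @param path file path; tab-separated text.
#' @export
write_pool_table <- function(pool, path) {
  df <- do.call(rbind, lapply(pool, function(m) {
    data.frame(id = m$id, fiber_type = m$fiber_type,
               x_thr = m$curve$x_thr, f_thr = m$curve$f_thr,
               x_sat = m$curve$x_sat, f_sat = m$curve$f_sat,
               process = m$process$kind,
               dispersion = if (is.null(m$process$dispersion)) NA else m$process$dispersion,
               width = if (is.null(m$process$width)) NA else m$process$width,
               isi_floor = m$process$isi_floor,
               morphology_id = m$morphology_id,
               amplitude = m$amplitude, duration = m$duration)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motoneuron pool table written by [write_pool_table()]
#'
#' @param path file path.
#' @return List of [motoneuron_spec()].
#' @export
read_pool_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    motoneuron_spec(
      id = r$id, fiber_type = r$fiber_type,
      curve = firing_curve(r$x_thr, r$f_thr, r$x_sat, r$f_sat),
      process = point_process(r$process,
                              dispersion = if (is.na(r$dispersion)) NULL else r$dispersion,
                              width = if (is.na(r$width)) NULL else r$width,
                              isi_floor = r$isi_floor),
      morphology_id = r$morphology_id,
      amplitude = r$amplitude, duration = r$duration)
  })
}

#' Export spike trains as a two-column event list
#'
#' @param trains list of `spike_train` objects.
#' @param path file path; tab-separated columns `motoneuron_id`, `time_s`.
#' @export
write_spike_events <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$event_times)) return(NULL)
    data.frame(motoneuron_id = tr$motoneuron_id, time_s = tr$event_times)
  }))
  if (is.null(df))
    df <- data.frame(motoneuron_id = integer(0), time_s = numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
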