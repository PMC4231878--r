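# Shared fixture builders; everything is generated in code.

quick_grid <- function(duration = 1, rate = 20000) time_grid(rate, duration)

# a motoneuron with a fixed curve, handy for deterministic train tests
unit_with_rate <- function(f, process = point_process("identity"),
                           duration = 0.004, amplitude = 60) {
  motoneuron_spec(1, "S",
                  curve = firing_curve(0, f, 0.5, f),
                  process = process,
                  morphology_id = "symmetric_1peak",
                  amplitude = amplitude, duration = duration)
}

# explicit spike train without running the generator
manual_train <- function(times, grid, id = 1) {
  structure(list(event_times = times, motoneuron_id = id, grid = grid),
            class = "spike_train")
}

# brute-force per-sample spike occupancy counter (oracle for percent_overlap)
overlap_oracle <- function(trains, durations, grid) {
  n <- grid$n_samples
  fs <- grid$sampling_rate
  counts <- integer(n)
  for (k in seq_along(trains)) {
    active <- logical(n)
    len <- max(1L, as.integer(round(durations[k] * fs)))
    for (ev in trains[[k]]$event_times) {
      i0 <- as.integer(round(ev * fs)) + 1L
      if (i0 > n) next
      active[i0:min(n, i0 + len - 1L)] <- TRUE
    }
    counts <- counts + active
  }
  100 * mean(counts >= 2L)
}

# brute-force per-event accumulation (oracle for record()/render)
record_oracle <- function(trains, templates, H, grid) {
  n <- grid$n_samples
  z <- matrix(0, nrow = nrow(H), ncol = n)
  for (e in seq_len(nrow(H))) {
    for (a in seq_along(trains)) {
      w <- templates[[a]]$samples
      for (ev in trains[[a]]$event_times) {
        i0 <- as.integer(round(ev * grid$sampling_rate)) + 1L
        if (i0 > n) next
        j <- i0:min(n, i0 + length(w) - 1L)
        z[e, j] <- z[e, j] + H[e, a] * w[seq_along(j)]
      }
    }
  }
  z
}
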