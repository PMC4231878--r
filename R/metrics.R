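## Analysis metrics: spike overlap, composite rate, bandpass + Welch spectra,
## moving-average decoding, quiescent normalization.

#' Percent spike overlap across axons
#'
#' Fraction of recording time during which spikes from two or more axons are
#' simultaneously present on the electrode, as a percentage. An axon's spike
#' occupies the half-open interval `[event, event + duration)` (half-open so
#' abutting spikes are not double counted); a sample counts as overlap when
#' at least two distinct axons are active there. Overlap distorts composite
#' waveforms and is a key difficulty knob for spike-based decoders.
#'
#' @param trains list of `spike_train` objects (the axons on one electrode).
#' @param durations numeric vector of per-axon template durations in seconds
#'   (recycled if length 1).
#' @param grid the [time_grid()].
#' @return Percentage of samples with >= 2 active axons, in [0, 100].
#' @export
percent_overlap <- function(trains, durations, grid) {
  if (length(trains) < 1) stop_validation("need at least one spike train")
  durations <- rep_len(durations, length(trains))
  n <- grid$n_samples
  fs <- grid$sampling_rate
  occ <- integer(n)
  for (k in seq_along(trains)) {
    ev <- trains[[k]]$event_times
    if (!length(ev)) next
    s <- as.integer(round(ev * fs)) + 1L
    s <- s[s <= n]
    if (!length(s)) next
    len <- max(1L, as.integer(round(durations[k] * fs)))
    e <- pmin(n, s + len - 1L)
    # difference-array occupancy, binarized per axon
    d <- tabulate(s, n + 1L) - tabulate(pmin(e + 1L, n + 1L), n + 1L)
    occ <- occ + as.integer(cumsum(d[seq_len(n)]) > 0L)
  }
  100 * mean(occ >= 2L)
}

#' Composite firing rate of an electrode
#'
#' Total number of spikes summed over all contributing axons, divided by the
#' observation window.
#'
#' @param trains list of `spike_train` objects.
#' @param window observation window in seconds, > 0.
#' @return Spikes per second.
#' @export
composite_rate <- function(trains, window) {
  if (window <= 0) stop_validation("window must be > 0")
  sum(vapply(trains, function(tr) length(tr$event_times), integer(1))) / window
}

#' Zero-phase Butterworth band-pass filter
#'
#' A Butterworth band-pass of the given overall order (poles split evenly
#' between the two band edges) applied forward-backward with
#' [signal::filtfilt()] so the output has zero phase shift and spike timing
#' is unaffected. DC is rejected by construction.
#'
#' @param trace numeric signal.
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @param rate sampling rate in Hz.
#' @param order overall filter order (even), default 4.
#' @return Filtered trace.
#' @export
bandpass <- function(trace, low = 80, high = 4000, rate, order = 4) {
  nyq <- rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop_validation("need 0 < low < high < Nyquist")
  if (order %% 2 != 0) stop_validation("order must be even")
  bf <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  # reflect-pad both ends so filter start-up transients stay out of the data
  n <- length(trace)
  pad <- min(n - 1, ceiling(3 * rate / low))
  padded <- c(2 * trace[1] - trace[(pad + 1):2],
              trace,
              2 * trace[n] - trace[(n - 1):(n - pad)])
  out <- signal::filtfilt(bf, padded)
  out[(pad + 1):(pad + n)]
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed segments of `window_sec`
#' seconds with the given fractional overlap, each demeaned, scaled so that
#' the one-sided PSD integrates to the signal variance (Parseval).
#'
#' @param trace numeric signal.
#' @param rate sampling rate in Hz.
#' @param window_sec segment length in seconds (default 0.5).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return data.frame with columns `frequency` (Hz) and `power`
#'   (units^2 / Hz), one-sided.
#' @export
psd_welch <- function(trace, rate, window_sec = 0.5, overlap = 0.5) {
  L <- as.integer(round(window_sec * rate))
  if (length(trace) < L)
    stop_validation("trace shorter than one Welch window")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(trace) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))  # Hann
  U <- sum(w^2)
  acc <- numeric(L %/% 2 + 1)
  for (s0 in starts) {
    seg <- trace[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2 / (rate * U)
    half <- P[seq_len(L %/% 2 + 1)]
    # one-sided: double all bins except DC (and Nyquist for even L)
    half[2:(length(half) - 1)] <- 2 * half[2:(length(half) - 1)]
    if (L %% 2 == 1) half[length(half)] <- 2 * half[length(half)]
    acc <- acc + half
  }
  data.frame(frequency = (seq_along(acc) - 1) * rate / L,
             power = acc / length(starts))
}

#' Spectral summary of a recording trace
#'
#' Welch PSD (0.5 s windows, 50% overlap by default) reduced to the total
#' power (PSD integrated over the analysis band) and the power-weighted mean
#' frequency within that band.
#'
#' @param trace numeric signal (at least one window long).
#' @param grid the [time_grid()].
#' @param band analysis band in Hz, default `c(80, 4000)` matching the
#'   band-pass used upstream.
#' @param window_sec,overlap Welch parameters.
#' @return Object of class `spectral_summary`: `total_power`,
#'   `mean_frequency`, `psd` (the full frequency/power table).
#' @export
spectral_summary <- function(trace, grid, band = c(80, 4000),
                             window_sec = 0.5, overlap = 0.5) {
  psd <- psd_welch(trace, grid$sampling_rate, window_sec, overlap)
  df <- psd$frequency[2] - psd$frequency[1]
  sel <- psd$frequency >= band[1] & psd$frequency <= band[2]
  p <- psd$power[sel]
  f <- psd$frequency[sel]
  total <- sum(p) * df
  structure(list(total_power = total,
                 mean_frequency = if (total > 0) sum(f * p) / sum(p) else NA_real_,
                 psd = psd),
            class = "spectral_summary")
}

#' Moving-average decoder
#'
#' The simplest intent estimator: rectify the trace (squaring by default,
#' absolute value optionally), average over a sliding window (default
#' 200 ms; causal, with partial windows at the start), and optionally
#' normalize the result to [0, 1] over the trial.
#'
#' @param trace recorded (or simulated) electrode signal.
#' @param rate sampling rate in Hz.
#' @param window averaging window in seconds (>= 2 samples).
#' @param transform `"square"` or `"abs"`.
#' @param normalize rescale output to [0, 1] over the trial (default TRUE).
#' @return Decoded trajectory, same length as `trace`.
#' @export
moving_average_decode <- function(trace, rate, window = 0.2,
                                  transform = c("square", "abs"),
                                  normalize = TRUE) {
  transform <- match.arg(transform)
  k <- as.integer(round(window * rate))
  if (k < 2) stop_validation("window must span at least 2 samples")
  r <- if (transform == "square") trace^2 else abs(trace)
  ma <- moving_average(r, k)
  if (!normalize) return(ma)
  rng <- range(ma)
  if (rng[2] == rng[1]) return(rep(0, length(ma)))
  (ma - rng[1]) / (rng[2] - rng[1])
}

# Causal moving average with partial windows at the start.
moving_average <- function(x, k) {
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  head_n <- seq_len(min(k, n))
  out[head_n] <- cs[head_n] / head_n
  if (n > k) out[(k + 1):n] <- (cs[(k + 1):n] - cs[1:(n - k)]) / k
  out
}

#' Normalize a trace by its quiescent-phase standard deviation
#'
#' Scales the whole trace by the standard deviation measured during a
#' quiescent (null motor intent) segment, putting recordings from different
#' electrodes or sessions on a common noise-referenced scale.
#'
#' @param trace numeric signal.
#' @param quiescent_idx integer indices of the quiescent segment (>= 100
#'   samples, all within the trace).
#' @return `trace / sd(trace[quiescent_idx])`.
#' @export
quiescent_normalize <- function(trace, quiescent_idx) {
  if (length(quiescent_idx) < 100)
    stop_validation("quiescent segment must have at least 100 samples")
  if (any(quiescent_idx < 1 | quiescent_idx > length(trace)))
    stop_validation("quiescent segment outside the trace")
  s <- sd(trace[quiescent_idx])
  if (s == 0) stop_validation("zero-variance quiescent segment")
  trace / s
}

#' Fit the log-log slope of a noise PSD
#'
#' Linear regression of `log10(power)` on `log10(frequency)` over a mid-band
#' frequency range of the Welch PSD; used to verify 1/f^beta noise synthesis
#' (expected slope `-beta`).
#'
#' @param trace noise trace.
#' @param rate sampling rate in Hz.
#' @param f_range frequency range for the fit (default 10 Hz to a quarter of
#'   the sampling rate).
#' @return Fitted slope.
#' @export
psd_loglog_slope <- function(trace, rate, f_range = c(10, rate / 4)) {
  psd <- psd_welch(trace, rate, window_sec = min(1, length(trace) / rate / 8))
  sel <- psd$frequency >= f_range[1] & psd$frequency <= f_range[2] & psd$power > 0
  fit <- stats::lm(log10(power) ~ log10(frequency), data = psd[sel, ])
  unname(stats::coef(fit)[2])
}
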