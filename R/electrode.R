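## Electrode mixing (H = C B), noise models, and recording assembly.

#' Electrode mixing matrices
#'
#' `B` (l x m) maps the m axons onto l *virtual* electrodes, one per motor
#' pool, so `v(t) = B y(t)` are the crosstalk-free pool signals. `C` (l x l)
#' mixes virtual electrodes into physical electrodes, modeling crosstalk
#' between motor pools; with `C = I` (the usual LIFE assumption, since an
#' electrode in one fascicle records from one pool) `H = B`. Gains near 1
#' represent close, unencapsulated fibers; increased distance, encapsulation,
#' and (static) drift are modeled by smaller values.
#'
#' @param B l x m non-negative gain matrix (pool -> virtual electrodes).
#' @param C l x l non-negative crosstalk matrix; default identity.
#' @return Object of class `electrode_mapping` with derived `H = C %*% B`
#'   and electrode count `l`.
#' @export
electrode_mapping <- function(B, C = NULL) {
  B <- as.matrix(B)
  l <- nrow(B)
  if (is.null(C)) C <- diag(l)
  C <- as.matrix(C)
  if (nrow(C) != l || ncol(C) != l)
    stop_validation("C must be ", l, " x ", l, " to match B")
  if (any(!is.finite(B)) || any(B < 0) || any(!is.finite(C)) || any(C < 0))
    stop_validation("mixing gains must be finite and >= 0")
  structure(list(B = B, C = C, H = C %*% B, l = l), class = "electrode_mapping")
}

#' Compose B and C into a mixing specification
#'
#' Convenience wrapper equivalent to [electrode_mapping()]; kept as the
#' explicit "H = C B" composition step.
#'
#' @inheritParams electrode_mapping
#' @return An `electrode_mapping`.
#' @export
compose_mapping <- function(B, C = NULL) electrode_mapping(B, C)

#' Virtual-electrode (pure motor pool) signals
#'
#' @param axons an `axon_signals` object.
#' @param mapping an [electrode_mapping()].
#' @return l x n_samples matrix `v(t) = B y(t)`.
#' @export
virtual_signals <- function(axons, mapping) {
  if (ncol(mapping$B) != nrow(axons$values))
    stop_validation("B column count != axon count")
  mapping$B %*% axons$values
}

#' Noise standard deviation for a target SNR
#'
#' The SNR convention ties the noise scale to the dynamic range of the pure
#' neural signal: `sigma = (Q_99.9 - Q_0.1) / (3 * snr)`, where the Qs are
#' the 99.9th and 0.1st percentiles of the noise-free electrode trace.
#'
#' @param pure_trace noise-free composite electrode trace.
#' @param snr target signal-to-noise ratio, > 0.
#' @return Noise standard deviation in recording units.
#' @export
noise_sigma_from_snr <- function(pure_trace, snr) {
  if (!is.numeric(snr) || snr <= 0) stop_validation("snr must be > 0")
  q <- quantile(pure_trace, c(0.999, 0.001), names = FALSE)
  span <- q[1] - q[2]
  if (span <= 0)
    stop_validation("constant trace: SNR scaling undefined")
  span / (3 * snr)
}

#' Measured SNR of a recording
#'
#' Recomputes the SNR convention of [noise_sigma_from_snr()] from generated
#' data: percentile span of the pure trace over three times the noise
#' standard deviation.
#'
#' @param pure_trace noise-free electrode trace.
#' @param noise_trace the additive noise that was applied.
#' @return Measured SNR.
#' @export
measured_snr <- function(pure_trace, noise_trace) {
  q <- quantile(pure_trace, c(0.999, 0.001), names = FALSE)
  (q[1] - q[2]) / (3 * sd(noise_trace))
}

#' Noise model specification
#'
#' @param model `"none"`, `"powerlaw"` (1/f^beta spectral synthesis),
#'   `"gaussian_snr"` (band-limited Gaussian white noise calibrated to a
#'   target SNR), or `"file"` (noise time series from delimited text).
#' @param beta spectral exponent for `powerlaw`, >= 0 (0 = white).
#' @param amplitude output standard deviation for `powerlaw`.
#' @param snr target SNR for `gaussian_snr`, > 0.
#' @param band length-2 passband in Hz for `gaussian_snr`; must lie inside
#'   (0, Nyquist).
#' @param shared_across_electrodes if TRUE all electrodes receive the same
#'   noise realization; default FALSE (independent noise per electrode).
#' @param path,rate source file and its sampling rate for `"file"` (one
#'   column, no header; linearly resampled onto the grid if rates differ).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("none", "powerlaw", "gaussian_snr", "file"),
                       beta = 2, amplitude = 1, snr = 3,
                       band = c(100, 7500), shared_across_electrodes = FALSE,
                       path = NULL, rate = NULL) {
  model <- match.arg(model)
  if (model == "powerlaw" && beta < 0) stop_validation("beta must be >= 0")
  if (model == "gaussian_snr") {
    if (snr <= 0) stop_validation("snr must be > 0")
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
      stop_validation("band must be increasing and positive")
  }
  if (model == "file" && (is.null(path) || is.null(rate)))
    stop_config("file noise requires path and rate")
  structure(list(model = model, beta = beta, amplitude = amplitude, snr = snr,
                 band = band, shared_across_electrodes = shared_across_electrodes,
                 path = path, rate = rate),
            class = "noise_spec")
}

#' Synthesize power-law (1/f^beta) noise
#'
#' Spectral synthesis: white Gaussian noise is shaped in the frequency domain
#' by `|f|^(-beta/2)` with the DC bin zeroed (the shaping gain is symmetric,
#' so Hermitian symmetry is preserved and the output is real), then scaled to
#' the requested standard deviation.
#'
#' @param beta spectral exponent >= 0; the PSD falls as `f^-beta`.
#' @param amplitude output standard deviation.
#' @param grid the [time_grid()].
#' @param seed integer seed.
#' @return Numeric noise trace of length `grid$n_samples`.
#' @export
generate_powerlaw_noise <- function(beta, amplitude, grid, seed) {
  if (beta < 0) stop_validation("beta must be >= 0")
  n <- grid$n_samples
  x <- with_seed(seed, rnorm(n))
  X <- fft(x)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)                      # two-sided |frequency| index
  gain <- c(0, (k[-1] * grid$sampling_rate / n)^(-beta / 2))
  y <- Re(fft(X * gain, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- sd(y)
  if (s == 0) return(y)
  y * (amplitude / s)
}

#' Generate band-limited Gaussian noise calibrated to a target SNR
#'
#' White Gaussian noise is band-limited with a zero-phase 4th-order
#' Butterworth band-pass, then rescaled so that its standard deviation equals
#' [noise_sigma_from_snr()] of the pure electrode trace.
#'
#' @param spec a [noise_spec()] with `model = "gaussian_snr"`.
#' @param pure_trace the noise-free composite trace of the electrode.
#' @param grid the [time_grid()].
#' @param seed integer seed.
#' @param sigma optional pre-computed noise standard deviation; overrides the
#'   SNR calibration (used when one noise floor must be held fixed across
#'   several trials).
#' @return Numeric noise trace.
#' @export
generate_gaussian_noise <- function(spec, pure_trace, grid, seed, sigma = NULL) {
  nyq <- grid$sampling_rate / 2
  if (spec$band[2] >= nyq)
    stop_validation("noise band must lie below the Nyquist frequency")
  if (is.null(sigma)) sigma <- noise_sigma_from_snr(pure_trace, spec$snr)
  x <- with_seed(seed, rnorm(grid$n_samples))
  bf <- signal::butter(2, spec$band / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  y * (sigma / sd(y))
}

read_noise_file <- function(spec, grid) {
  v <- scan(spec$path, quiet = TRUE)
  t_src <- (seq_along(v) - 1) / spec$rate
  approx(t_src, v, xout = grid_times(grid), rule = 2)$y
}

#' Assemble a multi-electrode recording
#'
#' Computes `z(t) = H y(t) + W(t)` and retains full ground truth: the pure
#' (noise-free) electrode traces, the per-electrode noise, the mixing, and
#' the contributing spike trains.
#'
#' @param axons an `axon_signals` object (carries its spike trains).
#' @param mapping an [electrode_mapping()].
#' @param noise a [noise_spec()].
#' @param grid the [time_grid()].
#' @param seed integer master seed; per-electrode noise substreams are
#'   derived from it.
#' @param noise_sigma optional numeric vector (length l) of fixed noise
#'   standard deviations, bypassing per-trace SNR calibration.
#' @return Object of class `recording`: `grid`, `values` (l x n_samples),
#'   `pure`, `noise`, `mapping`, `trains`, `noise_model`.
#' @export
record <- function(axons, mapping, noise = noise_spec("none"), grid = axons$grid,
                   seed = 1, noise_sigma = NULL) {
  if (ncol(mapping$H) != nrow(axons$values))
    stop_validation("H column count != axon count")
  pure <- mapping$H %*% axons$values
  l <- mapping$l
  W <- matrix(0, nrow = l, ncol = grid$n_samples)
  if (noise$model != "none") {
    for (e in seq_len(l)) {
      sd_e <- derive_seed(seed, "noise",
                          if (noise$shared_across_electrodes) 0 else e)
      W[e, ] <- switch(noise$model,
        powerlaw = generate_powerlaw_noise(noise$beta, noise$amplitude, grid, sd_e),
        gaussian_snr = generate_gaussian_noise(noise, pure[e, ], grid, sd_e,
                                               sigma = noise_sigma[e]),
        file = read_noise_file(noise, grid))
    }
  }
  structure(list(grid = grid, values = pure + W, pure = pure, noise = W,
                 mapping = mapping, trains = axons$trains,
                 noise_model = noise$model),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d electrode(s), %g s @ %g Hz, noise: %s\n",
              nrow(x$values), x$grid$duration, x$grid$sampling_rate,
              x$noise_model))
  invisible(x)
}

#' Write a recording as multichannel delimited text with a manifest
#'
#' Produces `<path>` (tab-separated, `time_s` + one column per electrode) and
#' `<path>.manifest.json` (channel labels, rate, seed, config hash if given).
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @param seed seed used for the run (recorded in the manifest).
#' @param config_hash optional configuration hash string.
#' @export
write_recording <- function(rec, path, seed = NA, config_hash = NA) {
  df <- data.frame(time_s = grid_times(rec$grid), t(rec$values))
  names(df) <- c("time_s", paste0("electrode", seq_len(nrow(rec$values))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(channels = names(df)[-1],
                   sampling_rate = rec$grid$sampling_rate,
                   duration = rec$grid$duration,
                   noise_model = rec$noise_model,
                   seed = seed, config_hash = config_hash,
                   package_version = as.character(utils::packageVersion("lifesim")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
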