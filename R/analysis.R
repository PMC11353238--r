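# Spectral and spatiotemporal analyses: Welch PSD, relative band power,
# activity maps, spectrogram, amplitude x frequency entrainment sweep.

# Periodic Hann window (standard for averaged periodograms).
hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Welch power spectral density
#'
#' Averaged periodogram over overlapping Hann-windowed segments.  The signal
#' is demeaned globally and each segment is demeaned again before windowing.
#' The estimate is a one-sided density scaled so that
#' `sum(power) * df` approximates the signal variance (Parseval).
#'
#' @param x sampled signal.
#' @param fs sampling rate, Hz.
#' @param window_s segment length, seconds (default 1).
#' @param overlap_frac fractional overlap between segments (default 0.5).
#' @return An object of class `tacs_spectrum`: list with `freqs` (Hz),
#'   `power` (density, signal-units^2/Hz), `fs`, `window_s`, `overlap_frac`,
#'   `n_segments`.
#' @examples
#' t <- seq(0, 10, by = 1 / 200)
#' sp <- welch_psd(sin(2 * pi * 4 * t), fs = 200)
#' sp$freqs[which.max(sp$power)]
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap_frac = 0.5) {
  nper <- as.integer(round(window_s * fs))
  if (nper < 4) stop("window too short: fewer than 4 samples", call. = FALSE)
  if (length(x) < nper) {
    stop("signal (", length(x), " samples) is shorter than one window (",
         nper, " samples); use a shorter window_s", call. = FALSE)
  }
  x <- x - mean(x)
  step <- max(1L, as.integer(round(nper * (1 - overlap_frac))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann(nper)
  norm <- fs * sum(w^2)
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / norm
    p <- p[seq_len(nfreq)]
    # fold two-sided density into one-sided (not doubling DC / Nyquist)
    dbl <- seq(2L, nfreq - if (nper %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  structure(list(freqs = (seq_len(nfreq) - 1L) * fs / nper,
                 power = acc / length(starts),
                 fs = fs, window_s = window_s, overlap_frac = overlap_frac,
                 n_segments = length(starts)),
            class = "tacs_spectrum")
}

#' @export
print.tacs_spectrum <- function(x, ...) {
  cat(sprintf("tacs_spectrum: %d bins, df = %.3g Hz, %d segments of %g s\n",
              length(x$freqs), x$freqs[2] - x$freqs[1], x$n_segments,
              x$window_s))
  cat(sprintf("  peak: %.3g Hz\n", x$freqs[which.max(x$power)]))
  invisible(x)
}

#' @export
plot.tacs_spectrum <- function(x, xlim = c(0, 20), ...) {
  graphics::plot(x$freqs, x$power, type = "h", xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "PSD",
                 main = "Welch power spectral density", ...)
  invisible(x)
}

# Sum of power*df over bins whose frequency lies in [lo, hi] (inclusive,
# with a small tolerance against floating-point bin edges).
band_power <- function(spec, lo, hi) {
  df <- spec$freqs[2] - spec$freqs[1]
  keep <- spec$freqs >= lo - 1e-9 & spec$freqs <= hi + 1e-9
  if (!any(keep)) stop("no spectral bins inside band [", lo, ", ", hi, "] Hz",
                       call. = FALSE)
  sum(spec$power[keep]) * df
}

#' Relative band power around a target frequency
#'
#' Fraction of spectral power in `[f0 - half_band, f0 + half_band]` relative
#' to the power in `total_band`.  This is the entrainment measure used
#' throughout the package: a value near 1 means the activity is essentially
#' a pure oscillation at `f0`.
#'
#' @param spec a `tacs_spectrum`.
#' @param f0 target frequency, Hz.
#' @param half_band half-width of the target band, Hz (default 0.5).
#' @param total_band reference band, Hz (default `c(0.5, 50)`).
#' @return A fraction in \[0, 1\].
#' @export
relative_power <- function(spec, f0, half_band = 0.5,
                           total_band = c(0.5, 50)) {
  stopifnot(inherits(spec, "tacs_spectrum"), half_band > 0)
  if (f0 < total_band[1] || f0 > total_band[2]) {
    stop("f0 must lie within total_band", call. = FALSE)
  }
  hi <- min(total_band[2], spec$freqs[length(spec$freqs)])
  band_power(spec, max(total_band[1], f0 - half_band),
             min(hi, f0 + half_band)) /
    band_power(spec, total_band[1], hi)
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the maximum-power bin within `band`.
#'
#' @param spec a `tacs_spectrum`.
#' @param band search band, Hz.
#' @return Frequency, Hz.
#' @export
dominant_frequency <- function(spec, band = c(0.5, 10)) {
  keep <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  if (!length(keep)) stop("no spectral bins inside the search band",
                          call. = FALSE)
  spec$freqs[keep[which.max(spec$power[keep])]]
}

#' Spatial activity map over the neuron grid
#'
#' Per-grid-cell spike count within `[t_center - half_window,
#' t_center + half_window]`, arranged by the population's 2-D coordinates.
#' Useful for visualising the lateral spread of an UP state.
#'
#' @param spikes data frame with `time_ms` and `neuron_id` (as in
#'   `tacs_sim$spikes_ex`).
#' @param grid_shape integer pair (rows, cols).
#' @param t_center window centre, ms.
#' @param half_window half window, ms.
#' @return A `rows x cols` matrix of spike counts.
#' @export
activity_map <- function(spikes, grid_shape, t_center, half_window) {
  n <- prod(grid_shape)
  keep <- spikes$time_ms >= t_center - half_window &
    spikes$time_ms <= t_center + half_window
  counts <- tabulate(spikes$neuron_id[keep], n)
  matrix(counts, nrow = grid_shape[1], ncol = grid_shape[2], byrow = TRUE)
}

#' Short-time spectrogram
#'
#' Hann-windowed FFT power over sliding windows; column `j` covers the
#' window centred at `times[j]`.
#'
#' @param x sampled signal.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param step_s hop between window centres, seconds.
#' @return An object of class `tacs_spectrogram`: `freqs` (Hz), `times` (s,
#'   window centres), `power` (freq x time matrix).
#' @export
spectrogram <- function(x, fs, window_s = 1, step_s = 0.25) {
  nper <- as.integer(round(window_s * fs))
  if (length(x) < nper) {
    stop("signal is shorter than one window; use a shorter window_s",
         call. = FALSE)
  }
  step <- max(1L, as.integer(round(step_s * fs)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann(nper)
  norm <- fs * sum(w^2)
  nfreq <- nper %/% 2 + 1L
  pw <- vapply(starts, function(s) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / norm
    p <- p[seq_len(nfreq)]
    dbl <- seq(2L, nfreq - if (nper %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    p
  }, numeric(nfreq))
  structure(list(freqs = (seq_len(nfreq) - 1L) * fs / nper,
                 times = (starts - 1L + nper / 2) / fs,
                 power = pw),
            class = "tacs_spectrogram")
}

#' @export
plot.tacs_spectrogram <- function(x, fmax = 20, ...) {
  keep <- x$freqs <= fmax
  graphics::image(x$times, x$freqs[keep], t(x$power[keep, , drop = FALSE]),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = "spectrogram", col = grDevices::hcl.colors(64),
                  ...)
  invisible(x)
}

#' Amplitude-by-frequency entrainment sweep (Arnold tongue)
#'
#' Runs the full simulation for every (amplitude, frequency) pair over
#' `n_seeds` seeds and records the mean relative power at the stimulation
#' frequency (for `frequency == 0` cells no stimulus is delivered and the
#' relative power is measured at `f0_baseline`, the endogenous frequency).
#' Wider high-power regions at higher amplitudes trace the Arnold tongue.
#'
#' @param amplitudes tACS amplitudes, pA.
#' @param frequencies tACS frequencies, Hz; 0 means unstimulated baseline.
#' @param config base [tacs_config()]; its seed spawns per-cell seeds.
#' @param n_seeds independent simulations per cell.
#' @param f0_baseline frequency at which baseline cells are scored, Hz.
#' @return An object of class `tacs_sweep`: `amplitudes`, `frequencies`,
#'   `relative_power` (amplitude x frequency matrix of seed means),
#'   `runs` (long data frame: amplitude, frequency, seed, relative_power).
#' @export
entrainment_sweep <- function(amplitudes, frequencies,
                              config = tacs_config(), n_seeds = 5,
                              f0_baseline = 4) {
  runs <- expand.grid(seed_idx = seq_len(n_seeds), frequency = frequencies,
                      amplitude = amplitudes)
  runs$seed <- config$seed + 1000L * (seq_len(nrow(runs)) - 1L)
  runs$relative_power <- NA_real_
  an <- config$analysis
  for (r in seq_len(nrow(runs))) {
    cfg <- config
    cfg$seed <- runs$seed[r]
    f <- runs$frequency[r]
    proto <- if (f > 0) {
      stimulus_protocol("tacs", amplitude = runs$amplitude[r], frequency = f)
    } else {
      stimulus_protocol("none")
    }
    sim <- run_simulation(cfg, proto)
    act <- population_activity(sim$spikes_ex$time_ms,
                               sim$spikes_ex$neuron_id, n = sim$n_ex,
                               bin_ms = an$psd_bin_ms,
                               duration_ms = sim$duration_ms)
    spec <- welch_psd(act$pct, fs = act$fs,
                      window_s = an$window_s, overlap_frac = an$overlap)
    f0 <- if (f > 0) f else f0_baseline
    runs$relative_power[r] <- relative_power(spec, f0, an$half_band,
                                             an$total_band)
  }
  mat <- matrix(NA_real_, length(amplitudes), length(frequencies),
                dimnames = list(amplitudes, frequencies))
  for (i in seq_along(amplitudes)) {
    for (j in seq_along(frequencies)) {
      sel <- runs$amplitude == amplitudes[i] &
        runs$frequency == frequencies[j]
      mat[i, j] <- mean(runs$relative_power[sel])
    }
  }
  structure(list(amplitudes = amplitudes, frequencies = frequencies,
                 relative_power = mat, seeds_per_cell = n_seeds,
                 runs = runs[, c("amplitude", "frequency", "seed",
                                 "relative_power")]),
            class = "tacs_sweep")
}

#' @export
print.tacs_sweep <- function(x, ...) {
  cat(sprintf("tacs_sweep: %d amplitudes x %d frequencies, %d seeds/cell\n",
              length(x$amplitudes), length(x$frequencies), x$seeds_per_cell))
  print(round(x$relative_power, 3))
  invisible(x)
}

#' @export
plot.tacs_sweep <- function(x, ...) {
  graphics::image(x$frequencies, x$amplitudes,
                  t(x$relative_power), xlab = "tACS frequency (Hz)",
                  ylab = "amplitude (pA)", main = "entrainment (relative power)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Export sweep results as long-format CSV
#'
#' @param sweep a `tacs_sweep`.
#' @param path output path; columns amplitude, frequency, seed,
#'   relative_power.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep$runs, path, row.names = FALSE)
  invisible(path)
}
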