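# Closed-loop controller: sliding-window FFT detection of the dominant
# frequency with statistical validation, phase/amplitude estimation at the
# dominant bin, and matched tACS triggering.

#' Segment a signal into overlapping sliding windows
#'
#' @param x sampled signal.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param step_s hop between window starts, seconds (> 0).
#' @return A list of demeaned numeric windows; each carries attributes
#'   `t_center` and `t_start` (seconds from the start of `x`).
#' @examples
#' length(sliding_windows(rnorm(2000), fs = 200, window_s = 2, step_s = 1))
#' @export
sliding_windows <- function(x, fs, window_s, step_s) {
  if (step_s <= 0) stop("step_s must be > 0", call. = FALSE)
  nper <- as.integer(round(window_s * fs))
  if (nper > length(x)) {
    stop("window (", nper, " samples) exceeds signal length (", length(x),
         ")", call. = FALSE)
  }
  step <- max(1L, as.integer(round(step_s * fs)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  lapply(starts, function(s) {
    w <- x[s:(s + nper - 1L)]
    w <- w - mean(w)
    attr(w, "t_start") <- (s - 1L) / fs
    attr(w, "t_center") <- (s - 1L + nper / 2) / fs
    w
  })
}

#' Detection criteria
#'
#' Validation thresholds for [detect_dominant_frequency()].  A peak must
#' exceed the mean of the *other* in-band magnitudes by `z_thresh` standard
#' deviations (default 4; see the methods vignette for the false-lock
#' calibration), its power must be at least 5 times the median in-band
#' power, a candidate whose subharmonic (f/2) carries more power is demoted
#' to it, and the candidate must agree within `consistency_tol` Hz across at
#' least `consistency_n` consecutive windows.
#'
#' @param band search band, Hz (default 3-10).
#' @param z_thresh peak-significance threshold, SDs above the in-band mean.
#' @param snr_min minimum ratio of peak power to median in-band power.
#' @param harmonic_check demote to the subharmonic when it dominates?
#' @param consistency_n required count of consecutive agreeing windows.
#' @param consistency_tol agreement tolerance, Hz.
#' @return A list of class `tacs_criteria`.
#' @export
detection_criteria <- function(band = c(3, 10), z_thresh = 4, snr_min = 5,
                               harmonic_check = TRUE, consistency_n = 3L,
                               consistency_tol = 0.5) {
  structure(list(band = band, z_thresh = z_thresh, snr_min = snr_min,
                 harmonic_check = harmonic_check,
                 consistency_n = as.integer(consistency_n),
                 consistency_tol = consistency_tol),
            class = "tacs_criteria")
}

# Single-window candidate: FFT magnitude spectrum restricted to the band.
window_candidate <- function(w, fs, criteria) {
  n <- length(w)
  mag <- Mod(stats::fft(w))[seq_len(n %/% 2 + 1L)]
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * fs / n
  inband <- which(freqs >= criteria$band[1] - 1e-9 &
                    freqs <= criteria$band[2] + 1e-9)
  if (length(inband) < 3) {
    stop("search band contains fewer than 3 FFT bins; use longer windows",
         call. = FALSE)
  }
  m <- mag[inband]
  peak <- which.max(m)
  f_cand <- freqs[inband[peak]]
  # harmonic analysis: if the subharmonic carries more power, the peak is a
  # harmonic of a slower rhythm
  if (criteria$harmonic_check) {
    sub_bin <- which.min(abs(freqs - f_cand / 2))
    if (freqs[sub_bin] >= criteria$band[1] - 1e-9 &&
        mag[sub_bin] > mag[inband[peak]]) {
      f_cand <- freqs[sub_bin]
      peak <- which(inband == sub_bin)
    }
  }
  # peak significance against the other in-band bins (the peak itself would
  # inflate the reference SD and cap the attainable z-score near 3)
  others <- m[-peak]
  z <- (m[peak] - mean(others)) / stats::sd(others)
  snr <- m[peak]^2 / stats::median(m^2)
  list(f = f_cand, z = z, snr = snr,
       significant = length(others) < 2 ||
         m[peak] > mean(others) + criteria$z_thresh * stats::sd(others),
       snr_ok = snr >= criteria$snr_min,
       t_center = attr(w, "t_center"))
}

#' Detect the dominant frequency across sliding windows
#'
#' Per window, the FFT magnitude spectrum restricted to the search band is
#' scanned for its peak; the candidate is validated by (a) peak significance
#' (magnitude above mean + `z_thresh` SD of in-band magnitudes), (b)
#' signal-to-noise ratio (peak power over median in-band power at least
#' `snr_min`), (c) harmonic analysis (demotion to a dominant subharmonic),
#' and (d) consistency (`consistency_n` consecutive windows agreeing within
#' `consistency_tol` Hz, all individually valid).  `passed` requires all
#' four; `f_hat` is the mean of the agreeing candidates.
#'
#' @param windows list of windows from [sliding_windows()].
#' @param fs sampling rate, Hz.
#' @param criteria a [detection_criteria()] list.
#' @return An object of class `tacs_detection`: `passed`, `f_hat` (Hz, `NA`
#'   when not passed), `window_times`, and a `diagnostics` data frame
#'   (per-window candidate, z, SNR, validity).
#' @export
detect_dominant_frequency <- function(windows, fs,
                                      criteria = detection_criteria()) {
  cands <- lapply(windows, window_candidate, fs = fs, criteria = criteria)
  diag <- data.frame(
    t_center = vapply(cands, `[[`, numeric(1), "t_center"),
    f_candidate = vapply(cands, `[[`, numeric(1), "f"),
    significance_z = vapply(cands, `[[`, numeric(1), "z"),
    snr = vapply(cands, `[[`, numeric(1), "snr"),
    valid = vapply(cands, function(cc) cc$significant && cc$snr_ok,
                   logical(1))
  )
  passed <- FALSE
  f_hat <- NA_real_
  n_need <- criteria$consistency_n
  if (nrow(diag) >= n_need) {
    for (i in seq_len(nrow(diag) - n_need + 1L)) {
      run <- diag[i:(i + n_need - 1L), ]
      if (all(run$valid) &&
          max(run$f_candidate) - min(run$f_candidate) <=
            criteria$consistency_tol + 1e-9) {
        passed <- TRUE
        f_hat <- mean(run$f_candidate)
        # extend the run forward while agreement holds
        j <- i + n_need
        while (j <= nrow(diag) && diag$valid[j] &&
               abs(diag$f_candidate[j] - f_hat) <= criteria$consistency_tol) {
          f_hat <- mean(diag$f_candidate[i:j])
          j <- j + 1L
        }
        break
      }
    }
  }
  structure(list(passed = passed, f_hat = f_hat,
                 window_times = diag$t_center, diagnostics = diag,
                 criteria = criteria, fs = fs),
            class = "tacs_detection")
}

#' @export
print.tacs_detection <- function(x, ...) {
  if (x$passed) {
    cat(sprintf("tacs_detection: PASSED, f_hat = %.3f Hz over %d windows\n",
                x$f_hat, nrow(x$diagnostics)))
  } else {
    cat(sprintf("tacs_detection: not passed (%d windows, %d individually valid)\n",
                nrow(x$diagnostics), sum(x$diagnostics$valid)))
  }
  invisible(x)
}

#' Estimate oscillation phase and amplitude at a detected frequency
#'
#' Takes the complex Fourier coefficient of the (demeaned) window at the bin
#' nearest `f_hat`.  Under the cosine convention
#' `x(t) ~ A cos(2 pi f t + phi)`, the coefficient's argument gives the
#' phase at the window start; the phase is rotated to the window centre and
#' then extrapolated to `t_ref` via
#' `phi(t_ref) = phi_center + 2 pi f (t_ref - t_center) / 1000`, wrapped to
#' `[0, 2 pi)`.  The amplitude is `2 |coef| / N` in signal units.
#'
#' @param window a window from [sliding_windows()] (carries its centre time)
#'   or any numeric vector with `t_center` supplied explicitly.
#' @param fs sampling rate, Hz.
#' @param f_hat target frequency, Hz (must be below Nyquist).
#' @param t_ref reference time, ms, on the same clock as `t_center`.
#' @param t_center window centre, ms; defaults to the window's
#'   `t_center` attribute (seconds) converted to ms.
#' @return A list with `phase` (radians in `[0, 2 pi)` at `t_ref`),
#'   `amplitude`, and `f_bin` (the exact bin frequency used).
#' @export
estimate_phase_amplitude <- function(window, fs, f_hat, t_ref,
                                     t_center = NULL) {
  if (!is.numeric(f_hat) || f_hat <= 0 || f_hat >= fs / 2) {
    stop("f_hat must lie in (0, fs/2)", call. = FALSE)
  }
  if (is.null(t_center)) {
    tc <- attr(window, "t_center")
    if (is.null(tc)) stop("t_center is required when the window carries no ",
                          "'t_center' attribute", call. = FALSE)
    t_center <- tc * 1000
  }
  n <- length(window)
  x <- window - mean(window)
  bin <- which.min(abs((seq_len(n %/% 2 + 1L) - 1L) * fs / n - f_hat))
  f_bin <- (bin - 1L) * fs / n
  coef <- sum(x * exp(-2i * pi * (bin - 1L) * (seq_len(n) - 1L) / n))
  amplitude <- 2 * Mod(coef) / n
  phi_start <- Arg(coef)
  phi_center <- phi_start + 2 * pi * f_bin * (n / 2) / fs
  phase <- (phi_center + 2 * pi * f_hat * (t_ref - t_center) / 1000) %%
    (2 * pi)
  list(phase = phase, amplitude = amplitude, f_bin = f_bin)
}

#' Build a tACS protocol matched to a detected oscillation
#'
#' Constructs a full-wave tACS protocol whose sine peaks align with the
#' peaks of the monitored oscillation: given the cosine-convention phase of
#' the signal at `onset`, the stimulus phase is chosen so that
#' `A sin(2 pi f t / 1000 + phase)` equals `A cos(2 pi f (t - onset) / 1000
#' + phase_at_onset)`.
#'
#' @param f_hat detected frequency, Hz.
#' @param phase_at_onset signal phase (cosine convention) at `onset`,
#'   radians.
#' @param onset stimulation onset, ms.
#' @param amplitude stimulus amplitude, pA.
#' @param offset stimulation offset, ms.
#' @param target see [stimulus_protocol()].
#' @return A `tacs_protocol`.
#' @export
matched_protocol <- function(f_hat, phase_at_onset, onset, amplitude = 5,
                             offset = Inf, target = "all") {
  phase <- (phase_at_onset + pi / 2 - 2 * pi * f_hat * onset / 1000) %%
    (2 * pi)
  stimulus_protocol("tacs", amplitude = amplitude, frequency = f_hat,
                    phase = phase, onset = onset, offset = offset,
                    target = target)
}

#' Run the closed-loop stimulation pipeline
#'
#' Simulates the network unstimulated while monitoring the excitatory
#' population-activity signal.  After every monitoring step
#' (`closed_loop$step_s` seconds) the accumulated signal is segmented into
#' sliding windows and [detect_dominant_frequency()] is applied.  On the
#' first passed detection, the phase and amplitude of the last window are
#' estimated at `f_hat`, extrapolated to the next step boundary, and a
#' matched tACS protocol is delivered for the remainder of the run
#' (amplitude 5 pA by default, or `gain * amplitude_hat` under the
#' proportional policy).  If no detection passes, the run completes
#' unstimulated.
#'
#' @param config a [tacs_config()]; `engine$duration_ms` is the total run
#'   length and the `closed_loop` block sets the monitoring and validation
#'   parameters.
#' @param backend simulation backend, as in [run_simulation()].
#' @return An object of class `tacs_closed_loop` (also a `tacs_sim`) with
#'   additional fields `detection` (the final `tacs_detection`),
#'   `detection_log` (per-window diagnostics across monitoring checks),
#'   `locked` (logical), `onset_ms`, and the delivered `protocol`.
#' @export
run_closed_loop <- function(config = tacs_config(), backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  validate_config(config)
  cl <- config$closed_loop
  eng <- config$engine
  dt <- eng$dt
  bin <- eng$bin_ms
  fs <- 1000 / bin
  duration <- eng$duration_ms
  nsteps_total <- as.integer(round(duration / dt))
  steps_per_chunk <- as.integer(round(cl$step_s * 1000 / dt))
  criteria <- detection_criteria(band = cl$band, z_thresh = cl$z_thresh,
                                 snr_min = cl$snr_min,
                                 consistency_n = cl$consistency_n,
                                 consistency_tol = cl$consistency_tol)

  set.seed(config$seed)
  setup <- make_sim_setup(config)
  state <- setup$state
  chunks <- list()
  stim_log <- numeric(0)
  sp_times <- numeric(0); sp_ids <- integer(0)
  step_now <- 0L
  detection <- NULL
  detection_log <- list()
  locked <- FALSE
  onset_ms <- NA_real_
  protocol <- stimulus_protocol("none")

  while (step_now < nsteps_total && !locked) {
    nsteps <- min(steps_per_chunk, nsteps_total - step_now)
    zero <- numeric(nsteps)
    ch <- run_chunk(setup, state, zero, zero, nsteps, dt,
                    step_now * dt, backend)
    state <- ch$state
    ch$offset_steps <- step_now
    chunks[[length(chunks) + 1L]] <- ch
    stim_log <- c(stim_log, zero)
    sp_times <- c(sp_times, (ch$spike_step_ex + step_now) * dt)
    sp_ids <- c(sp_ids, ch$spike_id_ex)
    step_now <- step_now + nsteps
    t_now <- step_now * dt

    if (t_now >= cl$window_s * 1000 + (cl$consistency_n - 1L) *
          cl$step_s * 1000) {
      act <- population_activity(sp_times, sp_ids, n = setup$pop_ex$n,
                                 bin_ms = bin, duration_ms = t_now)
      wins <- sliding_windows(act$pct, fs, cl$window_s, cl$step_s)
      det <- detect_dominant_frequency(wins, fs, criteria)
      detection_log[[length(detection_log) + 1L]] <-
        cbind(checked_at_ms = t_now, det$diagnostics)
      detection <- det
      if (det$passed) {
        locked <- TRUE
        onset_ms <- t_now
        last <- wins[[length(wins)]]
        pa <- estimate_phase_amplitude(last, fs, det$f_hat, t_ref = onset_ms)
        amp <- if (cl$amplitude_policy == "proportional") {
          cl$gain * pa$amplitude
        } else {
          cl$amplitude
        }
        protocol <- matched_protocol(det$f_hat, pa$phase, onset_ms,
                                     amplitude = amp)
        attr(protocol, "amplitude_hat") <- pa$amplitude
      }
    }
  }

  if (locked && step_now < nsteps_total) {
    nsteps <- nsteps_total - step_now
    times <- (step_now + seq_len(nsteps) - 1L) * dt
    sv <- stimulus_value(protocol, times)
    ch <- run_chunk(setup, state, sv,
                    if (protocol$target == "all") sv else numeric(nsteps),
                    nsteps, dt, step_now * dt, backend)
    state <- ch$state
    ch$offset_steps <- step_now
    chunks[[length(chunks) + 1L]] <- ch
    stim_log <- c(stim_log, sv)
    step_now <- step_now + nsteps
  }

  sim <- assemble_sim(config, protocol, chunks, setup, duration, stim_log)
  sim$detection <- detection
  sim$detection_log <- if (length(detection_log)) {
    do.call(rbind, detection_log)
  } else {
    NULL
  }
  sim$locked <- locked
  sim$onset_ms <- onset_ms
  class(sim) <- c("tacs_closed_loop", class(sim))
  sim
}

#' @export
print.tacs_closed_loop <- function(x, ...) {
  NextMethod()
  if (x$locked) {
    cat(sprintf("  closed loop: locked at t = %g ms, f_hat = %.3f Hz, phase %.3f rad\n",
                x$onset_ms, x$protocol$frequency, x$protocol$phase))
  } else {
    cat("  closed loop: no validated detection; run completed unstimulated\n")
  }
  invisible(x)
}

#' Write the closed-loop detection log as CSV
#'
#' @param sim a `tacs_closed_loop`.
#' @param path output path; columns `checked_at_ms`, `t_center`,
#'   `f_candidate`, `significance_z`, `snr`, `valid`.
#' @return `path`, invisibly.
#' @export
write_detection_log_csv <- function(sim, path) {
  if (is.null(sim$detection_log)) stop("no detection log recorded",
                                       call. = FALSE)
  utils::write.csv(sim$detection_log, path, row.names = FALSE)
  invisible(path)
}

#' Read an externally sampled signal from CSV
#'
#' Accepts two-column CSV files (`time_ms`, `value`) for offline use of the
#' detector on user-supplied signals.  The sampling rate is inferred from
#' the median time step.
#'
#' @param path CSV path.
#' @return A list with `time_ms`, `value` and `fs` (Hz).
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected columns time_ms, value", call. = FALSE)
  names(df)[1:2] <- c("time_ms", "value")
  dtms <- stats::median(diff(df$time_ms))
  list(time_ms = df$time_ms, value = df$value, fs = 1000 / dtms)
}
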