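# Sliding-window detection, phase/amplitude estimation, closed-loop control.

test_that("sliding windows have the contracted count, spacing and demeaning", {
  x <- rnorm(2000)  # 10 s at 200 Hz
  w <- sliding_windows(x, 200, window_s = 2, step_s = 1)
  expect_length(w, 9)
  expect_equal(attr(w[[1]], "t_center"), 1)
  expect_equal(attr(w[[2]], "t_center"), 2)
  expect_lt(abs(mean(w[[3]])), 1e-12)

  expect_length(sliding_windows(x, 200, 10, 1), 1)
  expect_error(sliding_windows(x, 200, 11, 1), "exceeds")
  expect_error(sliding_windows(x, 200, 2, 0), "step_s")
})

test_that("detector locks onto a noisy sinusoid and rejects white noise", {
  set.seed(10)
  sig <- synthetic_signal(c(4, 1, 0.7), noise_sd = 0.32, fs = 200,
                          duration_s = 10)
  det <- detect_dominant_frequency(
    sliding_windows(sig$value, 200, 2, 0.5), 200)
  expect_true(det$passed)
  expect_gte(det$f_hat, 3.5); expect_lte(det$f_hat, 4.5)
  expect_true(all(det$diagnostics$valid))

  set.seed(20)
  wn <- rnorm(2000)
  det0 <- detect_dominant_frequency(sliding_windows(wn, 200, 2, 0.5), 200)
  expect_false(det0$passed)
  expect_true(is.na(det0$f_hat))
})

test_that("a dominant fundamental wins over a weaker harmonic", {
  sig <- synthetic_signal(rbind(c(4, 1, 0), c(8, 0.5, 1)), noise_sd = 0.1,
                          fs = 200, duration_s = 10)
  set.seed(1)
  det <- detect_dominant_frequency(sliding_windows(sig$value, 200, 2, 0.5),
                                   200)
  expect_true(det$passed)
  expect_equal(det$f_hat, 4, tolerance = 0.26)
})

test_that("phase and amplitude estimates match the analytic coefficients", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  w <- sin(2 * pi * 4 * t)
  attr(w, "t_center") <- 1

  pa <- estimate_phase_amplitude(w, fs, 4, t_ref = 1000)
  # sine = cos(theta - pi/2); 4 Hz has integer cycles to the window centre
  expect_equal(pa$phase, 3 * pi / 2, tolerance = 0.01)
  expect_equal(pa$amplitude, 1, tolerance = 0.01)

  # shifting the reference by one period leaves the phase unchanged
  pa2 <- estimate_phase_amplitude(w, fs, 4, t_ref = 1250)
  expect_equal(pa2$phase, pa$phase, tolerance = 1e-9)

  # amplitude is linear in the signal amplitude
  for (A in c(0.5, 2, 7)) {
    wa <- A * sin(2 * pi * 4 * t)
    attr(wa, "t_center") <- 1
    expect_equal(estimate_phase_amplitude(wa, fs, 4, 1000)$amplitude, A,
                 tolerance = 0.01)
  }

  expect_error(estimate_phase_amplitude(w, fs, 150, 0), "Nyquist|fs/2")
})

test_that("detector recovers frequency, phase and amplitude across the sweep", {
  fs <- 200
  seed <- 0
  for (f in 3:10) {
    for (ph in c(0, pi / 2, pi, 3 * pi / 2)) {
      seed <- seed + 1
      set.seed(seed)
      A <- 1.5
      # generator uses sine phase; cosine-convention truth is ph - pi/2
      sig <- synthetic_signal(c(f, A, ph), noise_sd = 0.15, fs = fs,
                              duration_s = 10)
      wins <- sliding_windows(sig$value, fs, 2, 0.5)
      det <- detect_dominant_frequency(wins, fs)
      expect_true(det$passed)
      expect_lte(abs(det$f_hat - f), 0.5)  # one FFT bin at 2 s windows

      w <- wins[[5]]
      pa <- estimate_phase_amplitude(w, fs, det$f_hat, t_ref = 0)
      truth <- (ph - pi / 2) %% (2 * pi)
      dphi <- abs(pa$phase - truth) %% (2 * pi)
      expect_lt(min(dphi, 2 * pi - dphi), 0.3)
      expect_lt(abs(pa$amplitude - A) / A, 0.1)
    }
  }
})

test_that("matched protocols align the stimulus sine with the signal peaks", {
  # signal cos(2 pi f t / 1000 + phi0): peak where the phase is 0 (mod 2 pi)
  f <- 4; phi0 <- 1.2; onset <- 2000
  phase_at_onset <- (phi0 + 2 * pi * f * onset / 1000) %% (2 * pi)
  p <- matched_protocol(f, phase_at_onset, onset, amplitude = 5)
  tt <- seq(onset, onset + 500, by = 0.5)
  stim <- stimulus_value(p, tt)
  sig <- cos(2 * pi * f * tt / 1000 + phi0)
  expect_equal(stim, 5 * sig, tolerance = 1e-9)
})

test_that("unsatisfiable criteria reduce the closed loop to a plain run", {
  cfg <- tacs_config(seed = 31, engine = list(duration_ms = 4000),
                     closed_loop = list(snr_min = Inf))
  cl <- run_closed_loop(cfg)
  expect_false(cl$locked)
  expect_true(is.na(cl$onset_ms))
  plain <- run_simulation(tacs_config(seed = 31,
                                      engine = list(duration_ms = 4000)))
  expect_identical(cl$spikes_ex, plain$spikes_ex)
  expect_identical(cl$spikes_in, plain$spikes_in)
})

test_that("closed-loop lock boosts power at the detected frequency", {
  df <- run_closed_loop_experiment(tacs_config(), n_seeds = 1, seeds = 2,
                                   duration_ms = 7000)
  expect_true(df$locked)
  expect_gte(df$onset_ms, 3000)
  expect_gt(df$f_hat, 3); expect_lt(df$f_hat, 6)
  expect_gt(df$relative_power_post, df$relative_power_pre)
  expect_gt(df$peak_activity_ex, 50)
})

test_that("matched stimulation phase-locks the activity to the delivered waveform", {
  # detect the endogenous frequency, estimate its phase, stimulate matched,
  # and check that post-onset activity correlates with the delivered sine
  # and anti-correlates with its sign-flipped (anti-phase) copy
  lead_ms <- 4000; stim_ms <- 2000
  cfg <- tacs_config(seed = 11)
  cfg$engine$duration_ms <- lead_ms + stim_ms
  sim0 <- run_simulation(tacs_config(seed = 11,
                                     engine = list(duration_ms = lead_ms)))
  act <- sim0$activity_ex
  wins <- sliding_windows(act$pct, act$fs, 2, 0.5)
  det <- detect_dominant_frequency(wins, act$fs)
  expect_true(det$passed)
  pa <- estimate_phase_amplitude(wins[[length(wins)]], act$fs, det$f_hat,
                                 t_ref = lead_ms)
  proto <- matched_protocol(det$f_hat, pa$phase, onset = lead_ms,
                            amplitude = 5)
  sim <- run_simulation(cfg, proto)
  post <- sim$activity_ex$time >= lead_ms
  stim_at_bins <- stimulus_value(proto, sim$activity_ex$time[post])
  locked <- cor(stim_at_bins, sim$activity_ex$pct[post])
  expect_gt(locked, 0.2)
  expect_gt(locked, cor(-stim_at_bins, sim$activity_ex$pct[post]))
})

test_that("external signal CSV round-trips through the detector interface", {
  sig <- synthetic_signal(c(6, 2, 0), noise_sd = 0.2, fs = 100,
                          duration_s = 8)
  path <- file.path(tempdir(), "sig.csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path)
  expect_equal(back$fs, 100)
  expect_equal(back$value, sig$value)
  det <- detect_dominant_frequency(
    sliding_windows(back$value, back$fs, 2, 0.5), back$fs)
  expect_true(det$passed)
  expect_equal(det$f_hat, 6, tolerance = 0.26)
})
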