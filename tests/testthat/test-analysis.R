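# Welch PSD, relative power, activity maps, spectrogram.

test_that("Welch PSD localises sinusoids and scales with amplitude squared", {
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  sp <- welch_psd(sin(2 * pi * 4 * t), fs = 200)
  expect_equal(sp$freqs[which.max(sp$power)], 4)
  expect_true(all(sp$power >= 0))
  expect_true(!is.unsorted(sp$freqs) && max(sp$freqs) <= 100)

  # 2:1 amplitude ratio gives a 4:1 power ratio
  x <- 2 * sin(2 * pi * 4 * t) + sin(2 * pi * 7 * t)
  sp <- welch_psd(x, fs = 200)
  p4 <- sp$power[sp$freqs == 4]
  p7 <- sp$power[sp$freqs == 7]
  expect_equal(p4 / p7, 4, tolerance = 0.05)

  # constant input has (numerically) no power after demeaning
  spc <- welch_psd(rep(3.3, 1000), fs = 200)
  expect_lt(max(spc$power), 1e-20)

  expect_error(welch_psd(rnorm(50), fs = 200, window_s = 1), "shorter")
})

test_that("Welch total power approximates the signal variance (Parseval)", {
  set.seed(2)
  t <- seq(0, 60 - 1 / 100, by = 1 / 100)
  x <- sin(2 * pi * 3 * t) + 0.5 * rnorm(length(t))
  sp <- welch_psd(x, fs = 100, window_s = 2)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_equal(sum(sp$power) * df, var(x), tolerance = 0.05)
})

test_that("relative power reflects band concentration", {
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  # 2 s segments: the window mainlobe fits inside the 0.5 Hz half-band
  sine <- welch_psd(sin(2 * pi * 4 * t), fs = 200, window_s = 2)
  expect_gt(relative_power(sine, 4), 0.95)
  expect_lt(relative_power(sine, 7), 0.05)

  # white noise: band fraction ~ bandwidth ratio
  set.seed(3)
  wn <- welch_psd(rnorm(20000), fs = 200)
  rp <- relative_power(wn, 4)
  expect_gt(rp, 0.005); expect_lt(rp, 0.06)

  expect_error(relative_power(sine, 200), "total_band")

  # bounded in [0, 1] for arbitrary signals
  for (seed in 1:5) {
    set.seed(seed)
    sp <- welch_psd(cumsum(rnorm(2000)), fs = 200)
    r <- relative_power(sp, 4)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("dominant frequency scans only the requested band", {
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  x <- sin(2 * pi * 4 * t) + 2 * sin(2 * pi * 30 * t)
  sp <- welch_psd(x, fs = 200)
  expect_equal(dominant_frequency(sp, c(0.5, 10)), 4)
  expect_equal(dominant_frequency(sp, c(20, 50)), 30)
})

test_that("activity maps conserve spike counts on the grid", {
  spikes <- data.frame(time_ms = c(10, 11, 12, 100), neuron_id = c(1, 1, 7, 3))
  m <- activity_map(spikes, c(4, 4), t_center = 11, half_window = 5)
  expect_equal(dim(m), c(4, 4))
  expect_equal(sum(m), 3)             # the spike at 100 ms is outside
  expect_equal(m[1, 1], 2)            # neuron 1 -> row 1, col 1 (row-major)
  expect_equal(m[2, 3], 1)            # neuron 7 -> row 2, col 3
  empty <- activity_map(spikes[0, ], c(4, 4), 50, 10)
  expect_true(all(empty == 0))
})

test_that("spectrogram tracks a frequency step within one window", {
  fs <- 100
  t1 <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- c(sin(2 * pi * 4 * t1), sin(2 * pi * 7 * t1))
  sg <- spectrogram(x, fs, window_s = 1, step_s = 0.25)
  ridge <- sg$freqs[apply(sg$power, 2, which.max)]
  expect_true(all(ridge[sg$times < 4.5] == 4))
  expect_true(all(ridge[sg$times > 5.5] == 7))

  # stationary input keeps a constant ridge; silence stays silent
  sgs <- spectrogram(sin(2 * pi * 4 * t1), fs, 1, 0.5)
  expect_true(all(sg$freqs[apply(sgs$power, 2, which.max)] == 4))
  sg0 <- spectrogram(rep(0, 500), fs, 1, 0.5)
  expect_true(all(sg0$power == 0))
})

test_that("entrainment sweep returns a well-formed reproducible matrix", {
  cfg <- tacs_config(seed = 21, engine = list(duration_ms = 2500))
  sw <- entrainment_sweep(amplitudes = c(0, 5), frequencies = c(0, 4),
                          config = cfg, n_seeds = 1)
  expect_equal(dim(sw$relative_power), c(2, 2))
  expect_true(all(sw$relative_power >= 0 & sw$relative_power <= 1))
  expect_equal(nrow(sw$runs), 4)
  # the baseline column scores the endogenous band in every row
  expect_gt(min(sw$relative_power[, "0"]), 0)
  sw2 <- entrainment_sweep(amplitudes = c(0, 5), frequencies = c(0, 4),
                           config = cfg, n_seeds = 1)
  expect_identical(sw$relative_power, sw2$relative_power)
})
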