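# Simulation engine: determinism, backend agreement, activity binning,
# degenerate inputs, depression audit.

test_that("no drive means no spikes and flat activity", {
  cfg <- quick_cfg(duration_ms = 300)
  cfg$network$w_py_py <- 0
  cfg$network$w_py_in <- 0
  cfg$network$w_in_py <- 0
  cfg$noise$max_ex <- 0; cfg$noise$max_in <- 0
  cfg$noise$base_ex <- 0; cfg$noise$base_in <- 0
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$spikes_ex), 0)
  expect_equal(nrow(sim$spikes_in), 0)
  expect_true(all(sim$activity_ex$pct == 0))
  expect_true(all(sim$activity_in$pct == 0))
})

test_that("identical seeds reproduce rasters exactly; different seeds differ", {
  s1 <- run_simulation(quick_cfg(seed = 3))
  s2 <- run_simulation(quick_cfg(seed = 3))
  expect_identical(s1$spikes_ex, s2$spikes_ex)
  expect_identical(s1$spikes_in, s2$spikes_in)
  s3 <- run_simulation(quick_cfg(seed = 4))
  expect_false(identical(s1$spikes_ex, s3$spikes_ex))
})

test_that("compiled and reference backends agree draw for draw", {
  cfg <- quick_cfg(duration_ms = 400, seed = 6)
  cfg$stimulus <- utils::modifyList(cfg$stimulus,
                                    list(kind = "tacs", amplitude = 4))
  a <- run_simulation(cfg, backend = "cpp")
  b <- run_simulation(cfg, backend = "r")
  expect_identical(a$spikes_ex, b$spikes_ex)
  expect_identical(a$spikes_in, b$spikes_in)
  # trajectories agree to floating-point accumulation error; the rasters
  # above are the exact contract
  expect_lt(max(abs(a$traces$ex - b$traces$ex)), 1e-6)
  expect_lt(max(abs(a$traces$inh - b$traces$inh)), 1e-6)
})

test_that("spike times are on the dt grid and recorded traces stay subthreshold", {
  sim <- run_simulation(quick_cfg(duration_ms = 1000, seed = 2))
  expect_gt(nrow(sim$spikes_ex) + nrow(sim$spikes_in), 0)
  tms <- c(sim$spikes_ex$time_ms, sim$spikes_in$time_ms)
  expect_true(all(tms >= 0 & tms < 1000))
  expect_lt(max(abs(tms / 0.1 - round(tms / 0.1))), 1e-9)
  # traces record post-reset values, so stored V never exceeds threshold
  expect_true(all(sim$traces$ex < 30))
  expect_true(all(sim$traces$inh < 30))
})

test_that("population activity counts distinct neurons per bin", {
  # all neurons spiking in one bin give 100%
  act <- population_activity(rep(2.5, 16), 1:16, n = 16, bin_ms = 5,
                             duration_ms = 10)
  expect_equal(act$pct, c(100, 0))
  # half the population gives 50%
  act <- population_activity(rep(2.5, 8), 1:8, n = 16, bin_ms = 5,
                             duration_ms = 10)
  expect_equal(act$pct[1], 50)
  # one neuron spiking twice in a bin counts once
  act <- population_activity(c(1, 3, 7), c(4, 4, 4), n = 10, bin_ms = 5,
                             duration_ms = 10)
  expect_equal(act$pct, c(10, 10))
  # empty raster is a zero series, not an error
  act <- population_activity(numeric(0), integer(0), n = 10, bin_ms = 5,
                             duration_ms = 20)
  expect_equal(act$pct, rep(0, 4))
  expect_equal(act$fs, 200)
})

test_that("with synapses and noise off, constant drive gives clockwork firing", {
  cfg <- quick_cfg(duration_ms = 2000, seed = 8)
  cfg$network$w_py_py <- 0; cfg$network$w_py_in <- 0; cfg$network$w_in_py <- 0
  cfg$noise$max_ex <- 0; cfg$noise$max_in <- 0
  cfg$noise$base_ex <- 0; cfg$noise$base_in <- 0
  sim <- run_simulation(cfg, stimulus_protocol("tdcs", amplitude = 10))
  # every excitatory neuron fires, with identical inter-spike intervals
  expect_setequal(unique(sim$spikes_ex$neuron_id), 1:64)
  for (id in c(1, 20, 64)) {
    isi <- diff(sim$spikes_ex$time_ms[sim$spikes_ex$neuron_id == id])
    expect_gt(length(isi), 4)
    # after the u-transient settles, the cycle is clockwork
    late <- utils::tail(isi, 3)
    expect_lt(max(late) - min(late), 0.2)
  }
  # and matches the scalar reference integrator for a probed neuron
  set.seed(cfg$seed)
  pop_ex <- make_population("excitatory", grid_shape = c(8, 8))
  ref <- reference_neuron(pop_ex$a[1], pop_ex$b[1], pop_ex$c[1],
                          pop_ex$d_reset[1], I = 10, dt = 0.1,
                          nsteps = 20000)
  got <- sim$spikes_ex$time_ms[sim$spikes_ex$neuron_id == 1]
  expect_equal(got, (ref$spikes - 1) * 0.1)
})

test_that("disabling depression cannot reduce total excitatory output", {
  cfg <- tacs_config(seed = 5, engine = list(duration_ms = 1500))
  dep <- run_simulation(cfg)
  cfg$synapses$r_dep <- 1
  nodep <- run_simulation(cfg)
  expect_gte(nrow(nodep$spikes_ex), nrow(dep$spikes_ex))
})

test_that("raster CSV export is ordered and complete", {
  sim <- run_simulation(quick_cfg(duration_ms = 500, seed = 2))
  path <- file.path(tempdir(), "raster.csv")
  write_raster_csv(sim, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), nrow(sim$spikes_ex) + nrow(sim$spikes_in))
  expect_true(!is.unsorted(df$time_ms))
  expect_setequal(unique(df$population), c("excitatory", "inhibitory"))
})
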