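# Topology construction and synaptic state dynamics.

test_that("default network has the exact contracted out-degrees", {
  set.seed(1)
  t0 <- Sys.time()
  net <- build_network(tacs_config())
  build_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(build_s, 5)

  # interior PY neuron at grid (20, 20), row-major 0-based coords
  p <- 20L * 40L + 20L + 1L
  expect_length(net$py_py[[p]], 121)
  expect_length(net$py_in[[p]], 29)
  expect_length(net$in_py[[7]], 49)
  expect_true(all(lengths(net$in_py) == 49))

  # no self-connections, no duplicates
  expect_false(p %in% net$py_py[[p]])
  expect_false(any(vapply(net$py_py, anyDuplicated, integer(1)) > 0))
  expect_false(any(vapply(net$py_in, anyDuplicated, integer(1)) > 0))
  expect_false(any(vapply(net$in_py, anyDuplicated, integer(1)) > 0))

  # interior degrees hold wherever the neighbourhood is unclipped
  interior <- which(net$py_coords[, 1] >= 6 & net$py_coords[, 1] <= 33 &
                      net$py_coords[, 2] >= 6 & net$py_coords[, 2] <= 33)
  expect_true(all(lengths(net$py_py)[interior] == 121))
})

test_that("corner neurons get the clipped pool and local targets", {
  set.seed(2)
  net <- build_network(tacs_config())
  # corner (0,0): radius-6 patch is 7x7 minus self
  expect_length(net$py_py[[1]], 7 * 7 - 1)
  tg <- net$py_coords[net$py_py[[1]], , drop = FALSE]
  expect_true(all(tg[, 1] <= 6 & tg[, 2] <= 6))

  # PY->PY targets of an interior neuron stay within Chebyshev radius 6;
  # PY->IN targets within radius 3 of the mapped IN position
  p <- 20L * 40L + 20L + 1L
  pc <- net$py_coords[p, ]
  tg <- net$py_coords[net$py_py[[p]], , drop = FALSE]
  expect_true(all(pmax(abs(tg[, 1] - pc[1]), abs(tg[, 2] - pc[2])) <= 6))
  ic <- c(pc[1] %/% 2, pc[2] %/% 2)
  ti <- net$in_coords[net$py_in[[p]], , drop = FALSE]
  expect_true(all(pmax(abs(ti[, 1] - ic[1]), abs(ti[, 2] - ic[2])) <= 3))
})

test_that("degree contract holds at toy scale across seeds", {
  for (seed in 1:5) {
    set.seed(seed)
    net <- make_toy_network(c(8, 8), c(4, 4), degrees = c(8, 3, 5))
    expect_true(all(lengths(net$in_py) == 5))
    interior <- which(net$py_coords[, 1] >= net$radius_py_py &
                        net$py_coords[, 1] <= 7 - net$radius_py_py &
                        net$py_coords[, 2] >= net$radius_py_py &
                        net$py_coords[, 2] <= 7 - net$radius_py_py)
    expect_true(all(lengths(net$py_py)[interior] == 8))
  }
  expect_error(build_network(tacs_config(network = list(
    py_shape = c(4, 4), in_shape = c(2, 2), degree_py_py = 20,
    degree_py_in = 2, degree_in_py = 4))), "degree")
})

test_that("conductance decay follows the closed form and the semigroup law", {
  st <- make_synapse_state(2, 1)
  st$g_ex_py <- c(2, 0.5)
  st$g_in_py <- c(1, 3)
  out <- decay_conductances(st, dt = 2)
  expect_equal(out$g_ex_py, c(2, 0.5) * exp(-1))
  expect_equal(out$g_in_py, c(1, 3) * exp(-2 / 3))

  # two dt = 1 steps equal one dt = 2 step exactly
  two <- decay_conductances(decay_conductances(st, 1), 1)
  expect_equal(two$g_ex_py, out$g_ex_py)
  expect_equal(two$g_in_py, out$g_in_py)

  # dt -> 0 leaves conductances unchanged
  expect_equal(decay_conductances(st, 0)$g_ex_py, st$g_ex_py)
})

test_that("spike delivery applies depression-scaled PY->PY increments only", {
  set.seed(3)
  net <- make_toy_network(c(4, 4), c(2, 2), degrees = c(3, 2, 4))
  st <- make_synapse_state(16, 4)
  spikes_ex <- rep(FALSE, 16); spikes_ex[5] <- TRUE

  out <- deliver_spikes(net, st, spikes_ex, rep(FALSE, 4))
  tg <- net$py_py[[5]]
  expect_equal(out$g_ex_py[tg], rep(net$w_py_py, 3))
  expect_equal(sum(out$g_ex_py), 3 * net$w_py_py)
  expect_equal(out$g_ex_in[net$py_in[[5]]], rep(net$w_py_in, 2))

  # depressed presynaptic neuron scales PY->PY but not PY->IN
  st$d_dep[5] <- 0.6
  out <- deliver_spikes(net, st, spikes_ex, rep(FALSE, 4))
  expect_equal(out$g_ex_py[tg], rep(0.6 * net$w_py_py, 3))
  expect_equal(out$g_ex_in[net$py_in[[5]]], rep(net$w_py_in, 2))

  # inhibitory spike increments G_IN of its PY targets
  spikes_in <- c(TRUE, FALSE, FALSE, FALSE)
  out <- deliver_spikes(net, st, rep(FALSE, 16), spikes_in)
  expect_equal(out$g_in_py[net$in_py[[1]]], rep(net$w_in_py, 4))

  # empty masks are a no-op
  out <- deliver_spikes(net, st, rep(FALSE, 16), rep(FALSE, 4))
  expect_equal(out$g_ex_py, st$g_ex_py)
})

test_that("depression follows the multiplicative rule with exponential recovery", {
  st <- make_synapse_state(1, 1)
  spk <- TRUE

  # first spike: 1 -> (recovery no-op at d = 1) * 0.6
  st1 <- update_depression(st, spk, dt = 0.1)
  expect_equal(st1$d_dep, 0.6)

  # second spike one step later: closed form (1 - 0.4 exp(-0.1/300)) * 0.6
  st2 <- update_depression(st1, spk, dt = 0.1)
  expect_equal(st2$d_dep, (1 - 0.4 * exp(-0.1 / 300)) * 0.6)
  expect_lt(abs(st2$d_dep - 0.36), 0.001)

  # 300 ms of recovery from 0.6 reaches 1 - 0.4/e, independent of stepping
  st3 <- st; st3$d_dep <- 0.6
  for (k in 1:3000) st3 <- update_depression(st3, FALSE, dt = 0.1)
  expect_equal(st3$d_dep, 1 - 0.4 * exp(-1), tolerance = 1e-10)
})

test_that("depression and conductances stay in bounds under random spike trains", {
  set.seed(11)
  net <- make_toy_network(c(4, 4), c(2, 2), degrees = c(3, 2, 4))
  st <- make_synapse_state(16, 4)
  for (k in 1:500) {
    st <- decay_conductances(st, 0.1)
    spikes_ex <- runif(16) < 0.05
    spikes_in <- runif(4) < 0.05
    st <- deliver_spikes(net, st, spikes_ex, spikes_in)
    st <- update_depression(st, spikes_ex, 0.1)
    expect_true(all(st$d_dep > 0 & st$d_dep <= 1))
    expect_true(all(st$g_ex_py >= 0) && all(st$g_in_py >= 0) &&
                  all(st$g_ex_in >= 0))
  }
})

test_that("synaptic current follows the conductance-based form", {
  expect_equal(synaptic_current(0.07, 0, -65), 4.55)
  # at the GABA reversal potential inhibition exerts no current
  expect_equal(synaptic_current(0, 5, -80), 0)
  expect_equal(synaptic_current(0, 0, -55), 0)
  # vectorised
  expect_equal(synaptic_current(c(0.1, 0), c(0, 0.1), c(-70, -70)),
               c(7, -1))
})

test_that("network edge-list CSV round-trips", {
  set.seed(4)
  net <- make_toy_network(c(4, 4), c(2, 2), degrees = c(3, 2, 4))
  path <- file.path(tempdir(), "net.csv")
  write_network_csv(net, path)
  back <- read_network_csv(path)
  expect_equal(back$py_py, net$py_py)
  expect_equal(back$py_in, net$py_in)
  expect_equal(back$in_py, net$in_py)
  expect_equal(back$w_py_py, net$w_py_py)
})
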