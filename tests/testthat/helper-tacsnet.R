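# Shared oracles and small configurations.

# Scalar reference integrator for a single Izhikevich neuron: plain R loop,
# one neuron, forward Euler with simultaneous V/u update and reset.
# `I` is recycled to `nsteps`.  Returns the V/u trajectories (post-reset
# values) and spike step indices (1-based).
reference_neuron <- function(a, b, c, d, I, dt, nsteps,
                             V0 = -65, u0 = b * V0, threshold = 30) {
  I <- rep_len(I, nsteps)
  V <- numeric(nsteps)
  u <- numeric(nsteps)
  spikes <- integer(0)
  v <- V0
  uu <- u0
  for (k in seq_len(nsteps)) {
    vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - uu + I[k])
    un <- uu + dt * a * (b * v - uu)
    v <- vn
    uu <- un
    if (v >= threshold) {
      spikes <- c(spikes, k)
      v <- c
      uu <- uu + d
    }
    V[k] <- v
    u[k] <- uu
  }
  list(V = V, u = u, spikes = spikes)
}

# Small, fast full configuration for engine tests.
quick_cfg <- function(duration_ms = 500, seed = 1, ...) {
  toy_config(py_shape = c(8, 8), in_shape = c(4, 4), degrees = c(8, 3, 5),
             engine = list(duration_ms = duration_ms), seed = seed, ...)
}

# A single-population-style tacs_population with one neuron, for scalar
# comparisons against reference_neuron().
one_neuron_pop <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                           V = -65, u = b * V) {
  structure(list(n = 1L, kind = "excitatory", grid_shape = c(1L, 1L),
                 V = V, u = u, a = a, b = b, c = c, d_reset = d),
            class = "tacs_population")
}
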