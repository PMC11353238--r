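# Izhikevich membrane dynamics: heterogeneous populations, Euler step,
# spike detection and reset.

#' Create a neuron population
#'
#' Builds one population of Izhikevich neurons laid out on a 2-D grid.  Each
#' neuron follows the two-variable quadratic model
#' \deqn{dV/dt = 0.04 V^2 + 5V + 140 - u + I, \qquad du/dt = a(bV - u),}
#' with reset `V <- c`, `u <- u + d_reset` whenever `V >= 30` mV.
#'
#' Parameter heterogeneity follows the standard cortical-network convention:
#' one uniform deviate `rho` per neuron, with
#' * excitatory (regular-spiking to bursting): `a = 0.02`, `b = 0.2`,
#'   `c = -65 + 15 rho^2` (so `c` in \[-65, -50\] mV),
#'   `d_reset = 8 - 6 rho^2` (in \[2, 8\]);
#' * inhibitory (fast-spiking): `a = 0.02 + 0.08 rho`, `b = 0.25 - 0.05 rho`,
#'   `c = -65` mV, `d_reset = 2`.
#'
#' Initial conditions are `V = -65` mV and `u = b * V`.  Draws come from R's
#' global RNG; call `set.seed()` first for reproducibility.
#'
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param n number of neurons; must equal `prod(grid_shape)`.
#' @param grid_shape integer pair `(rows, cols)`.
#' @param pars neuron-parameter block, see `tacs_config()$neurons`.
#' @return An object of class `tacs_population`: a list with per-neuron
#'   vectors `V`, `u`, `a`, `b`, `c`, `d_reset` plus `n`, `kind`,
#'   `grid_shape`.
#' @examples
#' set.seed(1)
#' pop <- make_population("excitatory", 16, c(4, 4))
#' range(pop$c)
#' @export
make_population <- function(kind = c("excitatory", "inhibitory"),
                            n = prod(grid_shape), grid_shape,
                            pars = tacs_config()$neurons) {
  kind <- match.arg(kind)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || n != prod(grid_shape)) {
    stop("population size n (", n, ") must equal prod(grid_shape) (",
         prod(grid_shape), ")", call. = FALSE)
  }
  rho <- stats::runif(n)
  if (kind == "excitatory") {
    p <- pars$excitatory
    a <- rep(p$a, n)
    b <- rep(p$b, n)
    cc <- p$c_range[1] + (p$c_range[2] - p$c_range[1]) * rho^2
    d <- p$d_range[1] + (p$d_range[2] - p$d_range[1]) * rho^2
  } else {
    p <- pars$inhibitory
    a <- p$a_range[1] + (p$a_range[2] - p$a_range[1]) * rho
    b <- p$b_range[1] + (p$b_range[2] - p$b_range[1]) * rho
    cc <- rep(p$c, n)
    d <- rep(p$d_reset, n)
  }
  V <- rep(pars$v_init, n)
  structure(list(n = n, kind = kind, grid_shape = grid_shape,
                 V = V, u = b * V, a = a, b = b, c = cc, d_reset = d),
            class = "tacs_population")
}

#' Advance membrane dynamics by one Euler step
#'
#' Applies one forward-Euler step of the Izhikevich equations to every neuron
#' simultaneously (both derivatives evaluated at the incoming state):
#' `V <- V + dt * (0.04 V^2 + 5V + 140 - u + I_total)` and
#' `u <- u + dt * a * (bV - u)`.
#'
#' @param pop a `tacs_population`.
#' @param I_total per-neuron total input current (noise + stimulus +
#'   synaptic), pA-equivalent model units; recycled if scalar.
#' @param dt time step, ms (default 0.1).
#' @return The population with updated `V` and `u`.
#' @export
membrane_step <- function(pop, I_total, dt = 0.1) {
  stopifnot(inherits(pop, "tacs_population"), dt >= 0)
  bad <- which(!is.finite(pop$V) | !is.finite(pop$u))
  if (length(bad)) {
    stop("non-finite membrane state for ", pop$kind, " neuron ", bad[1],
         call. = FALSE)
  }
  V <- pop$V; u <- pop$u
  pop$V <- V + dt * (0.04 * V^2 + 5 * V + 140 - u + I_total)
  pop$u <- u + dt * pop$a * (pop$b * V - u)
  pop
}

#' Detect spikes and apply the reset rule
#'
#' Neurons with `V >= threshold` are flagged as spiking; for each, `V` is set
#' to its reset potential `c` and `u` is incremented by `d_reset`.  Other
#' neurons are untouched.
#'
#' @param pop a `tacs_population`.
#' @param threshold spike threshold, mV (default 30).
#' @return A list with `pop` (the updated population) and `spiked` (logical
#'   mask of spiking neurons).
#' @export
detect_and_reset <- function(pop, threshold = 30) {
  stopifnot(inherits(pop, "tacs_population"))
  spiked <- pop$V >= threshold
  if (any(spiked)) {
    pop$V[spiked] <- pop$c[spiked]
    pop$u[spiked] <- pop$u[spiked] + pop$d_reset[spiked]
  }
  list(pop = pop, spiked = spiked)
}

#' @export
print.tacs_population <- function(x, ...) {
  cat(sprintf("tacs_population: %d %s neurons on a %dx%d grid\n",
              x$n, x$kind, x$grid_shape[1], x$grid_shape[2]))
  cat(sprintf("  V in [%.2f, %.2f] mV; c in [%.2f, %.2f]; d_reset in [%.2f, %.2f]\n",
              min(x$V), max(x$V), min(x$c), max(x$c),
              min(x$d_reset), max(x$d_reset)))
  invisible(x)
}

#' Export sampled membrane traces as CSV
#'
#' Writes long-format traces (`time_ms`, `neuron_id`, `V_mV`) as recorded by
#' [run_simulation()].
#'
#' @param sim a `tacs_sim` result with recorded traces.
#' @param path output CSV path.
#' @param population which population's traces to write.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(sim, path,
                             population = c("excitatory", "inhibitory")) {
  population <- match.arg(population)
  tr <- if (population == "excitatory") sim$traces$ex else sim$traces$inh
  if (is.null(tr)) stop("no traces recorded for ", population, call. = FALSE)
  ids <- as.integer(colnames(tr))
  df <- data.frame(
    time_ms = rep(sim$trace_times, times = ncol(tr)),
    neuron_id = rep(ids, each = nrow(tr)),
    V_mV = as.vector(tr)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
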