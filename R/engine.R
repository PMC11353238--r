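# Simulation engine: orchestrates the per-step update loop, records rasters,
# traces and population-activity signals.  The default backend is the
# compiled loop in src/; a pure-R reference backend with identical RNG draw
# order exists for verification.

# Convert adjacency lists to 0-based CSR vectors for the compiled core.
network_csr <- function(net) {
  flat <- function(adj) {
    list(idx = as.integer(unlist(adj, use.names = FALSE) - 1L),
         ptr = as.integer(c(0L, cumsum(lengths(adj)))))
  }
  pp <- flat(net$py_py); pi_ <- flat(net$py_in); ip <- flat(net$in_py)
  list(py_py_idx = pp$idx, py_py_ptr = pp$ptr,
       py_in_idx = pi_$idx, py_in_ptr = pi_$ptr,
       in_py_idx = ip$idx, in_py_ptr = ip$ptr,
       w_py_py = net$w_py_py, w_py_in = net$w_py_in, w_in_py = net$w_in_py)
}

# Bundle everything the step loop needs; reused across chunks by the
# closed-loop controller.
make_sim_setup <- function(config) {
  pop_ex <- make_population("excitatory", grid_shape = config$network$py_shape,
                            pars = config$neurons)
  pop_in <- make_population("inhibitory", grid_shape = config$network$in_shape,
                            pars = config$neurons)
  net <- build_network(config)
  syn <- make_synapse_state(pop_ex$n, pop_in$n, config$synapses)
  state <- list(v_ex = pop_ex$V, u_ex = pop_ex$u,
                v_in = pop_in$V, u_in = pop_in$u,
                g_ex_py = syn$g_ex_py, g_in_py = syn$g_in_py,
                g_ex_in = syn$g_ex_in, d_dep = syn$d_dep)
  prm <- list(a_ex = pop_ex$a, b_ex = pop_ex$b, c_ex = pop_ex$c,
              d_ex = pop_ex$d_reset,
              a_in = pop_in$a, b_in = pop_in$b, c_in = pop_in$c,
              d_in = pop_in$d_reset,
              tau_ex = config$synapses$tau_ex, tau_in = config$synapses$tau_in,
              tau_d = config$synapses$tau_d, r_dep = config$synapses$r_dep,
              noise_max_ex = config$noise$max_ex,
              noise_max_in = config$noise$max_in,
              noise_base_ex = config$noise$base_ex,
              noise_base_in = config$noise$base_in,
              v_thresh = config$neurons$v_thresh,
              v_ampa = config$synapses$v_ampa,
              v_gaba = config$synapses$v_gaba)
  n_tr_ex <- min(config$engine$n_trace_ex, pop_ex$n)
  n_tr_in <- min(config$engine$n_trace_in, pop_in$n)
  list(pop_ex = pop_ex, pop_in = pop_in, net = net, csr = network_csr(net),
       prm = prm, state = state,
       trace_ex = seq_len(n_tr_ex) - 1L, trace_in = seq_len(n_tr_in) - 1L)
}

# Run `nsteps` of the loop from `t0`, given per-step stimulus currents.
# Returns spikes (steps are 0-based within the chunk), traces, final state.
run_chunk <- function(setup, state, stim_ex, stim_in, nsteps, dt, t0,
                      backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  if (backend == "cpp") {
    sim_core_cpp(state, setup$csr, setup$prm, stim_ex, stim_in,
                 as.integer(nsteps), dt, t0, setup$trace_ex, setup$trace_in)
  } else {
    sim_core_r(state, setup, stim_ex, stim_in, nsteps, dt)
  }
}

# Pure-R reference engine.  Mirrors the compiled loop step for step and
# draw for draw (runif(n_ex) then runif(n_in) per step).
sim_core_r <- function(state, setup, stim_ex, stim_in, nsteps, dt) {
  prm <- setup$prm
  net <- setup$net
  v_ex <- state$v_ex; u_ex <- state$u_ex
  v_in <- state$v_in; u_in <- state$u_in
  g_ex_py <- state$g_ex_py; g_in_py <- state$g_in_py
  g_ex_in <- state$g_ex_in; d_dep <- state$d_dep
  n_ex <- length(v_ex); n_in <- length(v_in)
  dec_ex <- exp(-dt / prm$tau_ex); dec_in <- exp(-dt / prm$tau_in)
  rec_d <- exp(-dt / prm$tau_d)
  sp_step_ex <- integer(0); sp_id_ex <- integer(0)
  sp_step_in <- integer(0); sp_id_in <- integer(0)
  tr_ex <- matrix(NA_real_, nsteps, length(setup$trace_ex))
  tr_in <- matrix(NA_real_, nsteps, length(setup$trace_in))

  for (k in seq_len(nsteps)) {
    g_ex_py <- g_ex_py * dec_ex
    g_in_py <- g_in_py * dec_in
    g_ex_in <- g_ex_in * dec_ex

    noise_ex <- prm$noise_base_ex + stats::runif(n_ex, 0, prm$noise_max_ex)
    I_ex <- noise_ex + stim_ex[k] +
      synaptic_current(g_ex_py, g_in_py, v_ex, prm$v_ampa, prm$v_gaba)
    vn <- v_ex + dt * (0.04 * v_ex^2 + 5 * v_ex + 140 - u_ex + I_ex)
    un <- u_ex + dt * prm$a_ex * (prm$b_ex * v_ex - u_ex)
    if (any(!is.finite(vn)) || any(!is.finite(un))) {
      stop("non-finite state at step ", k, ", excitatory neuron ",
           which(!is.finite(vn) | !is.finite(un))[1], call. = FALSE)
    }
    v_ex <- vn; u_ex <- un

    noise_in <- prm$noise_base_in + stats::runif(n_in, 0, prm$noise_max_in)
    I_in <- noise_in + stim_in[k] +
      synaptic_current(g_ex_in, 0, v_in, prm$v_ampa, prm$v_gaba)
    vn <- v_in + dt * (0.04 * v_in^2 + 5 * v_in + 140 - u_in + I_in)
    un <- u_in + dt * prm$a_in * (prm$b_in * v_in - u_in)
    if (any(!is.finite(vn)) || any(!is.finite(un))) {
      stop("non-finite state at step ", k, ", inhibitory neuron ",
           which(!is.finite(vn) | !is.finite(un))[1], call. = FALSE)
    }
    v_in <- vn; u_in <- un

    spk_ex <- v_ex >= prm$v_thresh
    if (any(spk_ex)) {
      ids <- which(spk_ex)
      sp_step_ex <- c(sp_step_ex, rep.int(k - 1L, length(ids)))
      sp_id_ex <- c(sp_id_ex, ids)
      v_ex[ids] <- prm$c_ex[ids]
      u_ex[ids] <- u_ex[ids] + prm$d_ex[ids]
    }
    spk_in <- v_in >= prm$v_thresh
    if (any(spk_in)) {
      ids <- which(spk_in)
      sp_step_in <- c(sp_step_in, rep.int(k - 1L, length(ids)))
      sp_id_in <- c(sp_id_in, ids)
      v_in[ids] <- prm$c_in[ids]
      u_in[ids] <- u_in[ids] + prm$d_in[ids]
    }

    for (p in which(spk_ex)) {
      tg <- net$py_py[[p]]
      g_ex_py[tg] <- g_ex_py[tg] + d_dep[p] * net$w_py_py
      ti <- net$py_in[[p]]
      g_ex_in[ti] <- g_ex_in[ti] + net$w_py_in
    }
    for (q in which(spk_in)) {
      tg <- net$in_py[[q]]
      g_in_py[tg] <- g_in_py[tg] + net$w_in_py
    }

    d_dep <- 1 - (1 - d_dep) * rec_d
    if (any(spk_ex)) d_dep[spk_ex] <- d_dep[spk_ex] * prm$r_dep

    if (length(setup$trace_ex)) tr_ex[k, ] <- v_ex[setup$trace_ex + 1L]
    if (length(setup$trace_in)) tr_in[k, ] <- v_in[setup$trace_in + 1L]
  }

  list(spike_step_ex = sp_step_ex, spike_id_ex = sp_id_ex,
       spike_step_in = sp_step_in, spike_id_in = sp_id_in,
       traces_ex = tr_ex, traces_in = tr_in,
       state = list(v_ex = v_ex, u_ex = u_ex, v_in = v_in, u_in = u_in,
                    g_ex_py = g_ex_py, g_in_py = g_in_py,
                    g_ex_in = g_ex_in, d_dep = d_dep))
}

# Assemble a tacs_sim object from chunk outputs.
assemble_sim <- function(config, protocol, chunks, setup, duration_ms,
                         stim_log) {
  dt <- config$engine$dt
  spikes_ex <- do.call(rbind, lapply(chunks, function(ch) {
    data.frame(time_ms = (ch$spike_step_ex + ch$offset_steps) * dt,
               neuron_id = ch$spike_id_ex)
  }))
  spikes_in <- do.call(rbind, lapply(chunks, function(ch) {
    data.frame(time_ms = (ch$spike_step_in + ch$offset_steps) * dt,
               neuron_id = ch$spike_id_in)
  }))
  tr_ex <- do.call(rbind, lapply(chunks, `[[`, "traces_ex"))
  tr_in <- do.call(rbind, lapply(chunks, `[[`, "traces_in"))
  if (!is.null(tr_ex) && ncol(tr_ex)) colnames(tr_ex) <- setup$trace_ex + 1L
  if (!is.null(tr_in) && ncol(tr_in)) colnames(tr_in) <- setup$trace_in + 1L
  n_ex <- setup$pop_ex$n; n_in <- setup$pop_in$n
  bin <- config$engine$bin_ms
  act_ex <- population_activity(spikes_ex$time_ms, spikes_ex$neuron_id,
                                n = n_ex, bin_ms = bin,
                                duration_ms = duration_ms)
  act_in <- population_activity(spikes_in$time_ms, spikes_in$neuron_id,
                                n = n_in, bin_ms = bin,
                                duration_ms = duration_ms)
  structure(list(
    spikes_ex = spikes_ex, spikes_in = spikes_in,
    activity_ex = act_ex, activity_in = act_in,
    traces = list(ex = tr_ex, inh = tr_in),
    trace_times = seq(0, by = dt, length.out = nrow(tr_ex %||% matrix(0, 0, 0))),
    stimulus_log = stim_log, protocol = protocol,
    dt = dt, duration_ms = duration_ms,
    n_ex = n_ex, n_in = n_in,
    seed = config$seed, config = config
  ), class = "tacs_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a network simulation
#'
#' Simulates the full two-population network for `config$engine$duration_ms`
#' milliseconds.  Each dt step (default 0.1 ms) applies, in order:
#' conductance decay, total input current (noise + stimulus + synaptic),
#' the Euler membrane update, spike detection/reset, spike delivery, and the
#' short-term depression update.  The run is fully determined by
#' `config$seed`.
#'
#' @param config a [tacs_config()].
#' @param protocol a [stimulus_protocol()]; `NULL` falls back to the
#'   `stimulus` block of `config`.
#' @param backend `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical output, much slower).
#' @return An object of class `tacs_sim` with spike rasters (`spikes_ex`,
#'   `spikes_in`: `time_ms`, `neuron_id`), percentage-activity series
#'   (`activity_ex`, `activity_in`), sampled membrane `traces`, the delivered
#'   `stimulus_log`, the seed and a config echo.
#' @examples
#' cfg <- tacs_config(network = list(py_shape = c(8, 8), in_shape = c(4, 4),
#'                                   degree_py_py = 8, degree_py_in = 3,
#'                                   degree_in_py = 5),
#'                    engine = list(duration_ms = 200))
#' sim <- run_simulation(cfg)
#' summary(sim)
#' @export
run_simulation <- function(config = tacs_config(), protocol = NULL,
                           backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  validate_config(config)
  if (is.null(protocol)) {
    protocol <- do.call(stimulus_protocol, config$stimulus)
  }
  set.seed(config$seed)
  setup <- make_sim_setup(config)
  dt <- config$engine$dt
  duration <- config$engine$duration_ms
  nsteps <- as.integer(round(duration / dt))
  times <- (seq_len(nsteps) - 1L) * dt
  sv <- stimulus_value(protocol, times)
  stim_ex <- sv
  stim_in <- if (protocol$target == "all") sv else numeric(nsteps)
  ch <- run_chunk(setup, setup$state, stim_ex, stim_in, nsteps, dt, 0,
                  backend)
  ch$offset_steps <- 0L
  assemble_sim(config, protocol, list(ch), setup, duration, sv)
}

#' Population activity: percentage of neurons spiking per time bin
#'
#' Counts, per bin, the number of *distinct* neurons that fired at least one
#' spike, normalised by the population size and expressed as a percentage.
#'
#' @param times spike times, ms.
#' @param ids spike neuron ids (parallel to `times`).
#' @param n population size.
#' @param bin_ms bin width, ms (default 5).
#' @param duration_ms signal duration, ms; bins span `[0, duration_ms)`.
#' @return An object of class `tacs_activity`: list with `time` (bin
#'   centres, ms), `pct` (percentages in \[0, 100\]), `fs` (sampling rate,
#'   Hz), `bin_ms` and `n`.
#' @examples
#' population_activity(c(1, 2, 3), c(1, 1, 2), n = 4, bin_ms = 5,
#'                     duration_ms = 10)$pct
#' @export
population_activity <- function(times, ids, n, bin_ms = 5, duration_ms) {
  stopifnot(bin_ms > 0, n >= 1)
  nbins <- as.integer(ceiling(duration_ms / bin_ms))
  if (length(times)) {
    b <- pmin(as.integer(times %/% bin_ms), nbins - 1L)
    key <- !duplicated(b * as.double(n) + ids)
    counts <- tabulate(b[key] + 1L, nbins)
  } else {
    counts <- integer(nbins)
  }
  structure(list(time = (seq_len(nbins) - 0.5) * bin_ms,
                 pct = 100 * counts / n,
                 fs = 1000 / bin_ms, bin_ms = bin_ms, n = n),
            class = "tacs_activity")
}

#' @export
print.tacs_sim <- function(x, ...) {
  cat(sprintf("tacs_sim: %g ms at dt %g ms, %d PY + %d IN neurons (seed %s)\n",
              x$duration_ms, x$dt, x$n_ex, x$n_in, format(x$seed)))
  print(x$protocol)
  cat(sprintf("  spikes: %d excitatory, %d inhibitory\n",
              nrow(x$spikes_ex), nrow(x$spikes_in)))
  cat(sprintf("  peak activity: %.1f%% PY, %.1f%% IN\n",
              max(x$activity_ex$pct), max(x$activity_in$pct)))
  invisible(x)
}

#' @export
summary.tacs_sim <- function(object, ...) {
  psd_bin <- object$config$analysis$psd_bin_ms
  act <- population_activity(object$spikes_ex$time_ms,
                             object$spikes_ex$neuron_id, n = object$n_ex,
                             bin_ms = psd_bin,
                             duration_ms = object$duration_ms)
  spec <- welch_psd(act$pct, fs = act$fs,
                    window_s = min(object$config$analysis$window_s,
                                   object$duration_ms / 2000))
  f_dom <- dominant_frequency(spec, band = c(0.5, 10))
  out <- list(
    duration_ms = object$duration_ms,
    n_spikes_ex = nrow(object$spikes_ex),
    n_spikes_in = nrow(object$spikes_in),
    rate_ex_hz = nrow(object$spikes_ex) / object$n_ex /
      (object$duration_ms / 1000),
    rate_in_hz = nrow(object$spikes_in) / object$n_in /
      (object$duration_ms / 1000),
    peak_activity_ex = max(object$activity_ex$pct),
    peak_activity_in = max(object$activity_in$pct),
    dominant_freq_hz = f_dom,
    protocol = object$protocol
  )
  class(out) <- "summary.tacs_sim"
  out
}

#' @export
print.summary.tacs_sim <- function(x, ...) {
  cat(sprintf("Simulation of %g ms\n", x$duration_ms))
  cat(sprintf("  mean firing rate: %.2f Hz (PY), %.2f Hz (IN)\n",
              x$rate_ex_hz, x$rate_in_hz))
  cat(sprintf("  peak activity: %.1f%% (PY), %.1f%% (IN)\n",
              x$peak_activity_ex, x$peak_activity_in))
  cat(sprintf("  dominant frequency of PY activity: %.2f Hz\n",
              x$dominant_freq_hz))
  invisible(x)
}

#' Plot a simulation result
#'
#' Draws the spike raster (excitatory below, inhibitory above) and the two
#' population-activity series; if a stimulus was delivered its waveform is
#' overlaid on the activity panel.
#'
#' @param x a `tacs_sim`.
#' @param max_points cap on raster points drawn (downsampled beyond this).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.tacs_sim <- function(x, max_points = 2e5, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  thin <- function(df) {
    if (nrow(df) > max_points) df[seq(1, nrow(df), length.out = max_points), ]
    else df
  }
  se <- thin(x$spikes_ex); si <- thin(x$spikes_in)
  graphics::plot(se$time_ms, se$neuron_id, pch = ".", col = "firebrick",
                 xlim = c(0, x$duration_ms), ylim = c(1, x$n_ex + x$n_in),
                 xlab = "time (ms)", ylab = "neuron",
                 main = "spike raster (red PY, blue IN)")
  graphics::points(si$time_ms, si$neuron_id + x$n_ex, pch = ".",
                   col = "navy")
  graphics::plot(x$activity_ex$time, x$activity_ex$pct, type = "l",
                 col = "firebrick", ylim = c(0, 100), xlab = "time (ms)",
                 ylab = "% spiking neurons", main = "population activity")
  graphics::lines(x$activity_in$time, x$activity_in$pct, col = "navy")
  if (!is.null(x$stimulus_log) && any(x$stimulus_log != 0)) {
    stim_t <- seq(0, by = x$dt, length.out = length(x$stimulus_log))
    keep <- seq(1, length(stim_t), by = max(1, length(stim_t) %/% 4000))
    amp <- max(abs(x$stimulus_log))
    graphics::lines(stim_t[keep], 50 + 40 * x$stimulus_log[keep] / amp,
                    col = "darkgreen", lty = 3)
  }
  invisible(x)
}

#' Export a spike raster as CSV
#'
#' @param sim a `tacs_sim`.
#' @param path output CSV path; columns `time_ms`, `population`, `neuron_id`.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(sim, path) {
  df <- rbind(
    cbind(sim$spikes_ex, population = "excitatory"),
    cbind(sim$spikes_in, population = "inhibitory")
  )
  df <- df[order(df$time_ms), c("time_ms", "population", "neuron_id")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
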