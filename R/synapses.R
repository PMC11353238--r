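# Network topology (three fixed-out-degree projections on 2-D grids) and
# synaptic state: exponential conductance decay, spike delivery, short-term
# depression.

# 0-based (row, col) coordinates for ids 1..n on an (rows x cols) grid,
# row-major: id = row * cols + col + 1.
grid_coords <- function(shape) {
  idx <- seq_len(prod(shape)) - 1L
  cbind(row = idx %/% shape[2], col = idx %% shape[2])
}

# Smallest Chebyshev radius whose neighbourhood pool can hold `degree`
# targets.  `exclude_self` for within-population projections.
min_radius <- function(degree, exclude_self) {
  r <- 1L
  pool <- function(r) (2L * r + 1L)^2 - as.integer(exclude_self)
  while (pool(r) < degree) r <- r + 1L
  r
}

# Ids of grid cells within Chebyshev distance `radius` of (row, col),
# clipped at the edges (no wraparound).
chebyshev_patch <- function(row, col, shape, radius) {
  rows <- max(0L, row - radius):min(shape[1] - 1L, row + radius)
  cols <- max(0L, col - radius):min(shape[2] - 1L, col + radius)
  as.integer(outer(rows * shape[2], cols, "+") + 1L)
}

#' Build the three-projection synaptic network
#'
#' Constructs the connectivity of the model: pyramidal (PY) neurons on one
#' 2-D grid, inhibitory (IN) neurons on another, and three projections with
#' fixed out-degrees sampled without replacement:
#'
#' * PY->PY: each PY neuron targets `min(degree, pool)` distinct PY neurons
#'   drawn uniformly from its local Chebyshev neighbourhood, excluding itself.
#' * PY->IN: the PY position `(i, j)` maps to IN position
#'   `(floor(i/2), floor(j/2))` (for the default 40x40 -> 20x20 geometry the
#'   divisor is the grid-size ratio); targets are drawn from the IN
#'   neighbourhood of that position.
#' * IN->PY: each IN neuron targets `degree` PY neurons drawn uniformly from
#'   the whole PY grid (global inhibitory feedback).
#'
#' Neighbourhood radii are the smallest Chebyshev radii whose interior pools
#' hold the requested degree (radius 6 for the default PY->PY degree 121,
#' radius 3 for PY->IN degree 29); neurons near an edge have their pool
#' clipped, so their out-degree is the pool size when that is smaller.
#'
#' Per-synapse conductance increments are the configured `w_*` values scaled
#' by `g_unit`, the conductance unit calibration (see the methods vignette):
#' the stored network weights are `w * g_unit`.
#'
#' @param config network block of a [tacs_config()] (or a full config).
#' @return An object of class `tacs_network`: adjacency lists `py_py`,
#'   `py_in`, `in_py` (integer target ids per source neuron), weights
#'   `w_py_py`, `w_py_in`, `w_in_py`, grid shapes and coordinates.
#' @examples
#' set.seed(1)
#' net <- build_network(tacs_config(network = list(
#'   py_shape = c(8, 8), in_shape = c(4, 4),
#'   degree_py_py = 8, degree_py_in = 3, degree_in_py = 5)))
#' lengths(net$py_py)[1:4]
#' @export
build_network <- function(config = tacs_config()) {
  net <- if (inherits(config, "tacs_config")) config$network else config
  py_shape <- as.integer(net$py_shape)
  in_shape <- as.integer(net$in_shape)
  n_py <- prod(py_shape); n_in <- prod(in_shape)
  if (net$degree_py_py >= n_py || net$degree_py_in > n_in ||
      net$degree_in_py > n_py) {
    stop("requested out-degree exceeds the available population",
         call. = FALSE)
  }
  py_coords <- grid_coords(py_shape)
  in_coords <- grid_coords(in_shape)
  r_pp <- min_radius(net$degree_py_py, exclude_self = TRUE)
  r_pi <- min_radius(net$degree_py_in, exclude_self = FALSE)
  ratio <- py_shape %/% in_shape  # PY->IN grid mapping divisor

  py_py <- vector("list", n_py)
  py_in <- vector("list", n_py)
  for (p in seq_len(n_py)) {
    i <- py_coords[p, 1L]; j <- py_coords[p, 2L]
    pool <- chebyshev_patch(i, j, py_shape, r_pp)
    pool <- pool[pool != p]
    k <- min(net$degree_py_py, length(pool))
    py_py[[p]] <- sort(sample(pool, k))
    ii <- min(i %/% ratio[1], in_shape[1] - 1L)
    jj <- min(j %/% ratio[2], in_shape[2] - 1L)
    pool_in <- chebyshev_patch(ii, jj, in_shape, r_pi)
    k <- min(net$degree_py_in, length(pool_in))
    py_in[[p]] <- sort(sample(pool_in, k))
  }
  in_py <- lapply(seq_len(n_in), function(q) {
    sort(sample.int(n_py, net$degree_in_py))
  })

  g_unit <- if (is.null(net$g_unit)) 1 else net$g_unit
  structure(list(py_py = py_py, py_in = py_in, in_py = in_py,
                 w_py_py = net$w_py_py * g_unit,
                 w_py_in = net$w_py_in * g_unit,
                 w_in_py = net$w_in_py * g_unit,
                 py_shape = py_shape, in_shape = in_shape,
                 py_coords = py_coords, in_coords = in_coords,
                 radius_py_py = r_pp, radius_py_in = r_pi),
            class = "tacs_network")
}

#' @export
print.tacs_network <- function(x, ...) {
  cat(sprintf("tacs_network: %d PY (%dx%d), %d IN (%dx%d)\n",
              prod(x$py_shape), x$py_shape[1], x$py_shape[2],
              prod(x$in_shape), x$in_shape[1], x$in_shape[2]))
  cat(sprintf("  PY->PY: interior degree %d (radius %d), w = %g\n",
              max(lengths(x$py_py)), x$radius_py_py, x$w_py_py))
  cat(sprintf("  PY->IN: interior degree %d (radius %d), w = %g\n",
              max(lengths(x$py_in)), x$radius_py_in, x$w_py_in))
  cat(sprintf("  IN->PY: degree %d (global), w = %g\n",
              max(lengths(x$in_py)), x$w_in_py))
  invisible(x)
}

#' Initialise synaptic state
#'
#' Summed conductances start at zero; the per-PY-neuron depression variable
#' `d_dep` starts fully recovered at 1.
#'
#' @param n_ex,n_in population sizes.
#' @param pars synapse block of a [tacs_config()].
#' @return An object of class `tacs_synapse_state` with fields `g_ex_py`,
#'   `g_in_py` (conductances onto PY neurons), `g_ex_in` (excitatory
#'   conductance onto IN neurons), `d_dep`, and the kinetic constants.
#' @export
make_synapse_state <- function(n_ex, n_in, pars = tacs_config()$synapses) {
  structure(list(g_ex_py = numeric(n_ex), g_in_py = numeric(n_ex),
                 g_ex_in = numeric(n_in), d_dep = rep(1, n_ex),
                 tau_ex = pars$tau_ex, tau_in = pars$tau_in,
                 tau_d = pars$tau_d, r_dep = pars$r_dep,
                 v_ampa = pars$v_ampa, v_gaba = pars$v_gaba),
            class = "tacs_synapse_state")
}

#' Decay synaptic conductances
#'
#' Applies the exponential decay `G <- G * exp(-dt / tau)` elementwise, with
#' `tau_ex` for excitatory and `tau_in` for inhibitory conductances.  The
#' update satisfies the semigroup property: two steps of `dt` equal one step
#' of `2 dt` exactly.
#'
#' @param state a `tacs_synapse_state`.
#' @param dt elapsed time, ms.
#' @return The decayed state.
#' @export
decay_conductances <- function(state, dt) {
  stopifnot(inherits(state, "tacs_synapse_state"), dt >= 0)
  f_ex <- exp(-dt / state$tau_ex)
  f_in <- exp(-dt / state$tau_in)
  state$g_ex_py <- state$g_ex_py * f_ex
  state$g_ex_in <- state$g_ex_in * f_ex
  state$g_in_py <- state$g_in_py * f_in
  state
}

#' Deliver presynaptic spikes to postsynaptic conductances
#'
#' For each spiking PY neuron `p`, every PY target gains
#' `d_dep[p] * w_py_py` of excitatory conductance (depression scales only the
#' PY->PY projection) and every IN target gains `w_py_in` undepressed.  For
#' each spiking IN neuron, every PY target gains `w_in_py` of inhibitory
#' conductance.
#'
#' @param net a `tacs_network`.
#' @param state a `tacs_synapse_state`.
#' @param spikes_ex,spikes_in logical spike masks for the two populations.
#' @return The updated state.
#' @export
deliver_spikes <- function(net, state, spikes_ex, spikes_in) {
  stopifnot(length(spikes_ex) == length(state$g_ex_py),
            length(spikes_in) == length(net$in_py))
  for (p in which(spikes_ex)) {
    tg <- net$py_py[[p]]
    state$g_ex_py[tg] <- state$g_ex_py[tg] + state$d_dep[p] * net$w_py_py
    ti <- net$py_in[[p]]
    state$g_ex_in[ti] <- state$g_ex_in[ti] + net$w_py_in
  }
  for (q in which(spikes_in)) {
    tg <- net$in_py[[q]]
    state$g_in_py[tg] <- state$g_in_py[tg] + net$w_in_py
  }
  state
}

#' Update short-term depression
#'
#' The per-PY-neuron depression variable recovers exponentially towards 1
#' with time constant `tau_d` (300 ms), then each spiking neuron's variable
#' is multiplied by the depression coefficient `r_dep` (0.6):
#' `d_dep <- 1 - (1 - d_dep) * exp(-dt / tau_d)`, then `d_dep <- d_dep * r`
#' for spikers.  `d_dep` therefore stays in (0, 1].
#'
#' @param state a `tacs_synapse_state`.
#' @param spikes_ex logical mask of spiking PY neurons.
#' @param dt time step, ms.
#' @return The updated state.
#' @export
update_depression <- function(state, spikes_ex, dt) {
  stopifnot(inherits(state, "tacs_synapse_state"))
  state$d_dep <- 1 - (1 - state$d_dep) * exp(-dt / state$tau_d)
  if (any(spikes_ex)) {
    state$d_dep[spikes_ex] <- state$d_dep[spikes_ex] * state$r_dep
  }
  state
}

#' Synaptic current from summed conductances
#'
#' Conductance-based current `-g_ex (V - V_AMPA) - g_in (V - V_GABA)` with
#' reversal potentials 0 mV (AMPA) and -80 mV (GABA) by default.
#'
#' @param g_ex,g_in per-neuron summed conductances.
#' @param V per-neuron membrane potential, mV.
#' @param v_ampa,v_gaba reversal potentials, mV.
#' @return Per-neuron synaptic current.
#' @examples
#' synaptic_current(0.07, 0, -65)  # 4.55 pA of depolarising drive
#' @export
synaptic_current <- function(g_ex, g_in, V, v_ampa = 0, v_gaba = -80) {
  -g_ex * (V - v_ampa) - g_in * (V - v_gaba)
}

#' Export a network as an edge-list CSV with a JSON header
#'
#' Writes one CSV (`projection`, `pre_id`, `post_id`) and a JSON sidecar
#' (same path with extension `.json`) recording weights and grid shapes, so
#' topologies can be diffed across versions.
#'
#' @param net a `tacs_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  edges <- function(adj, name) {
    data.frame(projection = name,
               pre_id = rep(seq_along(adj), lengths(adj)),
               post_id = unlist(adj, use.names = FALSE))
  }
  df <- rbind(edges(net$py_py, "py_py"), edges(net$py_in, "py_in"),
              edges(net$in_py, "in_py"))
  utils::write.csv(df, path, row.names = FALSE)
  hdr <- list(w_py_py = net$w_py_py, w_py_in = net$w_py_in,
              w_in_py = net$w_in_py, py_shape = net$py_shape,
              in_shape = net$in_shape)
  jsonlite::write_json(hdr, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from an edge-list CSV written by [write_network_csv()]
#'
#' @param path CSV path (expects the JSON sidecar next to it).
#' @return A `tacs_network`.
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                             simplifyVector = TRUE)
  py_shape <- as.integer(hdr$py_shape); in_shape <- as.integer(hdr$in_shape)
  n_py <- prod(py_shape); n_in <- prod(in_shape)
  adj <- function(name, n) {
    sub <- df[df$projection == name, ]
    out <- split(as.integer(sub$post_id),
                 factor(sub$pre_id, levels = seq_len(n)))
    lapply(unname(out), sort)
  }
  structure(list(py_py = adj("py_py", n_py), py_in = adj("py_in", n_py),
                 in_py = adj("in_py", n_in),
                 w_py_py = hdr$w_py_py, w_py_in = hdr$w_py_in,
                 w_in_py = hdr$w_in_py,
                 py_shape = py_shape, in_shape = in_shape,
                 py_coords = grid_coords(py_shape),
                 in_coords = grid_coords(in_shape),
                 radius_py_py = NA_integer_, radius_py_in = NA_integer_),
            class = "tacs_network")
}
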