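# Configuration: defaults, merging, validation, YAML round-trip.

#' Default simulation configuration
#'
#' Builds the full nested configuration used by [run_simulation()],
#' [run_closed_loop()] and the analysis helpers.  Defaults are the model's
#' canonical values: a 40x40 pyramidal (PY) grid and 20x20 inhibitory (IN)
#' grid, fixed out-degrees 121/29/49 for the PY->PY, PY->IN and IN->PY
#' projections with conductance increments 0.0006/0.0002/0.0004 (in units of
#' `g_unit`; see below), synaptic decay constants 2 ms (AMPA) and 3 ms
#' (GABA), short-term depression factor 0.6 recovering with a 300 ms time
#' constant, per-step uniform noise up to 5 pA (PY) and 2 pA (IN) on top of
#' a constant background current, Euler integration at dt = 0.1 ms, and a
#' 5 pA / 4 Hz stimulus template.
#'
#' Two calibration parameters place the network in its slow-oscillation
#' regime (the methods vignette derives both): `noise$base_ex` /
#' `noise$base_in` (constant background currents, 0.9 / 0.36 pA) hold the
#' pyramidal population just above its ~4 pA rheobase so UP states nucleate
#' at the endogenous ~4 Hz rate, and `network$g_unit` (5) sets the
#' conductance units of the `w_*` increments so that recurrent excitation
#' can regenerate a propagating UP state.
#'
#' Activity percentages and the closed-loop detector use `engine$bin_ms`
#' (5 ms, fs 200 Hz); Welch/relative-power analyses consume the signal
#' re-binned at `analysis$psd_bin_ms` (50 ms), whose 10 Hz Nyquist limit
#' restricts the scored band to the slow rhythm and its first harmonic.
#'
#' Overrides are given as nested named lists and are merged recursively;
#' unknown keys are rejected so typos fail loudly.
#'
#' @param ... named top-level blocks (e.g. `engine = list(duration_ms = 2000)`).
#' @return A nested list of class `tacs_config`.
#' @examples
#' cfg <- tacs_config(engine = list(duration_ms = 1000), seed = 42)
#' cfg$engine$duration_ms
#' @export
tacs_config <- function(...) {
  defaults <- list(
    network = list(
      py_shape = c(40L, 40L),
      in_shape = c(20L, 20L),
      degree_py_py = 121L,
      degree_py_in = 29L,
      degree_in_py = 49L,
      w_py_py = 6e-4,
      w_py_in = 2e-4,
      w_in_py = 4e-4,
      g_unit = 5
    ),
    neurons = list(
      excitatory = list(a = 0.02, b = 0.2,
                        c_range = c(-65, -50), d_range = c(8, 2)),
      inhibitory = list(a_range = c(0.02, 0.1), b_range = c(0.25, 0.2),
                        c = -65, d_reset = 2),
      v_init = -65,
      v_thresh = 30
    ),
    synapses = list(
      tau_ex = 2,
      tau_in = 3,
      tau_d = 300,
      r_dep = 0.6,
      v_ampa = 0,
      v_gaba = -80
    ),
    noise = list(base_ex = 0.9, base_in = 0.36, max_ex = 5, max_in = 2),
    stimulus = list(kind = "none", amplitude = 5, frequency = 4, phase = 0,
                    mode = "full", onset = 0, offset = Inf, target = "all"),
    engine = list(dt = 0.1, duration_ms = 5000, bin_ms = 5,
                  n_trace_ex = 3L, n_trace_in = 3L),
    # window_s = 2 so the Hann mainlobe (+/- 1 bin) fits inside the
    # half_band = 0.5 Hz scoring band; a 1 s window leaks a third of a pure
    # tone's power outside the band
    analysis = list(window_s = 2, overlap = 0.5, half_band = 0.5,
                    total_band = c(0.5, 50), psd_bin_ms = 50),
    closed_loop = list(window_s = 2, step_s = 0.5, band = c(3, 10),
                       z_thresh = 4, snr_min = 5,
                       consistency_n = 3L, consistency_tol = 0.5,
                       amplitude_policy = "fixed", amplitude = 5, gain = 50),
    seed = 1L
  )
  cfg <- merge_config(defaults, list(...), path = "")
  class(cfg) <- "tacs_config"
  validate_config(cfg)
  cfg
}

# Recursive merge of overrides into defaults; unknown keys are an error.
merge_config <- function(defaults, override, path = "") {
  if (length(override) == 0L) return(defaults)
  nms <- names(override)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("configuration overrides must be named (at '", path, "')",
         call. = FALSE)
  }
  for (nm in nms) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(override[[nm]])) {
        stop("configuration key '", key, "' must be a named list",
             call. = FALSE)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]], key)
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

#' Validate a configuration
#'
#' Checks structural and numeric constraints (positive time steps, feasible
#' out-degrees, valid stimulus protocol, ...) and returns the configuration
#' invisibly.  Error messages name the offending key.
#'
#' @param config a `tacs_config` list.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) stop("invalid configuration: '", key, "' ", what,
                          call. = FALSE)
  }
  net <- config$network
  chk(length(net$py_shape) == 2 && all(net$py_shape >= 1),
      "network.py_shape", "must be two positive integers")
  chk(length(net$in_shape) == 2 && all(net$in_shape >= 1),
      "network.in_shape", "must be two positive integers")
  n_py <- prod(net$py_shape); n_in <- prod(net$in_shape)
  chk(net$degree_py_py < n_py, "network.degree_py_py",
      "exceeds the pyramidal population")
  chk(net$degree_py_in <= n_in, "network.degree_py_in",
      "exceeds the inhibitory population")
  chk(net$degree_in_py <= n_py, "network.degree_in_py",
      "exceeds the pyramidal population")
  chk(all(c(net$w_py_py, net$w_py_in, net$w_in_py) >= 0),
      "network.w_*", "weights must be non-negative")
  eng <- config$engine
  chk(is.numeric(eng$dt) && eng$dt > 0, "engine.dt", "must be > 0")
  chk(eng$duration_ms > 0, "engine.duration_ms", "must be > 0")
  chk(eng$bin_ms > 0, "engine.bin_ms", "must be > 0")
  syn <- config$synapses
  chk(syn$tau_ex > 0 && syn$tau_in > 0 && syn$tau_d > 0,
      "synapses.tau_*", "time constants must be > 0")
  chk(syn$r_dep > 0 && syn$r_dep <= 1, "synapses.r_dep", "must be in (0, 1]")
  chk(config$noise$max_ex >= 0 && config$noise$max_in >= 0,
      "noise.max_*", "must be >= 0")
  st <- config$stimulus
  chk(st$kind %in% c("none", "tdcs", "tacs"), "stimulus.kind",
      "must be one of none/tdcs/tacs")
  chk(st$amplitude >= 0, "stimulus.amplitude", "must be >= 0")
  if (st$kind == "tacs") {
    chk(st$frequency > 0, "stimulus.frequency", "must be > 0 for tACS")
  }
  chk(st$mode %in% c("full", "depolarizing_only", "hyperpolarizing_only"),
      "stimulus.mode", "is not a recognised rectification mode")
  if (st$mode != "full") {
    chk(st$kind == "tacs", "stimulus.mode",
        "half-wave rectification requires kind == 'tacs'")
  }
  chk(st$offset > st$onset, "stimulus.offset", "must exceed stimulus.onset")
  chk(st$target %in% c("all", "excitatory_only"), "stimulus.target",
      "must be 'all' or 'excitatory_only'")
  cl <- config$closed_loop
  chk(cl$window_s > 0 && cl$step_s > 0, "closed_loop.window_s/step_s",
      "must be > 0")
  chk(length(cl$band) == 2 && cl$band[1] > 0 && cl$band[2] > cl$band[1],
      "closed_loop.band", "must be an increasing positive pair")
  chk(cl$amplitude_policy %in% c("fixed", "proportional"),
      "closed_loop.amplitude_policy", "must be 'fixed' or 'proportional'")
  invisible(config)
}

#' Load a configuration from a YAML file
#'
#' Missing keys take their defaults from [tacs_config()]; unknown keys are
#' rejected.  An empty file yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return A validated `tacs_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(tacs_config, raw)
}

#' Save a configuration to a YAML file
#'
#' The written file round-trips losslessly through [load_config()].
#'
#' @param config a `tacs_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "tacs_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.tacs_config <- function(x, ...) {
  n_py <- prod(x$network$py_shape); n_in <- prod(x$network$in_shape)
  cat("tacsnet configuration\n")
  cat(sprintf("  network : %d PY (%dx%d) + %d IN (%dx%d), degrees %d/%d/%d\n",
              n_py, x$network$py_shape[1], x$network$py_shape[2],
              n_in, x$network$in_shape[1], x$network$in_shape[2],
              x$network$degree_py_py, x$network$degree_py_in,
              x$network$degree_in_py))
  cat(sprintf("  engine  : dt %.3g ms, duration %.4g ms, activity bin %.3g ms\n",
              x$engine$dt, x$engine$duration_ms, x$engine$bin_ms))
  cat(sprintf("  stimulus: %s", x$stimulus$kind))
  if (x$stimulus$kind != "none") {
    cat(sprintf(" (%.3g pA", x$stimulus$amplitude))
    if (x$stimulus$kind == "tacs")
      cat(sprintf(", %.3g Hz, mode %s", x$stimulus$frequency, x$stimulus$mode))
    cat(")")
  }
  cat(sprintf("\n  seed    : %s\n", format(x$seed)))
  invisible(x)
}
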