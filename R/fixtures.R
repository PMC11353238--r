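# Synthetic-signal and toy-network generators: ground-truth oscillatory
# fixtures for validating the spectral analyses and the detector without
# running the full simulator.

#' Generate a synthetic oscillatory signal with known ground truth
#'
#' Sum of sinusoids plus Gaussian noise:
#' `x(t) = sum_k A_k sin(2 pi f_k t + phi_k) + N(0, noise_sd)`.
#' The returned ground truth records each component so detector and spectrum
#' estimates can be asserted against known values.
#'
#' @param components matrix-like with one row per component:
#'   `(frequency_hz, amplitude, phase_rad)`; a plain vector of length 3 is a
#'   single component.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param fs sampling rate, Hz; all component frequencies must be below
#'   `fs / 2`.
#' @param duration_s signal length, seconds.
#' @return A list of class `tacs_signal`: `time_s`, `value`, `fs`,
#'   `truth` (data frame `frequency`, `amplitude`, `phase`), `noise_sd`.
#' @examples
#' sig <- synthetic_signal(c(4, 1, 0), noise_sd = 0, fs = 200,
#'                         duration_s = 2)
#' max(abs(sig$value - sin(2 * pi * 4 * sig$time_s)))
#' @export
synthetic_signal <- function(components, noise_sd = 0, fs = 200,
                             duration_s = 10) {
  if (is.null(dim(components))) {
    components <- matrix(components, ncol = 3, byrow = TRUE)
  }
  components <- as.matrix(components)
  if (ncol(components) != 3) {
    stop("components must have columns (frequency, amplitude, phase)",
         call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (any(components[, 1] >= fs / 2)) {
    stop("component frequency at or above Nyquist (fs/2 = ", fs / 2, " Hz)",
         call. = FALSE)
  }
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  for (k in seq_len(nrow(components))) {
    x <- x + components[k, 2] *
      sin(2 * pi * components[k, 1] * t + components[k, 3])
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(t), 0, noise_sd)
  structure(list(time_s = t, value = x, fs = fs,
                 truth = data.frame(frequency = components[, 1],
                                    amplitude = components[, 2],
                                    phase = components[, 3]),
                 noise_sd = noise_sd),
            class = "tacs_signal")
}

#' Write a synthetic signal to CSV with a JSON ground-truth sidecar
#'
#' The CSV has columns `time_ms`, `value` (readable by
#' [read_signal_csv()]); the sidecar (same path, `.json`) records the
#' components, noise level and sampling rate.
#'
#' @param sig a `tacs_signal`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  utils::write.csv(data.frame(time_ms = sig$time_s * 1000,
                              value = sig$value),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = sig$fs, noise_sd = sig$noise_sd, truth = sig$truth),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Miniature network for fast engine tests
#'
#' Builds a reduced-scale network with the same construction rules as
#' [build_network()] (local fixed-degree PY->PY and PY->IN, global IN->PY,
#' automatically chosen neighbourhood radii).
#'
#' @param py_shape,in_shape grid shapes (defaults 8x8 and 4x4).
#' @param degrees integer triple: out-degrees for PY->PY, PY->IN, IN->PY.
#' @return A `tacs_network`.
#' @export
make_toy_network <- function(py_shape = c(8, 8), in_shape = c(4, 4),
                             degrees = c(8, 3, 5)) {
  build_network(toy_config(py_shape, in_shape, degrees))
}

#' Reduced-scale configuration for tests and examples
#'
#' A full [tacs_config()] whose network block is shrunk to a toy geometry;
#' every other block keeps its defaults unless overridden via `...`.
#'
#' @param py_shape,in_shape grid shapes.
#' @param degrees out-degree triple (PY->PY, PY->IN, IN->PY).
#' @param ... further overrides passed to [tacs_config()].
#' @return A `tacs_config`.
#' @export
toy_config <- function(py_shape = c(8, 8), in_shape = c(4, 4),
                       degrees = c(8, 3, 5), ...) {
  tacs_config(network = list(py_shape = py_shape, in_shape = in_shape,
                             degree_py_py = as.integer(degrees[1]),
                             degree_py_in = as.integer(degrees[2]),
                             degree_in_py = as.integer(degrees[3])),
              ...)
}
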