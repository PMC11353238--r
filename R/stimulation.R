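# Stimulation waveforms (tDCS, tACS with half-wave rectified variants) and
# background noise currents.

#' Construct a stimulation protocol
#'
#' Describes an injected current waveform.  `tdcs` is a constant current of
#' the given amplitude; `tacs` is `A * sin(2 pi f t / 1000 + phase)` with `t`
#' in ms.  Rectified tACS variants zero one half-cycle:
#' `depolarizing_only` keeps `max(0, sine)`, `hyperpolarizing_only` keeps
#' `min(0, sine)`.  Outside `[onset, offset)` the delivered current is 0.
#'
#' @param kind `"none"`, `"tdcs"` or `"tacs"`.
#' @param amplitude peak current, pA (>= 0).
#' @param frequency tACS frequency, Hz.
#' @param phase tACS phase offset, radians.
#' @param mode rectification mode; non-`"full"` modes require `kind = "tacs"`.
#' @param onset,offset stimulation window, ms.
#' @param target `"all"` or `"excitatory_only"`.
#' @return An object of class `tacs_protocol`.
#' @examples
#' p <- stimulus_protocol("tacs", amplitude = 5, frequency = 4)
#' stimulus_value(p, c(0, 62.5, 187.5))
#' @export
stimulus_protocol <- function(kind = c("none", "tdcs", "tacs"),
                              amplitude = 5, frequency = 4, phase = 0,
                              mode = c("full", "depolarizing_only",
                                       "hyperpolarizing_only"),
                              onset = 0, offset = Inf,
                              target = c("all", "excitatory_only")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  target <- match.arg(target)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (kind == "tacs" && frequency <= 0) {
    stop("tACS requires frequency > 0", call. = FALSE)
  }
  if (mode != "full" && kind != "tacs") {
    stop("half-wave rectification applies to tACS only", call. = FALSE)
  }
  if (offset <= onset) stop("offset must exceed onset", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 phase = phase %% (2 * pi), mode = mode,
                 onset = onset, offset = offset, target = target),
            class = "tacs_protocol")
}

#' Evaluate a stimulation waveform
#'
#' @param proto a `tacs_protocol` (or `NULL`, treated as no stimulation).
#' @param t time(s), ms; vectorised.
#' @return Delivered current, pA, one value per element of `t`.
#' @export
stimulus_value <- function(proto, t) {
  if (is.null(proto) || proto$kind == "none") return(numeric(length(t)))
  active <- t >= proto$onset & t < proto$offset
  out <- numeric(length(t))
  if (proto$kind == "tdcs") {
    out[active] <- proto$amplitude
  } else {
    s <- proto$amplitude *
      sin(2 * pi * proto$frequency * t[active] / 1000 + proto$phase)
    s <- switch(proto$mode,
                full = s,
                depolarizing_only = pmax(0, s),
                hyperpolarizing_only = pmin(0, s))
    out[active] <- s
  }
  out
}

#' @export
print.tacs_protocol <- function(x, ...) {
  if (x$kind == "none") {
    cat("tacs_protocol: no stimulation\n")
    return(invisible(x))
  }
  desc <- if (x$kind == "tdcs") {
    sprintf("tDCS %.3g pA", x$amplitude)
  } else {
    sprintf("tACS %.3g pA @ %.3g Hz, phase %.3f rad, mode %s",
            x$amplitude, x$frequency, x$phase, x$mode)
  }
  cat(sprintf("tacs_protocol: %s, window [%g, %g) ms, target %s\n",
              desc, x$onset, x$offset, x$target))
  invisible(x)
}

#' Draw per-neuron background noise currents
#'
#' Independent per-neuron, per-step uniform draws: `Uniform[0, max_ex]` pA
#' for excitatory neurons and `Uniform[0, max_in]` pA for inhibitory neurons
#' (defaults 5 and 2).  Uses R's global RNG; excitatory draws come first.
#'
#' @param n_ex,n_in population sizes.
#' @param max_ex,max_in noise maxima, pA.
#' @return A list with components `ex` and `inh`.
#' @export
noise_draw <- function(n_ex, n_in, max_ex = 5, max_in = 2) {
  list(ex = stats::runif(n_ex, 0, max_ex),
       inh = stats::runif(n_in, 0, max_in))
}
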