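# Canonical stimulation experiments: baseline dynamics, tACS vs tDCS,
# half-wave rectified variants, frequency mismatch, entrainment sweep and
# the closed-loop run, each summarised per seed.

stim_conditions <- c("baseline", "tacs", "tdcs", "depolarizing",
                     "hyperpolarizing", "tacs_mismatch")

# One seed of one condition.  Stimulated conditions run an unstimulated
# lead-in (default 2 s) used to estimate the ongoing oscillation's phase;
# sinusoidal 4 Hz conditions are then phase-aligned at onset.  All summary
# measures are computed on the stimulated segment only (the whole run for
# baseline).
stim_experiment_run <- function(condition, config, lead_ms = 2000,
                                stim_ms = 5000, backend = "cpp") {
  condition <- match.arg(condition, stim_conditions)
  an <- config$analysis
  dt <- config$engine$dt
  bin <- config$engine$bin_ms

  f_stim <- if (condition == "tacs_mismatch") 7 else 4
  amp <- config$stimulus$amplitude
  if (condition == "baseline") lead_ms <- 0

  cfg <- config
  cfg$engine$duration_ms <- lead_ms + stim_ms
  set.seed(cfg$seed)
  setup <- make_sim_setup(cfg)
  state <- setup$state
  chunks <- list()
  phase_aligned <- NA

  if (lead_ms > 0) {
    nlead <- as.integer(round(lead_ms / dt))
    zero <- numeric(nlead)
    ch <- run_chunk(setup, state, zero, zero, nlead, dt, 0, backend)
    state <- ch$state
    ch$offset_steps <- 0L
    chunks[[1]] <- ch
  }

  proto <- switch(condition,
    baseline = stimulus_protocol("none"),
    tdcs = stimulus_protocol("tdcs", amplitude = amp, onset = lead_ms),
    tacs_mismatch = stimulus_protocol("tacs", amplitude = amp,
                                      frequency = f_stim, phase = 0,
                                      onset = lead_ms),
    {
      # 4 Hz sinusoidal conditions: align the sine's phase with the ongoing
      # oscillation estimated from the lead-in activity
      mode <- switch(condition, tacs = "full",
                     depolarizing = "depolarizing_only",
                     hyperpolarizing = "hyperpolarizing_only")
      lead_act <- population_activity(chunks[[1]]$spike_step_ex * dt,
                                      chunks[[1]]$spike_id_ex,
                                      n = setup$pop_ex$n,
                                      bin_ms = an$psd_bin_ms,
                                      duration_ms = lead_ms)
      win_s <- min(2, lead_ms / 1000)
      wins <- sliding_windows(lead_act$pct, lead_act$fs, win_s, win_s / 2)
      pa <- estimate_phase_amplitude(wins[[length(wins)]], lead_act$fs,
                                     f_stim, t_ref = lead_ms)
      phase_aligned <- pa$phase
      p <- matched_protocol(f_stim, pa$phase, lead_ms, amplitude = amp)
      p$mode <- mode
      p
    })

  nstim <- as.integer(round(stim_ms / dt))
  times <- (as.integer(round(lead_ms / dt)) + seq_len(nstim) - 1L) * dt
  sv <- stimulus_value(proto, times)
  ch <- run_chunk(setup, state, sv,
                  if (proto$target == "all") sv else numeric(nstim),
                  nstim, dt, lead_ms, backend)
  ch$offset_steps <- as.integer(round(lead_ms / dt))
  chunks[[length(chunks) + 1L]] <- ch

  # analyse the stimulated segment only: activity peaks at the engine bin,
  # spectra on the coarser PSD binning
  t_ex <- (ch$spike_step_ex) * dt
  t_in <- (ch$spike_step_in) * dt
  act_ex <- population_activity(t_ex, ch$spike_id_ex, n = setup$pop_ex$n,
                                bin_ms = bin, duration_ms = stim_ms)
  act_in <- population_activity(t_in, ch$spike_id_in, n = setup$pop_in$n,
                                bin_ms = bin, duration_ms = stim_ms)
  act_psd <- population_activity(t_ex, ch$spike_id_ex, n = setup$pop_ex$n,
                                 bin_ms = an$psd_bin_ms,
                                 duration_ms = stim_ms)
  spec <- welch_psd(act_psd$pct, fs = act_psd$fs, window_s = an$window_s,
                    overlap_frac = an$overlap)
  f0 <- if (condition %in% c("baseline", "tdcs")) 4 else f_stim
  data.frame(
    condition = condition,
    seed = config$seed,
    f_stim = if (condition %in% c("baseline", "tdcs")) NA_real_ else f_stim,
    stim_phase = if (is.na(phase_aligned)) NA_real_ else phase_aligned,
    dominant_freq = dominant_frequency(spec, band = c(0.5, 10)),
    relative_power = relative_power(spec, f0, an$half_band, an$total_band),
    peak_activity_ex = max(act_ex$pct),
    peak_activity_in = max(act_in$pct)
  )
}

#' Run a canonical stimulation experiment over seeds
#'
#' Repeats one stimulation condition over `n_seeds` independent seeds and
#' summarises each run on the stimulated segment: dominant frequency of the
#' excitatory activity PSD, relative power at the target frequency
#' (stimulation frequency, or the endogenous 4 Hz for baseline/tDCS), and
#' peak percentage of spiking neurons per population.
#'
#' Conditions: `"baseline"` (noise only), `"tacs"` (full-wave 4 Hz,
#' phase-aligned to the ongoing oscillation estimated from a 2 s lead-in),
#' `"tdcs"` (constant current), `"depolarizing"` / `"hyperpolarizing"`
#' (half-wave rectified 4 Hz tACS), `"tacs_mismatch"` (full-wave 7 Hz).
#' Amplitude comes from `config$stimulus$amplitude` (default 5 pA).
#'
#' @param condition one of the conditions above.
#' @param config base [tacs_config()].
#' @param n_seeds number of independent runs.
#' @param seeds explicit seed vector (overrides `n_seeds`).
#' @param lead_ms unstimulated lead-in, ms.
#' @param stim_ms analysed (stimulated) duration, ms.
#' @param backend simulation backend.
#' @return A data frame with one row per seed.
#' @export
run_stim_experiment <- function(condition, config = tacs_config(),
                                n_seeds = 5,
                                seeds = config$seed + seq_len(n_seeds) - 1L,
                                lead_ms = 2000, stim_ms = 5000,
                                backend = "cpp") {
  condition <- match.arg(condition, stim_conditions)
  out <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    stim_experiment_run(condition, cfg, lead_ms = lead_ms,
                        stim_ms = stim_ms, backend = backend)
  })
  do.call(rbind, out)
}

#' Run the closed-loop experiment over seeds
#'
#' Runs [run_closed_loop()] for each seed and summarises the post-onset
#' segment: peak per-bin percentage of spiking neurons in each population,
#' their mean, the detected frequency, and the relative power at the
#' detected frequency before and after onset.
#'
#' @param config base [tacs_config()]; the default run length for this
#'   experiment is 8000 ms (about 3 s of monitoring before lock plus 5 s of
#'   matched stimulation).
#' @param n_seeds number of independent runs.
#' @param seeds explicit seed vector.
#' @param duration_ms total run length, ms.
#' @param backend simulation backend.
#' @return A data frame with one row per seed.
#' @export
run_closed_loop_experiment <- function(config = tacs_config(), n_seeds = 5,
                                       seeds = config$seed +
                                         seq_len(n_seeds) - 1L,
                                       duration_ms = 8000,
                                       backend = "cpp") {
  an <- config$analysis
  out <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    cfg$engine$duration_ms <- duration_ms
    sim <- run_closed_loop(cfg, backend = backend)
    if (sim$locked) {
      post <- sim$activity_ex$time >= sim$onset_ms
      post_in <- sim$activity_in$time >= sim$onset_ms
      peak_ex <- max(sim$activity_ex$pct[post])
      peak_in <- max(sim$activity_in$pct[post_in])
      psd_act <- population_activity(sim$spikes_ex$time_ms,
                                     sim$spikes_ex$neuron_id,
                                     n = sim$n_ex,
                                     bin_ms = an$psd_bin_ms,
                                     duration_ms = sim$duration_ms)
      post_psd <- psd_act$time >= sim$onset_ms
      spec_post <- welch_psd(psd_act$pct[post_psd], psd_act$fs,
                             window_s = an$window_s,
                             overlap_frac = an$overlap)
      rp_post <- relative_power(spec_post, sim$protocol$frequency,
                                an$half_band, an$total_band)
      rp_pre <- if (sum(!post_psd) >= an$window_s * psd_act$fs) {
        spec_pre <- welch_psd(psd_act$pct[!post_psd], psd_act$fs,
                              window_s = an$window_s,
                              overlap_frac = an$overlap)
        relative_power(spec_pre, sim$protocol$frequency, an$half_band,
                       an$total_band)
      } else {
        NA_real_
      }
      data.frame(seed = s, locked = TRUE, onset_ms = sim$onset_ms,
                 f_hat = sim$protocol$frequency,
                 peak_activity_ex = peak_ex, peak_activity_in = peak_in,
                 peak_activity_mean = (peak_ex + peak_in) / 2,
                 relative_power_pre = rp_pre,
                 relative_power_post = rp_post)
    } else {
      data.frame(seed = s, locked = FALSE, onset_ms = NA_real_,
                 f_hat = NA_real_, peak_activity_ex = NA_real_,
                 peak_activity_in = NA_real_,
                 peak_activity_mean = NA_real_,
                 relative_power_pre = NA_real_,
                 relative_power_post = NA_real_)
    }
  })
  do.call(rbind, out)
}

#' Reproduce a named results-section experiment
#'
#' Convenience driver running one of the package's canonical experiments at
#' default parameters and writing its per-seed summary (and, for `sweep`,
#' the long-format matrix) as CSV into `out_dir`.
#'
#' @param name one of `"baseline"`, `"tacs_vs_tdcs"`, `"halfwave"`,
#'   `"sweep"`, `"closed_loop"`.
#' @param out_dir output directory (created if missing).
#' @param config base [tacs_config()].
#' @param n_seeds seeds per condition (sweep uses `n_seeds` per cell).
#' @param sweep_amplitudes,sweep_frequencies sweep axes.
#' @return The summary data frame, invisibly.
#' @export
reproduce_experiment <- function(name = c("baseline", "tacs_vs_tdcs",
                                          "halfwave", "sweep",
                                          "closed_loop"),
                                 out_dir = ".", config = tacs_config(),
                                 n_seeds = 5,
                                 sweep_amplitudes = c(1, 5, 10, 15),
                                 sweep_frequencies = 0:9) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_df <- switch(name,
    baseline = run_stim_experiment("baseline", config, n_seeds),
    tacs_vs_tdcs = rbind(
      run_stim_experiment("tacs", config, n_seeds),
      run_stim_experiment("tdcs", config, n_seeds)),
    halfwave = rbind(
      run_stim_experiment("tacs", config, n_seeds),
      run_stim_experiment("depolarizing", config, n_seeds),
      run_stim_experiment("hyperpolarizing", config, n_seeds)),
    sweep = {
      sw <- entrainment_sweep(sweep_amplitudes, sweep_frequencies, config,
                              n_seeds)
      write_sweep_csv(sw, file.path(out_dir, "sweep_runs.csv"))
      utils::write.csv(sw$relative_power,
                       file.path(out_dir, "sweep_matrix.csv"))
      sw$runs
    },
    closed_loop = run_closed_loop_experiment(config, n_seeds))
  utils::write.csv(summary_df,
                   file.path(out_dir, paste0(name, "_summary.csv")),
                   row.names = FALSE)
  save_config(config, file.path(out_dir, paste0(name, "_config.yaml")))
  invisible(summary_df)
}
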