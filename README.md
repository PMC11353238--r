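# tacsnet

Spiking cortical network simulation of transcranial alternating current
stimulation (tACS) entrainment, with a closed-loop controller that detects
the network's endogenous rhythm and delivers matched stimulation.

## The scientific problem

Weak transcranial electric currents (a few pA per neuron at the cellular
scale) can entrain ongoing cortical oscillations, but *why* alternating
current (tACS) outperforms direct current (tDCS), what the depolarizing and
hyperpolarizing half-cycles each contribute, and how to pick the right
frequency and phase are mechanistic questions best answered in a model where
every spike is observable. `tacsnet` implements such a model for
computational neuroscientists studying slow cortical rhythms and
neurostimulation protocols:

* **Network** — 1600 pyramidal (PY) neurons on a 40x40 grid and 400
  inhibitory (IN) neurons on a 20x20 grid.  Izhikevich dynamics

  ```
  dV/dt = 0.04 V^2 + 5V + 140 - u + I_noise + I_stim - G_EX (V - V_AMPA) - G_IN (V - V_GABA)
  du/dt = a (bV - u),          spike: V >= 30 mV  =>  V <- c, u <- u + d
  ```

  with standard heterogeneity (excitatory `c` in [-65, -50] mV, `d` in
  [2, 8]; inhibitory `a` in [0.02, 0.1], `b` in [0.2, 0.25]), integrated by
  forward Euler at dt = 0.1 ms in a compiled (Rcpp) core.
* **Synapses** — three fixed-out-degree projections (PY->PY 121 local,
  PY->IN 29 local, IN->PY 49 global), exponential conductance decay
  (tau = 2 / 3 ms), and short-term depression on PY->PY efferents
  (factor r = 0.6 per presynaptic spike, recovery tau_d = 300 ms).
* **Dynamics** — with per-step uniform noise (up to 5 / 2 pA) on a small
  constant background current, the network alternates spontaneously between
  UP states (propagating waves of firing) and quiescent DOWN states at an
  endogenous rate near 4 Hz.
* **Stimulation** — tDCS (constant), tACS (`A sin(2 pi f t + phi)`), and
  half-wave rectified tACS variants, delivered to all neurons or only the
  excitatory population.
* **Analyses** — Welch power spectra of the percentage-of-spiking-neurons
  signal, *relative power* (band power at f0 +/- 0.5 Hz over total band
  power) as the entrainment measure, spatial activity maps, spectrograms,
  and amplitude x frequency entrainment sweeps (Arnold tongue).
* **Closed loop** — sliding-window FFT detection of the dominant frequency
  with statistical validation (peak significance, SNR, harmonic and
  consistency checks), phase/amplitude estimation from the Fourier
  coefficient at the dominant bin, and automatic delivery of
  frequency/phase-matched tACS.

## Worked example

```r
library(tacsnet)

## 5 s of spontaneous activity
sim <- run_simulation(tacs_config(seed = 1))
summary(sim)
#> Simulation of 5000 ms
#>   mean firing rate: 5.52 Hz (PY), 5.20 Hz (IN)
#>   peak activity: 70.9% (PY), 36.0% (IN)
#>   dominant frequency of PY activity: 4.50 Hz
```

The unstimulated network fires in brief network-wide UP states about 4.5
times per second: each PY neuron spikes ~5.5 times per second, and at the
crest of an UP state ~71% of the excitatory population fires within one
5 ms bin.

```r
## closed the loop: monitor, detect, stimulate matched
cl <- run_closed_loop(tacs_config(seed = 1, engine = list(duration_ms = 8000)))
cl
#> tacs_sim: 8000 ms at dt 0.1 ms, 1600 PY + 400 IN neurons (seed 1)
#> tacs_protocol: tACS 5 pA @ 4.5 Hz, phase 5.532 rad, mode full, window [3000, Inf) ms, target all
#>   spikes: 130883 excitatory, 60073 inhibitory
#>   peak activity: 99.9% PY, 89.2% IN
#>   closed loop: locked at t = 3000 ms, f_hat = 4.500 Hz, phase 5.532 rad

plot(cl)   # raster + activity with the delivered waveform overlaid
```

After 3 s of monitoring, the detector validates a 4.5 Hz dominant rhythm,
extrapolates its phase to the onset time, and delivers phase-matched 5 pA
tACS; nearly the whole excitatory population then fires on every stimulus
cycle.  `run_stim_experiment()` repeats the canonical stimulation
conditions (baseline, tACS, tDCS, half-wave variants, mismatched frequency)
over seeds, and `entrainment_sweep()` maps relative power over the
amplitude x frequency plane.

A command-line interface with the verbs `simulate`, `closed-loop`, `sweep`,
`analyze` and `reproduce` is installed under `exec/`.

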