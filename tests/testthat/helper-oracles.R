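## Independent oracles used across tests. These deliberately avoid the
## package's internals: plain loops and direct indexing only.

## Brute-force peak-triggered average + peak ratio for one trigger set.
oracle_pta_ratio <- function(x, fs, trigger_times, half_window = 0.5,
                             ratio_window = 0.2) {
  L <- round(half_window * fs)
  segs <- NULL
  for (tt in trigger_times) {
    i <- round(tt * fs) + 1L          # t0 = 0 throughout the fixtures
    if (i - L >= 1 && i + L <= length(x))
      segs <- cbind(segs, x[(i - L):(i + L)])
  }
  avg <- rowMeans(segs)
  avg <- avg - mean(avg)
  lag <- ((-L):L) / fs
  v <- avg[abs(lag) <= ratio_window + 1e-9]
  max(v) - min(v)
}

## Biphasic epileptiform waveform used to build detection fixtures:
## derivative-of-Gaussian with its positive extremum (+1) at t = 0.
oracle_biphasic <- function(t, sigma) {
  u <- (t - sigma) / sigma
  -u * exp(-u^2 / 2) / exp(-0.5)
}

## GCaMP-like unit-peak transient kernel.
oracle_kernel <- function(t, rise = 0.1, decay = 1.0) {
  k <- ifelse(t >= 0, (1 - exp(-t / rise)) * exp(-t / decay), 0)
  tmax <- rise * log(1 + decay / rise)
  k / ((1 - exp(-tmax / rise)) * exp(-tmax / decay))
}

## Study-condition fixture for the phase-locking suites: one EA of ~27 s
## carrying a sparse train of discrete sharp peaks (the per-EA peak counts
## reported for threshold-detected EA peaks), plus calcium cells.
phase_lock_fixture <- function(n_cells, coupled, seed, jitter_sd = 0.02,
                               coupling_prob = 0.9, min_peaks = 0) {
  k <- 0
  repeat {
    eo <- epiphase::make_ecog(epiphase::ecog_params(
      duration = 60, stim_onset = 10, ea_delay = 3, ea_duration = 27,
      peak_rate = 1.7, seed = seed + 10000 * k))
    if (length(eo$truth$peak_times) >= min_peaks) break
    k <- k + 1          # enforce the experiment's minimum-peak precondition
  }
  ca <- epiphase::make_calcium(
    eo$truth,
    epiphase::calcium_params(
      n_cells = n_cells, coupled_fraction = if (coupled) 1 else 0,
      coupling_prob = coupling_prob, jitter_sd = jitter_sd,
      baseline_event_rate = 0.2, event_amplitude = 1.0, noise_sd = 0.2,
      seed = seed + 1),
    total_duration = 60)
  list(peaks = eo$truth$peak_times, traces = ca$traces, truth = ca$truth)
}
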