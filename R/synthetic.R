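## Synthetic ECoG / calcium / spike-train generator with known ground truth.
## Stands in for in vivo recordings so every downstream stage is testable:
## 1/f-shaped baseline ECoG carrying a theta-band train of sharp biphasic
## epileptiform peaks, GCaMP-like calcium transients optionally coupled to
## those peaks, and pre/post-stimulus Poisson spike-rate steps.

#' Parameters for the synthetic ECoG generator
#'
#' @param duration total recording length (s).
#' @param fs sampling rate (Hz); 400 Hz matches typical subdural ECoG
#'   acquisition.
#' @param baseline_sd standard deviation of the 1/f-shaped baseline
#'   (signal units).
#' @param one_over_f_exponent spectral exponent of the baseline (power
#'   ~ 1/f^exponent).
#' @param stim_onset light-stimulation onset (s).
#' @param ea_delay delay from stimulation onset to epileptiform-activity (EA)
#'   onset (s).
#' @param ea_duration EA length (s).
#' @param peak_rate Poisson rate of discrete epileptiform peaks inside the EA
#'   window (Hz); the 5 Hz default sits inside the 4-8 Hz theta band so the
#'   EA segment carries a theta-band spectral signature.
#' @param peak_amplitude peak height in multiples of `baseline_sd`.
#' @param peak_width width parameter (Gaussian sigma, s) of the biphasic
#'   peak waveform.
#' @param seed integer seed; identical parameters + seed give identical
#'   output.
#' @return A validated list of class `ecog_params`.
#' @export
ecog_params <- function(duration = 60, fs = 400, baseline_sd = 1,
                        one_over_f_exponent = 1, stim_onset = 10,
                        ea_delay = 3.4, ea_duration = 23, peak_rate = 5,
                        peak_amplitude = 10, peak_width = 0.02, seed = 1) {
  p <- list(duration = duration, fs = fs, baseline_sd = baseline_sd,
            one_over_f_exponent = one_over_f_exponent,
            stim_onset = stim_onset, ea_delay = ea_delay,
            ea_duration = ea_duration, peak_rate = peak_rate,
            peak_amplitude = peak_amplitude, peak_width = peak_width,
            seed = as.integer(seed))
  if (p$ea_delay < 0) stop("ea_delay must be >= 0")
  if (p$stim_onset + p$ea_delay + p$ea_duration > p$duration)
    stop("EA window must end within the recording")
  if (p$peak_rate <= 0) stop("peak_rate must be > 0")
  if (p$peak_width <= 0 || p$baseline_sd < 0) stop("invalid ecog_params")
  class(p) <- "ecog_params"
  p
}

#' Parameters for the synthetic calcium generator
#'
#' Each cell's trace is a sum of double-exponential transients
#' `(1 - exp(-t/rise)) * exp(-t/decay)` (normalized to unit peak, scaled by
#' `event_amplitude`) plus white noise. Coupled cells fire at ECoG peak times
#' (each peak kept with probability `coupling_prob`, jittered by
#' `N(0, jitter_sd^2)`) plus background Poisson events; uncoupled cells fire
#' background events only.
#'
#' @param n_cells number of cells.
#' @param fs calcium sampling rate (Hz); 20 Hz is a typical miniscope rate
#'   (the acquisition rate of the emulated system is not published).
#' @param coupled_fraction fraction of cells coupled to the ECoG peaks.
#' @param coupling_prob probability that a coupled cell fires on a given
#'   ECoG peak.
#' @param jitter_sd SD of the coupling time jitter (s).
#' @param baseline_event_rate Poisson rate of background transients (Hz).
#' @param kernel_rise,kernel_decay transient rise/decay time constants (s);
#'   defaults emulate GCaMP6m-like kinetics. Requires
#'   `kernel_decay > kernel_rise > 0`.
#' @param event_amplitude peak height of one transient (signal units).
#' @param noise_sd SD of the additive white noise.
#' @param seed integer seed, fanned out to per-cell substreams.
#' @return A validated list of class `calcium_params`.
#' @export
calcium_params <- function(n_cells = 50, fs = 20, coupled_fraction = 0.5,
                           coupling_prob = 0.9, jitter_sd = 0.02,
                           baseline_event_rate = 0.2, kernel_rise = 0.1,
                           kernel_decay = 1.0, event_amplitude = 1.0,
                           noise_sd = 0.2, seed = 1) {
  p <- list(n_cells = as.integer(n_cells), fs = fs,
            coupled_fraction = coupled_fraction,
            coupling_prob = coupling_prob, jitter_sd = jitter_sd,
            baseline_event_rate = baseline_event_rate,
            kernel_rise = kernel_rise, kernel_decay = kernel_decay,
            event_amplitude = event_amplitude, noise_sd = noise_sd,
            seed = as.integer(seed))
  if (p$coupled_fraction < 0 || p$coupled_fraction > 1 ||
      p$coupling_prob < 0 || p$coupling_prob > 1)
    stop("coupled_fraction and coupling_prob must lie in [0, 1]")
  if (!(p$kernel_decay > p$kernel_rise && p$kernel_rise > 0))
    stop("kernel_decay > kernel_rise > 0 required")
  if (p$n_cells < 1) stop("n_cells must be >= 1")
  class(p) <- "calcium_params"
  p
}

## Unit-peak double-exponential calcium kernel, zero for t < 0.
calcium_kernel <- function(t, rise, decay) {
  k <- ifelse(t >= 0, (1 - exp(-t / rise)) * exp(-t / decay), 0)
  tmax <- rise * log(1 + decay / rise)
  k / ((1 - exp(-tmax / rise)) * exp(-tmax / decay))
}

## Biphasic epileptiform peak waveform: derivative-of-Gaussian of width
## sigma, shifted so its positive extremum (value +1) lies exactly at t = 0.
biphasic_peak <- function(t, sigma) {
  u <- (t - sigma) / sigma
  -u * exp(-u^2 / 2) / exp(-0.5)
}

## Independent per-cell substream seeds derived from one global seed.
substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic ECoG recording with a known EA window
#'
#' Baseline is Gaussian noise spectrally shaped to `1/f^exponent` and
#' renormalized to `baseline_sd`. Inside the EA window
#' `[stim_onset + ea_delay, stim_onset + ea_delay + ea_duration)` sharp
#' biphasic peaks are added at homogeneous Poisson times; the truth records
#' their exact centers (positive extremum of each waveform).
#'
#' @param p an [ecog_params()] object.
#' @return list with `ts` (a `time_series`) and `truth` (class
#'   `synth_ground_truth`: `ea_onset`, `ea_offset`, `peak_times`, `seed`).
#' @export
make_ecog <- function(p = ecog_params()) {
  stopifnot(inherits(p, "ecog_params"))
  set.seed(p$seed)
  n <- round(p$duration * p$fs)
  X <- stats::fft(stats::rnorm(n))
  k <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))   # symmetric bin index
  wgt <- ifelse(k > 0, k^(-p$one_over_f_exponent / 2), 0)
  x <- Re(stats::fft(X * wgt, inverse = TRUE)) / n
  if (p$baseline_sd > 0) x <- x / stats::sd(x) * p$baseline_sd else x <- x * 0

  ea_onset <- p$stim_onset + p$ea_delay
  ea_offset <- ea_onset + p$ea_duration
  n_pk <- stats::rpois(1, p$peak_rate * p$ea_duration)
  peak_times <- sort(stats::runif(n_pk, ea_onset, ea_offset))
  tt <- (seq_len(n) - 1L) / p$fs
  amp <- p$peak_amplitude * p$baseline_sd
  for (pk in peak_times) {
    i0 <- max(1L, floor((pk - 8 * p$peak_width) * p$fs) + 1L)
    i1 <- min(n, ceiling((pk + 8 * p$peak_width) * p$fs) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + amp * biphasic_peak(tt[idx] - pk, p$peak_width)
  }
  truth <- structure(
    list(ea_onset = ea_onset, ea_offset = ea_offset, peak_times = peak_times,
         stim_onset = p$stim_onset, coupled_flags = logical(0),
         true_event_times = list(), seed = p$seed),
    class = "synth_ground_truth")
  list(ts = time_series(x, fs = p$fs, label = "ECoG_synth", units = "a.u."),
       truth = truth)
}

#' Generate synthetic calcium traces coupled to ECoG peaks
#'
#' @param truth a `synth_ground_truth` from [make_ecog()] supplying the ECoG
#'   peak times.
#' @param p a [calcium_params()] object.
#' @param total_duration recording length (s); must cover the EA window.
#' @return list with `traces` (a `multi_trace`) and `truth` (the input truth
#'   augmented with `coupled_flags` and per-cell `true_event_times`).
#' @export
make_calcium <- function(truth, p = calcium_params(), total_duration = 60) {
  stopifnot(inherits(p, "calcium_params"))
  if (total_duration < truth$ea_offset)
    stop("total_duration must cover the EA window")
  n <- round(total_duration * p$fs)
  tt <- (seq_len(n) - 1L) / p$fs
  n_coupled <- round(p$coupled_fraction * p$n_cells)
  coupled <- seq_len(p$n_cells) <= n_coupled
  seeds <- substream_seeds(p$seed, p$n_cells)
  vals <- matrix(0, nrow = p$n_cells, ncol = n)
  events <- vector("list", p$n_cells)
  for (c in seq_len(p$n_cells)) {
    set.seed(seeds[c])
    ev <- numeric(0)
    if (coupled[c] && length(truth$peak_times)) {
      keep <- stats::runif(length(truth$peak_times)) < p$coupling_prob
      ev <- truth$peak_times[keep] +
        stats::rnorm(sum(keep), 0, p$jitter_sd)
    }
    n_bg <- stats::rpois(1, p$baseline_event_rate * total_duration)
    ev <- sort(c(ev, stats::runif(n_bg, 0, total_duration)))
    x <- stats::rnorm(n, 0, p$noise_sd)
    for (e in ev) {
      i0 <- max(1L, floor(e * p$fs) + 1L)
      idx <- i0:n
      x[idx] <- x[idx] + p$event_amplitude *
        calcium_kernel(tt[idx] - e, p$kernel_rise, p$kernel_decay)
    }
    vals[c, ] <- x
    events[[c]] <- ev
  }
  truth$coupled_flags <- coupled
  truth$true_event_times <- events
  list(traces = multi_trace(vals, fs = p$fs), truth = truth)
}

#' Generate per-trial Poisson spike trains with a rate step at stimulation
#'
#' Homogeneous Poisson at `pre_rate` before `stim_onset` and `post_rate`
#' from `stim_onset` to the trial end.
#'
#' @param pre_rate,post_rate firing rates (Hz, >= 0).
#' @param stim_onset stimulation onset within the trial (s).
#' @param stim_duration nominal stimulation length (s); recorded in the
#'   result attributes only.
#' @param n_trials number of trials.
#' @param trial_length trial length (s).
#' @param seed integer seed, fanned out per trial.
#' @return list of numeric spike-time vectors, one per trial, each sorted
#'   within `[0, trial_length)`.
#' @export
make_spiketrains <- function(pre_rate, post_rate, stim_onset = 12,
                             stim_duration = 5, n_trials = 6,
                             trial_length = 24, seed = 1) {
  if (pre_rate < 0 || post_rate < 0) stop("rates must be >= 0")
  seeds <- substream_seeds(seed, n_trials)
  trains <- lapply(seq_len(n_trials), function(tr) {
    set.seed(seeds[tr])
    pre <- if (pre_rate > 0)
      stats::runif(stats::rpois(1, pre_rate * stim_onset), 0, stim_onset)
    else numeric(0)
    post_len <- trial_length - stim_onset
    post <- if (post_rate > 0)
      stats::runif(stats::rpois(1, post_rate * post_len),
                   stim_onset, trial_length)
    else numeric(0)
    sort(c(pre, post))
  })
  attr(trains, "stim_onset") <- stim_onset
  attr(trains, "stim_duration") <- stim_duration
  attr(trains, "trial_length") <- trial_length
  trains
}
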