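## Single-cell trial metrics: threshold spike detection, PSTH, the
## responsiveness criterion, input resistance from I-V data, and the
## behavioral discrimination index.

#' Threshold-based spike detection
#'
#' A spike is timestamped at the extremum of each contiguous
#' threshold-crossing run (positive- or negative-going per `polarity`);
#' crossings closer than the refractory period are merged keeping the
#' larger extremum.
#'
#' @param ts a high-pass/extracellular-like `time_series`.
#' @param threshold threshold magnitude in signal units (finite); positive
#'   polarity detects excursions above `threshold`, negative polarity
#'   excursions below `-threshold`.
#' @param refractory minimum spike separation (s, default 0.001).
#' @param polarity `"positive"` (default) detects upward crossings,
#'   `"negative"` downward.
#' @return list of class `spike_train`: sorted `spike_times` (s), `window`
#'   (recording extent), `threshold`, `polarity`.
#' @export
detect_spikes <- function(ts, threshold, refractory = 0.001,
                          polarity = c("positive", "negative")) {
  stopifnot(inherits(ts, "time_series"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  polarity <- match.arg(polarity)
  x <- if (polarity == "negative") -ts$values else ts$values
  idx <- supra_runs_peaks(x, threshold, ts$fs, refractory)
  structure(list(spike_times = ts$t0 + (idx - 1L) / ts$fs,
                 window = c(ts$t0, ts$t0 + ts_duration(ts)),
                 threshold = threshold, polarity = polarity),
            class = "spike_train")
}

#' Peri-stimulus time histogram
#'
#' Half-open contiguous bins over the window; counts sum to the total
#' number of spikes in the window. A trailing partial bin is dropped with a
#' warning when `bin_size` does not divide the window length.
#'
#' @param trains list of numeric spike-time vectors (one per trial), or of
#'   `spike_train` objects.
#' @param window numeric `c(start, stop)` (s).
#' @param bin_size bin width (s).
#' @return list of class `psth`: `bin_edges`, `counts` (trials x bins
#'   matrix), `rate` (Hz, trial-averaged per bin), `n_trials`.
#' @export
psth <- function(trains, window, bin_size) {
  tt <- lapply(trains, function(tr)
    if (inherits(tr, "spike_train")) tr$spike_times else as.numeric(tr))
  len <- window[2] - window[1]
  nb <- floor(len / bin_size + 1e-9)
  if (nb * bin_size < len - 1e-9)
    warning("bin_size does not divide the window; trailing partial bin dropped")
  if (nb < 1) stop("window shorter than one bin")
  edges <- window[1] + (0:nb) * bin_size
  counts <- t(vapply(tt, function(s) {
    s <- s[s >= window[1] - 1e-12 & s < window[1] + nb * bin_size - 1e-12]
    tabulate(pmin(floor((s - window[1]) / bin_size) + 1L, nb), nbins = nb)
  }, integer(nb)))
  structure(list(bin_edges = edges, counts = counts,
                 rate = colMeans(counts) / bin_size,
                 n_trials = length(tt)),
            class = "psth")
}

#' Trial-repetition responsiveness criterion
#'
#' Per trial, the pre-stimulus mean rate over `[stim_onset - pre_len,
#' stim_onset)` and post-stimulus mean rate over `[stim_onset, stim_onset +
#' post_len)` are computed from PSTH bins of `bin_size`; the trial counts as
#' increased iff the post mean strictly exceeds the pre mean. A cell is
#' responsive iff at least `min_increased` trials are increased.
#'
#' @param trains list of per-trial spike-time vectors.
#' @param stim_onset stimulation onset (s).
#' @param pre_len,post_len analysis window lengths (s, defaults 12).
#' @param bin_size PSTH bin (s, default 3).
#' @param min_increased minimum number of increased trials (default 2).
#' @return list of class `responsiveness_result`: per-trial `pre_mean` /
#'   `post_mean` (Hz), `increased`, `n_increased_trials`, `responsive`.
#' @export
responsiveness <- function(trains, stim_onset, pre_len = 12, post_len = 12,
                           bin_size = 3, min_increased = 2) {
  pre <- psth(trains, c(stim_onset - pre_len, stim_onset), bin_size)
  post <- psth(trains, c(stim_onset, stim_onset + post_len), bin_size)
  pre_mean <- rowSums(pre$counts) / pre_len
  post_mean <- rowSums(post$counts) / post_len
  inc <- post_mean > pre_mean
  structure(list(pre_mean = pre_mean, post_mean = post_mean,
                 increased = inc, n_increased_trials = sum(inc),
                 responsive = sum(inc) >= min_increased,
                 min_increased = min_increased),
            class = "responsiveness_result")
}

#' Input resistance from an I-V table
#'
#' Least-squares slope of steady-state voltage (mV) against injected
#' current (pA) over the closed fit range; mV/pA equals GOhm, reported in
#' MOhm (slope * 1000).
#'
#' @param current injected currents (pA).
#' @param voltage steady-state voltage responses (mV).
#' @param fit_range closed current range used for the fit (pA, default
#'   `c(-100, -40)`).
#' @return input resistance in MOhm.
#' @export
input_resistance <- function(current, voltage, fit_range = c(-100, -40)) {
  stopifnot(length(current) == length(voltage))
  sel <- current >= fit_range[1] & current <= fit_range[2]
  if (sum(sel) < 2) stop("need >= 2 I-V pairs inside the fit range")
  slope <- stats::coef(stats::lm(voltage[sel] ~ current[sel]))[2]
  unname(slope) * 1000
}

#' Object-displacement discrimination index
#'
#' `di = 100 * (t_relocated - t_unmoved) / (t_relocated + t_unmoved)`;
#' in the training phase a subject with `di > exclusion_cut` is excluded.
#'
#' @param t_relocated,t_unmoved exploration times (s) of the relocated and
#'   unmoved object; their sum must be positive.
#' @param phase `"training"` or `"test"`.
#' @param exclusion_cut training-phase exclusion cutoff (default 20).
#' @return list with `di` and `excluded`.
#' @export
discrimination_index <- function(t_relocated, t_unmoved,
                                 phase = c("test", "training"),
                                 exclusion_cut = 20) {
  phase <- match.arg(phase)
  tot <- t_relocated + t_unmoved
  if (tot <= 0) stop("total exploration time must be positive")
  di <- 100 * (t_relocated - t_unmoved) / tot
  list(di = di, excluded = phase == "training" && di > exclusion_cut)
}
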