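## Peak-triggered averages (PTA) of calcium activity around ECoG peaks, the
## shuffled-surrogate null, the peak-ratio z-score with the 1.96 decision
## rule, the per-EA phase-locked fraction and calcium AUC.

## Shared PTA core on a raw sample vector. Peak times are snapped to the
## nearest sample of the signal's own grid; peaks whose full +-half_window
## does not fit inside the recording are dropped (and counted). The same
## routine serves the real peaks and every shuffled replicate.
pta_core <- function(x, t0, fs, peak_times, half_window) {
  L <- round(half_window * fs)
  idx <- round((peak_times - t0) * fs) + 1L
  keep <- idx - L >= 1L & idx + L <= length(x)
  n_used <- sum(keep)
  if (n_used == 0L) stop("no peaks with a full +-", half_window,
                         " s window inside the recording")
  seg <- matrix(x[outer((-L):L, idx[keep], "+")], nrow = 2L * L + 1L)
  avg <- rowMeans(seg)
  off <- mean(avg)
  list(avg = avg - off, lag = ((-L):L) / fs, n_used = n_used,
       n_dropped = length(peak_times) - n_used, offset = off)
}

#' Peak-triggered average of a signal around ECoG peak times
#'
#' Extracts `+-half_window` segments centered (nearest-sample) on each peak,
#' averages them, and subtracts the average's own mean. Applied to a calcium
#' trace this is the phase-locking effect trace; applied to the ECoG channel
#' itself it gives the ECoG PTA for reporting.
#'
#' @param signal a `time_series`, or a `multi_trace` together with `cell`.
#' @param peak_times ECoG peak times (s).
#' @param half_window half window length (s, default 0.5).
#' @param cell cell id or index when `signal` is a `multi_trace`.
#' @return list of class `pta_result`: `avg_trace`, `lag` (s),
#'   `n_peaks_used`, `n_dropped`, `normalization_offset`, `lag_fs`,
#'   `cell_id`.
#' @export
peak_triggered_average <- function(signal, peak_times, half_window = 0.5,
                                   cell = NULL) {
  if (inherits(signal, "multi_trace")) {
    if (is.null(cell)) stop("cell required for a multi_trace")
    signal <- mt_cell(signal, cell)
  }
  stopifnot(inherits(signal, "time_series"))
  r <- pta_core(signal$values, signal$t0, signal$fs, peak_times, half_window)
  structure(list(avg_trace = r$avg, lag = r$lag, n_peaks_used = r$n_used,
                 n_dropped = r$n_dropped, normalization_offset = r$offset,
                 lag_fs = signal$fs,
                 cell_id = if (nzchar(signal$label)) signal$label else NA),
            class = "pta_result")
}

#' Peak ratio of an averaged trace
#'
#' Maximum minus minimum of the PTA samples with `|lag| <= window` (closed
#' at both ends); the phase-locking effect size.
#'
#' @param pta a [peak_triggered_average()] result, or a bare numeric
#'   avg-trace (then `lag_fs` must be given).
#' @param window half width of the ratio window (s, default 0.2).
#' @param lag_fs lag-grid sampling rate when `pta` is a bare vector.
#' @return scalar `max - min` within the window.
#' @export
peak_ratio <- function(pta, window = 0.2, lag_fs = NULL) {
  if (inherits(pta, "pta_result")) {
    avg <- pta$avg_trace; lag <- pta$lag
  } else {
    if (is.null(lag_fs)) stop("lag_fs required for a bare avg trace")
    L <- (length(pta) - 1L) / 2
    avg <- pta; lag <- ((-L):L) / lag_fs
  }
  if (max(lag) < window - 1e-9)
    stop("lag grid does not cover +-", window, " s")
  v <- avg[abs(lag) <= window + 1e-9]
  max(v) - min(v)
}

#' Shuffled-surrogate null distribution of the peak ratio
#'
#' For each of `n_shuffles` replicates, `n_peaks` trigger times are drawn
#' uniformly (with replacement) from `[t_first_peak, t_last_peak]`, snapped
#' to the signal's sample grid, and pushed through exactly the same PTA +
#' peak-ratio computation as the real peaks (including the edge-retention
#' rule).
#'
#' Seed protocol (relied upon by reproducibility checks): after
#' `set.seed(seed)`, replicate r consumes the r-th block of `n_peaks`
#' consecutive `runif(n_peaks, t_first_peak, t_last_peak)` variates.
#'
#' @param trace one cell's `time_series`.
#' @param n_peaks number of real ECoG peaks to mimic per replicate.
#' @param t_first_peak,t_last_peak time range of the real peaks (s).
#' @param n_shuffles number of surrogate replicates (default 1000).
#' @param seed integer RNG seed.
#' @param half_window,ratio_window PTA and peak-ratio windows (s).
#' @return list of class `null_distribution`: `shuffled_peak_ratios`, `mu`,
#'   `sigma` (population SD), `n_shuffles`, `seed`.
#' @export
shuffled_null <- function(trace, n_peaks, t_first_peak, t_last_peak,
                          n_shuffles = 1000, seed = 1, half_window = 0.5,
                          ratio_window = 0.2) {
  stopifnot(inherits(trace, "time_series"))
  if (!(t_first_peak < t_last_peak))
    stop("t_first_peak must precede t_last_peak")
  set.seed(seed)
  ratios <- numeric(n_shuffles)
  for (r in seq_len(n_shuffles)) {
    tt <- stats::runif(n_peaks, t_first_peak, t_last_peak)
    p <- pta_core(trace$values, trace$t0, trace$fs, tt, half_window)
    ratios[r] <- peak_ratio(p$avg, window = ratio_window, lag_fs = trace$fs)
  }
  mu <- mean(ratios)
  sigma <- sqrt(mean((ratios - mu)^2))     # population SD over the shuffles
  structure(list(shuffled_peak_ratios = ratios, mu = mu, sigma = sigma,
                 n_shuffles = n_shuffles, seed = seed),
            class = "null_distribution")
}

#' Phase-locking z-score and decision
#'
#' `z = (peak_ratio - mu) / sigma` against the shuffled null; a cell is
#' phase-locked iff `z > z_threshold` (strict inequality).
#'
#' @param peak_ratio the cell's real peak ratio.
#' @param null a [shuffled_null()] result.
#' @param z_threshold decision threshold (default 1.96).
#' @param cell_id optional identifier carried through.
#' @return list of class `phase_lock_stats`: `cell_id`, `peak_ratio`, `mu`,
#'   `sigma`, `z`, `locked`, `z_threshold`.
#' @export
phase_lock_z <- function(peak_ratio, null, z_threshold = 1.96,
                         cell_id = NA) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$sigma <= 0)
    stop("degenerate null: sigma = 0, phase locking undefined")
  z <- (peak_ratio - null$mu) / null$sigma
  structure(list(cell_id = cell_id, peak_ratio = peak_ratio, mu = null$mu,
                 sigma = null$sigma, z = z, locked = z > z_threshold,
                 z_threshold = z_threshold),
            class = "phase_lock_stats")
}

#' Percentage of phase-locked cells
#'
#' @param stats a list of [phase_lock_z()] results (or a data frame with a
#'   `locked` column).
#' @return percentage in `[0, 100]`.
#' @export
phase_locked_fraction <- function(stats) {
  locked <- if (is.data.frame(stats)) stats$locked
            else vapply(stats, function(s) isTRUE(s$locked), TRUE)
  if (!length(locked)) stop("no cells")
  100 * sum(locked) / length(locked)
}

#' Phase-locking analysis of all cells of a multi_trace
#'
#' Convenience driver: per cell, computes the real PTA peak ratio from the
#' ECoG peak times, builds the shuffled null, and applies the z-score rule.
#' Per-cell null seeds are fanned out from `seed`.
#'
#' @param traces a `multi_trace` of calcium traces.
#' @param peak_times real ECoG peak times (s).
#' @param n_shuffles surrogates per cell (default 1000).
#' @param seed integer seed.
#' @param z_threshold decision threshold (default 1.96).
#' @param half_window,ratio_window PTA and peak-ratio windows (s).
#' @return data frame, one row per cell: `cell_id`, `peak_ratio`, `mu`,
#'   `sigma`, `z`, `locked`; attribute `phase_locked_pct`.
#' @export
phase_lock_cells <- function(traces, peak_times, n_shuffles = 1000,
                             seed = 1, z_threshold = 1.96, half_window = 0.5,
                             ratio_window = 0.2) {
  stopifnot(inherits(traces, "multi_trace"))
  if (length(peak_times) < 2L) stop("need at least two ECoG peaks")
  a <- min(peak_times); b <- max(peak_times)
  seeds <- substream_seeds(seed, length(traces$cell_ids))
  rows <- lapply(seq_along(traces$cell_ids), function(i) {
    ts <- mt_cell(traces, traces$cell_ids[i])
    pr <- peak_ratio(peak_triggered_average(ts, peak_times, half_window),
                     window = ratio_window)
    nd <- shuffled_null(ts, length(peak_times), a, b, n_shuffles, seeds[i],
                        half_window, ratio_window)
    st <- phase_lock_z(pr, nd, z_threshold, cell_id = traces$cell_ids[i])
    data.frame(cell_id = st$cell_id, peak_ratio = st$peak_ratio,
               mu = st$mu, sigma = st$sigma, z = st$z, locked = st$locked,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "phase_locked_pct") <- 100 * mean(out$locked)
  out
}

#' Calcium area under the curve after stimulation
#'
#' Trapezoidal integral of each raw trace over
#' `[stim_onset, stim_onset + window)` (no baseline subtraction by default).
#'
#' @param traces a `multi_trace` (or single `time_series`).
#' @param stim_onset stimulation onset (s).
#' @param window integration window length (s, default 50).
#' @param subtract_baseline optional: subtract the pre-stimulus mean
#'   (`[t0, stim_onset)`) before integrating (default `FALSE`).
#' @return data frame with `cell_id` and `auc` (signal units * s).
#' @export
calcium_auc <- function(traces, stim_onset, window = 50,
                        subtract_baseline = FALSE) {
  if (inherits(traces, "time_series"))
    traces <- multi_trace(matrix(traces$values, nrow = 1), fs = traces$fs,
                          t0 = traces$t0,
                          cell_ids = if (nzchar(traces$label)) traces$label
                                     else "cell_1")
  stopifnot(inherits(traces, "multi_trace"))
  tv <- traces$t0 + (seq_len(ncol(traces$values)) - 1L) / traces$fs
  if (stim_onset + window > max(tv) + 1 / traces$fs + 1e-9)
    stop("AUC window exceeds the recording")
  ## closed integration range: the endpoint sample (when present) is
  ## included so the trapezoid spans the full `window` seconds
  sel <- tv >= stim_onset - 1e-9 & tv <= stim_onset + window + 1e-9
  auc <- vapply(seq_len(nrow(traces$values)), function(i) {
    x <- traces$values[i, ]
    if (subtract_baseline) {
      pre <- tv < stim_onset - 1e-9
      if (any(pre)) x <- x - mean(x[pre])
    }
    pracma::trapz(tv[sel], x[sel])
  }, 0)
  data.frame(cell_id = traces$cell_ids, auc = auc, stringsAsFactors = FALSE)
}
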