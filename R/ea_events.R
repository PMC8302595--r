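## Epileptiform-activity (EA) event handling: threshold-based ECoG peak
## detection, episode characterization (delay, duration, Racine encoding)
## and pulse-train stimulation protocols.

#' Threshold specification for peak/spike detection
#'
#' Either an absolute threshold in signal units, or a robust relative
#' threshold `median + k * MAD` computed on a baseline segment.
#'
#' @param k MAD multiplier (default 5).
#' @param absolute absolute threshold value; overrides `k` when given.
#' @param baseline a `time_series` baseline segment (required for the
#'   relative form).
#' @return list of class `threshold_spec`.
#' @export
threshold_spec <- function(k = 5, absolute = NULL, baseline = NULL) {
  structure(list(k = k, absolute = absolute, baseline = baseline),
            class = "threshold_spec")
}

resolve_threshold <- function(spec) {
  if (!inherits(spec, "threshold_spec")) {
    if (is.numeric(spec) && length(spec) == 1L) return(spec)  # bare absolute
    stop("threshold must be a threshold_spec or a single number")
  }
  if (!is.null(spec$absolute)) return(spec$absolute)
  if (is.null(spec$baseline))
    stop("relative threshold requested but no baseline segment given")
  b <- spec$baseline$values
  stats::median(b) + spec$k * stats::mad(b)
}

## Local maxima of contiguous supra-threshold runs, merged within a
## refractory period keeping the larger maximum. Returns sample indices.
supra_runs_peaks <- function(x, thr, fs, refractory) {
  above <- x > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  idx <- mapply(function(a, b) {
    seg <- x[a:b]
    a + which.max(seg) - 1L    # ties broken to the earliest sample
  }, rs, re)
  vals <- x[idx]
  ## refractory merging
  keep <- integer(0)
  cur <- idx[1]; curv <- vals[1]
  for (i in seq_along(idx)[-1]) {
    if ((idx[i] - cur) / fs < refractory) {
      if (vals[i] > curv) { cur <- idx[i]; curv <- vals[i] }
    } else {
      keep <- c(keep, cur); cur <- idx[i]; curv <- vals[i]
    }
  }
  c(keep, cur)
}

#' Detect ECoG peaks inside an EA window
#'
#' A peak is the local-maximum sample of each contiguous supra-threshold run
#' (positive-going signal; negate the trace for negative spikes). Runs
#' closer than the refractory period are merged keeping the larger maximum.
#'
#' @param ts a `time_series`.
#' @param ea_window numeric `c(start, stop)` (s), half-open, within the
#'   recording.
#' @param threshold a [threshold_spec()] or a bare absolute value.
#' @param refractory minimum peak separation (s, default 0.1 - half a theta
#'   period at typical ~5 Hz peak rates).
#' @return list of class `peak_set`: `peak_times` (s, sorted),
#'   `threshold_used`, `refractory`, `ea_window`.
#' @export
detect_peaks <- function(ts, ea_window, threshold = threshold_spec(),
                         refractory = 0.1) {
  stopifnot(inherits(ts, "time_series"), length(ea_window) == 2L)
  seg <- segment(ts, ea_window[1], ea_window[2])
  thr <- resolve_threshold(threshold)
  idx <- supra_runs_peaks(seg$values, thr, seg$fs, refractory)
  structure(list(peak_times = seg$t0 + (idx - 1L) / seg$fs,
                 threshold_used = thr, refractory = refractory,
                 ea_window = as.numeric(ea_window)),
            class = "peak_set")
}

#' Characterize EA episodes relative to their triggering stimulations
#'
#' Each EA event is paired with the latest stimulation at or before its
#' onset; delay is the time from stimulation onset to EA onset, duration the
#' EA event's own length.
#'
#' @param stim an `event_table` of stimulation events.
#' @param ea an `event_table` of EA events.
#' @param racine_score integer score(s) in 0..5 (0 = no EA), recycled.
#' @return data frame of class `ea_episode` with `stim_onset`, `ea_onset`,
#'   `ea_offset`, `delay`, `duration`, `racine_score`.
#' @export
characterize_ea <- function(stim, ea, racine_score = NA_integer_) {
  stopifnot(inherits(stim, "event_table"), inherits(ea, "event_table"))
  score <- rep_len(as.integer(racine_score), nrow(ea))
  rows <- lapply(seq_len(nrow(ea)), function(i) {
    on <- ea$onset[i]
    prior <- stim$onset[stim$onset <= on + 1e-9]
    if (!length(prior))
      stop("unprovoked EA has no stimulus: EA at ", on, " s")
    s0 <- max(prior)
    data.frame(stim_onset = s0, ea_onset = on,
               ea_offset = on + ea$duration[i],
               delay = on - s0, duration = ea$duration[i],
               racine_score = score[i])
  })
  d <- do.call(rbind, rows)
  class(d) <- c("ea_episode", "data.frame")
  d
}

#' Modified Racine scale lookup
#'
#' The fixed 5-level behavioral/EEG rubric used to score induced seizures.
#'
#' @param score integer in 1..5.
#' @return one-row data frame with `score`, `behavior`, `eeg`.
#' @export
racine_label <- function(score) {
  tab <- racine_table()
  if (!(length(score) == 1L && score %in% 1:5))
    stop("no EA / out of scale: Racine score must be in 1..5, got ", score)
  tab[tab$score == score, , drop = FALSE]
}

#' @rdname racine_label
#' @export
racine_table <- function() {
  data.frame(
    score = 1:5,
    behavior = c(
      "Sudden behavioral arrest, motionless staring with orofacial automatism (mouth and facial movements)",
      "Head nodding with severe facial clonus",
      "Unilateral or bilateral forelimb clonus without rearing",
      "Bilateral forelimb clonus with rearing",
      "Wild running, jumping, vocalization and severe clonus"),
    eeg = c(
      "Single High amplitude activity/slow waves",
      "Spikes, sharp waves",
      "Spikes or poly spikes, sharp waves",
      "Spike bursts/spike and wave discharges",
      "Spike bursts/spike and wave discharges"),
    stringsAsFactors = FALSE)
}

#' Build a periodic optogenetic pulse-train protocol
#'
#' E.g. 40 Hz stimulation for 10 s with 0.013 s on / 0.012 s off gives 400
#' intervals of 0.025 s.
#'
#' @param frequency pulse frequency (Hz).
#' @param on_time,off_time pulse on/off times (s, > 0);
#'   `on_time + off_time` must equal `1/frequency` within 1e-9.
#' @param total_duration train length (s).
#' @return list of class `stim_protocol` with `n_intervals` and an
#'   `event_table` of on-pulses.
#' @export
build_pulse_train <- function(frequency, on_time, off_time, total_duration) {
  if (on_time <= 0 || off_time <= 0) stop("on_time and off_time must be > 0")
  if (abs(on_time + off_time - 1 / frequency) > 1e-9)
    stop("inconsistent period: on_time + off_time != 1/frequency")
  n <- round(total_duration * frequency)
  structure(list(frequency = frequency, on_time = on_time,
                 off_time = off_time, total_duration = total_duration,
                 n_intervals = n,
                 events = event_table(onset = (seq_len(n) - 1L) / frequency,
                                      duration = on_time,
                                      kind = "stim_blue")),
            class = "stim_protocol")
}

#' Suggest EA on/offset bounds from the ECoG signal
#'
#' Automated stand-in for visual EA scoring: the candidate onset is the
#' first supra-threshold peak after stimulation onset; the offset is the end
#' of the last supra-threshold run that is followed by at least `quiet_gap`
#' of sub-threshold signal. Supra-threshold runs separated by `>= quiet_gap`
#' start a new candidate window, so multiple bursts yield multiple windows.
#'
#' @param ts a `time_series` extending past `stim_onset`.
#' @param stim_onset stimulation onset (s).
#' @param threshold a [threshold_spec()] or bare absolute value.
#' @param quiet_gap minimum sub-threshold gap that terminates an EA (s).
#' @return data frame with one row per candidate window (`ea_onset`,
#'   `ea_offset`), or zero rows ("no EA") when nothing is supra-threshold.
#' @export
suggest_ea_bounds <- function(ts, stim_onset, threshold = threshold_spec(),
                              quiet_gap = 2) {
  stopifnot(inherits(ts, "time_series"))
  thr <- resolve_threshold(threshold)
  x <- ts$values
  above <- x > thr
  empty <- data.frame(ea_onset = numeric(0), ea_offset = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  on_t <- ts$t0 + (rs - 1L) / ts$fs
  off_t <- ts$t0 + re / ts$fs
  keep <- off_t > stim_onset
  on_t <- on_t[keep]; re <- re[keep]; rs <- rs[keep]; off_t <- off_t[keep]
  if (!length(on_t)) return(empty)
  ## group runs separated by < quiet_gap
  grp <- cumsum(c(1, (on_t[-1] - off_t[-length(off_t)]) >= quiet_gap))
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    ## onset = first supra-threshold *peak* (maximum of the first run)
    first_run <- which(sel)[1]
    seg <- x[rs[first_run]:re[first_run]]
    pk_t <- ts$t0 + (rs[first_run] + which.max(seg) - 2L) / ts$fs
    data.frame(ea_onset = pk_t, ea_offset = max(off_t[sel]))
  }))
  rownames(out) <- NULL
  out
}
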