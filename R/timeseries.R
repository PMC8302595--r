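#' Uniformly sampled single-channel signal
#'
#' Container for one uniformly sampled real-valued channel (an ECoG channel, a
#' single-cell voltage trace, or one calcium trace). Sample `k` (0-based) lies
#' at time `t0 + k/fs`; all downstream windows are half-open `[start, stop)`.
#'
#' @param values numeric vector of finite samples (at least one).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param label free-text channel label.
#' @param units free-text physical units of `values`.
#' @return An object of class `time_series` with fields `values`, `fs`, `t0`,
#'   `label`, `units`.
#' @examples
#' ts <- time_series(sin(2 * pi * 6 * (0:799) / 400), fs = 400)
#' ts_times(ts)[1:3]
#' @export
time_series <- function(values, fs, t0 = 0, label = "", units = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time_series needs at least one sample")
  if (!all(is.finite(values))) stop("time_series values must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(
    list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0),
         label = as.character(label), units = as.character(units)),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples @ %g Hz, t = [%g, %g) s %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs, x$t0, x$t0 + length(x$values) / x$fs,
              if (nzchar(x$units)) paste0("[", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a time_series
#' @param ts a `time_series`.
#' @return numeric vector of sample times (s).
#' @export
ts_times <- function(ts) ts$t0 + (seq_along(ts$values) - 1L) / ts$fs

#' Duration of a time_series in seconds
#' @param ts a `time_series`.
#' @export
ts_duration <- function(ts) length(ts$values) / ts$fs

#' Rectangular cells-by-samples calcium trace matrix
#'
#' All rows share one time base (`t0`, `fs`).
#'
#' @param values numeric matrix, one row per cell.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample (s).
#' @param cell_ids unique identifiers, one per row; defaults to
#'   `cell_1 ... cell_n`.
#' @return An object of class `multi_trace`.
#' @export
multi_trace <- function(values, fs, t0 = 0, cell_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("multi_trace values must all be finite")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values)) stop("one cell_id per row required")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  rownames(values) <- cell_ids
  structure(list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0),
                 cell_ids = cell_ids),
            class = "multi_trace")
}

#' @export
print.multi_trace <- function(x, ...) {
  cat(sprintf("<multi_trace> %d cells x %d samples @ %g Hz, t0 = %g s\n",
              nrow(x$values), ncol(x$values), x$fs, x$t0))
  invisible(x)
}

#' Extract one cell of a multi_trace as a time_series
#' @param mt a `multi_trace`.
#' @param cell a cell id (character) or row index.
#' @export
mt_cell <- function(mt, cell) {
  if (is.character(cell) && !(cell %in% mt$cell_ids))
    stop("unknown cell id: ", cell)
  time_series(mt$values[cell, ], fs = mt$fs, t0 = mt$t0,
              label = if (is.character(cell)) cell else mt$cell_ids[cell])
}

#' Event table (stimulations, EA episodes, peaks, spikes)
#'
#' A data frame with columns `onset` (s), `duration` (s, >= 0), `kind` and
#' `attrs` (free-form key=value string, JSON on disk). Rows are kept sorted by
#' onset.
#'
#' @param onset numeric onsets (s).
#' @param duration numeric durations (s, >= 0); recycled if length 1.
#' @param kind character event kind; one of `stim_blue`, `stim_orange`, `ea`,
#'   `peak`, `spike`, `custom`.
#' @param attrs character vector of per-event attribute strings (may be `""`).
#' @return A `data.frame` of class `event_table`, sorted by onset.
#' @export
event_table <- function(onset = numeric(), duration = 0, kind = "custom",
                        attrs = "") {
  n <- length(onset)
  duration <- rep_len(as.numeric(duration), n)
  kind <- rep_len(as.character(kind), n)
  attrs <- rep_len(as.character(attrs), n)
  if (any(duration < 0)) stop("event durations must be >= 0")
  ok <- c("stim_blue", "stim_orange", "ea", "peak", "spike", "custom")
  if (n && !all(kind %in% ok))
    stop("unknown event kind; allowed: ", paste(ok, collapse = ", "))
  d <- data.frame(onset = as.numeric(onset), duration = duration,
                  kind = kind, attrs = attrs, stringsAsFactors = FALSE)
  d <- d[order(d$onset), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("event_table", "data.frame")
  d
}

#' Half-open segment of a time_series
#'
#' Selects samples with `start <= t < stop` (clipped to the recording).
#' The returned `t0` is the time of the first included sample, so
#' `segment(segment(ts, a, b), a, b)` is idempotent and adjacent segments
#' `[a,b)`, `[b,c)` tile `[a,c)` without overlap.
#'
#' @param ts a `time_series`.
#' @param start,stop window bounds in seconds, `start < stop`.
#' @return a `time_series`; error if the selection is empty.
#' @export
segment <- function(ts, start, stop) {
  stopifnot(inherits(ts, "time_series"))
  if (!(start < stop)) stop("segment requires start < stop")
  n <- length(ts$values)
  ## first sample index k (0-based) with t0 + k/fs >= start
  k0 <- ceiling((start - ts$t0) * ts$fs - 1e-9)
  k0 <- max(k0, 0)
  ## last included: t0 + k/fs < stop
  k1 <- ceiling((stop - ts$t0) * ts$fs - 1e-9) - 1
  k1 <- min(k1, n - 1)
  if (k0 > k1) stop("empty selection: [", start, ", ", stop,
                    ") contains no samples")
  time_series(ts$values[(k0 + 1L):(k1 + 1L)], fs = ts$fs,
              t0 = ts$t0 + k0 / ts$fs, label = ts$label, units = ts$units)
}

#' Read a delimited trace table
#'
#' CSV with a header row; optionally a first column `time_s` (any monotone
#' uniformly spaced time column works), remaining columns one signal each.
#' The sampling rate is inferred from the median time step (relative
#' tolerance 1e-6; larger jitter is an error) or supplied via `fs_override`.
#'
#' @param path CSV file path.
#' @param time_column_present logical; if `NULL` (default) auto-detected from a
#'   first column named `time_s`.
#' @param fs_override sampling rate in Hz when no time column exists.
#' @return `time_series` (one signal column) or `multi_trace` (several); with
#'   a time column, `t0` is its first entry, otherwise 0.
#' @export
read_trace_table <- function(path, time_column_present = NULL,
                             fs_override = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (nrow(d) == 0L) stop("empty trace table: ", path)
  if (is.null(time_column_present))
    time_column_present <- identical(names(d)[1], "time_s")
  if (time_column_present) {
    tv <- as.numeric(d[[1]])
    steps <- diff(tv)
    if (any(steps <= 0)) stop("time column must be strictly increasing")
    med <- stats::median(steps)
    if (max(abs(steps - med)) > 1e-6 * med)
      stop("non-uniform sampling: time steps deviate beyond 1e-6 relative")
    fs <- 1 / med
    t0 <- tv[1]
    d <- d[, -1, drop = FALSE]
  } else {
    if (is.null(fs_override))
      stop("fs_override required when no time column is present")
    fs <- fs_override
    t0 <- 0
  }
  m <- as.matrix(d)
  if (anyNA(m)) stop("NaN/NA samples are rejected, not imputed")
  if (ncol(m) == 1L)
    time_series(m[, 1], fs = fs, t0 = t0, label = colnames(m)[1])
  else
    multi_trace(t(m), fs = fs, t0 = t0, cell_ids = colnames(m))
}

#' Write a trace table
#'
#' Inverse of [read_trace_table()]: writes a CSV with a `time_s` column
#' followed by one column per signal.
#'
#' @param x a `time_series` or `multi_trace`.
#' @param path output CSV path.
#' @export
write_trace_table <- function(x, path) {
  if (inherits(x, "time_series")) {
    d <- data.frame(time_s = ts_times(x), signal = x$values)
    names(d)[2] <- if (nzchar(x$label)) x$label else "signal"
  } else if (inherits(x, "multi_trace")) {
    tv <- x$t0 + (seq_len(ncol(x$values)) - 1L) / x$fs
    d <- data.frame(time_s = tv, t(x$values), check.names = FALSE)
  } else stop("x must be a time_series or multi_trace")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write event tables
#'
#' CSV with header `onset,duration,kind,attrs`. Round trips are lossless;
#' rows are re-sorted by onset on read; negative durations are rejected.
#'
#' @param path CSV path.
#' @return [read_events()] returns an `event_table`.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, colClasses = c("numeric", "numeric",
                                            "character", "character"))
  if (!identical(names(d), c("onset", "duration", "kind", "attrs")))
    stop("event CSV must have header onset,duration,kind,attrs")
  if (anyNA(d$onset) || anyNA(d$duration)) stop("unparseable event row")
  event_table(d$onset, d$duration, d$kind, d$attrs)
}

#' @rdname read_events
#' @param ev an `event_table`.
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "event_table"))
  utils::write.csv(as.data.frame(ev), path, row.names = FALSE)
  invisible(path)
}
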