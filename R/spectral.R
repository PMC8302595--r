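## ECoG band power (Blackman-windowed FFT) and complex Morlet wavelet
## time-frequency analysis.

#' Frequency band definitions
#'
#' Half-open bands `[f_lo, f_hi)`; the defaults are the standard ECoG theta
#' (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz) bands. Half-open intervals
#' make adjacent bands a partition (no double counting at 8 and 13 Hz).
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @return A one-row data frame; combine with `rbind`.
#' @export
band_def <- function(name, f_lo, f_hi) {
  if (!(f_lo >= 0 && f_lo < f_hi)) stop("need 0 <= f_lo < f_hi")
  data.frame(name = name, f_lo = f_lo, f_hi = f_hi,
             stringsAsFactors = FALSE)
}

#' @rdname band_def
#' @export
default_bands <- function() {
  rbind(band_def("theta", 4, 8),
        band_def("alpha", 8, 13),
        band_def("beta", 13, 30))
}

#' Window layout for short-time band power
#'
#' `n_windows` Blackman-tapered windows of `window_len_samples` samples with
#' fractional overlap `overlap_fraction`. The hop is
#' `round(window_len * (1 - overlap))`; the default layout (10 windows of
#' 512 samples, 50% overlap) spans (512 + 9 * 256) / fs, i.e. 7.04 s at
#' 400 Hz.
#'
#' @param n_windows number of windows (default 10).
#' @param window_len_samples samples per window (default 512, >= 8).
#' @param overlap_fraction overlap in `[0, 1)` (default 0.5).
#' @return list of class `window_spec` with the parameters.
#' @export
window_spec <- function(n_windows = 10, window_len_samples = 512,
                        overlap_fraction = 0.5) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (window_len_samples < 8) stop("window_len_samples must be >= 8")
  structure(list(n_windows = as.integer(n_windows),
                 window_len_samples = as.integer(window_len_samples),
                 overlap_fraction = overlap_fraction),
            class = "window_spec")
}

#' @rdname window_spec
#' @param spec a `window_spec`.
#' @param fs sampling rate (Hz).
#' @return `window_layout()` returns a list with 0-based `starts` (sample
#'   indices) and `total_duration` (s).
#' @export
window_layout <- function(spec = window_spec(), fs) {
  stopifnot(inherits(spec, "window_spec"), fs > 0)
  hop <- round(spec$window_len_samples * (1 - spec$overlap_fraction))
  starts <- (seq_len(spec$n_windows) - 1L) * hop
  total <- (spec$window_len_samples + (spec$n_windows - 1L) * hop) / fs
  list(starts = starts, hop = hop, total_duration = total)
}

## One-sided periodogram of a single mean-removed, Blackman-tapered window.
## Power-spectrum scaling: P = s * |FFT|^2 / (N * sum(w^2)) with s = 2 for
## interior bins, 1 for DC/Nyquist, so that sum(P) equals the tapered
## window's taper-normalized mean square (Parseval) and a unit-amplitude
## sinusoid totals ~0.5 regardless of taper.
periodogram_window <- function(x, w) {
  n <- length(x)
  xt <- (x - mean(x)) * w
  X <- stats::fft(xt)
  nf <- n %/% 2 + 1L
  sc <- rep(2, nf); sc[1] <- 1; if (n %% 2 == 0) sc[nf] <- 1
  list(freq_per_sample = (seq_len(nf) - 1L) / n,
       power = Mod(X[seq_len(nf)])^2 * sc / (n * sum(w^2)))
}

#' Absolute band power of an ECoG segment
#'
#' Per window: mean removal, Blackman taper, one-sided periodogram with
#' taper-power normalization; band power is the sum of periodogram bins with
#' `f_lo <= f < f_hi`, averaged over the windows. Windows are anchored at
#' the start of the segment; samples past the layout are ignored.
#'
#' @param ts a `time_series`, at least as long as the window layout.
#' @param bands a band data frame ([default_bands()] style).
#' @param spec a [window_spec()].
#' @return data frame of class `band_power_result` with columns `name`,
#'   `f_lo`, `f_hi`, `absolute_power`.
#' @export
band_power <- function(ts, bands = default_bands(), spec = window_spec()) {
  stopifnot(inherits(ts, "time_series"))
  lay <- window_layout(spec, ts$fs)
  need <- spec$window_len_samples + (spec$n_windows - 1L) * lay$hop
  if (length(ts$values) < need)
    stop("signal too short for the window layout: need ", need,
         " samples, have ", length(ts$values))
  if (any(bands$f_hi > ts$fs / 2 + 1e-9))
    stop("band above Nyquist (", ts$fs / 2, " Hz)")
  w <- as.numeric(signal::blackman(spec$window_len_samples))
  acc <- NULL
  for (s in lay$starts) {
    pg <- periodogram_window(
      ts$values[(s + 1L):(s + spec$window_len_samples)], w)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
  }
  P <- acc / spec$n_windows
  f <- pg$freq_per_sample * ts$fs
  res <- bands
  res$absolute_power <- vapply(seq_len(nrow(bands)), function(i)
    sum(P[f >= bands$f_lo[i] - 1e-9 & f < bands$f_hi[i] - 1e-9]), 0)
  class(res) <- c("band_power_result", "data.frame")
  res
}

#' Band power normalized to a baseline segment
#'
#' @param stim_ts,baseline_ts `time_series` segments (stimulation epoch and
#'   pre-stimulus baseline), each long enough for the window layout.
#' @inheritParams band_power
#' @return data frame with `absolute_power` (stimulation),
#'   `baseline_power` and `normalized_power` (their ratio) per band.
#' @export
normalized_band_power <- function(stim_ts, baseline_ts,
                                  bands = default_bands(),
                                  spec = window_spec()) {
  stim <- band_power(stim_ts, bands, spec)
  base <- band_power(baseline_ts, bands, spec)
  if (any(base$absolute_power <= 0))
    stop("baseline band power is zero; normalized power undefined")
  stim$baseline_power <- base$absolute_power
  stim$normalized_power <- stim$absolute_power / stim$baseline_power
  stim
}

#' Complex Morlet wavelet power
#'
#' Convolves the signal with the complex Morlet wavelet
#' `psi(t) = (pi * fb)^(-1/2) * exp(2i * pi * fc * t) * exp(-t^2 / fb)`
#' (the Matlab `cmor` convention) and returns `|coefficient|^2` per sample.
#' The wavelet is truncated at `|t| <= 5 * sqrt(fb / 2)`; the signal is
#' mean-padded at the edges and samples within half the truncated support of
#' either edge are flagged unreliable.
#'
#' @param ts a `time_series` longer than the truncated wavelet support.
#' @param fc central frequency (Hz, default 4 - the theta-band tracker).
#' @param fb bandwidth parameter (default 0.5).
#' @return list of class `wavelet_power`: `times` (s), `power`, `edge`
#'   (logical, TRUE where within half the wavelet support of an edge),
#'   `fc`, `fb`, `fs`.
#' @export
morlet_power <- function(ts, fc = 4, fb = 0.5) {
  stopifnot(inherits(ts, "time_series"))
  fs <- ts$fs
  L <- round(5 * sqrt(fb / 2) * fs)
  n <- length(ts$values)
  if (n <= 2L * L)
    stop("signal shorter than the truncated wavelet support")
  tw <- ((-L):L) / fs
  psi <- (pi * fb)^(-0.5) * exp(2i * pi * fc * tw) * exp(-tw^2 / fb)
  xp <- c(rep(mean(ts$values), L), ts$values, rep(mean(ts$values), L))
  m <- length(xp); K <- length(psi)
  nfft <- stats::nextn(m + K - 1L, 2)
  conv <- stats::fft(stats::fft(c(xp, rep(0, nfft - m))) *
                     stats::fft(c(psi, rep(0, nfft - K))),
                     inverse = TRUE) / nfft
  coef <- conv[K:(K + n - 1L)] / fs      # discretized convolution integral
  edge <- rep(FALSE, n)
  half <- ceiling(L / 2)
  edge[seq_len(min(half, n))] <- TRUE
  edge[seq.int(max(1L, n - half + 1L), n)] <- TRUE
  structure(list(times = ts_times(ts), power = Mod(coef)^2, edge = edge,
                 fc = fc, fb = fb, fs = fs),
            class = "wavelet_power")
}

#' Mean wavelet power over a half-open interval
#'
#' @param wp a [morlet_power()] result.
#' @param start,stop interval bounds (s), half-open `[start, stop)`.
#' @return arithmetic mean of the power samples in the interval.
#' @export
mean_power_in_interval <- function(wp, start, stop) {
  stopifnot(inherits(wp, "wavelet_power"))
  sel <- wp$times >= start - 1e-9 & wp$times < stop - 1e-9
  if (!any(sel)) stop("interval [", start, ", ", stop,
                      ") contains no power samples")
  mean(wp$power[sel])
}
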