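## Minimal plain EDF (16-bit) support for ECoG channels.
## One data record spanning the whole recording; EDF+ annotations are out of
## scope. Values round-trip within the format's 16-bit quantization of the
## declared physical range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

edf_num <- function(x, width = 8) {
  for (dg in 7:1) {
    s <- sprintf(paste0("%.", dg, "g"), x)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  edf_pad(substr(s, 1, width), width)
}

#' Write time series to a plain EDF file
#'
#' All channels must share the same total duration (sampling rates may
#' differ). The whole recording is stored as a single EDF data record; each
#' channel is quantized to 16 bits over its own physical range.
#'
#' @param channels a `time_series` or list of them; channel labels are taken
#'   from their `label` fields.
#' @param path output file path.
#' @param units physical dimension string written per channel (defaults to
#'   each channel's `units`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(channels, path, units = NULL) {
  if (inherits(channels, "time_series")) channels <- list(channels)
  ns <- length(channels)
  if (ns < 1L) stop("no channels to write")
  durs <- vapply(channels, ts_duration, 0)
  if (max(durs) - min(durs) > 1e-9)
    stop("all channels must have the same total duration")
  labels <- vapply(seq_len(ns), function(i) {
    l <- channels[[i]]$label
    if (nzchar(l)) l else paste0("ch", i)
  }, "")
  if (is.null(units)) units <- vapply(channels, function(ch) ch$units, "")
  units <- rep_len(units, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic fixture", 80),
    edf_pad("epiphase", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(1, 8), edf_num(durs[1], 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)

  rng <- lapply(channels, function(ch) {
    lo <- min(ch$values); hi <- max(ch$values)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    c(lo, hi)
  })
  field <- function(f, w) writeChar(paste0(vapply(seq_len(ns), f, ""),
                                           collapse = ""), con, eos = NULL)
  field(function(i) edf_pad(labels[i], 16), 16)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad(units[i], 8), 8)
  field(function(i) edf_num(rng[[i]][1], 8), 8)
  field(function(i) edf_num(rng[[i]][2], 8), 8)
  field(function(i) edf_pad(-32768, 8), 8)
  field(function(i) edf_pad(32767, 8), 8)
  field(function(i) edf_pad("", 80), 80)
  field(function(i) edf_pad(length(channels[[i]]$values), 8), 8)
  field(function(i) edf_pad("", 32), 32)

  for (i in seq_len(ns)) {
    ## header fields are re-parsed so quantization uses the stored range
    lo <- as.numeric(edf_num(rng[[i]][1], 8))
    hi <- as.numeric(edf_num(rng[[i]][2], 8))
    dig <- round((channels[[i]]$values - lo) / (hi - lo) * 65535 - 32768)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read one channel from a plain EDF file
#'
#' @param path EDF file path.
#' @param channel_label label of the channel to extract; an error listing the
#'   available channels is raised if absent.
#' @return a `time_series` with the EDF-declared sampling rate and `t0 = 0`.
#' @export
read_edf <- function(path, channel_label) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80); rd(8); rd(8)
  if (!identical(ver, "0")) stop("unreadable file: not plain EDF")
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)              # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)              # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  j <- match(channel_label, labels)
  if (is.na(j))
    stop("channel '", channel_label, "' not found; available: ",
         paste(labels, collapse = ", "))
  out <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (i == j) out <- c(out, v)
    }
  }
  phys <- pmin_[j] + (out + 32768) / 65535 * (pmax_[j] - pmin_[j])
  time_series(phys, fs = spr[j] / rec_dur, t0 = 0,
              label = labels[j], units = units[j])
}
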