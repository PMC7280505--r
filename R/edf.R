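# Minimal EDF (European Data Format, 16-bit) reader/writer for single- or
# few-channel physiological time series. Covers the plain EDF subset this
# pipeline needs: no annotations, one fixed record duration, integer samples
# per record.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write uniform series to an EDF file
#'
#' 16-bit EDF with one data record per second; every channel must therefore
#' have an integer sampling rate. Physical range is taken from the data.
#'
#' @param path output path.
#' @param channels named list of [uniform_series()]; names become labels.
#' @param phys_dim physical dimension label(s), recycled over channels.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, channels, phys_dim = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  rates <- vapply(channels, function(s) s$rate, numeric(1))
  if (any(abs(rates - round(rates)) > 1e-9))
    stop("EDF writer requires integer sampling rates", call. = FALSE)
  ns <- length(channels)
  if (is.null(phys_dim))
    phys_dim <- vapply(channels, function(s) s$units, character(1))
  phys_dim <- rep_len(phys_dim, ns)
  n_sec <- min(vapply(channels, function(s)
    length(s$values) %/% s$rate, numeric(1)))
  if (n_sec < 1) stop("need at least one full second of data", call. = FALSE)

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- channels[[i]]$values[seq_len(n_sec * rates[i])]
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- as.integer(round((v - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad("X", 80), edf_pad("Startdate X", 80),
                edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
                edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
                edf_pad(n_sec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  field <- function(vals, width)
    paste(vapply(vals, edf_pad, character(1), width = width), collapse = "")
  hdr <- paste0(hdr,
                field(names(channels), 16), field(rep("", ns), 80),
                field(phys_dim, 8),
                field(sprintf("%.6g", pmin_), 8),
                field(sprintf("%.6g", pmax_), 8),
                field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
                field(rep("", ns), 80), field(round(rates), 8),
                field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  for (rec in seq_len(n_sec)) {
    for (i in seq_len(ns)) {
      idx <- ((rec - 1) * rates[i] + 1):(rec * rates[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read channels (or a two-channel derivation) from an EDF file
#'
#' @param path EDF path.
#' @param channel a channel label, or two labels `c("C3", "C4")` to return
#'   their difference (a cross-cerebral derivation).
#' @param units unit label for the returned series (defaults to the file's
#'   physical dimension of the first requested channel).
#' @return A [uniform_series()].
#' @export
read_edf <- function(path, channel, units = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))

  want <- match(channel, labels)
  if (anyNA(want))
    stop(sprintf("channel(s) not found: %s",
                 paste(channel[is.na(want)], collapse = ", ")), call. = FALSE)
  if (length(want) > 1 && length(unique(spr[want])) != 1)
    stop("derivation channels must share a sampling rate", call. = FALSE)

  raw <- lapply(want, function(i) numeric(n_rec * spr[i]))
  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      k <- match(i, want)
      if (!is.na(k))
        raw[[k]][((rec - 1) * spr[i] + 1):(rec * spr[i])] <-
          pmin_[i] + (v - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    }
  }
  vals <- if (length(raw) == 2) raw[[1]] - raw[[2]] else raw[[1]]
  if (is.null(units)) units <- dims[want[1]]
  uniform_series(vals, rate = spr[want[1]] / rec_dur, units = units)
}
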