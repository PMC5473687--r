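#' Photon stream (T3 mode)
#'
#' In-memory representation of a time-tagged photon record stream:
#' per-record detector channel, TCSPC time within the period in raw ticks
#' (`dtime`), and the (overflow-unrolled) excitation sync counter.
#'
#' @param channel integer vector (0-14; 15 is reserved for
#'   overflow/markers on disk).
#' @param dtime integer ticks within the period (0-4095).
#' @param nsync absolute sync counts, non-decreasing.
#' @param resolution_ns TCSPC resolution (ns per tick).
#' @param sync_rate_hz excitation sync rate (Hz).
#' @param markers optional data.frame(`nsync`, `bits`) of marker records.
#' @return an object of class `photon_stream`.
#' @export
photon_stream <- function(channel, dtime, nsync, resolution_ns,
                          sync_rate_hz, markers = NULL) {
  stopifnot(length(channel) == length(dtime),
            length(dtime) == length(nsync))
  if (length(nsync) > 1 && any(diff(nsync) < 0))
    stop("nsync must be non-decreasing")
  if (any(channel < 0 | channel > 14))
    stop("channel must be in 0..14")
  if (any(dtime < 0 | dtime > 4095))
    stop("dtime must fit in 12 bits (0..4095)")
  structure(list(
    records = data.frame(channel = as.integer(channel),
                         dtime = as.integer(dtime),
                         nsync = as.numeric(nsync)),
    resolution_ns = as.numeric(resolution_ns),
    sync_rate_hz = as.numeric(sync_rate_hz),
    markers = markers %||% data.frame(nsync = numeric(), bits = integer())),
    class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf(
    "<photon_stream> %d photons, %d markers, %.4g ns/tick, sync %.4g Hz\n",
    nrow(x$records), nrow(x$markers), x$resolution_ns, x$sync_rate_hz))
  invisible(x)
}

#' Photon arrival times of a stream
#'
#' @param stream a [photon_stream()].
#' @return numeric vector of arrival times within the period (ns),
#'   `dtime * resolution`.
#' @export
photon_times_ns <- function(stream) {
  stream$records$dtime * stream$resolution_ns
}

PT3_IDENT <- "PicoHarp 300"
PT3_VERSION <- "2.0"

#' Write a photon stream as a PT3 (T3 mode) file
#'
#' Minimal PicoHarp-300 T3 layout: a fixed header (identifier, format
#' version, TCSPC resolution, sync rate, record count) followed by 32-bit
#' records packing 4-bit channel, 12-bit dtime and 16-bit sync count.
#' Overflow records (channel 15, dtime 0) are inserted whenever the sync
#' counter crosses a 65,536 boundary; markers are channel-15 records with
#' non-zero dtime bits.
#'
#' @param stream a [photon_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pt3 <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  rec <- stream$records
  mk <- stream$markers
  ev <- rbind(
    data.frame(nsync = rec$nsync, channel = rec$channel, dtime = rec$dtime),
    if (nrow(mk)) data.frame(nsync = mk$nsync, channel = 15L,
                             dtime = as.integer(mk$bits)))
  ev <- ev[order(ev$nsync), , drop = FALSE]
  words <- numeric(0)
  ovf <- 0
  for (i in seq_len(nrow(ev))) {
    while (ev$nsync[i] - ovf >= 65536) {
      words <- c(words, pack_t3(15L, 0L, 0L))  # overflow record
      ovf <- ovf + 65536
    }
    words <- c(words, pack_t3(ev$channel[i], ev$dtime[i], ev$nsync[i] - ovf))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad_raw(PT3_IDENT, 16L), con)
  writeBin(pad_raw(PT3_VERSION, 6L), con)
  writeBin(stream$resolution_ns, con, size = 4, endian = "little")
  writeBin(as.integer(stream$sync_rate_hz), con, size = 4, endian = "little")
  writeBin(length(words), con, size = 4, endian = "little")
  writeBin(as.integer(ifelse(words >= 2^31, words - 2^32, words)),
           con, size = 4, endian = "little")
  invisible(path)
}

#' Read a PT3 (T3 mode) file
#'
#' Parses the header and 32-bit T3 records, unrolling channel-15 overflow
#' records (each adds 65,536 to the sync counter) and exposing channel-15
#' marker records separately.
#'
#' @param path file path.
#' @return a [photon_stream()].
#' @export
read_pt3 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ident <- raw_string(readBin(con, raw(), 16))
  if (!identical(ident, PT3_IDENT))
    stop("not a PT3 file (identifier: ", ident, ")")
  ver <- raw_string(readBin(con, raw(), 6))
  if (!identical(ver, PT3_VERSION))
    stop("unknown PT3 format version: ", ver)
  res <- readBin(con, numeric(), 1, size = 4, endian = "little")
  sync <- readBin(con, integer(), 1, size = 4, endian = "little")
  nrec <- readBin(con, integer(), 1, size = 4, endian = "little")
  raw <- readBin(con, integer(), nrec, size = 4, endian = "little")
  if (length(raw) < nrec)
    stop("truncated PT3 stream at byte offset ",
         34 + 4 * length(raw), ": expected ", nrec, " records, got ",
         length(raw))
  u <- ifelse(raw < 0, raw + 2^32, as.numeric(raw))
  channel <- u %/% 2^28
  dtime <- (u %/% 2^16) %% 4096
  ns16 <- u %% 65536
  special <- channel == 15
  is_ovf <- special & dtime == 0
  # overflow applies to subsequent records; photons/markers never add to it,
  # so the running total at a photon equals the overflow accumulated before it
  ovf <- cumsum(ifelse(is_ovf, 65536, 0))
  nsync_abs <- ns16 + ovf
  ph <- !special
  mk <- special & !is_ovf
  photon_stream(channel[ph], dtime[ph], nsync_abs[ph],
                resolution_ns = res, sync_rate_hz = sync,
                markers = data.frame(nsync = nsync_abs[mk],
                                     bits = as.integer(dtime[mk])))
}

pack_t3 <- function(channel, dtime, nsync) {
  if (dtime < 0 || dtime > 4095)
    stop("dtime ", dtime, " not representable in 12 bits")
  if (nsync < 0 || nsync > 65535)
    stop("nsync residual out of 16-bit range")
  channel * 2^28 + dtime * 2^16 + nsync
}

pad_raw <- function(s, n) {
  b <- charToRaw(s)
  c(b, raw(n - length(b)))
}

raw_string <- function(b) {
  z <- which(b == as.raw(0))
  rawToChar(if (length(z)) b[seq_len(min(z) - 1L)] else b)
}
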