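#' @title Core data model and interchange formats
#' @description Recordings travel as HDF5 (one 16-bit integer dataset per
#' channel plus a uV-per-LSB scale factor, sampling rate and phase
#' boundaries as root attributes); spike trains and burst tables travel as
#' plain CSV. All times are seconds, indices are 0-based in file headers,
#' and intervals are half-open `[start, end)`.
#' @name io
NULL

#' Construct a recording
#'
#' @param data Numeric matrix, samples x channels, in uV.
#' @param sampling_rate Sampling rate, Hz.
#' @param phase_boundaries Length-2 numeric: seconds at which baseline ends
#'   and exposure ends; must be strictly increasing and inside the record.
#' @param channel_ids Optional channel identifiers.
#' @return Object of class `mea_recording`.
#' @export
new_recording <- function(data, sampling_rate, phase_boundaries,
                          channel_ids = seq_len(ncol(data))) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), sampling_rate > 0)
  if (length(phase_boundaries) != 2 || diff(phase_boundaries) <= 0 ||
      phase_boundaries[1] <= 0 ||
      phase_boundaries[2] >= nrow(data) / sampling_rate + 1e-9)
    stop("phase boundaries must be strictly increasing and inside the record",
         call. = FALSE)
  structure(list(data = data, sampling_rate = sampling_rate,
                 phase_boundaries = as.numeric(phase_boundaries),
                 channel_ids = channel_ids),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %.1f s @ %g Hz (phases at %g s, %g s)\n",
              ncol(x$data), nrow(x$data) / x$sampling_rate, x$sampling_rate,
              x$phase_boundaries[1], x$phase_boundaries[2]))
  invisible(x)
}

#' Write / read a recording as HDF5
#'
#' Layout: one dataset `/channel_<k>` of 16-bit integers per channel
#' (0-based `k`), root attributes `sampling_rate` (Hz), `phase_boundaries`
#' (seconds), `scale_uv_per_lsb` (uV per integer step) and `channel_ids`.
#' A write-then-read round trip reproduces voltages within one quantization
#' step and metadata exactly.
#'
#' @param recording An `mea_recording`.
#' @param path Output file path (overwritten if present).
#' @param scale_uv_per_lsb uV per least-significant bit; by default chosen
#'   from the data range to use the full int16 span.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `mea_recording`.
#' @export
write_recording <- function(recording, path, scale_uv_per_lsb = NULL) {
  stopifnot(inherits(recording, "mea_recording"))
  if (is.null(scale_uv_per_lsb)) {
    m <- max(abs(range(recording$data)), 1e-12)
    scale_uv_per_lsb <- m / 32000
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (j in seq_len(ncol(recording$data))) {
    name <- sprintf("channel_%d", j - 1L)
    q <- as.integer(pmin(pmax(round(recording$data[, j] / scale_uv_per_lsb),
                              -32768), 32767))
    rhdf5::h5createDataset(fid, name, dims = length(q),
                           H5type = "H5T_STD_I16LE", chunk = min(length(q), 65536))
    rhdf5::h5write(q, fid, name)
  }
  root <- rhdf5::H5Gopen(fid, "/")
  rhdf5::h5writeAttribute(recording$sampling_rate, root, "sampling_rate")
  rhdf5::h5writeAttribute(recording$phase_boundaries, root, "phase_boundaries")
  rhdf5::h5writeAttribute(scale_uv_per_lsb, root, "scale_uv_per_lsb")
  rhdf5::h5writeAttribute(as.integer(recording$channel_ids), root, "channel_ids")
  rhdf5::H5Gclose(root)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  for (key in c("sampling_rate", "phase_boundaries", "scale_uv_per_lsb"))
    if (is.null(at[[key]]))
      stop(sprintf("format error: missing root attribute '%s'", key),
           call. = FALSE)
  ls <- rhdf5::h5ls(path)
  dsets <- ls$name[grepl("^channel_", ls$name)]
  dsets <- dsets[order(as.integer(sub("channel_", "", dsets)))]
  if (!length(dsets)) stop("format error: no channel datasets", call. = FALSE)
  scale <- as.numeric(at$scale_uv_per_lsb)
  cols <- lapply(dsets, function(d)
    as.numeric(rhdf5::h5read(path, d)) * scale)
  ids <- if (!is.null(at$channel_ids)) as.vector(at$channel_ids)
         else seq_along(dsets)
  new_recording(do.call(cbind, cols),
                sampling_rate = as.numeric(at$sampling_rate),
                phase_boundaries = as.numeric(at$phase_boundaries),
                channel_ids = ids)
}

#' Construct a spike train set
#'
#' @param times List of per-channel numeric vectors of spike times in
#'   seconds; each must be strictly increasing.
#' @param n_channels Number of channels (defaults to `length(times)`).
#' @param protocol Optional [mea_protocol()].
#' @return Object of class `mea_spiketrains`.
#' @export
mea_spiketrains <- function(times, n_channels = length(times), protocol = NULL) {
  for (ch in seq_along(times)) {
    tt <- times[[ch]]
    if (length(tt) > 1 && any(diff(tt) <= 0))
      stop(sprintf("validation error: spike times not strictly increasing on channel %d", ch),
           call. = FALSE)
  }
  if (length(times) < n_channels)
    times <- c(times, rep(list(numeric(0)), n_channels - length(times)))
  structure(list(times = times, n_channels = as.integer(n_channels),
                 protocol = protocol),
            class = "mea_spiketrains")
}

#' Write / read spike trains as CSV
#'
#' CSV dialect: comma separator, `.` decimal, UTF-8, header row with
#' columns `channel` (0-based), `time_s`. Times round-trip to at least
#' 0.1 ms precision.
#'
#' @param trains An `mea_spiketrains`.
#' @param path File path.
#' @return `write_spike_csv` returns `path` invisibly; `read_spike_csv`
#'   returns an `mea_spiketrains`.
#' @export
write_spike_csv <- function(trains, path) {
  stopifnot(inherits(trains, "mea_spiketrains"))
  n <- vapply(trains$times, length, integer(1))
  df <- data.frame(channel = rep(seq_along(trains$times) - 1L, n),
                   time_s = unlist(trains$times))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, colClasses = list(numeric = "time_s"))
  if (!all(c("channel", "time_s") %in% names(df)))
    stop("format error: expected columns 'channel', 'time_s'", call. = FALSE)
  if (nrow(df) == 0) return(mea_spiketrains(list(), n_channels = 0L))
  nch <- max(df$channel) + 1L
  times <- lapply(seq_len(nch) - 1L, function(ch)
    as.numeric(df$time_s[df$channel == ch]))
  for (ch in seq_along(times))
    if (anyDuplicated(times[[ch]]))
      stop(sprintf("validation error: duplicate spike time on channel %d", ch - 1L),
           call. = FALSE)
  mea_spiketrains(times, n_channels = nch)
}

#' Write / read a burst table as CSV
#'
#' Columns: `channel` (0-based), `start_s`, `end_s`, `n_spikes`,
#' `network_flag`.
#'
#' @param bursts An `mea_bursts` data.frame (columns `channel`, `start`,
#'   `end`, `n_spikes`, `network`).
#' @param path File path.
#' @return `write_burst_csv` returns `path` invisibly; `read_burst_csv`
#'   returns an `mea_bursts` data.frame.
#' @export
write_burst_csv <- function(bursts, path) {
  df <- data.frame(channel = bursts$channel - 1L,
                   start_s = bursts$start, end_s = bursts$end,
                   n_spikes = bursts$n_spikes,
                   network_flag = as.integer(bursts$network))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_burst_csv
#' @export
read_burst_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  out <- data.frame(channel = df$channel + 1L, start = df$start_s,
                    end = df$end_s, n_spikes = df$n_spikes,
                    network = as.logical(df$network_flag))
  class(out) <- c("mea_bursts", "data.frame")
  out
}
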