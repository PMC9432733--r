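#' Burst detection parameters
#'
#' Parameters of the logISI burst detector: the histogram of log inter-spike
#' intervals is searched for an intra-burst peak (below the cap) and a
#' subsequent slower peak; if the valley between them is deep enough (void
#' parameter), the valley ISI becomes the burst threshold, otherwise the cap
#' is used.
#'
#' @param isi_threshold_cap Maximum intra-burst ISI threshold, ms.
#' @param min_spikes_per_burst Minimum spikes per burst.
#' @param bins_per_decade Histogram bins per log10 decade.
#' @param void_parameter_min Minimum void parameter for accepting the
#'   inter-peak valley as the threshold.
#' @param network_burst_overlap_fraction Fraction of active channels that
#'   must burst near-simultaneously for a network-burst flag.
#' @param network_burst_window Coincidence window for network-burst
#'   labelling, ms.
#' @return Object of class `mea_burst_params`.
#' @export
burst_params <- function(isi_threshold_cap = 100,
                         min_spikes_per_burst = 5,
                         bins_per_decade = 10,
                         void_parameter_min = 0.7,
                         network_burst_overlap_fraction = 0.2,
                         network_burst_window = 100) {
  stopifnot(isi_threshold_cap > 0, min_spikes_per_burst >= 2,
            bins_per_decade >= 1)
  structure(list(isi_threshold_cap = isi_threshold_cap,
                 min_spikes_per_burst = min_spikes_per_burst,
                 bins_per_decade = bins_per_decade,
                 void_parameter_min = void_parameter_min,
                 network_burst_overlap_fraction = network_burst_overlap_fraction,
                 network_burst_window = network_burst_window),
            class = "mea_burst_params")
}

#' Histogram of log10 inter-spike intervals
#'
#' @param spike_times Sorted spike times, seconds.
#' @param params A [burst_params()].
#' @return List with `mids` (bin centres, log10 ms), `counts` (smoothed by
#'   a 3-bin moving average), `raw_counts`, `breaks`. Empty (`length 0`)
#'   when fewer than 2 spikes.
#' @export
logisi_histogram <- function(spike_times, params = burst_params()) {
  if (length(spike_times) < 2)
    return(list(mids = numeric(0), counts = numeric(0),
                raw_counts = numeric(0), breaks = numeric(0)))
  isi_ms <- diff(spike_times) * 1000
  isi_ms <- isi_ms[isi_ms > 0]
  if (!length(isi_ms))
    return(list(mids = numeric(0), counts = numeric(0),
                raw_counts = numeric(0), breaks = numeric(0)))
  l <- log10(isi_ms)
  step <- 1 / params$bins_per_decade
  breaks <- seq(floor(min(l) / step) * step - step / 2,
                ceiling(max(l) / step) * step + step, by = step)
  h <- hist(l, breaks = breaks, plot = FALSE)
  if (length(h$counts) >= 3) {
    counts <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
    counts[is.na(counts)] <- h$counts[is.na(counts)]  # edge bins unsmoothed
  } else counts <- as.numeric(h$counts)
  list(mids = h$mids, counts = counts, raw_counts = h$counts, breaks = breaks)
}

# indices of local maxima (strict rise, non-strict fall) of a positive series
.local_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- 2:(n - 1)
  idx[y[idx] > y[idx - 1] & y[idx] >= y[idx + 1] & y[idx] > 0]
}

#' logISI burst threshold
#'
#' Locates the intra-burst peak (below the cap) of the log-ISI histogram
#' and scans subsequent peaks; the first inter-peak valley whose void
#' parameter `1 - h_valley / sqrt(h_peak1 * h_peak2)` reaches
#' `void_parameter_min` gives the ISI threshold. With no qualifying pair
#' the threshold falls back to the cap.
#'
#' @param histogram Result of [logisi_histogram()].
#' @param params A [burst_params()].
#' @return ISI threshold in ms.
#' @export
logisi_threshold <- function(histogram, params = burst_params()) {
  cap <- params$isi_threshold_cap
  if (!length(histogram$counts)) return(cap)
  peaks <- .local_peaks(histogram$counts)
  below <- peaks[histogram$mids[peaks] < log10(cap)]
  if (!length(below)) return(cap)
  p1 <- below[which.max(histogram$counts[below])]
  later <- peaks[peaks > p1]
  for (p2 in later) {
    seg <- (p1 + 1):(p2 - 1)
    if (!length(seg)) next
    vi <- seg[which.min(histogram$counts[seg])]
    void <- 1 - histogram$counts[vi] /
      sqrt(histogram$counts[p1] * histogram$counts[p2])
    if (is.finite(void) && void >= params$void_parameter_min)
      return(min(10^histogram$mids[vi], cap))  # valley ISI, capped, ms
  }
  cap
}

#' Detect bursts in one spike train
#'
#' Maximal runs of consecutive ISIs at or below the threshold containing at
#' least `min_spikes_per_burst` spikes become bursts; burst start/end are
#' the first/last spike times of the run.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param threshold_ms ISI threshold, ms (> 0).
#' @param params A [burst_params()].
#' @return data.frame with `start`, `end`, `n_spikes` (possibly 0 rows).
#' @export
detect_bursts <- function(spike_times, threshold_ms,
                          params = burst_params()) {
  stopifnot(threshold_ms > 0)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (length(spike_times) < params$min_spikes_per_burst) return(empty)
  small <- diff(spike_times) <= threshold_ms / 1000
  r <- rle(small)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run <- which(r$values & r$lengths + 1L >= params$min_spikes_per_burst)
  if (!length(run)) return(empty)
  data.frame(start = spike_times[starts[run]],
             end = spike_times[ends[run] + 1L],
             n_spikes = r$lengths[run] + 1L)
}

#' Detect bursts on all channels
#'
#' Per channel: build the log-ISI histogram over the whole record, derive
#' the channel's ISI threshold, and extract bursts.
#'
#' @param trains An `mea_spiketrains`.
#' @param params A [burst_params()].
#' @return `mea_bursts` data.frame: `channel`, `start`, `end`, `n_spikes`,
#'   `network` (NA until [label_network_bursts()] is applied).
#' @export
detect_bursts_all <- function(trains, params = burst_params()) {
  out <- lapply(seq_len(trains$n_channels), function(ch) {
    st <- trains$times[[ch]]
    thr <- logisi_threshold(logisi_histogram(st, params), params)
    b <- detect_bursts(st, thr, params)
    if (nrow(b)) cbind(channel = ch, b, network = NA) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(channel = integer(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0),
                      network = logical(0))
  class(out) <- c("mea_bursts", "data.frame")
  out
}

#' Label network bursts
#'
#' Flags bursts whose start times coincide (within the network-burst
#' window) across at least `network_burst_overlap_fraction` of the active
#' channels.
#'
#' @param bursts An `mea_bursts` data.frame.
#' @param active_channels Channels considered active (default: all channels
#'   present in `bursts`).
#' @param params A [burst_params()].
#' @return The burst table with the `network` flag filled in.
#' @export
label_network_bursts <- function(bursts, active_channels = NULL,
                                 params = burst_params()) {
  if (is.null(active_channels)) active_channels <- unique(bursts$channel)
  need <- max(2, ceiling(params$network_burst_overlap_fraction *
                           length(active_channels)))
  w <- params$network_burst_window / 1000
  o <- order(bursts$start)
  st <- bursts$start[o]; ch <- bursts$channel[o]
  n <- length(st)
  flag <- logical(n)
  lo <- findInterval(st - w, st) + 1L
  hi <- findInterval(st + w, st)
  for (i in seq_len(n)) {
    if (hi[i] - lo[i] + 1L < need) next
    flag[i] <- length(unique(ch[lo[i]:hi[i]])) >= need
  }
  bursts$network[o] <- flag
  bursts
}
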