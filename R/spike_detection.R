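#' Spike detection parameters
#'
#' Parameters for signal conditioning and the differential-threshold
#' precision timing spike detection (PTSD) stage, and for the separate
#' waveform path (5 x noise-sd amplitude threshold, 40-sample snippets).
#'
#' @param highpass_cutoff High-pass cutoff, Hz (4th-order Butterworth,
#'   zero-phase).
#' @param differential_threshold_multiplier Peak-to-peak threshold in units
#'   of the channel noise sd.
#' @param peak_lifetime_period Window (ms) within which the opposite-sign
#'   extremum must occur.
#' @param refractory Minimum separation between accepted spikes, ms; closer
#'   events collapse to the larger one.
#' @param snippet_threshold_multiplier Trough amplitude threshold (in noise
#'   sds) for snippet extraction.
#' @param snippet_pre,snippet_post Snippet extent before/after the trough, ms.
#' @return Object of class `mea_detection_params`.
#' @export
detection_params <- function(highpass_cutoff = 70,
                             differential_threshold_multiplier = 8,
                             peak_lifetime_period = 2.0,
                             refractory = 1.0,
                             snippet_threshold_multiplier = 5,
                             snippet_pre = 0.8,
                             snippet_post = 3.2) {
  stopifnot(refractory > 0, peak_lifetime_period > 0)
  structure(list(highpass_cutoff = highpass_cutoff,
                 differential_threshold_multiplier = differential_threshold_multiplier,
                 peak_lifetime_period = peak_lifetime_period,
                 refractory = refractory,
                 snippet_threshold_multiplier = snippet_threshold_multiplier,
                 snippet_pre = snippet_pre, snippet_post = snippet_post),
            class = "mea_detection_params")
}

#' Zero-phase Butterworth high-pass filter
#'
#' Forward-backward (zero-phase) application of a 4th-order Butterworth
#' high-pass filter to every channel; removes DC exactly.
#'
#' @param recording An `mea_recording`.
#' @param params A [detection_params()].
#' @return The filtered `mea_recording`.
#' @export
highpass_filter <- function(recording, params = detection_params()) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$sampling_rate
  if (params$highpass_cutoff >= fs / 2)
    stop("parameter error: high-pass cutoff must be below the Nyquist frequency",
         call. = FALSE)
  if (any(!is.finite(recording$data)))
    stop("signal contains non-finite values", call. = FALSE)
  bf <- signal::butter(4, params$highpass_cutoff / (fs / 2), type = "high")
  out <- recording
  for (j in seq_len(ncol(recording$data))) {
    x <- recording$data[, j]
    x <- x - mean(x)  # exact DC removal before filtering
    out$data[, j] <- signal::filtfilt(bf, x)
  }
  out
}

#' Robust noise standard deviation
#'
#' Median absolute deviation estimator `median(|x - median(x)|) / 0.6745`,
#' robust to spike contamination.
#'
#' @param x Numeric signal (>= 1 s recommended).
#' @return Estimated noise sd, in the units of `x`.
#' @export
estimate_noise_sd <- function(x) {
  stats::median(abs(x - stats::median(x))) / 0.6745
}

# running max over the w samples strictly after (fwd) / before (bwd) each
# sample, via log2(w) pmax passes on shifted copies
.run_max <- function(x, w, forward = TRUE) {
  n <- length(x)
  shift1 <- function(v, k) {
    if (k >= n) return(rep(-Inf, n))
    if (forward) c(v[-seq_len(k)], rep(-Inf, k))
    else c(rep(-Inf, k), v[seq_len(n - k)])
  }
  # m holds max over offsets [1 .. len]
  m <- shift1(x, 1L)
  len <- 1L
  while (2L * len <= w) {
    m <- pmax(m, shift1(m, len))
    len <- 2L * len
  }
  if (len < w) m <- pmax(m, shift1(shift1(x, w - len), len))
  m
}

#' PTSD spike detection
#'
#' Differential-threshold precision timing spike detection: local negative
#' extrema are accepted as spikes when the peak-to-peak excursion between
#' the extremum and the opposite-sign extremum within the peak lifetime
#' period exceeds `differential_threshold_multiplier` times the channel
#' noise sd. The spike time is the sample of the negative extremum; events
#' closer than the refractory period collapse to the larger one.
#'
#' @param x Filtered single-channel signal, uV.
#' @param sampling_rate Hz.
#' @param params A [detection_params()].
#' @param noise_sd Channel noise sd; estimated with [estimate_noise_sd()]
#'   when `NULL`.
#' @return Numeric vector of spike times in seconds (0-based samples:
#'   sample `i` maps to time `i / sampling_rate`).
#' @export
detect_spikes_ptsd <- function(x, sampling_rate, params = detection_params(),
                               noise_sd = NULL) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(x)
  thr <- params$differential_threshold_multiplier * noise_sd
  if (thr <= 0) thr <- .Machine$double.eps
  w <- max(1L, round(params$peak_lifetime_period / 1000 * sampling_rate))

  mid <- 2:(n - 1)
  is_min <- x[mid] < x[mid - 1] & x[mid] <= x[mid + 1]
  cand <- mid[is_min]
  if (!length(cand)) return(numeric(0))

  fwd <- .run_max(x, w, forward = TRUE)
  bwd <- .run_max(x, w, forward = FALSE)
  ptp <- pmax(fwd[cand], bwd[cand]) - x[cand]
  cand <- cand[ptp > thr]
  if (!length(cand)) return(numeric(0))

  # refractory: collapse events closer than refractory to the deeper trough
  refr <- params$refractory / 1000 * sampling_rate
  keep <- integer(0)
  cur <- cand[1]
  for (i in cand[-1]) {
    if (i - cur < refr) {
      if (x[i] < x[cur]) cur <- i
    } else {
      keep <- c(keep, cur)
      cur <- i
    }
  }
  keep <- c(keep, cur)
  (keep - 1) / sampling_rate
}

#' Extract 40-sample waveform snippets
#'
#' For the waveform path only spikes whose trough exceeds
#' `snippet_threshold_multiplier` times the noise sd (in the negative
#' direction) are snipped; the window is 8 samples before the trough, the
#' trough, and 31 samples after (40 samples = 4 ms at 10 kHz). Spikes too
#' close to the record edges are dropped and counted.
#'
#' @param x Filtered single-channel signal, uV.
#' @param spike_times Spike times in seconds (trough positions).
#' @param sampling_rate Hz.
#' @param params A [detection_params()].
#' @param noise_sd Channel noise sd; estimated when `NULL`.
#' @return List with `snippets` (matrix, one 40-sample row per kept spike),
#'   `times` (kept spike times), `n_dropped_edge`, `n_below_threshold`.
#' @export
extract_snippets <- function(x, spike_times, sampling_rate,
                             params = detection_params(), noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(x)
  pre <- 8L; post <- 31L
  s <- round(spike_times * sampling_rate) + 1L  # 1-based trough sample
  in_range <- s - pre >= 1L & s + post <= length(x)
  n_edge <- sum(!in_range)
  s <- s[in_range]; tt <- spike_times[in_range]
  deep <- x[s] < -params$snippet_threshold_multiplier * noise_sd
  n_small <- sum(!deep)
  s <- s[deep]; tt <- tt[deep]
  snips <- if (length(s))
    t(vapply(s, function(i) x[(i - pre):(i + post)], numeric(pre + post + 1L)))
  else matrix(numeric(0), 0, pre + post + 1L)
  list(snippets = snips, times = tt,
       n_dropped_edge = n_edge, n_below_threshold = n_small)
}

#' Detect spikes on every channel of a recording
#'
#' Applies [highpass_filter()], estimates per-channel noise, runs
#' [detect_spikes_ptsd()] and (optionally) [extract_snippets()] per channel.
#'
#' @param recording An `mea_recording`.
#' @param params A [detection_params()].
#' @param snippets Also extract waveform snippets?
#' @return List with `trains` (`mea_spiketrains`), `noise_sd` (per channel),
#'   and, when `snippets = TRUE`, `snippets` (per-channel list as returned
#'   by [extract_snippets()]).
#' @export
detect_spikes <- function(recording, params = detection_params(),
                          snippets = FALSE) {
  filt <- highpass_filter(recording, params)
  fs <- filt$sampling_rate
  nch <- ncol(filt$data)
  times <- vector("list", nch)
  nsd <- numeric(nch)
  snp <- if (snippets) vector("list", nch) else NULL
  for (j in seq_len(nch)) {
    x <- filt$data[, j]
    nsd[j] <- estimate_noise_sd(x)
    times[[j]] <- detect_spikes_ptsd(x, fs, params, noise_sd = nsd[j])
    if (snippets)
      snp[[j]] <- extract_snippets(x, times[[j]], fs, params, noise_sd = nsd[j])
  }
  out <- list(trains = mea_spiketrains(times, n_channels = nch),
              noise_sd = nsd)
  if (snippets) out$snippets <- snp
  out
}
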