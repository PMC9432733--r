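#' Recording protocol specification
#'
#' Describes the three-phase exposure protocol used throughout the package:
#' a baseline phase, an exposure (treatment) phase, and a post-exposure
#' washout phase, recorded continuously on a multichannel MEA. Defaults
#' follow the standard 30 min baseline / 15 min exposure / 45 min washout
#' protocol on a 60-channel array sampled at 10 kHz per channel.
#'
#' Phases are contiguous, non-overlapping and half-open:
#' baseline `[0, t1)`, exposure `[t1, t2)`, post `[t2, total)`.
#'
#' @param baseline_duration Baseline duration in seconds (> 0).
#' @param exposure_duration Exposure duration in seconds (> 0).
#' @param post_duration Post-exposure duration in seconds (> 0).
#' @param n_channels Number of MEA channels (positive integer).
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `mea_protocol`.
#' @examples
#' p <- mea_protocol()
#' phase_window(p, "exposure")
#' @export
mea_protocol <- function(baseline_duration = 1800, exposure_duration = 900,
                         post_duration = 2700, n_channels = 60,
                         sampling_rate = 10000) {
  if (any(c(baseline_duration, exposure_duration, post_duration) <= 0))
    stop("protocol error: all phase durations must be > 0", call. = FALSE)
  if (n_channels < 1 || n_channels != round(n_channels))
    stop("protocol error: n_channels must be a positive integer", call. = FALSE)
  if (sampling_rate <= 0)
    stop("protocol error: sampling_rate must be > 0", call. = FALSE)
  structure(list(
    baseline_duration = baseline_duration,
    exposure_duration = exposure_duration,
    post_duration = post_duration,
    n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate,
    t_exposure_on = baseline_duration,
    t_exposure_off = baseline_duration + exposure_duration,
    total_duration = baseline_duration + exposure_duration + post_duration
  ), class = "mea_protocol")
}

#' @export
print.mea_protocol <- function(x, ...) {
  cat(sprintf(
    "MEA protocol: %g s baseline | %g s exposure | %g s post; %d channels @ %g Hz\n",
    x$baseline_duration, x$exposure_duration, x$post_duration,
    x$n_channels, x$sampling_rate))
  invisible(x)
}

#' Phase time window
#'
#' Half-open time window `[start, end)` of one protocol phase.
#'
#' @param protocol A [mea_protocol()].
#' @param phase One of `"baseline"`, `"exposure"`, `"post"`.
#' @return Numeric length-2 vector `c(start, end)` in seconds.
#' @export
phase_window <- function(protocol, phase = c("baseline", "exposure", "post")) {
  phase <- match.arg(phase)
  switch(phase,
    baseline = c(0, protocol$t_exposure_on),
    exposure = c(protocol$t_exposure_on, protocol$t_exposure_off),
    post     = c(protocol$t_exposure_off, protocol$total_duration))
}

#' Map times to protocol phases
#'
#' @param times Numeric vector of times in seconds.
#' @param protocol A [mea_protocol()].
#' @return Factor with levels `baseline`, `exposure`, `post`.
#' @export
phase_of <- function(times, protocol) {
  out <- ifelse(times < protocol$t_exposure_on, "baseline",
         ifelse(times < protocol$t_exposure_off, "exposure", "post"))
  factor(out, levels = c("baseline", "exposure", "post"))
}

#' Network activity model
#'
#' Statistical model of spontaneous activity of a mature cultured cortical
#' network: synchronous network bursts recruiting most channels, a smaller
#' population of isolated single-channel bursts, and tonic background
#' spiking outside bursts. Defaults describe a mature, strongly
#' network-bursting culture in which network bursts make up 60-80% of all
#' bursts.
#'
#' @param network_burst_rate Network burst events per minute.
#' @param burst_participation Probability that a channel is recruited by a
#'   network burst event (in (0, 1]).
#' @param intra_burst_rate Within-burst firing rate, spikes/s.
#' @param burst_duration_mean Mean burst duration, seconds.
#' @param burst_duration_cv Coefficient of variation of (log-normal) burst
#'   durations.
#' @param isolated_burst_fraction Fraction of a channel's bursts that are
#'   isolated (non-network) bursts; default 0.3 so that network bursts are
#'   ~70% of the total.
#' @param background_rate Tonic outside-burst firing rate, spikes/s.
#' @param channel_rate_heterogeneity CV of per-channel log-normal rate
#'   multipliers applied to background and intra-burst rates.
#' @param burst_jitter_sd Cross-channel burst-onset jitter sd, seconds.
#' @return An object of class `mea_network_model`.
#' @export
network_model <- function(network_burst_rate = 10,
                          burst_participation = 0.85,
                          intra_burst_rate = 60,
                          burst_duration_mean = 0.3,
                          burst_duration_cv = 0.3,
                          isolated_burst_fraction = 0.3,
                          background_rate = 0.8,
                          channel_rate_heterogeneity = 0.25,
                          burst_jitter_sd = 0.020) {
  stopifnot(network_burst_rate >= 0, intra_burst_rate >= 0,
            background_rate >= 0, burst_duration_mean > 0,
            burst_duration_cv >= 0, channel_rate_heterogeneity >= 0,
            burst_jitter_sd >= 0)
  if (burst_participation <= 0 || burst_participation > 1)
    stop("burst_participation must be in (0, 1]", call. = FALSE)
  if (isolated_burst_fraction < 0 || isolated_burst_fraction >= 1)
    stop("isolated_burst_fraction must be in [0, 1)", call. = FALSE)
  structure(list(
    network_burst_rate = network_burst_rate,
    burst_participation = burst_participation,
    intra_burst_rate = intra_burst_rate,
    burst_duration_mean = burst_duration_mean,
    burst_duration_cv = burst_duration_cv,
    isolated_burst_fraction = isolated_burst_fraction,
    background_rate = background_rate,
    channel_rate_heterogeneity = channel_rate_heterogeneity,
    burst_jitter_sd = burst_jitter_sd
  ), class = "mea_network_model")
}

#' Treatment effect preset
#'
#' Mechanism-level description of what one treatment does to the network
#' during the exposure phase: multiplicative scalings of burst rate,
#' background rate, burst duration and intra-burst rate, a scaling of
#' cross-channel burst-onset jitter (desynchronisation), an optional
#' post-exposure rebound (a transient boost of the network burst rate after
#' treatment withdrawal), a scaling of action-potential width at the
#' waveform level, and an exponential onset time constant governing the
#' transition into (and out of) the scaled regime.
#'
#' @param name Preset identifier.
#' @param burst_rate_scale Multiplier on burst rates during exposure.
#' @param background_rate_scale Multiplier on the background spike rate.
#' @param burst_duration_scale Multiplier on mean burst duration.
#' @param intra_burst_rate_scale Multiplier on the within-burst rate.
#' @param jitter_scale Multiplier on cross-channel burst-onset jitter sd.
#' @param rebound Logical; transient rebound of network bursting after
#'   exposure offset.
#' @param rebound_magnitude Multiplier on the network burst rate during the
#'   rebound epoch.
#' @param rebound_duration Rebound epoch duration, seconds (<= 120).
#' @param ap_halfwidth_scale Multiplier on AP waveform width during
#'   exposure (amplitude unchanged).
#' @param onset_time_constant Exponential transition time constant, seconds.
#' @return An object of class `mea_preset`.
#' @seealso [builtin_presets()]
#' @export
effect_preset <- function(name,
                          burst_rate_scale = 1,
                          background_rate_scale = 1,
                          burst_duration_scale = 1,
                          intra_burst_rate_scale = 1,
                          jitter_scale = 1,
                          rebound = FALSE,
                          rebound_magnitude = 1,
                          rebound_duration = 60,
                          ap_halfwidth_scale = 1,
                          onset_time_constant = 30) {
  scales <- c(burst_rate_scale, background_rate_scale, burst_duration_scale,
              intra_burst_rate_scale, jitter_scale, ap_halfwidth_scale,
              rebound_magnitude)
  if (any(scales <= 0)) stop("preset scales must be > 0", call. = FALSE)
  if (rebound_duration > 120)
    stop("rebound_duration must be <= 120 s", call. = FALSE)
  structure(list(
    name = name,
    burst_rate_scale = burst_rate_scale,
    background_rate_scale = background_rate_scale,
    burst_duration_scale = burst_duration_scale,
    intra_burst_rate_scale = intra_burst_rate_scale,
    jitter_scale = jitter_scale,
    rebound = rebound,
    rebound_magnitude = rebound_magnitude,
    rebound_duration = rebound_duration,
    ap_halfwidth_scale = ap_halfwidth_scale,
    onset_time_constant = onset_time_constant
  ), class = "mea_preset")
}

#' Built-in treatment presets
#'
#' Three presets spanning the experimental arms of the study design the
#' generator emulates:
#' \describe{
#'   \item{`sham`}{No treatment; all multipliers 1, rebound off.}
#'   \item{`rf`}{RF-field-like inhibition: moderate suppression of bursting
#'     (stronger than of tonic spiking), mild burst shortening, mild
#'     desynchronisation, no post-exposure rebound, AP narrowing.}
#'   \item{`mu`}{Muscimol-like (GABA-A agonist) inhibition: strong and
#'     near-equal suppression of bursting and spiking, burst shortening
#'     with slightly elevated intra-burst rate, strong desynchronisation,
#'     a short (~1 min) post-inhibitory rebound of network bursting after
#'     washout, AP narrowing.}
#' }
#'
#' The numeric values are calibration defaults chosen so that the measured
#' pipeline outputs (after burst detection and the metric panel, not a
#' pass-through of the preset) land on the reference effect sizes; all are
#' overridable via [effect_preset()].
#'
#' @return Named list of [effect_preset()] objects: `sham`, `rf`, `mu`.
#' @export
builtin_presets <- function() {
  list(
    sham = effect_preset("sham"),
    rf = effect_preset("rf",
      burst_rate_scale = 0.63,
      background_rate_scale = 0.843,
      burst_duration_scale = 0.85,
      intra_burst_rate_scale = 1.0,
      jitter_scale = 1.5,
      rebound = FALSE,
      ap_halfwidth_scale = 0.93),
    mu = effect_preset("mu",
      burst_rate_scale = 0.41,
      background_rate_scale = 0.386,
      burst_duration_scale = 0.7,
      intra_burst_rate_scale = 1.1,
      jitter_scale = 3.0,
      rebound = TRUE,
      rebound_magnitude = 3.0,
      rebound_duration = 60,
      ap_halfwidth_scale = 0.93)
  )
}

#' @export
print.mea_preset <- function(x, ...) {
  cat(sprintf("Effect preset '%s':\n", x$name))
  cat(sprintf("  burst rate x%.2f, background x%.2f, duration x%.2f, intra-burst x%.2f\n",
              x$burst_rate_scale, x$background_rate_scale,
              x$burst_duration_scale, x$intra_burst_rate_scale))
  cat(sprintf("  jitter x%.2f, AP width x%.2f, onset tau %g s, rebound %s\n",
              x$jitter_scale, x$ap_halfwidth_scale, x$onset_time_constant,
              if (x$rebound) sprintf("x%.1f for %g s", x$rebound_magnitude,
                                     x$rebound_duration) else "off"))
  invisible(x)
}
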