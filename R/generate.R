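#' @title Synthetic spike-train generator
#' @description Event-level generator producing per-channel spike trains with
#' the statistical structure the downstream analysis assumes: network burst
#' events drawn from a (phase-modulated) Poisson process that recruit most
#' channels near-synchronously, per-channel isolated bursts, log-normal burst
#' durations, flat intra-burst Poisson firing, tonic Poisson background
#' spiking, and treatment effects applied as multiplicative scalings with an
#' exponential onset transition. A muscimol-like preset appends a transient
#' rebound epoch of elevated network bursting after exposure offset.
#' @name generate
NULL

# deterministic per-channel substream seed, kept below 2^31
.channel_seed <- function(seed, channel) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L + 7919L * as.integer(channel)
}

#' Treatment transition weight
#'
#' Weight in `[0, 1]` of the treatment effect at time `t`: 0 during
#' baseline, rising as `1 - exp(-(t - t_on)/tau)` during exposure, and
#' decaying back as `w(t_off) * exp(-(t - t_off)/tau)` after exposure ends.
#' A multiplicative scale `s` acts at time `t` as `1 + (s - 1) * w(t)`.
#'
#' @param t Numeric vector of times, seconds.
#' @param protocol A [mea_protocol()].
#' @param preset An [effect_preset()] (uses `onset_time_constant`).
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
effect_weight <- function(t, protocol, preset) {
  tau <- preset$onset_time_constant
  t1 <- protocol$t_exposure_on
  t2 <- protocol$t_exposure_off
  w_end <- 1 - exp(-(t2 - t1) / tau)
  w <- numeric(length(t))
  inexp <- t >= t1 & t < t2
  w[inexp] <- 1 - exp(-(t[inexp] - t1) / tau)
  inpost <- t >= t2
  w[inpost] <- w_end * exp(-(t[inpost] - t2) / tau)
  w
}

# scale multiplier at time t for a preset scale value s
.scale_at <- function(t, s, protocol, preset) {
  1 + (s - 1) * effect_weight(t, protocol, preset)
}

# inhomogeneous Poisson sampler by thinning on [t0, t1)
.sample_inhom <- function(rate_fn, rate_max, t0, t1) {
  if (rate_max <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate_max * (t1 - t0))
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < rate_fn(cand) / rate_max
  cand[keep]
}

#' Generate synthetic spike trains with ground-truth bursts
#'
#' Draws one complete simulated MEA recording at the event level (spike
#' times only). Network burst events are Poisson with a rate scaled by the
#' preset during exposure (exponential transition); each event recruits each
#' channel independently with probability `burst_participation`, with a
#' Gaussian cross-channel onset jitter whose sd is scaled by the preset's
#' `jitter_scale` during exposure. Per-channel burst spikes are drawn at a
#' flat intra-burst rate over a log-normal duration; isolated bursts are
#' added per channel so that they make up `isolated_burst_fraction` of that
#' channel's bursts; outside-burst spikes are Poisson background. If the
#' preset has `rebound = TRUE`, the network burst rate is additionally
#' multiplied by `rebound_magnitude` for `rebound_duration` seconds after
#' exposure ends.
#'
#' @param protocol A [mea_protocol()].
#' @param model A [network_model()].
#' @param preset An [effect_preset()].
#' @param seed Integer seed; fixes all randomness (same seed, same output).
#' @return A list of class `mea_simulation` with components:
#'   \item{trains}{`mea_spiketrains`: list with `times` (per-channel sorted
#'     numeric vectors, seconds), `n_channels`, `protocol`.}
#'   \item{ground_truth}{`mea_bursts` data.frame: `channel`, `start`, `end`,
#'     `n_spikes`, `network` (logical flag; TRUE when the burst came from a
#'     network event).}
#' @examples
#' sim <- generate_spike_trains(
#'   mea_protocol(60, 30, 30, n_channels = 4),
#'   network_model(), builtin_presets()$sham, seed = 1)
#' head(sim$ground_truth)
#' @export
generate_spike_trains <- function(protocol, model, preset, seed) {
  stopifnot(inherits(protocol, "mea_protocol"),
            inherits(model, "mea_network_model"),
            inherits(preset, "mea_preset"))
  total <- protocol$total_duration
  t2 <- protocol$t_exposure_off

  set.seed(as.integer(seed))
  # per-channel rate multipliers (log-normal, mean 1, CV = heterogeneity)
  cv <- model$channel_rate_heterogeneity
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    ch_mult <- stats::rlnorm(protocol$n_channels, -sdl^2 / 2, sdl)
  } else ch_mult <- rep(1, protocol$n_channels)

  # network burst events
  base_rate <- model$network_burst_rate / 60
  reb_on <- preset$rebound
  reb_win <- c(t2, t2 + preset$rebound_duration)
  net_rate_fn <- function(t) {
    r <- base_rate * .scale_at(t, preset$burst_rate_scale, protocol, preset)
    if (reb_on) r <- r * ifelse(t >= reb_win[1] & t < reb_win[2],
                                preset$rebound_magnitude, 1)
    r
  }
  rmax <- base_rate * max(1, preset$burst_rate_scale) *
    (if (reb_on) preset$rebound_magnitude else 1)
  net_events <- .sample_inhom(net_rate_fn, rmax, 0, total)

  # log-normal duration parameters
  dcv <- model$burst_duration_cv
  dsig <- sqrt(log(1 + dcv^2))

  f <- model$isolated_burst_fraction
  iso_base <- base_rate * model$burst_participation * f / max(1 - f, 1e-12)
  iso_rate_fn <- function(t)
    iso_base * .scale_at(t, preset$burst_rate_scale, protocol, preset)
  iso_max <- iso_base * max(1, preset$burst_rate_scale)

  times <- vector("list", protocol$n_channels)
  gt <- vector("list", protocol$n_channels)

  for (ch in seq_len(protocol$n_channels)) {
    set.seed(.channel_seed(seed, ch))

    # recruitment + jittered onsets for network events
    part <- stats::runif(length(net_events)) < model$burst_participation
    ev <- net_events[part]
    jsd <- model$burst_jitter_sd *
      .scale_at(ev, preset$jitter_scale, protocol, preset)
    onsets_net <- ev + stats::rnorm(length(ev), 0, jsd)

    onsets_iso <- .sample_inhom(iso_rate_fn, iso_max, 0, total)
    onsets <- c(onsets_net, onsets_iso)
    isnet <- rep(c(TRUE, FALSE), c(length(onsets_net), length(onsets_iso)))
    o <- order(onsets)
    onsets <- onsets[o]; isnet <- isnet[o]

    # burst durations and spike counts
    dmean <- model$burst_duration_mean *
      .scale_at(onsets, preset$burst_duration_scale, protocol, preset)
    dur <- stats::rlnorm(length(onsets), log(dmean) - dsig^2 / 2, dsig)
    irate <- model$intra_burst_rate * ch_mult[ch] *
      .scale_at(onsets, preset$intra_burst_rate_scale, protocol, preset)

    # clamp to the record and enforce per-channel non-overlap
    keep <- onsets >= 0 & onsets < total
    onsets <- onsets[keep]; dur <- dur[keep]
    isnet <- isnet[keep]; irate <- irate[keep]
    ends <- pmin(onsets + dur, total)
    if (length(onsets) > 1) {
      keep <- rep(TRUE, length(onsets))
      last_end <- -Inf
      for (i in seq_along(onsets)) {
        if (onsets[i] < last_end) keep[i] <- FALSE
        else last_end <- ends[i]
      }
      onsets <- onsets[keep]; ends <- ends[keep]
      isnet <- isnet[keep]; irate <- irate[keep]
    }

    nsp <- stats::rpois(length(onsets), irate * (ends - onsets))
    burst_spikes <- if (length(onsets))
      unlist(lapply(seq_along(onsets), function(i) {
        if (nsp[i] == 0) return(numeric(0))
        stats::runif(nsp[i], onsets[i], ends[i])
      })) else numeric(0)

    # background (outside-burst tonic) spiking
    bg <- model$background_rate * ch_mult[ch]
    bg_fn <- function(t)
      bg * .scale_at(t, preset$background_rate_scale, protocol, preset)
    bg_spikes <- .sample_inhom(
      bg_fn, bg * max(1, preset$background_rate_scale), 0, total)

    st <- sort(c(burst_spikes, bg_spikes))
    st <- st[st > 0 & st < total]
    st <- st[!duplicated(st)]
    times[[ch]] <- st

    keep <- nsp > 0
    gt[[ch]] <- data.frame(
      channel = rep.int(ch, sum(keep)),
      start = onsets[keep], end = ends[keep],
      n_spikes = nsp[keep], network = isnet[keep])
  }

  trains <- structure(list(times = times,
                           n_channels = protocol$n_channels,
                           protocol = protocol),
                      class = "mea_spiketrains")
  ground_truth <- do.call(rbind, gt)
  class(ground_truth) <- c("mea_bursts", "data.frame")
  structure(list(trains = trains, ground_truth = ground_truth),
            class = "mea_simulation")
}

#' @export
print.mea_spiketrains <- function(x, ...) {
  n <- vapply(x$times, length, integer(1))
  cat(sprintf("MEA spike trains: %d channels, %d spikes total (%.1f per channel on average)\n",
              x$n_channels, sum(n), mean(n)))
  invisible(x)
}

#' @export
print.mea_simulation <- function(x, ...) {
  print(x$trains)
  cat(sprintf("Ground truth: %d bursts (%.0f%% network)\n",
              nrow(x$ground_truth), 100 * mean(x$ground_truth$network)))
  invisible(x)
}

#' Biphasic waveform template
#'
#' Parametric extracellular action-potential shape: an inverted (negative)
#' Gaussian trough followed by a smaller positive after-peak,
#' `v(t) = -A_t exp(-t^2 / 2 s_t^2) + A_p exp(-(t - d)^2 / 2 s_p^2)`,
#' with `s_t` set from the trough full width at half maximum.
#'
#' @param trough_amp Trough amplitude, uV (positive number; plotted negative).
#' @param trough_fwhm Trough full width at half maximum, ms.
#' @param peak_amp After-peak amplitude, uV.
#' @param peak_delay Delay of the after-peak centre after the trough, ms.
#' @param peak_width_sd Gaussian sd of the after-peak, ms.
#' @param class_hint One of `"MAJ"`, `"AUX"`, `"MIN"`.
#' @param abundance Relative abundance of this template on its channel.
#' @return Object of class `mea_template`.
#' @export
waveform_template <- function(trough_amp, trough_fwhm, peak_amp = 0.3 * trough_amp,
                              peak_delay = 0.8, peak_width_sd = 0.4,
                              class_hint = "MAJ", abundance = 1) {
  stopifnot(trough_amp > 0, trough_fwhm > 0, peak_amp >= 0)
  structure(list(trough_amp = trough_amp, trough_fwhm = trough_fwhm,
                 peak_amp = peak_amp, peak_delay = peak_delay,
                 peak_width_sd = peak_width_sd, class_hint = class_hint,
                 abundance = abundance),
            class = "mea_template")
}

#' Evaluate a waveform template
#'
#' @param template A [waveform_template()].
#' @param t_ms Times in ms relative to the trough.
#' @param width_scale Multiplier applied to the template's time axis
#'   (widths scaled, amplitudes unchanged).
#' @return Voltages in uV.
#' @export
template_voltage <- function(template, t_ms, width_scale = 1) {
  t_ms <- t_ms / width_scale
  s_t <- template$trough_fwhm / (2 * sqrt(2 * log(2)))
  -template$trough_amp * exp(-t_ms^2 / (2 * s_t^2)) +
    template$peak_amp *
      exp(-(t_ms - template$peak_delay)^2 / (2 * template$peak_width_sd^2))
}

#' Per-channel waveform template bank
#'
#' @param templates List (one element per channel) of lists of
#'   [waveform_template()] objects; abundances are normalised to sum to 1
#'   within each channel.
#' @param noise_sd Additive Gaussian noise sd, uV.
#' @return Object of class `mea_waveform_bank`.
#' @export
waveform_bank <- function(templates, noise_sd = 3) {
  stopifnot(noise_sd >= 0)
  templates <- lapply(templates, function(tl) {
    ab <- vapply(tl, function(x) x$abundance, numeric(1))
    for (i in seq_along(tl)) {
      tl[[i]]$abundance <- ab[i] / sum(ab)
      if (tl[[i]]$trough_amp < 5 * noise_sd)
        warning("template trough amplitude below 5 x noise sd; it will be undetectable")
    }
    tl
  })
  structure(list(templates = templates, noise_sd = noise_sd,
                 n_channels = length(templates)),
            class = "mea_waveform_bank")
}

#' Default waveform bank
#'
#' One to three templates per channel (a dominant unit and up to two
#' smaller ones) with trough amplitudes well above the detectability limit.
#'
#' @param n_channels Number of channels.
#' @param noise_sd Noise sd, uV.
#' @param seed Integer seed.
#' @return A [waveform_bank()].
#' @export
default_waveform_bank <- function(n_channels, noise_sd = 3, seed = 1) {
  set.seed(as.integer(seed))
  tls <- lapply(seq_len(n_channels), function(ch) {
    k <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
    amps <- c(stats::runif(1, 40, 60), stats::runif(1, 25, 40),
              stats::runif(1, 16, 25))[1:k]
    abund <- c(0.72, 0.2, 0.08)[1:k]
    hints <- c("MAJ", "AUX", "MIN")[1:k]
    lapply(1:k, function(i)
      waveform_template(amps[i], stats::runif(1, 0.35, 0.6),
                        peak_amp = 0.3 * amps[i],
                        class_hint = hints[i], abundance = abund[i]))
  })
  waveform_bank(tls, noise_sd = noise_sd)
}

#' Render a raw voltage recording from spike trains
#'
#' Places one waveform template (chosen by abundance) at every spike time on
#' top of Gaussian noise. During the exposure phase template widths are
#' multiplied by the preset's `ap_halfwidth_scale` (with the exponential
#' onset transition) while amplitudes are unchanged.
#'
#' @param trains An `mea_spiketrains` object (times within the protocol).
#' @param bank A [waveform_bank()] with one template list per channel.
#' @param protocol A [mea_protocol()].
#' @param preset An [effect_preset()].
#' @param seed Integer seed.
#' @return An `mea_recording` (see [read_recording()]).
#' @export
render_raw_recording <- function(trains, bank, protocol, preset, seed) {
  stopifnot(inherits(trains, "mea_spiketrains"),
            inherits(bank, "mea_waveform_bank"))
  if (bank$n_channels < trains$n_channels)
    stop("waveform bank has fewer channels than the spike trains", call. = FALSE)
  fs <- protocol$sampling_rate
  n <- round(protocol$total_duration * fs)
  # snippet window compatibility: template must fit in [-0.8, 3.2] ms
  for (tl in bank$templates) for (tp in tl) {
    s_t <- tp$trough_fwhm / (2 * sqrt(2 * log(2)))
    if (3 * s_t > 0.8 || tp$peak_delay + 3 * tp$peak_width_sd > 3.2)
      stop("template longer than the 4 ms snippet window", call. = FALSE)
  }
  set.seed(as.integer(seed))
  data <- matrix(0, nrow = n, ncol = trains$n_channels)
  win <- -8:32  # samples around the trough covering [-0.8, 3.2] ms
  for (ch in seq_len(trains$n_channels)) {
    set.seed(.channel_seed(seed, ch) + 1L)
    x <- if (bank$noise_sd > 0) stats::rnorm(n, 0, bank$noise_sd) else numeric(n)
    st <- trains$times[[ch]]
    st <- st[st >= 0 & st < protocol$total_duration]
    tl <- bank$templates[[ch]]
    ab <- vapply(tl, function(z) z$abundance, numeric(1))
    pick <- if (length(tl) > 1)
      sample.int(length(tl), length(st), replace = TRUE, prob = ab)
    else rep.int(1L, length(st))
    wscale <- 1 + (preset$ap_halfwidth_scale - 1) *
      effect_weight(st, protocol, preset)
    for (i in seq_along(st)) {
      s0 <- round(st[i] * fs)
      idx <- s0 + win
      ok <- idx >= 0 & idx < n
      if (!any(ok)) next
      v <- template_voltage(tl[[pick[i]]], win[ok] / fs * 1000,
                            width_scale = wscale[i])
      x[idx[ok] + 1L] <- x[idx[ok] + 1L] + v
    }
    data[, ch] <- x
  }
  new_recording(data, sampling_rate = fs,
                phase_boundaries = c(protocol$t_exposure_on,
                                     protocol$t_exposure_off),
                channel_ids = seq_len(trains$n_channels))
}
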