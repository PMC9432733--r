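#' @title Network activity metric panel
#' @description Per-channel and pooled (MEA-level) activity metrics per
#' protocol phase: mean bursting rate (MBR, bursts/min), mean inter-burst
#' interval (IBI, s; gap from burst end to next burst start), mean burst
#' duration (BD, s), mean intra-burst spike rate (IBSR, spikes/s inside
#' bursts) and mean spiking rate of spikes outside bursts (MSR, spikes/s).
#' Treatment effects are expressed as the fractional variation
#' `R = M_exposure / M_baseline` of each metric; cross-channel synchrony as
#' the CV (percent ratio of the average within-channel sd to the pooled
#' mean) and spatial variability as the normalised RMSE of channel-level
#' normalised values around the MEA-level value.
#' @name metrics
NULL

#' Active channel filter
#'
#' A channel is active when, during baseline, it shows both spiking and
#' bursting activity: total spike rate at least `rate_min` and at least
#' `min_bursts` bursts.
#'
#' @param trains An `mea_spiketrains`.
#' @param bursts An `mea_bursts` table.
#' @param protocol A [mea_protocol()].
#' @param rate_min Minimum baseline spike rate, spikes/s.
#' @param min_bursts Minimum baseline burst count.
#' @return Integer vector of active channel indices.
#' @export
active_channel_filter <- function(trains, bursts, protocol,
                                  rate_min = 0.02, min_bursts = 2) {
  win <- phase_window(protocol, "baseline")
  dur <- diff(win)
  act <- vapply(seq_len(trains$n_channels), function(ch) {
    nspk <- sum(trains$times[[ch]] >= win[1] & trains$times[[ch]] < win[2])
    nb <- sum(bursts$channel == ch & bursts$start >= win[1] &
                bursts$start < win[2])
    (nspk / dur) >= rate_min && nb >= min_bursts
  }, logical(1))
  if (!any(act))
    stop("pipeline error: no active channels at baseline", call. = FALSE)
  which(act)
}

# per-channel event-level values for one phase: BD, IBI (end-to-next-start
# gaps), per-burst IBSR; plus spike/burst-time accounting for MBR and MSR
.phase_events <- function(trains, bursts, protocol, phase, channels) {
  win <- phase_window(protocol, phase)
  dur <- diff(win)
  lapply(channels, function(ch) {
    b <- bursts[bursts$channel == ch & bursts$start >= win[1] &
                  bursts$start < win[2], , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    st <- trains$times[[ch]]
    st <- st[st >= win[1] & st < win[2]]
    inburst <- if (nrow(b)) sum(b$n_spikes) else 0
    btime <- if (nrow(b)) sum(b$end - b$start) else 0
    list(channel = ch,
         bd = if (nrow(b)) b$end - b$start else numeric(0),
         ibi = if (nrow(b) >= 2) b$start[-1] - b$end[-nrow(b)] else numeric(0),
         ibsr = if (nrow(b)) b$n_spikes / (b$end - b$start) else numeric(0),
         n_bursts = nrow(b), n_spikes = length(st),
         inburst_spikes = inburst, inburst_time = btime,
         duration = dur)
  })
}

#' Compute the metric panel for one phase
#'
#' Per-channel values with pooled (unweighted mean over channels)
#' MEA-level values as an attribute. A channel with fewer than two bursts
#' in the phase has an undefined IBI (NA, excluded from pooling); a channel
#' with no bursts has NA BD/IBSR and MBR 0.
#'
#' @param trains An `mea_spiketrains`.
#' @param bursts An `mea_bursts` table.
#' @param protocol A [mea_protocol()].
#' @param phase `"baseline"`, `"exposure"` or `"post"`.
#' @param channels Active channels (see [active_channel_filter()]).
#' @return data.frame of class `mea_panel` with columns `channel`, `mbr`,
#'   `ibi`, `bd`, `ibsr`, `msr`; attributes `pooled` (named means over
#'   channels) and `phase`.
#' @export
compute_panel <- function(trains, bursts, protocol, phase,
                          channels = seq_len(trains$n_channels)) {
  ev <- .phase_events(trains, bursts, protocol, phase, channels)
  rows <- lapply(ev, function(e) {
    data.frame(
      channel = e$channel,
      mbr = e$n_bursts / e$duration * 60,
      ibi = if (length(e$ibi)) mean(e$ibi) else NA_real_,
      bd = if (length(e$bd)) mean(e$bd) else NA_real_,
      ibsr = if (e$inburst_time > 0) e$inburst_spikes / e$inburst_time
             else NA_real_,
      msr = (e$n_spikes - e$inburst_spikes) /
        max(e$duration - e$inburst_time, .Machine$double.eps))
  })
  panel <- do.call(rbind, rows)
  pooled <- vapply(c("mbr", "ibi", "bd", "ibsr", "msr"),
                   function(m) mean(panel[[m]], na.rm = TRUE), numeric(1))
  structure(panel, pooled = pooled, phase = phase,
            class = c("mea_panel", "data.frame"))
}

#' @export
print.mea_panel <- function(x, ...) {
  cat(sprintf("Metric panel (%s), %d channels. Pooled values:\n",
              attr(x, "phase"), nrow(x)))
  print(round(attr(x, "pooled"), 4))
  invisible(x)
}

#' Pooled values of a panel
#' @param panel An `mea_panel`.
#' @return Named numeric vector of MEA-level metric means.
#' @export
pooled_values <- function(panel) attr(panel, "pooled")

#' Baseline normalisation (fractional variation)
#'
#' The fractional variation of each metric,
#' `R = M_exposure / M_baseline`, at the pooled level and per channel.
#' Values with a zero (or undefined) baseline are flagged undefined (NA)
#' and excluded from pooling.
#'
#' @param panel_exposure,panel_baseline Panels from [compute_panel()] on
#'   the same channels.
#' @return data.frame with columns `metric`, `level` ("pooled" or
#'   "channel"), `channel` (NA for pooled), `R`.
#' @export
normalize_panel <- function(panel_exposure, panel_baseline) {
  stopifnot(identical(panel_exposure$channel, panel_baseline$channel))
  metrics <- c("mbr", "ibi", "bd", "ibsr", "msr")
  pe <- pooled_values(panel_exposure)
  pb <- pooled_values(panel_baseline)
  pooled <- data.frame(metric = metrics, level = "pooled",
                       channel = NA_integer_,
                       R = ifelse(pb[metrics] > 0, pe[metrics] / pb[metrics],
                                  NA_real_))
  per_ch <- do.call(rbind, lapply(metrics, function(m) {
    base <- panel_baseline[[m]]
    data.frame(metric = m, level = "channel",
               channel = panel_baseline$channel,
               R = ifelse(!is.na(base) & base > 0,
                          panel_exposure[[m]] / base, NA_real_))
  }))
  out <- rbind(pooled, per_ch)
  rownames(out) <- NULL
  out
}

#' Cross-channel synchrony (coefficient of variation)
#'
#' `CV = 100 * mean over channels of the within-channel sd of a burst
#' metric / pooled mean of the metric` (percent). Lower CV means higher
#' cross-channel synchronisation. Channels with fewer than two events for
#' the metric are excluded.
#'
#' @param trains An `mea_spiketrains`.
#' @param bursts An `mea_bursts` table.
#' @param protocol A [mea_protocol()].
#' @param phase Protocol phase.
#' @param metric One of `"ibi"`, `"bd"`, `"ibsr"`.
#' @param channels Active channels.
#' @return CV in percent (NA when undefined).
#' @export
cv_sync <- function(trains, bursts, protocol, phase, metric = c("ibi", "bd", "ibsr"),
                    channels = seq_len(trains$n_channels)) {
  metric <- match.arg(metric)
  ev <- .phase_events(trains, bursts, protocol, phase, channels)
  vals <- lapply(ev, function(e) e[[metric]])
  ok <- vapply(vals, function(v) length(v) >= 2, logical(1))
  if (!any(ok)) return(NA_real_)
  sds <- vapply(vals[ok], stats::sd, numeric(1))
  means <- vapply(vals[ok], mean, numeric(1))
  pooled_mean <- mean(means)
  if (pooled_mean <= 0) return(NA_real_)
  100 * mean(sds) / pooled_mean
}

#' Spatial variability (normalised RMSE)
#'
#' RMS deviation of channel-level normalised values `y_k` from the
#' MEA-level value `Y`, scaled by `Y`:
#' `Norm.RMSE = sqrt(sum((Y - y_k)^2) / K) / Y`. A value of 0.5 means the
#' mean inter-channel variation is 50% of the MEA-level value. Scale
#' invariant; 0 iff all channels equal the mean.
#'
#' @param y Channel-level normalised values `y_k`.
#' @param Y MEA-level value (defaults to `mean(y)`); must be > 0.
#' @return The Norm.RMSE statistic (NA when `Y` is 0 or `y` is empty).
#' @export
norm_rmse <- function(y, Y = mean(y)) {
  y <- y[!is.na(y)]
  if (!length(y) || is.na(Y) || Y == 0) return(NA_real_)
  sqrt(sum((Y - y)^2) / length(y)) / Y
}

#' Binned rate time course
#'
#' Event counts (spikes or burst starts, pooled over the given channels)
#' in non-overlapping bins tiling the record, converted to rates and
#' normalised by the baseline-phase mean rate.
#'
#' @param x An `mea_spiketrains` (spiking rate) or `mea_bursts` (bursting
#'   rate) object.
#' @param protocol A [mea_protocol()].
#' @param bin_width Bin width, seconds (60 for minute-binned courses, 10
#'   for fine sliding-window traces).
#' @param channels Channels to pool (default all).
#' @return data.frame of class `mea_timecourse` with columns `t_start`,
#'   `t_mid`, `phase`, `rate` (events/s) and `norm` (rate / baseline mean
#'   rate); attributes `bin_width` and `baseline_mean`.
#' @export
time_course <- function(x, protocol, bin_width = 60, channels = NULL) {
  if (protocol$total_duration <= bin_width)
    stop("record shorter than one bin", call. = FALSE)
  if (inherits(x, "mea_spiketrains")) {
    if (is.null(channels)) channels <- seq_len(x$n_channels)
    events <- unlist(x$times[channels])
  } else {
    if (is.null(channels)) channels <- unique(x$channel)
    events <- x$start[x$channel %in% channels]
  }
  n_bins <- floor(protocol$total_duration / bin_width)
  edges <- seq(0, by = bin_width, length.out = n_bins + 1)
  counts <- hist(events[events < edges[n_bins + 1]], breaks = edges,
                 plot = FALSE)$counts
  t_start <- edges[-(n_bins + 1)]
  rate <- counts / bin_width
  base <- t_start + bin_width <= protocol$t_exposure_on
  bmean <- mean(rate[base])
  out <- data.frame(t_start = t_start, t_mid = t_start + bin_width / 2,
                    phase = phase_of(t_start, protocol),
                    rate = rate,
                    norm = if (bmean > 0) rate / bmean else NA_real_)
  structure(out, bin_width = bin_width, baseline_mean = bmean,
            class = c("mea_timecourse", "data.frame"))
}

#' Initial inhibitory rate
#'
#' Ordinary least-squares slope of the normalised course through the first
#' five exposure-phase bins (units: fraction of baseline per minute;
#' negative values indicate inhibition).
#'
#' @param tc An `mea_timecourse` (minute bins recommended).
#' @param n_bins Number of leading exposure bins used (default 5).
#' @return Slope in fraction/min.
#' @export
initial_inhibitory_rate <- function(tc, n_bins = 5) {
  idx <- which(tc$phase == "exposure")
  if (length(idx) < n_bins)
    stop("need at least ", n_bins, " exposure bins", call. = FALSE)
  idx <- idx[seq_len(n_bins)]
  tmin <- tc$t_mid[idx] / 60
  y <- tc$norm[idx]
  sum((tmin - mean(tmin)) * (y - mean(y))) / sum((tmin - mean(tmin))^2)
}

#' Post-inhibitory rebound ratio
#'
#' `PIR = max of the first two post-exposure bins / reference level` of
#' the normalised course. Values well above 1 indicate a transient
#' overshoot of activity after treatment withdrawal.
#'
#' With `reference = "baseline"` (default) the reference is the
#' baseline-phase mean of the normalised course (1 by construction), so
#' PIR measures overshoot relative to the pre-treatment level: an
#' inhibited network that merely recovers to baseline scores ~1, and only
#' genuine rebound excitation scores above it. With
#' `reference = "exposure"` the reference is the mean of the last five
#' exposure bins; note that this variant scores above 1 for any
#' inhibition that simply washes out, because the denominator is the
#' inhibited floor.
#'
#' @param tc An `mea_timecourse` (minute bins recommended).
#' @param n_post Number of leading post bins considered (default 2).
#' @param n_exposure Number of trailing exposure bins for the
#'   exposure-floor reference (default 5).
#' @param reference `"baseline"` or `"exposure"`.
#' @return PIR ratio (NA when the reference level is 0).
#' @export
postinhibitory_rebound <- function(tc, n_post = 2, n_exposure = 5,
                                   reference = c("baseline", "exposure")) {
  reference <- match.arg(reference)
  pidx <- which(tc$phase == "post")
  eidx <- which(tc$phase == "exposure")
  if (length(pidx) < n_post || length(eidx) < n_exposure)
    stop("need at least ", n_post, " post and ", n_exposure,
         " exposure bins", call. = FALSE)
  ref <- if (reference == "exposure")
    mean(tc$norm[eidx[seq(length(eidx) - n_exposure + 1, length(eidx))]])
  else mean(tc$norm[tc$phase == "baseline"])
  if (is.na(ref) || ref == 0) return(NA_real_)
  max(tc$norm[pidx[seq_len(n_post)]]) / ref
}

#' Full event-level analysis of one culture
#'
#' Convenience wrapper chaining burst detection, the active-channel
#' filter, per-phase metric panels, baseline normalisation, synchrony CVs
#' and minute-binned time courses for one recording's spike trains.
#'
#' @param trains An `mea_spiketrains`.
#' @param protocol A [mea_protocol()].
#' @param params A [burst_params()].
#' @param bin_width Time-course bin width, seconds.
#' @return List of class `mea_culture_analysis` with elements `bursts`,
#'   `active`, `panels` (baseline/exposure/post), `normalized`, `cv`
#'   (per phase x metric), `tc_br`, `tc_sr` (burst/spike time courses),
#'   `iir_br`, `iir_sr`, `pir_br`, `pir_sr`.
#' @export
culture_metrics <- function(trains, protocol, params = burst_params(),
                            bin_width = 60) {
  bursts <- detect_bursts_all(trains, params)
  active <- active_channel_filter(trains, bursts, protocol)
  panels <- lapply(c(baseline = "baseline", exposure = "exposure",
                     post = "post"), function(ph)
    compute_panel(trains, bursts, protocol, ph, active))
  normalized <- normalize_panel(panels$exposure, panels$baseline)
  cv <- sapply(c(baseline = "baseline", exposure = "exposure"), function(ph)
    sapply(c(ibi = "ibi", bd = "bd", ibsr = "ibsr"), function(m)
      cv_sync(trains, bursts, protocol, ph, m, active)))
  tc_br <- time_course(bursts, protocol, bin_width, active)
  tc_sr <- time_course(trains, protocol, bin_width, active)
  structure(list(bursts = bursts, active = active, panels = panels,
                 normalized = normalized, cv = cv,
                 tc_br = tc_br, tc_sr = tc_sr,
                 iir_br = initial_inhibitory_rate(tc_br),
                 iir_sr = initial_inhibitory_rate(tc_sr),
                 pir_br = postinhibitory_rebound(tc_br),
                 pir_sr = postinhibitory_rebound(tc_sr)),
            class = "mea_culture_analysis")
}

#' @export
print.mea_culture_analysis <- function(x, ...) {
  r <- x$normalized
  pooled <- r[r$level == "pooled", ]
  cat(sprintf("Culture analysis: %d active channels, %d bursts\n",
              length(x$active), nrow(x$bursts)))
  cat("Normalized pooled metrics (exposure / baseline):\n")
  print(stats::setNames(round(pooled$R, 3), pooled$metric))
  cat(sprintf("Initial inhibitory rate (BR): %.3f /min; PIR (BR): %.2f\n",
              x$iir_br, x$pir_br))
  invisible(x)
}
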