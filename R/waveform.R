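#' @title Spike sorting and AP waveform features
#' @description Snippets are projected on their first three principal
#' components and clustered with Gaussian mixtures (1-4 components,
#' BIC-selected); snippets far from every component (squared Mahalanobis
#' distance beyond an outlier bound) stay unsorted. Clusters are ranked
#' MAJ / AUX / MIN by their share of the channel's sorted spikes, and
#' waveform features are measured on the cluster-mean snippet.
#'
#' Sign convention: the extracellular AP is inverted, so the biological
#' depolarization appears as the fast downstroke into the trough. The
#' "rising edge" slope reported here is the maximum-magnitude slope of the
#' pre-trough downstroke (depolarization equivalent) and the "falling
#' edge" slope is the maximum slope of the trough-to-peak recovery
#' (repolarization equivalent); both are reported as positive magnitudes
#' in uV/ms.
#' @name waveform
NULL

#' Sort spike snippets into units
#'
#' @param snippets Matrix of snippets (rows = spikes, 40 columns).
#' @param max_clusters Maximum number of mixture components.
#' @param outlier_mult Multiplier on the 0.99 chi-square quantile of the
#'   squared Mahalanobis distance beyond which a spike is left unsorted.
#' @param min_snippets Channels with fewer snippets are skipped (returns
#'   NULL).
#' @param n_pc Number of principal components used.
#' @return Integer vector of cluster labels per spike (0 = unsorted), or
#'   NULL when the channel is skipped. Deterministic for fixed input.
#' @export
sort_spikes <- function(snippets, max_clusters = 4, outlier_mult = 1.5,
                        min_snippets = 20, n_pc = 3) {
  if (is.null(snippets) || nrow(snippets) < min_snippets) return(NULL)
  pc <- stats::prcomp(snippets, center = TRUE, scale. = FALSE)
  d <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(d), drop = FALSE]
  # Mclust resolves mclustBIC in the caller's frame; evaluate inside an
  # environment parented by the mclust namespace so the lookup succeeds
  fit <- tryCatch(
    eval(quote(Mclust(scores, G = G, verbose = FALSE)),
         envir = list2env(list(scores = scores, G = 1:max_clusters),
                          parent = asNamespace("mclust"))),
    error = function(e) NULL)
  if (is.null(fit)) {  # degenerate covariance: single cluster fallback
    labels <- rep(1L, nrow(snippets))
    return(labels)
  }
  labels <- as.integer(fit$classification)
  # outlier bound: squared Mahalanobis distance to the assigned component
  bound <- outlier_mult * stats::qchisq(0.99, df = d)
  mu <- fit$parameters$mean
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = d)
  for (g in seq_len(fit$G)) {
    idx <- which(labels == g)
    if (!length(idx)) next
    sigma <- if (d == 1) {
      v <- fit$parameters$variance$sigmasq
      matrix(if (length(v) >= g) v[g] else v[1], 1, 1)
    } else {
      s <- fit$parameters$variance$sigma
      if (length(dim(s)) == 3) s[, , g] else s
    }
    md <- tryCatch(
      stats::mahalanobis(scores[idx, , drop = FALSE], mu[, g], sigma),
      error = function(e) rep(0, length(idx)))
    labels[idx[md > bound]] <- 0L
  }
  labels
}

#' Classify clusters as MAJ / AUX / MIN
#'
#' The largest cluster of a channel is the major (MAJ) unit; remaining
#' clusters holding at least `aux_fraction` of the channel's sorted spikes
#' are auxiliary (AUX); the rest are minor (MIN). Ties go to the
#' lower-numbered cluster.
#'
#' @param labels Integer cluster labels (0 = unsorted) from
#'   [sort_spikes()].
#' @param aux_fraction Minimum sorted-spike share for an AUX label.
#' @return data.frame with `cluster`, `n_spikes`, `fraction` (of sorted
#'   spikes), `class`.
#' @export
classify_clusters <- function(labels, aux_fraction = 0.15) {
  sorted <- labels[labels > 0]
  if (!length(sorted))
    return(data.frame(cluster = integer(0), n_spikes = integer(0),
                      fraction = numeric(0), class = character(0)))
  cl <- sort(unique(sorted))
  n <- vapply(cl, function(g) sum(sorted == g), integer(1))
  frac <- n / sum(n)
  maj <- cl[order(-n, cl)][1]  # largest; tie -> lower index
  class <- ifelse(cl == maj, "MAJ",
                  ifelse(frac >= aux_fraction, "AUX", "MIN"))
  data.frame(cluster = cl, n_spikes = n, fraction = frac, class = class)
}

#' AP waveform features of a mean snippet
#'
#' The snippet baseline is the mean of its first four samples. Features:
#' anti-peak amplitude (baseline minus trough minimum), peak amplitude
#' (post-trough maximum minus baseline), FWHM of the trough (time between
#' the two crossings of half the anti-peak depth, linearly interpolated),
#' and the maximum slopes of the pre-trough downstroke ("rising edge",
#' depolarization equivalent of the inverted extracellular wave) and of
#' the trough-to-peak recovery ("falling edge"), both positive, uV/ms.
#'
#' @param snippet Numeric vector (40 samples).
#' @param sampling_rate Hz.
#' @return List of class `mea_waveform_features`: `peak`, `anti_peak`
#'   (uV), `fwhm` (ms), `rising_slope`, `falling_slope` (uV/ms),
#'   `trough_index`.
#' @export
waveform_features <- function(snippet, sampling_rate = 10000) {
  stopifnot(is.numeric(snippet), length(snippet) >= 10)
  dt_ms <- 1000 / sampling_rate
  base <- mean(snippet[1:4])
  ti <- which.min(snippet)
  if (snippet[ti] >= base || ti <= 4 || ti >= length(snippet))
    stop("feature error: snippet has no trough below baseline", call. = FALSE)
  anti <- base - snippet[ti]
  after <- snippet[ti:length(snippet)]
  peak <- max(after) - base

  # FWHM via linear interpolation at the half-depth level
  level <- base - anti / 2
  left <- NA_real_
  for (i in seq(ti, 2)) {
    if (snippet[i - 1] > level && snippet[i] <= level) {
      left <- (i - 1) + (snippet[i - 1] - level) / (snippet[i - 1] - snippet[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ti, length(snippet) - 1)) {
    if (snippet[i] <= level && snippet[i + 1] > level) {
      right <- i + (level - snippet[i]) / (snippet[i + 1] - snippet[i])
      break
    }
  }
  fwhm <- if (is.na(left) || is.na(right)) NA_real_ else (right - left) * dt_ms

  d <- diff(snippet) / dt_ms
  rising <- if (ti > 1) max(abs(d[seq_len(ti - 1)])) else NA_real_
  pk_rel <- which.max(after)
  falling <- if (pk_rel > 1) max(d[ti:(ti + pk_rel - 2)]) else NA_real_
  structure(list(peak = peak, anti_peak = anti, fwhm = fwhm,
                 rising_slope = rising, falling_slope = falling,
                 trough_index = ti),
            class = "mea_waveform_features")
}

#' @export
print.mea_waveform_features <- function(x, ...) {
  cat(sprintf("AP features: anti-peak %.1f uV, peak %.1f uV, FWHM %.3f ms, slopes %.1f / %.1f uV/ms\n",
              x$anti_peak, x$peak, x$fwhm, x$rising_slope, x$falling_slope))
  invisible(x)
}

#' Phase-plot trajectory of a snippet
#'
#' Voltage against its central-difference time derivative.
#'
#' @param snippet Numeric vector of voltages, uV.
#' @param sampling_rate Hz.
#' @return data.frame with `v` (uV) and `dvdt` (uV/ms).
#' @export
phase_plot <- function(snippet, sampling_rate = 10000) {
  n <- length(snippet)
  dt_ms <- 1000 / sampling_rate
  dvdt <- c(snippet[2] - snippet[1],
            (snippet[3:n] - snippet[1:(n - 2)]) / 2,
            snippet[n] - snippet[n - 1]) / dt_ms
  data.frame(v = snippet, dvdt = dvdt)
}

#' Exposure/baseline waveform-feature ratios
#'
#' Snippets from the merged baseline + exposure record are sorted once;
#' for each MAJ or AUX unit the cluster-mean snippet is computed per phase
#' and each feature's exposure/baseline ratio is formed. The MEA-level
#' value is the unweighted mean over MAJ and AUX units. Units with fewer
#' than `min_per_phase` spikes in either phase are excluded.
#'
#' @param snippets Snippet matrix (spikes x 40) for one channel, merged
#'   across baseline and exposure.
#' @param times Spike times (s) aligned with the snippet rows.
#' @param labels Cluster labels from [sort_spikes()].
#' @param protocol A [mea_protocol()].
#' @param sampling_rate Hz.
#' @param min_per_phase Minimum spikes per phase for a unit to be used.
#' @return List with `units` (per-unit data.frame of ratios) and `mea`
#'   (named vector: mean ratio over MAJ+AUX units per feature), or NULL
#'   when no unit qualifies.
#' @export
feature_change <- function(snippets, times, labels, protocol,
                           sampling_rate = 10000, min_per_phase = 10) {
  if (is.null(labels)) return(NULL)
  cls <- classify_clusters(labels)
  cls <- cls[cls$class %in% c("MAJ", "AUX"), , drop = FALSE]
  if (!nrow(cls)) return(NULL)
  ph <- phase_of(times, protocol)
  feats <- c("peak", "anti_peak", "fwhm", "rising_slope", "falling_slope")
  rows <- list()
  for (i in seq_len(nrow(cls))) {
    g <- cls$cluster[i]
    bi <- labels == g & ph == "baseline"
    ei <- labels == g & ph == "exposure"
    if (sum(bi) < min_per_phase || sum(ei) < min_per_phase) next
    fb <- waveform_features(colMeans(snippets[bi, , drop = FALSE]), sampling_rate)
    fe <- waveform_features(colMeans(snippets[ei, , drop = FALSE]), sampling_rate)
    ratio <- vapply(feats, function(f) fe[[f]] / fb[[f]], numeric(1))
    rows[[length(rows) + 1]] <-
      cbind(data.frame(cluster = g, class = cls$class[i],
                       n_baseline = sum(bi), n_exposure = sum(ei)),
            as.data.frame(as.list(ratio)))
  }
  if (!length(rows)) return(NULL)
  units <- do.call(rbind, rows)
  mea <- vapply(feats, function(f) mean(units[[f]]), numeric(1))
  list(units = units, mea = mea)
}

#' Waveform analysis of a raw recording
#'
#' Full waveform path for one (typically short, few-channel) recording:
#' zero-phase filtering, PTSD detection, 5-sigma snippet extraction, spike
#' sorting on the merged baseline + exposure snippets, MAJ/AUX/MIN
#' classification and exposure/baseline feature ratios per channel.
#'
#' @param recording An `mea_recording`.
#' @param protocol A [mea_protocol()] matching the recording.
#' @param params A [detection_params()].
#' @return List with `channels` (per-channel list: labels, classes,
#'   feature ratios) and `mea` (feature ratios averaged over all MAJ+AUX
#'   units of all channels).
#' @export
analyze_waveforms <- function(recording, protocol,
                              params = detection_params()) {
  det <- detect_spikes(recording, params, snippets = TRUE)
  fs <- recording$sampling_rate
  per_ch <- vector("list", length(det$snippets))
  unit_rows <- list()
  for (j in seq_along(det$snippets)) {
    sn <- det$snippets[[j]]
    labels <- sort_spikes(sn$snippets)
    fc <- feature_change(sn$snippets, sn$times, labels, protocol, fs)
    per_ch[[j]] <- list(labels = labels,
                        classes = if (!is.null(labels))
                          classify_clusters(labels) else NULL,
                        change = fc)
    if (!is.null(fc)) unit_rows[[length(unit_rows) + 1]] <-
      cbind(channel = j, fc$units)
  }
  units <- if (length(unit_rows)) do.call(rbind, unit_rows) else NULL
  feats <- c("peak", "anti_peak", "fwhm", "rising_slope", "falling_slope")
  mea <- if (!is.null(units))
    vapply(feats, function(f) mean(units[[f]]), numeric(1)) else NULL
  list(channels = per_ch, units = units, mea = mea)
}
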