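# Shared fixtures: small protocols and hand-built objects used across tests.

small_protocol <- function(n_channels = 8)
  mea_protocol(600, 300, 300, n_channels = n_channels)

# a spike train with perfectly regular bursts: n_bursts bursts of
# n_spikes spikes at intra_isi (s), separated by gap (s), starting at t0
regular_burst_train <- function(n_bursts = 10, n_spikes = 10,
                                intra_isi = 0.005, gap = 2, t0 = 0.5) {
  starts <- t0 + (seq_len(n_bursts) - 1) * (gap + (n_spikes - 1) * intra_isi)
  sort(unlist(lapply(starts, function(s)
    s + (seq_len(n_spikes) - 1) * intra_isi)))
}

# burst table from explicit per-channel interval lists
make_bursts <- function(channel, start, end, n_spikes,
                        network = rep(NA, length(start))) {
  out <- data.frame(channel = channel, start = start, end = end,
                    n_spikes = n_spikes, network = network)
  class(out) <- c("mea_bursts", "data.frame")
  out
}

# total intersection / union length of two interval sets (matrices with
# columns start, end) -- brute-force oracle for burst overlap
interval_jaccard <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  if (length(grid) < 2) return(NA_real_)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  w <- diff(grid)
  ina <- sapply(mids, function(m) any(m >= a[, 1] & m < a[, 2]))
  inb <- sapply(mids, function(m) any(m >= b[, 1] & m < b[, 2]))
  sum(w[ina & inb]) / sum(w[ina | inb])
}

# minute-binned time course object built directly (for the closed-form
# slope / PIR cases)
make_timecourse <- function(norm, phase, bin_width = 60) {
  t_start <- (seq_along(norm) - 1) * bin_width
  structure(data.frame(t_start = t_start, t_mid = t_start + bin_width / 2,
                       phase = factor(phase,
                                      levels = c("baseline", "exposure", "post")),
                       rate = norm, norm = norm),
            bin_width = bin_width, baseline_mean = 1,
            class = c("mea_timecourse", "data.frame"))
}

# Monte-Carlo permutation oracle for a pairwise Conover comparison: permute
# group labels, recompute the Conover t for the pair, two-sided tail fraction
perm_conover_p <- function(values, groups, pair, B = 4000, seed = 1) {
  conover_t <- function(v, g) {
    g <- factor(g); r <- rank(v); N <- length(v)
    n_i <- tabulate(g); rbar <- tapply(r, g, mean)
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    H <- kruskal_wallis(v, g)$H
    se <- sqrt(S2 * (N - 1 - H) / (N - nlevels(g)) *
                 (1 / n_i[pair[1]] + 1 / n_i[pair[2]]))
    (rbar[pair[1]] - rbar[pair[2]]) / se
  }
  obs <- abs(conover_t(values, groups))
  set.seed(seed)
  hits <- sum(replicate(B, abs(conover_t(values, sample(groups))) >= obs - 1e-12))
  (hits + 1) / (B + 1)
}

# noise-free biphasic test snippet: Gaussian trough (depth uV, sd in ms)
# plus optional after-peak, sampled at fs over the standard 40-sample window
gaussian_snippet <- function(depth = 20, sd_ms = 0.2, peak = 0, fs = 10000) {
  t_ms <- (-8:31) / fs * 1000
  -depth * exp(-t_ms^2 / (2 * sd_ms^2)) +
    peak * exp(-(t_ms - 1)^2 / (2 * 0.3^2))
}
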