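make_rec <- function(x, fs = 10000) {
  n <- length(x)
  new_recording(matrix(x, ncol = 1), fs,
                phase_boundaries = c(n / fs / 3, 2 * n / fs / 3))
}

test_that("the high-pass filter removes DC exactly and respects its response", {
  fs <- 10000
  t <- seq(0, 5, by = 1 / fs)[-1]
  expect_lt(max(abs(highpass_filter(make_rec(rep(3.7, length(t))))$data)), 1e-9)
  # 1 Hz attenuated by > 40 dB
  slow <- highpass_filter(make_rec(sin(2 * pi * 1 * t)))$data[, 1]
  mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  expect_lt(max(abs(slow[mid])), 10^(-40 / 20))
  # 1 kHz passed within 1% (compare to the sampled input amplitude)
  x1k <- sin(2 * pi * 1000 * t)
  fast <- highpass_filter(make_rec(x1k))$data[, 1]
  expect_lt(abs(max(abs(fast[mid])) / max(abs(x1k[mid])) - 1), 0.01)
  expect_error(highpass_filter(make_rec(rep(0, 100), fs = 100)), "Nyquist")
})

test_that("the MAD noise estimator is accurate and robust", {
  set.seed(3)
  x <- rnorm(1e5, sd = 3)
  expect_lt(abs(estimate_noise_sd(x) / 3 - 1), 0.05)
  expect_equal(estimate_noise_sd(rep(0, 1000)), 0)
  # 1% spike contamination moves the estimate by < 5%
  xc <- x
  idx <- sample(1e5, 1e3)
  xc[idx] <- xc[idx] - 30
  expect_lt(abs(estimate_noise_sd(xc) / estimate_noise_sd(x) - 1), 0.05)
})

test_that("PTSD finds a lone biphasic pulse at its trough sample", {
  fs <- 10000
  x <- rep(0, 10000)
  x[5001] <- -10  # 0-based sample 5000
  x[5004] <- 3
  st <- detect_spikes_ptsd(x, fs, noise_sd = 1)
  expect_equal(st, 5000 / fs)
  expect_length(detect_spikes_ptsd(rep(0, 1000), fs, noise_sd = 1), 0)
})

test_that("sub-threshold excursions are not detected", {
  fs <- 10000
  x <- rep(0, 2000)
  x[1001] <- -4; x[1005] <- 3.5  # peak-to-peak 7.5 < 8 x sd
  expect_length(detect_spikes_ptsd(x, fs, noise_sd = 1), 0)
})

test_that("events inside the refractory period collapse to the larger one", {
  fs <- 10000
  x <- rep(0, 2000)
  x[1001] <- -10
  x[1006] <- -12  # 0.5 ms later, deeper
  st <- detect_spikes_ptsd(x, fs, noise_sd = 1)
  expect_equal(st, 1005 / fs)
})

test_that("detection is translation-equivariant", {
  fs <- 10000
  set.seed(4)
  x <- rnorm(20000)
  spikes <- c(4000, 9000, 15000)
  x[spikes + 1] <- x[spikes + 1] - 15
  k <- 137
  st1 <- detect_spikes_ptsd(x, fs, noise_sd = 1)
  st2 <- detect_spikes_ptsd(c(rep(0, k), x), fs, noise_sd = 1)
  keep <- st2 >= k / fs
  expect_equal(st2[keep], st1 + k / fs, tolerance = 1e-12)
})

test_that("snippet extraction applies the window, edge and 5-sigma rules", {
  fs <- 10000
  x <- rnorm(5000, sd = 1)
  x[1001] <- -20    # snippable
  x[2001] <- -4.9   # below 5 sigma
  x[4] <- -20       # too close to the start (sample 3, 0-based)
  out <- extract_snippets(x, c(3, 1000, 2000) / fs, fs, noise_sd = 1)
  expect_equal(ncol(out$snippets), 40)
  expect_equal(nrow(out$snippets), 1)
  expect_equal(out$times, 1000 / fs)
  expect_equal(out$n_dropped_edge, 1)
  expect_equal(out$n_below_threshold, 1)
  expect_equal(out$snippets[1, 9], x[1001])  # trough at position 9 (8 before)
})

test_that("detection on rendered recordings reaches 95% sensitivity at 8x noise", {
  proto <- mea_protocol(10, 10, 10, n_channels = 2)
  stats <- sapply(1:3, function(s) {
    set.seed(400 + s)
    times <- lapply(1:2, function(i) sort(runif(60, 0.1, 29.9)))
    # enforce 3 ms separation so ground truth is unambiguous
    times <- lapply(times, function(tt) tt[c(TRUE, diff(tt) > 0.003)])
    trains <- mea_spiketrains(times, protocol = proto)
    bank <- waveform_bank(lapply(1:2, function(i)
      list(waveform_template(24, 0.5))), noise_sd = 3)  # 8 x noise sd
    rec <- render_raw_recording(trains, bank, proto, builtin_presets()$sham,
                                seed = 400 + s)
    det <- detect_spikes(rec)
    res <- sapply(1:2, function(ch) {
      truth <- times[[ch]]
      found <- det$trains$times[[ch]]
      hits <- sum(sapply(truth, function(t0) any(abs(found - t0) <= 5e-4)))
      fp <- sum(sapply(found, function(t0) all(abs(truth - t0) > 5e-4)))
      c(sens = hits / length(truth),
        fdr = if (length(found)) fp / length(found) else 0)
    })
    rowMeans(res)
  })
  expect_gte(mean(stats["sens", ]), 0.95)
  expect_lte(mean(stats["fdr", ]), 0.05)
})
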