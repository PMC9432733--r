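test_that("protocol validation rejects degenerate inputs", {
  expect_error(mea_protocol(baseline_duration = 0), "duration")
  expect_error(mea_protocol(n_channels = 0), "n_channels")
  p <- mea_protocol()
  expect_equal(p$t_exposure_on, 1800)
  expect_equal(p$t_exposure_off, 2700)
  expect_equal(phase_window(p, "exposure"), c(1800, 2700))
  expect_equal(as.character(phase_of(c(0, 1800, 2699.9, 2700), p)),
               c("baseline", "exposure", "exposure", "post"))
})

test_that("built-in presets encode the treatment mechanisms", {
  p <- builtin_presets()
  sham <- p$sham
  expect_true(all(c(sham$burst_rate_scale, sham$background_rate_scale,
                    sham$burst_duration_scale, sham$intra_burst_rate_scale,
                    sham$jitter_scale, sham$ap_halfwidth_scale) == 1))
  expect_false(sham$rebound)
  expect_true(p$mu$rebound)
  expect_false(p$rf$rebound)
  expect_gt(p$mu$jitter_scale, p$rf$jitter_scale)
})

test_that("sham preset leaves the expected burst rate unchanged across phases", {
  proto <- small_protocol(20)
  events <- unlist(lapply(1:6, function(s) {
    sim <- generate_spike_trains(proto, network_model(),
                                 builtin_presets()$sham, seed = 100 + s)
    gt <- sim$ground_truth
    c(sum(gt$start < 600), sum(gt$start >= 600 & gt$start < 900))
  }))
  base_rate <- sum(events[c(TRUE, FALSE)]) / (6 * 600)
  exp_rate <- sum(events[c(FALSE, TRUE)]) / (6 * 300)
  expect_lt(abs(exp_rate / base_rate - 1), 0.1)
})

test_that("full participation with no isolated bursts yields only network bursts", {
  proto <- mea_protocol(300, 60, 60, n_channels = 6)
  mod <- network_model(burst_participation = 1, isolated_burst_fraction = 0)
  sim <- generate_spike_trains(proto, mod, builtin_presets()$sham, seed = 7)
  expect_true(all(sim$ground_truth$network))
  # every event present on (nearly) all channels: counts equal across channels
  cnt <- table(sim$ground_truth$channel)
  expect_equal(length(cnt), 6)
  expect_lt(diff(range(cnt)) / mean(cnt), 0.05)
})

test_that("mean per-channel ground-truth burst count matches the Poisson expectation", {
  # 12 events/min x 30 min x participation 0.8 = 288 per channel; short
  # bursts keep overlap pruning negligible
  proto <- mea_protocol(1800, 1, 1, n_channels = 60)
  mod <- network_model(network_burst_rate = 12, burst_participation = 0.8,
                       isolated_burst_fraction = 0,
                       burst_duration_mean = 0.02, intra_burst_rate = 500)
  counts <- sapply(1:12, function(s) {
    gt <- generate_spike_trains(proto, mod, builtin_presets()$sham,
                                seed = 200 + s)$ground_truth
    mean(table(factor(gt$channel[gt$start < 1800], levels = 1:60)))
  })
  expect_lt(abs(mean(counts) - 288), 15)
})

test_that("ground truth respects the protocol window and never overlaps in a channel", {
  sim <- generate_spike_trains(small_protocol(), network_model(),
                               builtin_presets()$mu, seed = 3)
  gt <- sim$ground_truth
  expect_true(all(gt$end > gt$start))
  expect_true(all(gt$start >= 0 & gt$end <= 1200))
  for (ch in unique(gt$channel)) {
    b <- gt[gt$channel == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  for (ch in seq_along(sim$trains$times)) {
    st <- sim$trains$times[[ch]]
    expect_true(all(st > 0 & st < 1200))
    expect_true(all(diff(st) > 0))
  }
})

test_that("the network-burst fraction sits in the 60-80% band under defaults", {
  fr <- sapply(1:3, function(s) {
    gt <- generate_spike_trains(small_protocol(30), network_model(),
                                builtin_presets()$sham,
                                seed = 300 + s)$ground_truth
    mean(gt$network)
  })
  expect_true(all(fr >= 0.6 & fr <= 0.8))
})

test_that("the generator is byte-deterministic in its seed", {
  a <- generate_spike_trains(small_protocol(4), network_model(),
                             builtin_presets()$mu, seed = 11)
  b <- generate_spike_trains(small_protocol(4), network_model(),
                             builtin_presets()$mu, seed = 11)
  expect_identical(a, b)
  c <- generate_spike_trains(small_protocol(4), network_model(),
                             builtin_presets()$mu, seed = 12)
  expect_false(identical(a$trains$times, c$trains$times))
})

test_that("effect weight is 0 at baseline, saturating in exposure, decaying post", {
  proto <- mea_protocol(100, 100, 100)
  pre <- effect_preset("x", onset_time_constant = 10)
  expect_equal(effect_weight(c(0, 50, 99.9), proto, pre), rep(0, 3))
  w <- effect_weight(c(100, 110, 190, 200, 210), proto, pre)
  expect_equal(w[1], 0, tolerance = 1e-12)
  expect_equal(w[2], 1 - exp(-1))
  expect_gt(w[3], 0.99)
  expect_equal(w[5], w[4] * exp(-1), tolerance = 1e-9)
})
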