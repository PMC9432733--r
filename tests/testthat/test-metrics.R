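toy_protocol <- mea_protocol(60, 30, 30, n_channels = 2)

# two hand-built channels: all quantities below are hand-computed
toy_trains <- local({
  ch1 <- sort(c(seq(5, 5.2, length.out = 30), seq(20, 20.4, length.out = 60),
                seq(40, 58, length.out = 10),        # baseline background
                seq(61, 61.2, length.out = 30),       # exposure burst
                seq(70, 88, length.out = 10)))        # exposure background
  ch2 <- sort(c(seq(10, 10.1, length.out = 20),
                seq(30, 55, length.out = 5),
                seq(65, 65.1, length.out = 20),
                seq(75, 88, length.out = 5)))
  mea_spiketrains(list(ch1, ch2), protocol = toy_protocol)
})

toy_bursts <- make_bursts(
  channel = c(1L, 1L, 2L, 1L, 2L),
  start = c(5, 20, 10, 61, 65),
  end = c(5.2, 20.4, 10.1, 61.2, 65.1),
  n_spikes = c(30L, 60L, 20L, 30L, 20L))

test_that("the metric panel matches the hand-computed toy example", {
  p <- compute_panel(toy_trains, toy_bursts, toy_protocol, "baseline", 1:2)
  expect_equal(p$mbr, c(2, 1))                    # bursts/min
  expect_equal(p$ibi, c(20 - 5.2, NA))            # end-to-next-start gap
  expect_equal(p$bd, c(0.3, 0.1))
  expect_equal(p$ibsr, c(90 / 0.6, 20 / 0.1))
  expect_equal(p$msr, c(10 / (60 - 0.6), 5 / (60 - 0.1)))
  pooled <- pooled_values(p)
  expect_equal(pooled[["mbr"]], 1.5)
  expect_equal(pooled[["ibi"]], 14.8)             # NA excluded from pooling
  expect_equal(pooled[["ibsr"]], 175)
})

test_that("simple panel arithmetic: 15 bursts in 15 min is 1/min; 30 spikes in 0.2 s is 150/s", {
  proto <- mea_protocol(900, 60, 60, n_channels = 1)
  starts <- seq(10, 850, length.out = 15)
  tt <- sort(unlist(lapply(starts, function(s) seq(s, s + 0.2, length.out = 30))))
  tr <- mea_spiketrains(list(tt), protocol = proto)
  b <- make_bursts(rep(1L, 15), starts, starts + 0.2, rep(30L, 15))
  p <- compute_panel(tr, b, proto, "baseline", 1)
  expect_equal(p$mbr, 1)
  expect_equal(p$ibsr, 150)
})

test_that("normalisation is the exposure/baseline ratio with zero-baseline flagging", {
  pb <- compute_panel(toy_trains, toy_bursts, toy_protocol, "baseline", 1:2)
  r_self <- normalize_panel(pb, pb)
  expect_true(all(r_self$R[r_self$level == "pooled"] == 1))
  pe <- compute_panel(toy_trains, toy_bursts, toy_protocol, "exposure", 1:2)
  r <- normalize_panel(pe, pb)
  expect_equal(r$R[r$metric == "mbr" & r$level == "pooled"],
               mean(c(2, 2)) / 1.5)  # 1 burst / 30 s = 2 per min on both
  # a zero-baseline metric is flagged undefined
  pb0 <- pb; pb0$msr <- c(0, 0)
  attr(pb0, "pooled")["msr"] <- 0
  r0 <- normalize_panel(pe, pb0)
  expect_true(all(is.na(r0$R[r0$metric == "msr"])))
})

test_that("active channels require both spiking and bursting at baseline", {
  proto <- mea_protocol(100, 10, 10, n_channels = 3)
  tr <- mea_spiketrains(list(
    numeric(0),                       # silent
    seq(1, 99, by = 0.25),            # spiking but no bursts
    sort(c(seq(10, 10.2, length.out = 20), seq(50, 50.2, length.out = 20)))),
    protocol = proto)
  b <- make_bursts(c(3L, 3L), c(10, 50), c(10.2, 50.2), c(20L, 20L))
  expect_equal(active_channel_filter(tr, b, proto), 3L)
  expect_error(active_channel_filter(tr, make_bursts(integer(0), numeric(0),
                                                     numeric(0), integer(0)),
                                     proto), "no active channels")
})

test_that("the synchrony CV matches direct arithmetic and degenerate cases", {
  proto <- mea_protocol(10, 1, 1, n_channels = 2)
  tr <- mea_spiketrains(list(numeric(0), numeric(0)), protocol = proto)
  # per-channel burst-duration sds {0.2, 0.4} around mean 1 -> CV = 30%
  b <- make_bursts(c(1L, 1L, 1L, 2L, 2L, 2L),
                   start = c(0.5, 2.5, 5, 0.5, 2.5, 5),
                   end = c(0.5 + 0.8, 2.5 + 1.0, 5 + 1.2,
                           0.5 + 0.6, 2.5 + 1.0, 5 + 1.4),
                   n_spikes = rep(10L, 6))
  expect_equal(cv_sync(tr, b, proto, "baseline", "bd", 1:2), 30)
  # identical bursts on all channels -> CV = 0
  b0 <- make_bursts(c(1L, 1L, 2L, 2L), c(1, 4, 1, 4), c(1.3, 4.3, 1.3, 4.3),
                    rep(10L, 4))
  expect_equal(cv_sync(tr, b0, proto, "baseline", "bd", 1:2), 0)
  # CV is invariant to channel relabeling
  b_sw <- b; b_sw$channel <- 3L - b$channel
  expect_equal(cv_sync(tr, b_sw, proto, "baseline", "bd", 1:2),
               cv_sync(tr, b, proto, "baseline", "bd", 1:2))
})

test_that("norm_rmse reproduces the worked examples and its invariances", {
  expect_equal(norm_rmse(c(1, 1, 1)), 0)
  expect_equal(norm_rmse(c(0.5, 1.5), Y = 1), 0.5)
  expect_equal(norm_rmse(c(0.8, 1.2), Y = 1), 0.2)
  expect_true(is.na(norm_rmse(c(-1, 1), Y = 0)))
  set.seed(6)
  for (i in 1:10) {
    y <- runif(8, 0.2, 2)
    c0 <- runif(1, 0.1, 10)
    expect_equal(norm_rmse(c0 * y), norm_rmse(y), tolerance = 1e-12)
  }
})

test_that("spike counts are conserved between in- and out-of-burst pools", {
  sim <- generate_spike_trains(small_protocol(6), network_model(),
                               builtin_presets()$mu, seed = 21)
  det <- detect_bursts_all(sim$trains)
  proto <- small_protocol(6)
  for (ch in 1:6) {
    for (ph in c("baseline", "exposure", "post")) {
      win <- phase_window(proto, ph)
      st <- sim$trains$times[[ch]]
      st <- st[st >= win[1] & st < win[2]]
      b <- det[det$channel == ch & det$start >= win[1] & det$start < win[2], ]
      inb <- sum(sapply(st, function(t0)
        any(t0 >= b$start & t0 <= b$end)))
      expect_equal(sum(b$n_spikes) + (length(st) - inb), length(st))
    }
  }
})

test_that("time courses are flat at 1 for homogeneous activity and step with the rate", {
  proto <- small_protocol(1)
  tr <- mea_spiketrains(list(seq(0.05, 1199.95, by = 0.1)), protocol = proto)
  tc <- time_course(tr, proto, 60)
  expect_equal(nrow(tc), 20)
  expect_true(all(abs(tc$norm - 1) < 1e-9))
  # rate halves at the phase boundary
  tr2 <- mea_spiketrains(list(sort(c(seq(0.05, 599.95, by = 0.1),
                                     seq(600.1, 1199.9, by = 0.2)))),
                         protocol = proto)
  tc2 <- time_course(tr2, proto, 60)
  expect_true(all(abs(tc2$norm[tc2$phase == "baseline"] - 1) < 0.01))
  expect_true(all(abs(tc2$norm[tc2$phase != "baseline"] - 0.5) < 0.01))
  expect_error(time_course(tr, proto, 2000), "shorter")
})

test_that("the initial inhibitory rate is the OLS slope over early exposure bins", {
  flat <- make_timecourse(rep(1, 12), rep(c("baseline", "exposure", "post"),
                                          c(5, 5, 2)))
  expect_equal(initial_inhibitory_rate(flat), 0)
  drop <- make_timecourse(c(rep(1, 5), 1, 0.875, 0.75, 0.625, 0.5, 0.5, 0.5),
                          rep(c("baseline", "exposure", "post"), c(5, 5, 2)))
  expect_equal(initial_inhibitory_rate(drop), -0.125)
})

test_that("PIR distinguishes recovery from genuine rebound", {
  phases <- rep(c("baseline", "exposure", "post"), c(3, 5, 3))
  # inhibited to 0.5, washout keeps 0.5: exposure-referenced PIR = 1,
  # baseline-referenced PIR = 0.5
  no_change <- make_timecourse(c(rep(1, 3), rep(0.5, 5), rep(0.5, 3)), phases)
  expect_equal(postinhibitory_rebound(no_change, reference = "exposure"), 1)
  expect_equal(postinhibitory_rebound(no_change, reference = "baseline"), 0.5)
  # overshoot to 1.8 in the first post bin
  reb <- make_timecourse(c(rep(1, 3), rep(0.5, 5), 1.8, 1, 1), phases)
  expect_equal(postinhibitory_rebound(reb), 1.8)
  expect_equal(postinhibitory_rebound(reb, reference = "exposure"), 3.6)
  # an all-zero exposure floor is flagged undefined
  dead <- make_timecourse(c(rep(1, 3), rep(0, 5), 1, 1, 1), phases)
  expect_true(is.na(postinhibitory_rebound(dead, reference = "exposure")))
})
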