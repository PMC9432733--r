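test_that("waveform features recover exact geometry of a triangular trough", {
  # descend 0 -> -10 over 4 samples, symmetric ascent: half-depth crossings
  # 0.2 ms either side of the trough -> FWHM = 0.4 ms at 10 kHz
  sn <- rep(0, 40)
  sn[17:25] <- c(-2.5, -5, -7.5, -10, -7.5, -5, -2.5, 0, 0)[1:9]
  f <- waveform_features(sn, 10000)
  expect_equal(f$anti_peak, 10)
  expect_equal(f$fwhm, 0.4)
  expect_equal(f$rising_slope, 25)   # 2.5 uV per 0.1 ms step
  expect_equal(f$falling_slope, 25)
})

test_that("a Gaussian trough has FWHM 2.3548 sigma within one sample", {
  sn <- gaussian_snippet(depth = 20, sd_ms = 0.2)
  f <- waveform_features(sn, 10000)
  expect_lt(abs(f$fwhm - 2 * sqrt(2 * log(2)) * 0.2), 0.1)
  # trough tail slightly depresses the 4-sample baseline estimate
  expect_equal(f$anti_peak, 20, tolerance = 0.02)
})

test_that("features scale linearly in amplitude with FWHM unchanged", {
  sn <- gaussian_snippet(depth = 15, sd_ms = 0.25, peak = 4)
  f1 <- waveform_features(sn, 10000)
  f2 <- waveform_features(2 * sn, 10000)
  expect_equal(f2$anti_peak, 2 * f1$anti_peak)
  expect_equal(f2$peak, 2 * f1$peak)
  expect_equal(f2$rising_slope, 2 * f1$rising_slope)
  expect_equal(f2$falling_slope, 2 * f1$falling_slope)
  expect_equal(f2$fwhm, f1$fwhm)
})

test_that("a snippet without a trough below baseline is a feature error", {
  expect_error(waveform_features(seq(0, 39) / 10, 10000), "feature error")
})

test_that("cluster classification follows the MAJ/AUX/MIN fraction rules", {
  labels <- rep(c(1L, 2L, 3L), c(70, 20, 10))
  cls <- classify_clusters(labels)
  expect_equal(cls$class, c("MAJ", "AUX", "MIN"))
  expect_equal(classify_clusters(rep(1L, 30))$class, "MAJ")
  # exact tie: lower cluster index wins MAJ
  tie <- classify_clusters(rep(c(2L, 1L), c(25, 25)))
  expect_equal(tie$class[tie$cluster == 1], "MAJ")
  expect_equal(tie$class[tie$cluster == 2], "AUX")
  # unsorted (0) labels are excluded from fractions
  cls0 <- classify_clusters(c(rep(0L, 50), rep(1L, 10)))
  expect_equal(cls0$fraction, 1)
})

test_that("sorting separates distinct templates and is permutation-stable", {
  set.seed(8)
  t_ms <- (-8:31) / 10
  a <- -40 * exp(-t_ms^2 / (2 * 0.2^2)) + 10 * exp(-(t_ms - 1)^2 / (2 * 0.3^2))
  b <- -22 * exp(-t_ms^2 / (2 * 0.35^2)) + 6 * exp(-(t_ms - 1)^2 / (2 * 0.3^2))
  n1 <- 120; n2 <- 60
  sn <- rbind(matrix(rep(a, n1), n1, byrow = TRUE),
              matrix(rep(b, n2), n2, byrow = TRUE)) +
    matrix(rnorm(40 * (n1 + n2), sd = 3), n1 + n2)
  truth <- rep(c(1L, 2L), c(n1, n2))
  labels <- sort_spikes(sn)
  sorted <- labels > 0
  expect_gte(mean(sorted), 0.9)
  expect_equal(length(unique(labels[sorted])), 2)
  agree <- max(mean((labels == labels[1])[sorted] == (truth == 1L)[sorted]),
               mean((labels != labels[1])[sorted] == (truth == 1L)[sorted]))
  expect_gte(agree, 0.9)
  # permutation of snippet order permutes labels consistently
  perm <- sample(n1 + n2)
  lp <- sort_spikes(sn[perm, ])
  tab <- table(lp, labels[perm])
  expect_equal(sum(apply(tab, 1, max)), sum(tab))
})

test_that("a single-template channel sorts into one cluster with >= 95% sorted", {
  set.seed(9)
  t_ms <- (-8:31) / 10
  a <- -45 * exp(-t_ms^2 / (2 * 0.25^2)) + 12 * exp(-(t_ms - 1)^2 / (2 * 0.3^2))
  sn <- matrix(rep(a, 150), 150, byrow = TRUE) + matrix(rnorm(6000, sd = 3), 150)
  labels <- sort_spikes(sn)
  expect_equal(length(unique(labels[labels > 0])), 1)
  expect_gte(mean(labels > 0), 0.95)
  # too few snippets: channel skipped
  expect_null(sort_spikes(sn[1:10, ]))
})

test_that("phase plots are degenerate for constants and elliptical for sinusoids", {
  pp0 <- phase_plot(rep(2, 40), 10000)
  expect_true(all(pp0$dvdt == 0))
  fs <- 10000
  tt <- (0:39) / fs
  A <- 10; f0 <- 250
  pp <- phase_plot(A * sin(2 * pi * f0 * tt), fs)
  omega_ms <- 2 * pi * f0 / 1000
  ell <- (pp$v / A)^2 + (pp$dvdt / (A * omega_ms))^2
  expect_lt(max(abs(ell[3:38] - 1)), 0.05)
  # narrowing a template at fixed amplitude raises max |dV/dt|
  wide <- phase_plot(gaussian_snippet(20, 0.3), fs)
  narrow <- phase_plot(gaussian_snippet(20, 0.2), fs)
  expect_gt(max(abs(narrow$dvdt)), max(abs(wide$dvdt)))
})

test_that("feature ratios track the rendered half-width change", {
  proto <- mea_protocol(60, 60, 30, n_channels = 1)
  set.seed(10)
  tt <- sort(c(runif(80, 1, 59), runif(80, 61, 119)))
  tt <- tt[c(TRUE, diff(tt) > 0.005)]
  trains <- mea_spiketrains(list(tt), protocol = proto)
  bank <- waveform_bank(list(list(waveform_template(45, 0.5))), noise_sd = 2)
  pre <- effect_preset("narrow", ap_halfwidth_scale = 0.9,
                       onset_time_constant = 1e-3)
  rec <- render_raw_recording(trains, bank, proto, pre, seed = 10)
  det <- detect_spikes(rec, snippets = TRUE)
  sn <- det$snippets[[1]]
  # single known unit: constrain the mixture so the deliberate width change
  # is measured as a within-unit phase ratio, not split into phase clusters
  labels <- sort_spikes(sn$snippets, max_clusters = 1)
  fc <- feature_change(sn$snippets, sn$times, labels, proto)
  expect_false(is.null(fc))
  expect_equal(unname(fc$mea["fwhm"]), 0.9, tolerance = 0.03)
  expect_equal(unname(fc$mea["anti_peak"]), 1, tolerance = 0.05)
  expect_gt(fc$mea[["rising_slope"]], 1)
  expect_gt(fc$mea[["falling_slope"]], 1)
  # identical phases give unit ratios: reuse baseline snippets for both
  half <- sn$times < 60
  fc1 <- feature_change(rbind(sn$snippets[half, ], sn$snippets[half, ]),
                        c(sn$times[half], sn$times[half] + 60),
                        rep(1L, 2 * sum(half)), proto)
  expect_true(all(abs(unlist(fc1$mea) - 1) < 1e-9))
})

test_that("MAJ and AUX clusters hold most sorted spikes on generator defaults", {
  proto <- mea_protocol(120, 60, 30, n_channels = 3)
  sim <- generate_spike_trains(proto,
                               network_model(network_burst_rate = 20,
                                             background_rate = 1.5),
                               builtin_presets()$sham, seed = 14)
  bank <- default_waveform_bank(3, seed = 14)
  rec <- render_raw_recording(sim$trains, bank, proto,
                              builtin_presets()$sham, seed = 14)
  det <- detect_spikes(rec, snippets = TRUE)
  fracs <- c()
  for (ch in 1:3) {
    labels <- sort_spikes(det$snippets[[ch]]$snippets)
    if (is.null(labels)) next
    cls <- classify_clusters(labels)
    fracs <- c(fracs, sum(cls$fraction[cls$class %in% c("MAJ", "AUX")]))
  }
  expect_true(length(fracs) >= 2)
  expect_gte(mean(fracs), 0.8)
})
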