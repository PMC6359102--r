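test_that("extremum detection handles flats, spikes, and separation", {
  expect_length(detect_extrema(rep(1, 10), "maxima"), 0)
  x <- numeric(21); x[11] <- 1
  expect_equal(detect_extrema(x, "maxima"), 11L)
  expect_equal(detect_extrema(-x, "minima"), 11L)
  expect_error(detect_extrema(c(1, 2), "maxima"), "at least 3")

  # sinusoid with 0.8 s period over 3 s at 128 Hz: 3-4 maxima ~102 apart
  t <- (0:383) / 128
  x <- sin(2 * pi * t / 0.8)
  pk <- detect_extrema(x, "maxima", min_separation = round(0.3 * 128))
  expect_true(length(pk) %in% c(3L, 4L))
  expect_true(all(abs(diff(pk) - 102.4) < 3))
  # analytic positions: maxima at t = 0.2 + 0.8 k
  expect_true(all(abs((pk - 1) / 128 - (0.2 + 0.8 * (seq_along(pk) - 1)))
                  < 2 / 128))

  # among close extrema the more extreme wins
  y <- c(0, 1, 0, 0.5, 0, 2, 0)
  expect_equal(detect_extrema(y, "maxima", min_separation = 3), c(2L, 6L))
})

test_that("IBI statistics recover the configured pulse train", {
  rec <- gen_bvp_signal(0, duration = 3, fs = 128, seed = 5,
                        base_ibi = 0.8, ibi_jitter_sd = 0)
  b <- wavelet_packet_split(rec$samples, "db4", 5)
  f <- ibi_features(b$low, 128)
  expect_gt(f$ibi_mean, 0.76)
  expect_lt(f$ibi_mean, 0.84)
  # constant spacing: spread bounded by trough-localization quantization
  # (band ripple shifts the argmin by up to ~3 samples)
  expect_lt(f$ibi_sd, 0.03)

  expect_error(ibi_features(rep(0, 384), 128), "insufficient beats")
})

test_that("exactly two diastolic points give a single IBI with zero spread", {
  # three systolic peaks -> two troughs -> one interval
  t <- (0:383) / 128
  x <- cos(2 * pi * (t - 0.5))
  f <- ibi_features(x, 128)
  expect_equal(f$ibi_sd, 0)
})

test_that("third-order cumulant equals the brute-force triple sum", {
  x <- c(1, -1, 2, 0)
  expect_equal(third_order_cumulant(x, c(0, 0)), brute_c3(x, 0, 0),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(16:256, 1))
    lags <- sample(-4:4, 2, replace = TRUE)
    expect_equal(third_order_cumulant(x, lags),
                 brute_c3(x, lags[1], lags[2]), tolerance = 1e-10)
  }
  # symmetric signals have vanishing odd moments
  t <- (0:255) / 64
  s <- sin(2 * pi * 3 * t + 0.7)
  expect_lt(abs(third_order_cumulant(s, c(0, 0))), 1e-6 * length(s))
  expect_equal(third_order_cumulant(rep(2, 50)), 0)
  expect_error(third_order_cumulant(rnorm(5), c(5, 0)), "lag exceeds")
})

test_that("cumulant lattice matches elementwise evaluation", {
  set.seed(9)
  x <- rnorm(64)
  lat <- cumulant_lattice(x, max_lag = 2)
  expect_equal(dim(lat), c(5, 5))
  expect_equal(lat["0", "0"], third_order_cumulant(x, c(0, 0)))
  expect_equal(lat["-2", "1"], brute_c3(x, -2, 1), tolerance = 1e-12)
})

test_that("SCR peak features count prominent maxima only", {
  expect_equal(gsr_peak_features(seq(0, 1, length.out = 50), 4),
               list(count = 0L, mean_amplitude = 0))
  # one triangular bump of height h on a flat baseline
  h <- 0.7
  bump <- c(rep(0, 10), seq(0, h, length.out = 6),
            seq(h, 0, length.out = 6)[-1], rep(0, 10))
  p <- gsr_peak_features(bump, 4)
  expect_equal(p$count, 1L)
  expect_equal(p$mean_amplitude, h, tolerance = 1e-9)
  # three injected SCRs, well separated
  rec <- gen_gsr_signal(0.5, duration = 40, fs = 4, seed = 2,
                        event_times = c(5, 17, 29))
  b <- wavelet_packet_split(rec$samples, "db4", 2)
  expect_equal(gsr_peak_features(b$low, 4)$count, 3L)
})

test_that("derivative statistics match a direct differencing oracle", {
  fs <- 4
  ramp <- seq(0, 3, by = 0.25)   # slope 1 in signal units/sample -> a = fs
  d <- derivative_stats(ramp, fs)
  expect_equal(d$d1_mean, 1)     # 0.25 * 4
  expect_equal(d$d1_sd, 0)
  expect_equal(d$d2_mean, 0)
  expect_equal(d$negslope_prop, 0)
  expect_equal(derivative_stats(rev(ramp), fs)$negslope_prop, 1)

  set.seed(21)
  x <- rnorm(40)
  d <- derivative_stats(x, fs)
  d1 <- (x[-1] - x[-length(x)]) * fs
  d2 <- (d1[-1] - d1[-length(d1)]) * fs
  expect_equal(d$d1_mean, mean(d1), tolerance = 1e-12)
  expect_equal(d$d1_sd, sqrt(mean((d1 - mean(d1))^2)), tolerance = 1e-12)
  expect_equal(d$d2_mean, mean(d2), tolerance = 1e-12)
  expect_equal(d$d2_sd, sqrt(mean((d2 - mean(d2))^2)), tolerance = 1e-12)
  expect_equal(d$negslope_prop, mean(d1 < 0), tolerance = 1e-12)
  expect_error(derivative_stats(c(1, 2), fs), "at least 3")
})

test_that("feature extraction is deterministic and complete", {
  seg <- make_segment(0.5, seed = 4)
  f1 <- extract_features(seg)
  f2 <- extract_features(seg)
  expect_identical(f1, f2)
  expect_named(f1, feature_names())
  expect_true(all(is.finite(f1)))
  expect_gte(f1[["gsr_negslope_prop_high"]], 0)
  expect_lte(f1[["gsr_negslope_prop_high"]], 1)

  seg0 <- seg
  seg0$channels$BVP <- rep(0, 384)
  expect_error(extract_features(seg0), "insufficient beats")
  seg1 <- seg; seg1$channels$GSR <- NULL
  expect_error(extract_features(seg1), "both BVP and GSR")
})

test_that("high-stress segments carry more SCR peaks on average", {
  counts <- vapply(1:30, function(s) {
    hi <- gen_gsr_signal(0.9, 30, 4, seed = s)
    lo <- gen_gsr_signal(0.1, 30, 4, seed = s + 500)
    bh <- wavelet_packet_split(hi$samples, "db4", 2)
    bl <- wavelet_packet_split(lo$samples, "db4", 2)
    gsr_peak_features(bh$low, 4)$count - gsr_peak_features(bl$low, 4)$count
  }, numeric(1))
  expect_gt(mean(counts), 0)
})

test_that("min-max scaler maps training range to [0,1] and clips", {
  tab <- data.frame(a = c(2, 4, 6), b = c(1, 1, 1))
  sc <- fit_scaler(tab)
  out <- apply_scaler(sc, tab)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0))
  new <- apply_scaler(sc, data.frame(a = c(0, 8), b = c(5, -5)))
  expect_equal(new$a, c(0, 1))
  expect_equal(new$b, c(0, 0))
  expect_error(fit_scaler(tab[0, ]), "empty")
})

test_that("Stroop label normalization maps 1..8 onto the unit scale", {
  expect_equal(normalize_stroop_label(1), 0)
  expect_equal(normalize_stroop_label(8), 1)
  expect_equal(normalize_stroop_label(5), 4 / 7)
})
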