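test_that("p2p and negative_ratio match hand values", {
  t <- (0:599) / 2000
  expect_equal(p2p(3 * sin(2 * pi * 10 * t)), 6, tolerance = 1e-3)
  expect_equal(p2p(rep(2, 100)), 0)
  expect_equal(p2p(synth_ied(2, 100, 2000)), 100, tolerance = 1)
  expect_error(p2p(numeric(0)), "non-empty")

  expect_equal(negative_ratio(sin(2 * pi * 10 * t)), 0.5, tolerance = 1e-3)
  # mean-zero fixture with min -3, max 1 -> 3/4 (offset removed by centring)
  expect_equal(negative_ratio(c(-3, 1, 1, 1) + 5), 0.75)
  # monophasic negative spike: ratio approaches 1
  expect_gt(negative_ratio(synth_ied(2, 100, 2000)), 0.9)
  expect_true(is.na(negative_ratio(rep(1, 10))))
})

test_that("negative_ratio/p2p invariances under offset and scaling", {
  set.seed(31)
  seg <- rnorm(600)
  expect_equal(negative_ratio(seg + 42), negative_ratio(seg))
  expect_equal(p2p(seg + 42), p2p(seg))
  expect_equal(p2p(3 * seg), 3 * p2p(seg))
  expect_equal(band_power_ratio(5 * seg, 2000, c(2, 8)),
               band_power_ratio(seg, 2000, c(2, 8)))
  expect_equal(band_power_ratio(5 * seg, 2000, c(28, 80)),
               band_power_ratio(seg, 2000, c(28, 80)))
})

test_that("band-power ratios recover pure tones and stay in [0,1]", {
  fs <- 2000
  t <- (0:599) / fs
  expect_gte(band_power_ratio(sin(2 * pi * 5 * t), fs, c(2, 8)), 0.9)
  s50 <- sin(2 * pi * 50 * t)
  expect_gte(band_power_ratio(s50, fs, c(28, 80)), 0.9)
  expect_lte(band_power_ratio(s50, fs, c(2, 8)), 0.05)
  set.seed(32)
  for (k in 1:10) {
    r <- band_power_ratio(rnorm(600), fs, c(28, 80))
    expect_gte(r, 0)
    expect_lte(r, 1)
  }
  expect_true(is.na(band_power_ratio(rep(0, 600), fs, c(2, 8))))
  expect_error(band_power_ratio(rnorm(600), fs, c(8, 2)), "increasing")
})

test_that("ied_rate counts events into 40-s bins", {
  p <- build_protocol("ISP2", 0, 1) # 600 s, 15 bins
  r0 <- ied_rate(numeric(0), p)
  expect_equal(nrow(r0), 15L)
  expect_true(all(r0$value == 0))
  r <- ied_rate(c(5, 15, 35, 45), p)
  expect_equal(r$value[1], 3)
  expect_equal(r$value[2], 1)
  expect_error(ied_rate(c(-1), p), "outside")
})

test_that("ied_rate bin counts match the Poisson mean across seeds", {
  p <- build_protocol("ISP2", 0, 1) # 600 s tiles into 15 bins of 40 s
  means <- vapply(1:50, function(s) {
    set.seed(400 + s)
    ev <- cumsum(rexp(600, rate = 0.5))
    ev <- ev[ev < 600]
    mean(ied_rate(ev, p)$value)
  }, numeric(1))
  # rate 0.5 Hz x 40 s = 20 per bin; 3 sigma of the 50-seed mean
  expect_lt(abs(mean(means) - 20), 3 * sqrt(20 / (50 * 15)))
})

test_that("bin_feature averages per bin and interpolates empty bins", {
  p <- build_protocol("ISP1", 0, 0) # 120 s, 3 bins
  b <- bin_feature(c(20, 60, 100), c(1, 2, 3), p)
  expect_equal(b$value, c(1, 2, 3))
  # empty interior bin between 1.0 and 2.0 -> 1.5
  b2 <- bin_feature(c(20, 100), c(1, 2), p)
  expect_equal(b2$value[2], 1.5)
  expect_true(b2$interpolated[2])
  expect_error(bin_feature(numeric(0), numeric(0), p), "no analyzable")
})

test_that("raising gamma_boost raises background gamma band power", {
  p <- build_protocol("ISP1", 0, 1)
  fs <- 2000
  means <- vapply(c(1, 1.5, 2.5), function(boost) {
    rec <- simulate_recording(p, effect_model(base_rate_hz = 0,
                                              gamma_boost = boost,
                                              artifact_amp = 0),
                              n_channels = 1, fs = fs, seed = 99)
    xf <- preprocess_wideband(rec$signal[1, ], fs)
    # background segments inside the ON phase
    centers <- seq(130, 230, by = 5)
    mean(vapply(centers, function(ct) {
      band_power_ratio(extract_segment(xf, fs, ct), fs, c(28, 80))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
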