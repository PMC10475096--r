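test_that("Butterworth and notch designs match the frozen reference", {
  # expected coefficients frozen from an independent reference
  # implementation (scipy.signal.butter / iirnotch, fs = 2000 Hz)
  bp <- butter_design(2, c(2, 300), "pass", 2000)
  expect_equal(bp$b, c(0.12970981, 0, -0.25941962, 0, 0.12970981),
               tolerance = 1e-7)
  expect_equal(bp$a, c(1, -2.74669423, 2.77238907, -1.30001508, 0.27434097),
               tolerance = 1e-7)
  bs <- butter_design(2, c(80, 120), "stop", 2000)
  expect_equal(bs$b, c(0.91496914, -3.48763151, 5.15343112, -3.48763151,
                       0.91496914), tolerance = 1e-7)
  expect_equal(bs$a, c(1, -3.64278713, 5.14618775, -3.3324759, 0.83718165),
               tolerance = 1e-7)
  nt <- iir_notch(50, 30, 2000)
  expect_equal(nt$b, c(0.99738884, -1.97021865, 0.99738884),
               tolerance = 1e-7)
  expect_equal(nt$a, c(1, -1.97021865, 0.99477767), tolerance = 1e-7)
})

test_that("cascade kills 50 Hz and passes 20 Hz within 1 dB", {
  fs <- 2000
  t <- (0:(10 * fs - 1)) / fs
  s50 <- sin(2 * pi * 50 * t)
  y50 <- preprocess_wideband(s50, fs)
  mid <- seq(2 * fs, 8 * fs) # avoid edges
  expect_lt(sqrt(mean(y50[mid]^2)) / sqrt(mean(s50[mid]^2)), 0.10)

  s20 <- sin(2 * pi * 20 * t)
  y20 <- preprocess_wideband(s20, fs)
  gain_db <- 20 * log10(sqrt(mean(y20[mid]^2)) / sqrt(mean(s20[mid]^2)))
  expect_lt(abs(gain_db), 1)
})

test_that("all-zero input stays zero and shapes are preserved", {
  fs <- 2000
  z <- matrix(0, nrow = 2, ncol = fs)
  out <- preprocess_wideband(z, fs)
  expect_identical(dim(out), dim(z))
  expect_true(all(out == 0))
  expect_error(preprocess_wideband(c(1, NA, 3), fs), "finite")
})

test_that("zero-phase filtering has no group delay on an IED", {
  fs <- 2000
  w <- synth_ied(2, 100, fs)
  x <- c(rep(0, 2 * fs), w, rep(0, 2 * fs))
  y <- preprocess_wideband(x, fs)
  cc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
})

test_that("stop-band filtering is idempotent up to 1%", {
  fs <- 2000
  set.seed(41)
  x <- rnorm(6 * fs)
  y1 <- preprocess_wideband(x, fs)
  y2 <- preprocess_wideband(y1, fs)
  # 90-110 Hz residue (deep in the 80-120 Hz stop band) after one pass vs
  # two passes, relative to the raw power in that band
  mid <- seq(fs, 5 * fs)
  powsb <- function(v) {
    n <- length(v)
    f <- (seq_len(n) - 1) * fs / n
    P <- Mod(fft(v))^2
    sum(P[f >= 90 & f <= 110])
  }
  r1 <- powsb(y1[mid])
  r2 <- powsb(y2[mid])
  tot <- powsb(x[mid])
  expect_lt(abs(r1 - r2) / tot, 0.01)
})

test_that("band edges at or above Nyquist are rejected", {
  cfg <- filter_config(bandpass_hz = c(2, 600))
  expect_error(preprocess_wideband(rnorm(100), 1000, cfg), "Nyquist")
  expect_error(filter_config(bandpass_hz = c(300, 2)), "increasing")
})

test_that("group_channels forms four distance-ordered groups", {
  lay <- ecog_layout(32)
  g <- group_channels(lay)
  expect_equal(sum(g == "Group#1"), 4L)
  expect_setequal(unique(g), paste0("Group#", 1:4))
  # Group#1 holds the four nearest sites
  near4 <- lay$channel[order(lay$dist_mm, lay$channel)][1:4]
  expect_setequal(which(g == "Group#1"), near4)
  # mean distance increases across groups
  md <- tapply(lay$dist_mm, g, mean)
  expect_true(all(diff(md[paste0("Group#", 1:4)]) > 0))
})

test_that("masked channels are excluded and 16 usable spread over groups", {
  lay <- ecog_layout(32)
  mask <- rep(c(TRUE, FALSE), 16)
  g <- group_channels(lay, mask)
  expect_true(all(is.na(g[mask])))
  expect_equal(sum(!is.na(g)), 16L)
  expect_error(group_channels(lay, rep(TRUE, 32)), "fewer than 4")
})

test_that("equidistant ties break deterministically by channel index", {
  lay <- data.frame(channel = 1:8,
                    dist_mm = c(0.1, 0.1, 0.1, 0.1, 1, 1, 1, 1))
  g1 <- group_channels(lay)
  g2 <- group_channels(lay)
  expect_identical(g1, g2)
  expect_equal(unname(g1[5:8]), paste0("Group#", c(2, 2, 3, 4)))
})
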