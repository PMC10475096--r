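test_that("adaptive threshold reproduces the hand-computed fixture", {
  # strict local maxima {4, 9}, overall mean 1 -> ((4+9)/2 + 1)/2 = 3.75
  w <- c(0, 4, 0, 9, rep(0, 9))
  expect_equal(mean(w), 1)
  expect_equal(adaptive_threshold(w), 3.75)
})

test_that("degenerate windows give an infinite threshold", {
  expect_equal(adaptive_threshold(rep(0, 100)), Inf)
  expect_equal(adaptive_threshold(rep(2.5, 100)), Inf)
  expect_error(adaptive_threshold(numeric(0)), "non-empty")
  expect_error(adaptive_threshold(c(1, -1, 2)), "non-negative")
})

test_that("detector equals the brute-force oracle on short windows", {
  fs <- FS_TEST
  cfg <- detector_config()
  set.seed(21)
  for (k in 1:5) {
    x <- make_background(1, fs)
    n_ev <- sample(0:2, 1)
    if (n_ev > 0) {
      tt <- c(0.3, 0.7)[seq_len(n_ev)]
      x <- inject_events(x, fs, tt, p2p = 6 * 2 * sd(x),
                         types = sample(1:2, n_ev, replace = TRUE))
    }
    xf <- preprocess_wideband(x, fs)
    got <- suppressWarnings(detect_ieds(xf, fs, cfg))
    want <- naive_detect(xf, fs, cfg)
    expect_equal(got$events$center_time_s, want, tolerance = 1e-9)
  }
})

test_that("detection is invariant to positive rescaling of the signal", {
  fs <- FS_TEST
  set.seed(22)
  x <- make_background(10, fs)
  x <- inject_events(x, fs, c(2, 5, 8), p2p = 6 * 2 * sd(x))
  xf <- preprocess_wideband(x, fs)
  d1 <- detect_ieds(xf, fs)
  d2 <- detect_ieds(xf * 37.5, fs)
  expect_equal(d1$events$center_time_s, d2$events$center_time_s)
})

test_that("injected events are found at their centres; noise yields none", {
  fs <- FS_TEST
  set.seed(23)
  bg <- make_background(10, fs)
  truth <- c(1.2, 3.1, 4.9, 6.6, 8.4)
  x <- inject_events(bg, fs, truth, p2p = 6 * 2 * sd(bg),
                     types = c(1, 2, 1, 2, 1))
  d <- detect_ieds(preprocess_wideband(x, fs), fs)
  expect_equal(nrow(d$events), 5L)
  expect_true(all(abs(sort(d$events$center_time_s) - truth) < 0.025))
  expect_equal(ncol(d$segments), round(0.3 * fs))

  d0 <- detect_ieds(preprocess_wideband(bg, fs), fs)
  expect_equal(nrow(d0$events), 0L)
})

test_that("flat input gives no events; short input warns", {
  fs <- FS_TEST
  expect_equal(nrow(detect_ieds(rep(0, 10 * fs), fs)$events), 0L)
  expect_warning(detect_ieds(rnorm(fs), fs), "truncated")
})

test_that("deduplication is idempotent", {
  centers <- c(1, 1.05, 1.1, 2, 2.3, 2.31, 5)
  k1 <- iednm:::dedup_keep(centers, 0.15)
  once <- centers[k1]
  k2 <- iednm:::dedup_keep(once, 0.15)
  expect_true(all(k2))
})

test_that("extract_segment honours length and edges", {
  fs <- FS_TEST
  x <- rnorm(10 * fs)
  expect_length(extract_segment(x, fs, 5), 600L)
  expect_error(extract_segment(x, fs, 0.1), "edge")
  expect_error(extract_segment(x, fs, 9.95), "edge")
  # segment of an injected event contains its global extremum
  bg <- make_background(10, fs)
  x2 <- inject_events(bg, fs, 4.0, p2p = 8 * 2 * sd(bg))
  xf <- preprocess_wideband(x2, fs)
  seg <- extract_segment(xf, fs, 4.0)
  expect_equal(min(seg), min(xf))
})

test_that("evaluate_detection implements the count-error accuracy", {
  win <- data.frame(start_s = seq(0, 90, 10), end_s = seq(10, 100, 10))
  truth <- as.numeric(sapply(seq(0, 90, 10), function(s) s + c(1, 3, 5, 7)))
  expect_equal(evaluate_detection(truth, truth, win), 100)
  # one window misses 2 of its 4 events -> 100*(1 - (2/4)/10) = 95
  det <- setdiff(truth, c(21, 23))
  expect_equal(evaluate_detection(det, truth, win), 95)
  expect_equal(evaluate_detection(numeric(0), truth, win), 0)
  expect_error(evaluate_detection(truth, truth, data.frame()), "non-empty")
})
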