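test_that("feature arrays have 12 (ISP1) or 15 (ISP2) elements", {
  p1 <- build_protocol("ISP1", 0, 5)
  p2 <- build_protocol("ISP2", 0, 5)
  b1 <- seq_len(length(protocol_bin_edges(p1)) - 1)
  b2 <- seq_len(length(protocol_bin_edges(p2)) - 1)
  for (tr in c(1, 3, 5)) {
    expect_length(build_feature_array(b1, p1, tr), 12L)
    expect_length(build_feature_array(b2, p2, tr), 15L)
  }
  # a constant series gives a constant X
  xc <- build_feature_array(rep(2, 48), p1, 2)
  expect_true(all(xc == 2))
  expect_error(build_feature_array(b1, p1, 6), "trial_index")
  expect_error(build_feature_array(b1[1:5], p1, 1), "cover")
})

test_that("PCtrl bins are shared and cycle bins are trial-specific", {
  p <- build_protocol("ISP1", 0, 2)
  v <- seq_len(21) # 3 PCtrl + 2 x 9 cycle bins
  x1 <- build_feature_array(v, p, 1)
  x2 <- build_feature_array(v, p, 2)
  expect_equal(as.numeric(x1[1:3]), as.numeric(x2[1:3]))
  expect_equal(as.numeric(x1[4:12]), 4:12)
  expect_equal(as.numeric(x2[4:12]), 13:21)
})

test_that("normalisation divides by the last PCtrl bin and is idempotent", {
  x <- c(2, 2, 2, 1, 1, 1, rep(3, 6))
  nx <- normalize_to_baseline(x)
  expect_equal(nx, c(1, 1, 1, 0.5, 0.5, 0.5, rep(1.5, 6)))
  expect_equal(normalize_to_baseline(nx), nx)
  expect_error(normalize_to_baseline(c(1, 1, 0, 2)), "zero")
})

test_that("rho categories follow the printed thresholds", {
  expect_equal(categorize_rho(0.39), "weak")
  expect_equal(categorize_rho(0.4), "moderate")
  expect_equal(categorize_rho(0.79), "moderate")
  expect_equal(categorize_rho(0.8), "strong")
  expect_equal(categorize_rho(0.87), "strong")
  expect_equal(categorize_rho(1.0), "strong")
  expect_equal(categorize_rho(0), "weak")
  expect_error(categorize_rho(1.2), "rho")
  expect_error(categorize_rho(-0.1), "rho")
})

test_that("identical cohorts give rho = 1, strong and significant", {
  x <- c(1, 1, 1, 0.7, 0.8, 0.7, 1, 1.1, 1, 1, 1, 1)
  sim <- similarity_rho(list(rat1 = x, rat2 = x, rat3 = x))
  expect_equal(sim$rho, 1, tolerance = 1e-12)
  expect_equal(sim$category, "strong")
  expect_true(sim$significant)
  expect_equal(sim$n_pairs, 3L)
})

test_that("negative correlations truncate to zero", {
  v <- sin(seq(0, 2 * pi, length.out = 12))
  # rats 1-2 anti-correlate with the grand average (dominated by rat 3):
  # grand = (-v - v + 4v)/3, so rho_r = -1, -1, +1 -> truncated mean 1/3
  sim <- similarity_rho(list(rat1 = -v, rat2 = -v, rat3 = 4 * v))
  expect_equal(sim$per_pair$r, c(-1, -1, 1), tolerance = 1e-12)
  expect_equal(sim$rho, 1 / 3, tolerance = 1e-12)
  # with two rats, forced anti-correlation and leave-one-out: rho = 0
  sim2 <- similarity_rho(list(rat1 = v, rat2 = -v), leave_one_out = TRUE)
  expect_equal(sim2$rho, 0, tolerance = 1e-12)
})

test_that("hand-built 3-rat cohort matches a brute-force Pearson oracle", {
  set.seed(51)
  arrays <- lapply(1:3, function(r) {
    m <- matrix(rnorm(2 * 12, mean = 1, sd = 0.3), nrow = 2)
    m
  })
  sim <- similarity_rho(arrays)
  # oracle: explicit covariance-formula Pearson, mean over rats
  grand <- colMeans(do.call(rbind, arrays))
  rho_hand <- mean(vapply(arrays, function(m) {
    v <- colMeans(m)
    num <- sum((grand - mean(grand)) * (v - mean(v)))
    den <- sqrt(sum((grand - mean(grand))^2) * sum((v - mean(v))^2))
    max(num / den, 0)
  }, numeric(1)))
  expect_equal(sim$rho, rho_hand, tolerance = 1e-12)
})

test_that("truncation never lowers rho", {
  set.seed(52)
  for (k in 1:10) {
    arrays <- lapply(1:4, function(r) rnorm(12))
    s_t <- similarity_rho(arrays, truncate_negative = TRUE)
    s_u <- similarity_rho(arrays, truncate_negative = FALSE)
    expect_gte(s_t$rho, s_u$rho - 1e-12)
  }
})

test_that("rho is invariant to a common positive rescaling", {
  set.seed(53)
  arrays <- lapply(1:3, function(r) abs(rnorm(12, 1, 0.2)))
  s1 <- similarity_rho(arrays)
  arrays_scaled <- lapply(arrays, function(a) {
    normalize_to_baseline(a * 7.3)
  })
  s2 <- similarity_rho(lapply(arrays_scaled, as.numeric))
  s1n <- similarity_rho(lapply(arrays, function(a) {
    as.numeric(normalize_to_baseline(a))
  }))
  expect_equal(s2$rho, s1n$rho, tolerance = 1e-12)
})

test_that("zero-variance arrays are excluded with a warning", {
  x <- c(1, 1, 1, 0.7, 0.8, 0.7, 1, 1.1, 1, 1, 1, 1)
  expect_warning(sim <- similarity_rho(list(x, rep(1, 12), x)), "zero variance")
  expect_equal(sim$n_pairs, 2L)
  expect_error(
    suppressWarnings(similarity_rho(list(rep(1, 12), rep(2, 12)))),
    "excluded")
  expect_error(similarity_rho(list(x)), "at least 2")
})
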