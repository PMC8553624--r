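test_that("cosinor recovers a noiseless cosine at machine precision", {
  s <- gen_rhythm_series(5, 2, 7, sigma = 0, n_per_time = 3)
  f <- cosinor_fit(s$time_h, s$value)
  expect_equal(f$mesor, 5, tolerance = 1e-9)
  expect_equal(f$amplitude, 2, tolerance = 1e-9)
  expect_equal(f$acrophase_h, 7, tolerance = 1e-9)
  expect_lt(f$p_zero_amplitude, 1e-6)
  # fitted curve identity y(t) = M + A cos(2 pi (t - phi)/24)
  expect_equal(predict(f, c(1, 7, 13, 19)),
               5 + 2 * cos(2 * pi * (c(1, 7, 13, 19) - 7) / 24),
               tolerance = 1e-9)
})

test_that("constant series give zero amplitude and a null p value", {
  s <- data.frame(time_h = rep(c(1, 7, 13, 19), each = 3), value = 3)
  f <- cosinor_fit(s$time_h, s$value)
  expect_equal(f$amplitude, 0, tolerance = 1e-9)
  expect_gte(f$p_zero_amplitude, 0.99)
})

test_that("cosinor is phase- and scale-equivariant", {
  set.seed(12)
  s <- gen_rhythm_series(10, 3, 5, sigma = 1, n_per_time = 4, seed = 12)
  f <- cosinor_fit(s$time_h, s$value)
  for (delta in c(3, 11.5, 20)) {
    fd <- cosinor_fit((s$time_h + delta) %% 24, s$value)
    expect_equal(fd$mesor, f$mesor, tolerance = 1e-9)
    expect_equal(fd$amplitude, f$amplitude, tolerance = 1e-9)
    expect_equal(circ_diff_h(fd$acrophase_h, (f$acrophase_h + delta) %% 24),
                 0, tolerance = 1e-9)
  }
  fc <- cosinor_fit(s$time_h, 2.5 * s$value)
  expect_equal(fc$mesor, 2.5 * f$mesor, tolerance = 1e-9)
  expect_equal(fc$amplitude, 2.5 * f$amplitude, tolerance = 1e-9)
  expect_equal(fc$acrophase_h, f$acrophase_h, tolerance = 1e-9)
})

test_that("cosinor rejects degenerate designs", {
  expect_error(cosinor_fit(c(1, 1, 7, 7), c(1, 2, 3, 4)), "distinct")
  expect_error(cosinor_fit(c(1, 7, 13), c(1, 2, 3)), "4 observations")
})

test_that("screen normalization follows the second-highest rule", {
  r <- screen_normalize(c(ZT1 = 10, ZT7 = 8, ZT13 = 6, ZT19 = 4),
                        isotype_mfi = 2)
  expect_equal(r$corrected, c(8, 6, 4, 2))
  expect_equal(r$second_highest, 6)
  expect_equal(unname(r$normalized), c(8, 6, 4, 2) / 6)
  expect_true(r$expressed)
  # ties all normalize to 1
  r2 <- screen_normalize(c(5, 5, 5, 5), isotype_mfi = 1)
  expect_equal(unname(r2$normalized), rep(1, 4))
  # 1.2% of the screen max -> flagged no/low expression
  r3 <- screen_normalize(c(1.2, 1.0, 0.8, 0.5), isotype_mfi = 0,
                         screen_max = 100)
  expect_false(r3$expressed)
  # idempotent on an already-normalized expressed row with zero isotype
  r4 <- screen_normalize(r$normalized, isotype_mfi = 0)
  expect_equal(unname(r4$normalized), unname(r$normalized),
               tolerance = 1e-12)
  # second-highest zero -> non-normalizable
  r5 <- screen_normalize(c(4, 1, 1, 0), isotype_mfi = 2)
  expect_false(r5$normalizable)
  expect_true(all(is.na(r5$normalized)))
  expect_error(screen_normalize(5), ">= 2 ZTs")
})

test_that("fold-change matrices are reciprocal pairwise ratios", {
  expect_equal(unname(fold_change_matrix(c(3, 3, 3))),
               matrix(1, 3, 3))
  expect_equal(unname(fold_change_matrix(c(2, 1))),
               matrix(c(1, 0.5, 2, 1), 2, 2))
  set.seed(4)
  v <- runif(5, 0.5, 4)
  m <- fold_change_matrix(v)
  expect_equal(m, outer(v, v, "/"), ignore_attr = TRUE)
  expect_equal(m * t(m), matrix(1, 5, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  mz <- fold_change_matrix(c(1, 0))
  expect_true(all(is.na(mz[, 2])))
})

test_that("profile integration rescales and collapses", {
  p <- c(`1` = 2, `7` = 10, `13` = 6, `19` = 4)
  out <- integrate_profiles(list(p, p))
  expect_equal(out$mean, (p - 2) / 8, ignore_attr = TRUE)
  expect_equal(out$sem, rep(0, 4))
  expect_equal(out$time_h, c(1, 7, 13, 19))
  # exactly antiphase rescaled profiles integrate flat at 0.5
  a <- c(0, 1, 0.5, 0.25); b <- 1 - a
  out2 <- integrate_profiles(list(a, b), times = c(1, 7, 13, 19))
  expect_equal(out2$mean, rep(0.5, 4))
  # min-max output always in [0, 1]
  set.seed(6)
  ps <- lapply(1:10, function(i) rnorm(4))
  out3 <- integrate_profiles(ps, times = c(1, 7, 13, 19))
  expect_true(all(out3$mean >= 0 & out3$mean <= 1))
  # flat profiles are excluded with a warning
  expect_warning(out4 <- integrate_profiles(list(p, rep(2, 4))),
                 "flat")
  expect_equal(out4$n_profiles[1], 1L)
  expect_error(suppressWarnings(integrate_profiles(list(rep(1, 4)))),
               "flat")
})

test_that("integrated synthetic profiles keep the common acrophase", {
  set.seed(8)
  profs <- lapply(1:50, function(i) {
    amp <- runif(1, 1, 5)
    m <- runif(1, 5, 20)
    s <- gen_rhythm_series(m, amp, 7, sigma = 0.2 * amp, n_per_time = 1,
                           seed = 800 + i)
    setNames(s$value, s$time_h)
  })
  out <- integrate_profiles(profs, times = c(1, 7, 13, 19))
  f <- cosinor_fit(out$time_h, out$mean)
  expect_lte(circ_diff_h(f$acrophase_h, 7), 1)
})

test_that("detrending is exact on ramps and preserves cosines", {
  t_min <- seq(0, 72 * 60)
  slope <- 3 / 60 # counts per minute
  ramp <- 100 + slope * t_min
  out <- detrend_lumi(t_min, ramp)
  expect_lt(max(abs(out$relative)), 1e-6 * (slope * 60) * 24)
  # constant + 24-h cosine: relative correlates with the cosine
  cosine <- cos(2 * pi * t_min / (24 * 60))
  out2 <- detrend_lumi(t_min, 50 + 10 * cosine)
  ref <- cosine[match(out2$time_min, t_min)]
  expect_gt(cor(out2$relative, ref), 0.99)
  # length contract: input length minus (window - 1)
  expect_equal(nrow(out2), length(t_min) - (24 * 60 + 1 - 1))
  expect_error(detrend_lumi(seq(0, 20 * 60), rnorm(1201)), "duration")
  expect_error(detrend_lumi(c(0, 1, 3), c(1, 2, 3)), "regular")
})

test_that("time-point ANOVA matches known identities", {
  set.seed(14)
  # two groups: F equals t^2 of the equal-variance t-test
  g1 <- rnorm(6); g2 <- rnorm(6, 1)
  a <- timepoint_anova(rep(c(1, 13), each = 6), c(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(a$F_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  # three groups against brute-force sums of squares
  y <- c(4, 5, 6, 7, 6, 7, 8, 9, 10, 11, 12, 13)
  g <- rep(c(1, 7, 13), each = 4)
  a3 <- timepoint_anova(g, y)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_manual <- (ssb / 2) / (ssw / 9)
  expect_equal(a3$F_statistic, f_manual, tolerance = 1e-9)
  expect_equal(nrow(a3$tukey), 3L)
  # identical group means with noise -> p far from significance
  base <- rnorm(5)
  same <- c(base, base + 1e-3, base - 1e-3)
  a4 <- timepoint_anova(rep(c(1, 7, 13), each = 5), same)
  expect_gt(a4$p, 0.9)
  expect_error(timepoint_anova(c(1, 1, 1), c(1, 2, 3)), "2 time points")
  expect_error(timepoint_anova(c(1, 7, 7), c(1, 2, 3)), "replicates")
})

test_that("significance tiers mirror the annotation convention", {
  expect_equal(significance_tier(c(0.2, 0.03, 0.004, 3e-4, 5e-6)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(significance_tier(0.004, symbol = "#"), "##")
})
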