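# Per-deployment signal processing: channel handling, landmark
# detection, smoothing, and the three decompression metrics.

test_that("outlier channels (saturated at 1e5 hPa) are dropped before averaging", {
  n <- 200
  ch <- cbind(rep(1010, n), rep(1e5, n), rep(1012, n))
  tr <- pressure_trace(ch, fs = 100)
  clean <- remove_outlier_channels(tr)
  expect_equal(ncol(clean$channels), 2L)
  expect_equal(mean_pressure(clean), rep(1011, n))

  healthy <- pressure_trace(cbind(rep(1000, n), rep(1002, n), rep(1004, n)))
  expect_equal(ncol(remove_outlier_channels(healthy)$channels), 3L)
  expect_equal(mean_pressure(healthy)[1], 1002)

  all_bad <- pressure_trace(matrix(1e5, n, 3))
  expect_error(remove_outlier_channels(all_bad), "AllChannelsInvalid")
})

test_that("injection is the first reading above 1005 hPa, matching a linear scan", {
  p <- c(rep(1000, 300), rep(1050, 200))
  expect_equal(detect_injection(p, fs = 100), 3.00)
  expect_error(detect_injection(rep(1000, 100), fs = 100), "NoInjection")

  set.seed(11)
  for (rep_i in 1:20) {
    p <- 1000 + rnorm(500, sd = 1.5)
    cross <- sample(50:450, 1)
    p[cross:500] <- p[cross:500] + 30
    oracle <- NA_integer_
    for (i in seq_along(p)) if (p[i] > 1005) { oracle <- i; break }
    expect_equal(detect_injection(p, fs = 100), (oracle - 1) / 100)
  }
})

test_that("Savitzky-Golay filter is exact on quadratics and matches a polyfit oracle", {
  x <- seq(0, 1, length.out = 101)
  quad <- 2 - 3 * x + 0.5 * x^2
  expect_lt(max(abs(smooth_sg(quad) - quad)), 1e-9)
  expect_equal(smooth_sg(rep(5, 50)), rep(5, 50))

  # oracle: independent least-squares fit of a local parabola per point
  set.seed(4)
  p <- rnorm(80)
  half <- 5
  oracle <- p
  for (i in seq_along(p)) {
    lo <- min(max(1, i - half), length(p) - 10)
    idx <- lo:(lo + 10)
    fit <- lm(y ~ x + I(x^2), data.frame(x = idx - i, y = p[idx]))
    oracle[i] <- unname(coef(fit)[1])
  }
  expect_equal(smooth_sg(p), oracle, tolerance = 1e-10)

  expect_error(smooth_sg(p, window = 10), "BadWindow")
  expect_error(smooth_sg(p[1:5], window = 11), "BadWindow")
})

test_that("pump nadir detection finds a sharp dip and honours the 20 hPa criterion", {
  fs <- 100
  tt <- (0:5999) / fs
  base <- ifelse(tt < 5, 1000, 1030)
  dip <- 130 * exp(-0.5 * ((tt - 25) / 0.05)^2)
  p <- base - ifelse(tt >= 5, dip, 0)
  nad <- detect_nadir(p, t_injection = 5, fs = fs, mode = "pump")
  expect_lt(abs(nad$t_nadir - 25), 0.1)
  expect_lt(abs(nad$nadir_pressure - 900), 2.5)   # SG attenuates the peak a little

  # a 10 hPa transient never qualifies
  p10 <- base - ifelse(tt >= 5, 10 / 130 * dip, 0)
  expect_error(detect_nadir(p10, 5, fs, mode = "pump"), "NoNadir")
})

test_that("control nadir is the raw window minimum, no smoothing", {
  fs <- 100
  tt <- (0:5999) / fs
  p <- ifelse(tt < 2, 1000, 1020)
  p[tt >= 12 & tt < 12.01] <- 980   # unique raw min at injection + 10 s
  nad <- detect_nadir(p, t_injection = 2, fs = fs, mode = "control")
  expect_equal(nad$nadir_pressure, 980)
  expect_equal(nad$t_nadir, 12)

  # window starts 5 s after injection: an earlier min is ignored
  p_early <- p
  p_early[tt >= 4 & tt < 4.01] <- 900
  nad2 <- detect_nadir(p_early, 2, fs, mode = "control")
  expect_equal(nad2$nadir_pressure, 980)
})

test_that("exit detection finds the tailwater plateau and accepts a manual override", {
  fs <- 100
  tt <- (0:5999) / fs
  p <- ifelse(tt < 27, 1030, 1010)   # step to plateau 2 s after a nadir at 25 s
  t_exit <- detect_exit(p, t_nadir = 25, fs = fs)
  expect_lt(abs(t_exit - 27), 0.15)
  expect_equal(detect_exit(p, 25, fs, manual_exit_s = 33.3), 33.3)

  drifting <- 1030 + cumsum(rep(0.5, 6000))   # 50 hPa/s drift, never settles
  expect_error(detect_exit(drifting, 25, fs), "NoExit")
})

test_that("LRP is ln(acclimation/nadir), strictly decreasing in the nadir", {
  expect_equal(compute_lrp(1000, 1000), 0)
  expect_equal(compute_lrp(854), log(1000 / 854), tolerance = 1e-12)
  expect_equal(round(compute_lrp(854), 4), 0.1578)
  nadirs <- seq(500, 1500, by = 50)
  expect_true(all(diff(compute_lrp(nadirs)) < 0))
  expect_error(compute_lrp(-5), "NonPositivePressure")
})

test_that("ROC matches the exhaustive one-step difference oracle near the nadir", {
  fs <- 100
  marks <- passage_marks(5, 25, 45, 900)
  expect_equal(compute_roc(rep(1020, 6000), marks, fs), 0)

  ramp <- seq(0, by = 10, length.out = 6000)   # 10 hPa per sample
  expect_equal(compute_roc(ramp, marks, fs, smooth = FALSE), 1000 * fs / 100)

  set.seed(9)
  tt <- (0:5999) / fs
  p <- 1030 - 120 * exp(-0.5 * ((tt - 25) / 0.05)^2) + rnorm(6000)
  ps <- smooth_sg(p)
  win <- which(tt >= 24.5 & tt <= 25.5)
  oracle <- max(abs(ps[win][-1] - ps[win][-length(win)])) * fs
  expect_equal(compute_roc(p, marks, fs), oracle)
})

test_that("time normalization pins the landmarks and preserves linearity", {
  fs <- 100
  tt <- (0:5999) / fs
  marks <- passage_marks(5, 25, 45, nadir_pressure = 1030 - 25 * 2)
  p <- 1030 - 2 * pmin(tt, 25) + 3 * pmax(tt - 25, 0)   # piecewise linear, min at 25 s
  nt <- normalize_time(p, marks, fs)
  expect_length(nt$u, 1001)
  expect_equal(nt$p[1], p[tt == 5])
  expect_equal(nt$p[501], p[tt == 25])
  expect_equal(nt$p[1001], p[tt == 45])
  # linear in u on each half
  expect_lt(max(abs(diff(diff(nt$p[1:501])))), 1e-9)
  expect_lt(max(abs(diff(diff(nt$p[501:1001])))), 1e-9)

  # analytic oracle: smooth trace, interpolation error below one-sample curvature
  p2 <- 1030 + 10 * sin(tt / 3)
  nt2 <- normalize_time(p2, marks, fs)
  t_of_u <- ifelse(nt2$u <= 0.5, 5 + nt2$u / 0.5 * 20, 25 + (nt2$u - 0.5) / 0.5 * 20)
  expect_lt(max(abs(nt2$p - (1030 + 10 * sin(t_of_u / 3)))), 1e-3)

  # invariance to uniform time rescaling (same trace at double fs)
  fs2 <- 200
  tt2 <- (0:11999) / fs2
  p3 <- 1030 + 10 * sin(tt2 / 3)
  nt3 <- normalize_time(p3, marks, fs2)
  expect_equal(nt3$p, nt2$p, tolerance = 1e-4)
})

test_that("ensemble stats give mean +- SD per scenario, SD blank for n = 1", {
  df <- data.frame(
    scenario = c("A", "A", "B"),
    nadir = c(900, 1000, 950), lrp = c(0.1, 0, 0.05), roc = c(1, 2, 3)
  )
  es <- ensemble_stats(df)
  a <- es[es$scenario == "A", ]
  expect_equal(a$nadir_mean, 950)
  expect_equal(a$nadir_sd, sd(c(900, 1000)))
  b <- es[es$scenario == "B", ]
  expect_true(is.na(b$nadir_sd))
  expect_error(ensemble_stats(df[0, ]), "EmptyScenario")

  set.seed(2)
  big <- data.frame(scenario = "X", nadir = rnorm(40, 930, 20),
                    lrp = runif(40), roc = rexp(40))
  es2 <- ensemble_stats(big)
  expect_equal(es2$lrp_mean, mean(big$lrp))
  expect_equal(es2$roc_sd, sd(big$roc))
})

test_that("process_deployment chains the stages on a synthetic passage", {
  d <- gen_pressure_trace(trace_scenario("pump", nadir_depth_hPa = 120), seed = 5)
  bp <- process_deployment(d$trace)
  expect_s3_class(bp, "barotrauma_params")
  expect_lt(abs(bp$marks$t_nadir - d$truth$t_nadir), 0.1)
  expect_equal(bp$lrp, log(1000 / bp$nadir))
  expect_gte(bp$roc, 0)
  expect_equal(scenario_label(bp), "FNAFP_468")
})
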