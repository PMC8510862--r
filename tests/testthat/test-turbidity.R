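## Unit tests for the turbidity preprocessing chain and the regime
## detectors, mostly on constructed curves with known landmarks.

make_trace <- function(intensity, time = seq_along(intensity) - 1) {
  turbidity_trace(time, intensity)
}

test_that("slicing keeps one sample out of keep_every, starting at index 0", {
  tr <- make_trace(1:30)
  s3 <- slice_trace(tr, 3)
  expect_equal(s3$intensity, tr$intensity[seq(1, 30, by = 3)])
  expect_equal(s3$time, tr$time[seq(1, 30, by = 3)])
  expect_equal(slice_trace(tr, 1)$intensity, tr$intensity)
  tr100 <- make_trace(rnorm(100))
  expect_length(slice_trace(tr100, 3)$time, 34)  # ceiling(100/3)
  expect_error(slice_trace(make_trace(1:20), 25), "fewer than 2")
  expect_error(slice_trace(tr, 0), "positive integer")
})

test_that("Savitzky-Golay smoothing reproduces cubics and reduces noise", {
  t <- 0:40
  cubic <- 2 + 0.5 * t - 0.03 * t^2 + 0.001 * t^3
  sm <- smooth_trace(make_trace(cubic, t))
  interior <- 6:36  # full windows, away from the mirror-padded edges
  expect_equal(sm$intensity[interior], cubic[interior], tolerance = 1e-10)
  const <- smooth_trace(make_trace(rep(5, 30)))
  expect_equal(const$intensity, rep(5, 30))
  ## variance reduction on white noise, many seeds
  set.seed(101)
  ratios <- replicate(100, {
    x <- rnorm(60)
    var(smooth_trace(make_trace(x))$intensity) / var(x)
  })
  expect_true(all(ratios < 1))
})

test_that("too-short traces are rejected by the smoother", {
  expect_error(turbidity_trace(1:10, rnorm(10)), "at least 20")
})

test_that("min-max normalization maps onto [0,1] and is idempotent", {
  tr <- make_trace(c(2, 4, 6, rep(c(2, 6), 10)))
  nt <- normalize_trace(tr)
  expect_equal(nt$nt[1:3], c(0, 0.5, 1))
  expect_equal(min(nt$nt), 0)
  expect_equal(max(nt$nt), 1)
  expect_equal(nt$delta_turbidity, 4)
  nt2 <- normalize_trace(make_trace(nt$nt))
  expect_equal(nt2$nt, nt$nt, tolerance = 1e-15)
  expect_error(normalize_trace(make_trace(rep(3, 25))), "degenerate")
})

test_that("delta turbidity reports the raw intensity span", {
  intensity <- 1000 - 700 * exp(-(0:50 - 25)^2 / 50)
  nt <- normalize_trace(make_trace(intensity))
  expect_equal(nt$delta_turbidity, max(intensity) - min(intensity))
})

test_that("CFT is the time of the turbidity minimum, earliest on ties", {
  v <- c(seq(1, 0, by = -0.05), seq(0.05, 1, by = 0.05))  # vertex at t = 20
  expect_equal(detect_cft(normalize_trace(make_trace(v))), 20)
  expect_equal(detect_cft(normalize_trace(make_trace(seq(0, 1, length.out = 30)))), 0)
  expect_warning(detect_cft(normalize_trace(make_trace(seq(1, 0, length.out = 30)))),
                 "no lysis")
})

test_that("the slow-regime line is fitted between the 0.01 and 0.075 crossings", {
  t <- 0:120
  nt_vals <- c(seq(1, 0, length.out = 21), 0.005 * (1:100))
  nt <- normalize_trace(make_trace(nt_vals, t))
  fit <- fit_slow_regime(nt)
  expect_equal(fit$slope, 0.005, tolerance = 1e-9)
  ## window bounds are the first crossings of 0.01 and 0.075
  expect_equal(fit$window, c(22, 35))
  expect_error(fit_slow_regime(nt, low = 0.01, high = 0.012),
               "insufficient window")
})

test_that("TLT sits at the maximal derivative, ties to the earliest time", {
  t <- 0:200
  nt_vals <- c(seq(0.5, 0, length.out = 21), plogis(0.15 * (21:200 - 120)))
  nt <- normalize_trace(make_trace(nt_vals, t))
  expect_equal(detect_tlt(nt), 100, tolerance = 1)  # 120 - CFT(20)
  ## pure linear rise with exactly representable increments: the
  ## derivative ties everywhere and the earliest time wins
  lin <- normalize_trace(make_trace(c(seq(1, 0, length.out = 21),
                                      (1:180) / 256), t))
  expect_equal(detect_tlt(lin), 1)
})

test_that("the backward scan finds the departure from the slow line", {
  t <- 0:200
  cft <- 20
  slope <- 0.004
  base <- pmax(0, (t - cft) * slope)
  dep <- pmax(0, t - 120) * 0.01          # departs at t = 120 by +0.01/min
  y <- c(seq(0.5, 0, length.out = cft), base[t >= cft] + dep[t >= cft])
  nt <- normalize_trace(make_trace(pmin(y, 1), t))
  fit <- fit_slow_regime(nt)
  slt <- detect_slow_regime_end(nt, fit)
  expect_equal(slt + 20, 120, tolerance = 1.5)
  ## a curve that is the fit line itself never departs: SLT = TLT point
  tlt <- detect_tlt(nt)
  lin <- normalize_trace(make_trace(pmin(c(seq(0.5, 0, length.out = cft),
                                           base[t >= cft]), 1), t))
  fit_lin <- fit_slow_regime(lin)
  expect_equal(detect_slow_regime_end(lin, fit_lin), detect_tlt(lin),
               tolerance = 1e-9)
})

test_that("timescale assembly enforces the regime identities", {
  ## slt = 73, flt = 67 gives r_sl ~ 0.521
  g <- generate_phenomenological(synthetic_assay_config(noise_sd = 0))
  ts <- analyze_trace(g$traces[[1]], keep_every = 1L)
  expect_equal(ts$tlt, ts$slt + ts$flt)
  expect_equal(ts$r_sl + ts$r_fl, 1)
  expect_equal(73 / (73 + 67), 0.521, tolerance = 0.01)
  expect_equal(ts$r_sl, ts$slt / ts$tlt)
  expect_gt(ts$slow_slope, 0)
})

test_that("timescales are invariant under affine intensity rescaling", {
  g <- generate_phenomenological(synthetic_assay_config(noise_sd = 0.003,
                                                        seed = 11))
  tr <- g$traces[[1]]
  tr2 <- turbidity_trace(tr$time, 3.7 * tr$intensity + 250, tr$channel_id)
  a1 <- analyze_trace(tr, keep_every = 3L)
  a2 <- analyze_trace(tr2, keep_every = 3L)
  for (f in c("cft", "slt", "flt", "tlt", "end_of_lysis", "slow_slope",
              "r_sl"))
    expect_equal(a1[[f]], a2[[f]], tolerance = 1e-9)
  expect_equal(a2$delta_turbidity, 3.7 * a1$delta_turbidity,
               tolerance = 1e-9)
})

test_that("long-format CSV round-trips through the channel analyzer", {
  g <- generate_phenomenological(synthetic_assay_config(channels = 2,
                                                        noise_sd = 0.002,
                                                        seed = 5))
  df <- do.call(rbind, lapply(g$traces, function(tr)
    data.frame(time_min = tr$time, channel = tr$channel_id,
               intensity = tr$intensity)))
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  write.csv(df, csv, row.names = FALSE)
  traces <- read_turbidity_csv(csv)
  expect_named(traces, c("ch1", "ch2"))
  rep <- analyze_channels(csv, keep_every = 1L)
  expect_equal(nrow(rep), 2)
  expect_true(all(abs(rep$cft - g$truth$cft) <= 1))
})
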