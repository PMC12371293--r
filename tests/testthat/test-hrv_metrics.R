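test_that("rmssd and sdnn match hand-computed values and length rules", {
  # diffs 10, -20, 15 -> mean square 725/3 -> sqrt
  expect_equal(rmssd(c(800, 810, 790, 805)), sqrt(725 / 3), tolerance = 1e-9)
  expect_equal(round(rmssd(c(800, 810, 790, 805)), 3), 15.546)
  expect_equal(rmssd(c(900, 910, 890, 905)), rmssd(c(800, 810, 790, 805)))
  expect_equal(rmssd(rep(700, 10)), 0)
  expect_equal(sdnn(c(790, 810, 800)), 10)
  expect_equal(sdnn(rep(700, 5)), 0)
  for (f in list(rmssd, sdnn)) {
    expect_true(is.na(f(c(800, 810))))
    expect_true(is.na(f(numeric(0))))
  }
})

test_that("rmssd and sdnn are shift-invariant and scale linearly", {
  set.seed(11)
  for (rep in 1:20) {
    x <- stats::rnorm(30, 800, 40)
    c0 <- stats::runif(1, -200, 200)
    k <- stats::runif(1, 0.5, 3)
    expect_equal(rmssd(x + c0), rmssd(x), tolerance = 1e-10)
    expect_equal(sdnn(x + c0), sdnn(x), tolerance = 1e-10)
    expect_equal(rmssd(x * k), k * rmssd(x), tolerance = 1e-10)
    expect_equal(sdnn(x * k), k * sdnn(x), tolerance = 1e-10)
  }
})

test_that("mean RMSSD of iid Gaussian interval noise approaches sigma*sqrt(2)", {
  set.seed(21)
  sigma <- 10
  vals <- replicate(400, rmssd(800 + stats::rnorm(75, 0, sigma)))
  expect_equal(mean(vals), sigma * sqrt(2), tolerance = 0.02)
})

test_that("ln transform handles zero and missing", {
  expect_equal(ln_hrv(1), 0)
  expect_equal(ln_hrv(exp(1)), 1)
  expect_equal(round(ln_hrv(15.546), 3), 2.744)
  expect_true(all(is.na(ln_hrv(c(0, -3, NA)))))
})

test_that("minute segmentation yields one record per minute, half-open", {
  dw <- c(9, 21) * 3600
  b <- make_constant_beats(dw[1], dw[1] + 60, ibi = 800)
  s <- ibi_series("p1", "1", b$t, b$ibi)
  seg <- segment_minutes(s, dw, bands = FALSE)
  expect_equal(nrow(seg), 720)
  expect_equal(sum(seg$valid), 1)
  expect_equal(seg$n_beats[1], 75)   # 60 s / 0.8 s, boundary half-open
  expect_equal(seg$rmssd[1], 0)

  b10 <- make_constant_beats(dw[1], dw[1] + 600, ibi = 800)
  seg10 <- segment_minutes(ibi_series("p1", "1", b10$t, b10$ibi),
                           c(dw[1], dw[1] + 600), bands = FALSE)
  expect_equal(nrow(seg10), 10)
  expect_true(all(seg10$valid))
  expect_true(all(seg10$n_beats == 75))

  empty <- segment_minutes(ibi_series("p1", "1", numeric(0), numeric(0)),
                           dw, bands = FALSE)
  expect_equal(nrow(empty), 720)
  expect_false(any(empty$valid))

  expect_error(ibi_series("p1", "1", c(100, 99), c(800, 800)),
               class = "addhrvr_bad_input")
  expect_error(segment_minutes(s, c(dw[1] + 30, dw[2])),
               class = "addhrvr_bad_input")
})

test_that("band power concentrates at a synthesized modulation frequency", {
  # 0.1 Hz sinusoidal IBI modulation over 5 minutes
  t <- 0; tt <- c(); ibi <- c()
  while (t < 300) {
    x <- 800 + 50 * sin(2 * pi * 0.1 * t)
    tt <- c(tt, t); ibi <- c(ibi, x)
    t <- t + x / 1000
  }
  lf <- band_power(ibi, c(0.04, 0.15), t = tt)
  hf <- band_power(ibi, c(0.15, 0.40), t = tt)
  tot <- band_power(ibi, c(0, 2), t = tt)
  expect_gt(lf / hf, 10)
  expect_gt(lf / tot, 0.8)
  expect_gte(tot, lf + hf - 1e-8)

  expect_equal(band_power(rep(800, 100), c(0.15, 0.4)), 0, tolerance = 1e-6)
  # window shorter than 2 cycles of the band floor
  expect_true(is.na(band_power(rep(800, 20), c(0.04, 0.15))))
})

test_that("artifact rules fire on jumps and out-of-range intervals", {
  r <- artifact_rules()
  rec <- make_minutes(40, 1.3)[1, ]
  clean <- rep(800, 75)
  expect_true(validate_minute(rec, clean, r)$valid)
  bad_low <- c(rep(800, 74), 150)
  expect_false(validate_minute(rec, bad_low, r)$valid)
  jump <- c(rep(800, 40), 1200, rep(800, 34))   # 50 % change > 30 %
  v <- validate_minute(rec, jump, r)
  expect_false(v$valid)
  expect_true(all(is.na(unlist(v[c("rmssd", "sdnn", "hf", "lf")]))))
  expect_false(validate_minute(rec, rep(800, 20), r)$valid)  # too few beats
})

test_that("tightening artifact rules never turns an invalid minute valid", {
  set.seed(31)
  loose <- artifact_rules(max_rel_jump = 0.5, ibi_min = 250, ibi_max = 2200,
                          min_beats = 20)
  tight <- artifact_rules(max_rel_jump = 0.2, ibi_min = 400, ibi_max = 1500,
                          min_beats = 40)
  for (rep in 1:50) {
    n <- sample(10:90, 1)
    x <- stats::rnorm(n, stats::runif(1, 300, 1500), stats::runif(1, 5, 400))
    x <- abs(x) + 1
    loose_ok <- addhrvr:::check_artifacts(x, loose)
    tight_ok <- addhrvr:::check_artifacts(x, tight)
    expect_true(loose_ok || !tight_ok)
  }
})
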