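test_that("movement series respects scenario bounds and the seed", {
  set.seed(61)
  sed_only <- generate_met_series(states = c(sedentary = 1.3),
                                  trans = matrix(1, 1, 1))
  expect_true(all(sed_only >= 0.9 & sed_only <= 1.8))
  set.seed(7); a <- generate_met_series()
  set.seed(7); b <- generate_met_series()
  expect_identical(a, b)
})

test_that("long-run movement mean matches the bout-mixture expectation", {
  set.seed(62)
  P <- addhrvr:::default_met_trans()
  states <- addhrvr:::default_met_states()
  expected <- sum(oracle_stationary(P) * states)
  met <- unlist(replicate(8, generate_met_series(), simplify = FALSE))
  expect_equal(mean(met), expected, tolerance = 0.1)
})

test_that("episodes are disjoint, inside the window, Poisson in number", {
  set.seed(63)
  expect_equal(nrow(place_episodes(rate = 0)), 0)
  counts <- integer(400)
  for (r in 1:400) {
    ep <- place_episodes(rate = 2)
    counts[r] <- nrow(ep)
    if (nrow(ep) > 1) {
      expect_true(all(ep$start[-1] >= ep$end[-nrow(ep)]))
    }
    if (nrow(ep)) {
      expect_true(all(ep$start >= 1 & ep$end <= 721 & ep$end > ep$start))
    }
  }
  expect_equal(mean(counts), 2, tolerance = 0.1)
})

test_that("synthesized beat trains realize their minute RMSSD targets", {
  set.seed(64)
  met <- generate_met_series(c(32400, 32400 + 30 * 60),
                             states = c(sedentary = 1.3),
                             trans = matrix(1, 1, 1))
  targets <- stats::runif(30, 20, 60)
  ser <- generate_ibis(targets, met, day_window = c(32400, 32400 + 30 * 60))
  seg <- segment_minutes(ser, c(32400, 32400 + 30 * 60), met = met,
                         bands = FALSE)
  expect_true(all(seg$valid))
  expect_equal(seg$rmssd, targets, tolerance = 1e-6)
  # movement shortens intervals: check the heart-rate link end to end
  met_hi <- rep(6, 5); met_lo <- rep(1.3, 5)
  s_hi <- generate_ibis(rep(30, 5), met_hi, day_window = c(32400, 32700))
  s_lo <- generate_ibis(rep(30, 5), met_lo, day_window = c(32400, 32700))
  expect_lt(mean(s_hi$beats$ibi), mean(s_lo$beats$ibi))
})

test_that("the full beat-level chain recovers a noiseless calibration", {
  persons <- list(person_params(intercept = 70, slope = -8, noise_sd = 0,
                                episode_rate = 0))
  sim <- simulate_study(1, n_days = 0, persons = persons, fidelity = "ibi",
                        seed = 65)
  ct <- sim$calibration_table
  expect_equal(ct$intercept, 70, tolerance = 1e-4)
  expect_equal(ct$slope, -8, tolerance = 1e-4)
})

test_that("a deep 28-minute episode almost always triggers", {
  set.seed(66)
  cfg <- trigger_config()
  fired <- 0L
  for (r in 1:50) {
    met <- generate_met_series()
    cal_m <- make_minutes(55 - 4 * met + stats::rnorm(720, 0, 8), met)
    cal <- fit_calibration(cal_m)
    met2 <- generate_met_series()
    dip <- rep(0, 720); dip[100:139] <- 1    # 40-min episode, depth 1 SD
    day <- make_minutes(55 - 4 * met2 + stats::rnorm(720, 0, 8) -
                          dip * cal$sd, met2)
    ev <- detect_triggers(flag_minutes(cal, day, k = cfg$k), cfg)
    in_ep <- any(ev$time >= cfg$day_window[1] + 100 * 60 &
                   ev$time <= cfg$day_window[1] + 141 * 60)
    fired <- fired + in_ep
  }
  expect_gte(fired, 48L)   # >= 95 % across seeds
})

test_that("with no episodes the trigger rate matches a pure-noise replay", {
  set.seed(67)
  noise_sd <- 8
  met <- generate_met_series()
  cal_m <- make_minutes(55 - 4 * met + stats::rnorm(720, 0, noise_sd), met)
  cal <- fit_calibration(cal_m)
  cfg <- trigger_config()
  n_days <- 80
  engine_counts <- replicate(n_days, {
    met2 <- generate_met_series()
    day <- make_minutes(55 - 4 * met2 + stats::rnorm(720, 0, noise_sd), met2)
    nrow(detect_triggers(flag_minutes(cal, day, k = cfg$k), cfg))
  })
  # direct binomial-scan oracle under the same false-flag probability
  p0 <- stats::pnorm(-cfg$k * cal$sd / noise_sd)
  oracle_counts <- replicate(n_days, {
    nrow(oracle_detect(stats::runif(720) < p0))
  })
  expect_equal(mean(engine_counts), mean(oracle_counts), tolerance = 0.75)
})

test_that("self-reports shift exactly under zero noise and clip at bounds", {
  prompts <- data.frame(person_id = "p1", trigger_kind = "addhrvr",
                        in_episode = FALSE, stringsAsFactors = FALSE)
  prompts <- prompts[rep(1, 50), ]
  sr <- generate_selfreports(prompts, effect_params(), latent_sd = 0,
                             item_sd = 0,
                             disposition_probs = c(answered = 1, ignored = 0,
                                                   dismissed = 0,
                                                   incomplete = 0))
  sc <- score_prompts(sr)
  expect_equal(unique(sc$stress_post - sc$stress_pre), -0.12,
               tolerance = 1e-12)
  expect_equal(unique(sc$rumination_post - sc$rumination_pre), -0.11,
               tolerance = 1e-12)
  # reverse-coded items are stored as collected (reflected on the 1-5 scale)
  expect_equal(unique(sr$stress_pre_1), 6 - 2.2, tolerance = 1e-12)
  expect_equal(unique(sr$stress_pre_4), 2.2, tolerance = 1e-12)

  at_ceiling <- generate_selfreports(prompts, effect_params(
    time_effect_stress = 0.5), baseline_stress = 5, latent_sd = 0,
    item_sd = 0, disposition_probs = c(answered = 1, ignored = 0,
                                       dismissed = 0, incomplete = 0))
  sc5 <- score_prompts(at_ceiling)
  expect_true(all(sc5$stress_post <= 5))
})

test_that("disposition frequencies match their configured probabilities", {
  set.seed(68)
  prompts <- data.frame(person_id = "p1", trigger_kind = "random",
                        in_episode = FALSE)[rep(1, 4000), ]
  sr <- generate_selfreports(prompts)
  frac <- mean(sr$disposition == "answered")
  expect_equal(frac, 0.69, tolerance = 3 * sqrt(0.69 * 0.31 / 4000) / 0.69)
  # non-answered prompts carry no (complete) item data
  expect_true(all(is.na(sr$stress_pre_1[sr$disposition == "ignored"])))
  expect_true(all(is.na(sr$stress_post_1[sr$disposition == "incomplete"])))
  expect_true(all(!is.na(sr$stress_pre_1[sr$disposition == "incomplete"])))
})

test_that("cohort simulation is deterministic under the master seed", {
  s1 <- simulate_study(3, n_days = 1, seed = 99)
  s2 <- simulate_study(3, n_days = 1, seed = 99)
  expect_identical(s1$minutes, s2$minutes)
  expect_identical(s1$prompts, s2$prompts)
  expect_false(identical(s1$minutes,
                         simulate_study(3, n_days = 1, seed = 100)$minutes))
})

test_that("calibration recovery is unbiased across a simulated population", {
  sim <- simulate_study(100, n_days = 0, seed = 70)
  ct <- sim$calibration_table
  truth <- vapply(sim$persons, `[[`, numeric(1), "slope")
  err <- ct$slope - truth[match(ct$person_id, sprintf("p%03d", 1:100))]
  mc_se <- stats::sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 2 * mc_se)
})
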