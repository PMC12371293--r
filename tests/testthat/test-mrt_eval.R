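test_that("stress scoring reverses, averages and propagates missingness", {
  expect_equal(score_stress(c(1, 1, 1, 5)), 5)
  expect_equal(score_stress(c(3, 3, 3, 3)), 3)
  expect_equal(score_stress(c(5, 5, 5, 1)), 1)
  expect_true(is.na(score_stress(c(2, NA, 3, 4))))
  expect_error(score_stress(c(0, 3, 3, 3)), class = "addhrvr_bad_input")
  # reversal symmetry: score(raw) + score(6 - raw) = 6
  set.seed(71)
  for (r in 1:25) {
    raw <- sample(1:5, 4, replace = TRUE)
    expect_equal(score_stress(raw) + score_stress(6 - raw), 6)
  }
})

test_that("outcome windows use the stated pre/during/post offsets", {
  # minute RMSSD encodes its own index so spans are directly readable
  idx <- 1:720
  m <- make_minutes(exp(idx / 100), met = rep(1.5, 720))
  pr <- data.frame(person_id = "p1", day = "1", time = 43200,
                   trigger_kind = "addhrvr", intervention_kind = "breathing",
                   smoking = FALSE, prompt_id = "x1",
                   stringsAsFactors = FALSE)
  w <- build_windows(m, pr)
  # prompt 12:00, intervention 12:00-12:01
  i0 <- (43200 - 32400) / 60          # minutes elapsed at the prompt
  pre_idx <- (i0 - 10 + 1):i0                   # 11:50-11:59 starts
  during_idx <- (i0 - 1 + 1):(i0 + 3)           # 11:59-12:02 starts
  post_idx <- (i0 + 2 + 1):(i0 + 11 + 1)        # 12:02-12:11 starts
  expect_equal(w$ln_rmssd[w$time == "pre"], mean(pre_idx / 100))
  expect_equal(w$ln_rmssd[w$time == "during"], mean(during_idx / 100))
  expect_equal(w$ln_rmssd[w$time == "post"], mean(post_idx / 100))
  expect_equal(w$time_code, c(-1, 0, 1))

  # constant signal: all three windows agree
  mc <- make_minutes(rep(40, 720), rep(1.5, 720))
  wc <- build_windows(mc, pr)
  expect_equal(wc$ln_rmssd, rep(log(40), 3))

  # all pre-prompt minutes invalid -> missing pre outcome
  mi <- m; mi$valid[pre_idx] <- FALSE
  wi <- build_windows(mi, pr)
  expect_true(is.na(wi$ln_rmssd[wi$time == "pre"]))

  # prompt near the day edge: pre window truncated below the minimum
  pr_edge <- pr; pr_edge$time <- 32400 + 120
  we <- build_windows(m, pr_edge)
  expect_false("pre" %in% as.character(we$time))
})

test_that("window aggregation ignores minute ordering", {
  set.seed(72)
  m <- make_minutes(stats::runif(720, 20, 60), stats::runif(720, 1, 4))
  pr <- data.frame(person_id = "p1", day = "1", time = 50000,
                   trigger_kind = "random", intervention_kind = "breathing",
                   smoking = FALSE, prompt_id = "x1")
  w1 <- build_windows(m, pr)
  w2 <- build_windows(m[sample(720), ], pr)
  expect_equal(w1$ln_rmssd, w2$ln_rmssd)
  expect_equal(w1$met_mean, w2$met_mean)
})

test_that("the proximal model recovers window-level generating effects", {
  set.seed(73)
  w <- simulate_windows(n_persons = 60, prompts_per_person = 40)
  fit <- fit_proximal_model(w)
  co <- fit$coefficients
  grab <- function(term) co[co$term == term, ]
  for (chk in list(list("trigger:timepost", 0.12),
                   list("trigger:timeduring", 0.08),
                   list("met_c", -0.35))) {
    row <- grab(chk[[1]])
    expect_true(row$ci_lo <= chk[[2]] && chk[[2]] <= row$ci_hi)
  }
  expect_equal(fit$icc, fit$tau00 / (fit$tau00 + fit$sigma2))
  expect_equal(fit$icc, 0.35, tolerance = 0.25)
  expect_equal(fit$sigma2, 0.23, tolerance = 0.05)
})

test_that("the trigger-by-time(post) estimator is unbiased", {
  set.seed(74)
  est <- replicate(100, {
    w <- simulate_windows(n_persons = 25, prompts_per_person = 20)
    fit <- fit_proximal_model(w)
    co <- fit$coefficients
    co$estimate[co$term == "trigger:timepost"]
  })
  expect_lt(abs(mean(est) - 0.12), 0.02)
})

test_that("degenerate model inputs are refused", {
  set.seed(75)
  w <- simulate_windows(n_persons = 10, prompts_per_person = 10)
  expect_error(fit_proximal_model(w[w$person_id == "p001", ]),
               class = "addhrvr_bad_input")
  w1 <- w; w1$trigger_kind <- "random"
  expect_error(fit_proximal_model(w1), class = "addhrvr_bad_input")
  expect_error(fit_proximal_model(w, design = "study2"),
               class = "addhrvr_bad_input")   # no intervention arms
  expect_error(compare_virtual(w), class = "addhrvr_no_virtual")
})

test_that("reference rescaling obeys linear-model algebra", {
  set.seed(76)
  eff <- effect_params(during_boost = 0, post_boost = 0)
  w <- simulate_windows(n_persons = 40, prompts_per_person = 30,
                        effects = eff, design = "study2")
  # inject a mindful-only trigger boost in the during and post phases
  tr <- w$trigger_kind == "addhrvr" & w$intervention_kind == "mindful"
  w$ln_rmssd[tr & w$time == "during"] <-
    w$ln_rmssd[tr & w$time == "during"] + 0.10
  ext <- rescale_reference(w, design = "study2",
                           reference_intervention = "external")
  mnd <- rescale_reference(w, design = "study2",
                           reference_intervention = "mindful")
  ce <- ext$coefficients; cm <- mnd$coefficients
  pick <- function(co, term) co$estimate[co$term == term]
  # the two simple trigger-by-time effects differ by the three-way estimate
  three_way <- pick(ce, "triggeraddhrvr:interventionmindful:timeduring")
  expect_equal(pick(cm, "triggeraddhrvr:timeduring") -
                 pick(ce, "triggeraddhrvr:timeduring"),
               three_way, tolerance = 1e-6)
  # recovery: boost appears only under the mindful reference
  expect_equal(pick(cm, "triggeraddhrvr:timeduring"), 0.10,
               tolerance = 4 * cm$se[cm$term == "triggeraddhrvr:timeduring"])
  expect_lt(abs(pick(ce, "triggeraddhrvr:timeduring")),
            4 * ce$se[ce$term == "triggeraddhrvr:timeduring"])
  # swapping the reference twice restores the original fit
  again <- rescale_reference(w, design = "study2",
                             reference_intervention = "external")
  expect_equal(ce$estimate, again$coefficients$estimate, tolerance = 1e-10)
  expect_error(rescale_reference(w, reference_trigger = "nope"),
               class = "addhrvr_bad_input")
})

test_that("the virtual-trigger contrast separates boost from rebound", {
  set.seed(77)
  # intervention boost 0.17 vs spontaneous rebound 0.05 -> contrast 0.12
  w <- make_virtual_windows(post_shift = c(virtual = 0.05, random = 0.03,
                                           addhrvr = 0.17))
  fit <- compare_virtual(w)
  key <- fit$coefficients[fit$coefficients$term == "kindaddhrvr:timepost", ]
  expect_true(key$ci_lo <= 0.12 && 0.12 <= key$ci_hi)
  expect_gt(key$estimate, 0)
  # identical rebound and no intervention effect -> contrast near zero
  w0 <- make_virtual_windows(post_shift = c(virtual = 0.05, random = 0.05,
                                            addhrvr = 0.05))
  fit0 <- compare_virtual(w0)
  key0 <- fit0$coefficients[fit0$coefficients$term ==
                              "kindaddhrvr:timepost", ]
  expect_true(key0$ci_lo <= 0 && 0 <= key0$ci_hi)
})

test_that("self-report models estimate the pre-to-post decline", {
  set.seed(78)
  sim <- simulate_study(20, n_days = 2, seed = 780)
  scored <- score_prompts(sim$prompts[sim$prompts$disposition == "answered", ])
  long <- selfreport_long(scored)
  fit <- fit_proximal_model(long, outcome = "stress",
                            covariates = "smoking",
                            times = c("pre", "post"))
  co <- fit$coefficients
  row <- co[co$term == "timepost", ]
  expect_true(row$ci_lo <= -0.12 && -0.12 <= row$ci_hi)
})
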