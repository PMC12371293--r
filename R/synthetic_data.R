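# Synthetic ambulatory person-days.
#
# The generator realizes the statistical structure the detector and the
# proximal-effect models assume: per-minute RMSSD coupled negatively to
# movement with person-specific intercept/slope, episodic nonmetabolic
# suppression ("vulnerability episodes", the construct the trigger is meant
# to catch), intervention-contingent HRV boosts after AddHRVr-triggered
# prompts, and pre-to-post declines in stress/rumination ratings.  Every
# downstream stage is testable against known generating values without any
# external data.

#' Person-level generator parameters
#'
#' @param intercept calibration intercept, ms (resting RMSSD at MET 0).
#' @param slope movement coupling, ms per MET; negative for eligible persons.
#' @param noise_sd per-minute RMSSD noise SD, ms.
#' @param episode_rate vulnerability episodes per monitoring day.
#' @param episode_len mean episode length, minutes (shifted exponential,
#'   see [place_episodes()]).
#' @param episode_min minimum episode length, minutes.
#' @param episode_depth episode RMSSD suppression in units of the person's
#'   calibration-day SD (so detector sensitivity transfers across persons).
#' @param smoker logical; smokers get occasional smoking bouts that lower
#'   ln RMSSD by the configured smoking effect.
#' @return list of class `person_params`.
#' @export
person_params <- function(intercept = 55, slope = -4, noise_sd = 4,
                          episode_rate = 1.5, episode_len = 55,
                          episode_min = 45, episode_depth = 2,
                          smoker = FALSE) {
  stopifnot(noise_sd >= 0, episode_depth >= 0, episode_rate >= 0,
            episode_len > 0, episode_min >= 0, episode_min < episode_len)
  structure(list(intercept = intercept, slope = slope, noise_sd = noise_sd,
                 episode_rate = episode_rate, episode_len = episode_len,
                 episode_min = episode_min, episode_depth = episode_depth,
                 smoker = isTRUE(smoker)),
            class = "person_params")
}

#' Draw a population of person parameters
#'
#' Person intercepts, slopes and noise SDs are drawn from truncated normal
#' populations; episode parameters are shared.
#'
#' @param n number of persons.
#' @param intercept_mean,intercept_sd population of calibration intercepts (ms).
#' @param slope_mean,slope_sd population of slopes (ms/MET); draws are
#'   truncated below `slope_max` so every generated person is eligible.
#' @param slope_max upper truncation for slopes (must stay negative).
#' @param noise_mean,noise_sd_sd population of per-minute noise SDs (ms).
#' @param smoker_prob probability a person is a smoker.
#' @param ... fixed episode parameters passed to [person_params()].
#' @return list of `person_params`.
#' @export
sample_person_params <- function(n, intercept_mean = 55, intercept_sd = 8,
                                 slope_mean = -4, slope_sd = 1.2,
                                 slope_max = -0.5, noise_mean = 4,
                                 noise_sd_sd = 0.8, smoker_prob = 0.25,
                                 ...) {
  stopifnot(slope_max < 0)
  draw_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  ints <- draw_trunc(n, intercept_mean, intercept_sd, lo = 25)
  slps <- draw_trunc(n, slope_mean, slope_sd, hi = slope_max)
  nsds <- draw_trunc(n, noise_mean, noise_sd_sd, lo = 2)
  smk <- stats::runif(n) < smoker_prob
  lapply(seq_len(n), function(i)
    person_params(intercept = ints[i], slope = slps[i], noise_sd = nsds[i],
                  smoker = smk[i], ...))
}

#' Per-prompt effect parameters
#'
#' Generating values for the quantities the evaluation models estimate.
#' Boost terms are on the natural-log RMSSD scale and are applied to
#' AddHRVr-triggered prompts only (the trigger is the low-state detector),
#' so the fitted trigger-by-time interaction targets them directly.
#' `met_effect`, `smoking_effect`, the main effects and the variance
#' components are used by the window-level generator
#' ([simulate_windows()]).
#'
#' @param time_effect_stress pre-to-post shift of the stress score (Likert
#'   units).
#' @param time_effect_rumination pre-to-post shift of the rumination rating.
#' @param during_boost ln-ms boost during an AddHRVr-triggered intervention.
#' @param post_boost ln-ms boost over the 10 minutes after it.
#' @param met_effect ln-ms per MET (window-level generator).
#' @param smoking_effect ln-ms for momentary smoking.
#' @param trigger_main,time_during,time_post,intervention_main ln-ms main
#'   effects (window-level generator).
#' @param trigger_time_stress interaction of trigger kind with the stress
#'   time shift (0 by default: the decline is trigger-independent).
#' @param trigger_time_rumination same for rumination.
#' @return list of class `effect_params`.
#' @export
effect_params <- function(time_effect_stress = -0.12,
                          time_effect_rumination = -0.11,
                          during_boost = 0.08, post_boost = 0.12,
                          met_effect = -0.35, smoking_effect = -0.03,
                          trigger_main = -0.35, time_during = 0.17,
                          time_post = 0.03, intervention_main = -0.02,
                          trigger_time_stress = 0,
                          trigger_time_rumination = 0) {
  out <- as.list(environment())
  stopifnot(all(vapply(out, function(x) is.numeric(x) && is.finite(x),
                       logical(1))))
  structure(out, class = "effect_params")
}

# Default activity-bout Markov chain (per-minute states).  Mean dwell
# times: sedentary ~20 min, walking ~8 min, exercise ~10 min; stationary
# occupancy roughly two thirds sedentary, mean ~2 MET over a waking day.
default_met_states <- function() c(sedentary = 1.3, walking = 3.0,
                                   exercise = 6.0)
default_met_trans <- function() {
  matrix(c(0.950, 0.045, 0.005,
           0.115, 0.875, 0.010,
           0.040, 0.060, 0.900),
         nrow = 3, byrow = TRUE,
         dimnames = rep(list(names(default_met_states())), 2))
}

# Stationary distribution of a row-stochastic matrix.
stationary_dist <- function(P) {
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  qr.solve(A, c(rep(0, n), 1))
}

#' Generate a per-minute movement series
#'
#' Piecewise activity bouts: a per-minute Markov chain over activity states
#' (sedentary, walking, exercise by default) whose state MET value is
#' jittered multiplicatively and floored at 0.9 MET.  The chain starts from
#' its stationary distribution.
#'
#' @param day_window `[start, end)` seconds since midnight.
#' @param states named numeric vector of state MET values.
#' @param trans row-stochastic transition matrix, one row per state.
#' @param jitter relative uniform jitter half-width (0.1 = +/-10 %).
#' @return numeric vector, one MET value per minute, with the state sequence
#'   in attribute `"state"`.
#' @export
generate_met_series <- function(day_window = c(9L, 21L) * 3600,
                                states = default_met_states(),
                                trans = default_met_trans(),
                                jitter = 0.1) {
  n_min <- (day_window[2] - day_window[1]) %/% 60
  k <- length(states)
  stopifnot(k >= 1, is.matrix(trans), nrow(trans) == k, ncol(trans) == k,
            all(abs(rowSums(trans) - 1) < 1e-8))
  s <- integer(n_min)
  s[1] <- sample.int(k, 1, prob = stationary_dist(trans))
  if (n_min > 1)
    for (i in 2:n_min) s[i] <- sample.int(k, 1, prob = trans[s[i - 1], ])
  met <- pmax(0.9, states[s] * stats::runif(n_min, 1 - jitter, 1 + jitter))
  structure(unname(met), state = names(states)[s])
}

#' Place vulnerability episodes in a day
#'
#' A Poisson number of non-overlapping, minute-aligned episodes with
#' shifted-exponential lengths: a minimum length plus an exponential tail,
#' with overall mean `mean_len`.  The default minimum of 45 minutes reflects
#' the detection horizon of the trigger rule: a qualifying state must span
#' the 28-minute flag window plus the 10-minute evaluation windows around a
#' prompt, so sub-horizon dips are not the construct the detector is built
#' to catch.  Episodes that cannot be placed without overlap after many
#' attempts are dropped (only relevant for extreme rates).
#'
#' @param rate expected number of episodes per day.
#' @param mean_len mean episode length in minutes.
#' @param min_len minimum episode length in minutes (`< mean_len`).
#' @param day_window `[start, end)` seconds since midnight.
#' @return data frame `start`, `end`: 1-based minute indices, end exclusive.
#' @export
place_episodes <- function(rate = 1.5, mean_len = 55, min_len = 45,
                           day_window = c(9L, 21L) * 3600) {
  stopifnot(rate >= 0, mean_len > 0, min_len >= 0, min_len < mean_len)
  n_min <- (day_window[2] - day_window[1]) %/% 60
  n_ep <- stats::rpois(1, rate)
  placed <- data.frame(start = integer(0), end = integer(0))
  if (n_ep == 0) return(placed)
  lens <- min_len + stats::rexp(n_ep, 1 / (mean_len - min_len))
  lens <- pmin(n_min, pmax(1L, round(lens)))
  for (len in lens) {
    for (try in seq_len(200L)) {
      st <- sample.int(n_min - len + 1L, 1)
      en <- st + len
      if (!nrow(placed) || all(en <= placed$start | st >= placed$end)) {
        placed <- rbind(placed, data.frame(start = st, end = en))
        break
      }
    }
  }
  placed[order(placed$start), , drop = FALSE]
}

# Minute-aligned smoking bouts for smokers: Poisson(rate) bouts of fixed
# length; returns logical per-minute indicator.
smoking_minutes <- function(n_min, smoker, rate = 4, bout_len = 10L) {
  ind <- rep(FALSE, n_min)
  if (!smoker) return(ind)
  n_b <- stats::rpois(1, rate)
  if (n_b == 0) return(ind)
  for (st in sample.int(max(1L, n_min - bout_len), n_b, replace = TRUE))
    ind[st:min(n_min, st + bout_len - 1L)] <- TRUE
  ind
}

# One monitoring day, simulated minute by minute in real time.
#
# RMSSD for minute i is
#   max(floor, intercept + slope*met_i + eps_i - depth*sd_ref*[episode]) *
#     exp(boost_i + smoking_effect*[smoking bout])
# where boost_i collects during/post intervention boosts of earlier AddHRVr
# prompts.  The flag and trailing-window count are evaluated sequentially,
# so trigger emission respects causality: boosts of an emitted trigger can
# only affect later minutes.
simulate_monitoring_day <- function(person, cal, effects, config,
                                    day_label, rmssd_floor = 1) {
  dw <- config$day_window
  n_min <- (dw[2] - dw[1]) %/% 60
  met <- generate_met_series(dw)
  episodes <- place_episodes(person$episode_rate, person$episode_len,
                             min_len = person$episode_min, day_window = dw)
  in_ep <- rep(FALSE, n_min)
  for (j in seq_len(nrow(episodes)))
    in_ep[episodes$start[j]:(episodes$end[j] - 1L)] <- TRUE
  smoke <- smoking_minutes(n_min, person$smoker)
  eps <- stats::rnorm(n_min, 0, person$noise_sd)
  base_raw <- person$intercept + person$slope * met + eps -
    person$episode_depth * cal$sd * in_ep
  pred <- cal$intercept + cal$slope * met
  randoms <- schedule_random(config)

  boost <- numeric(n_min)
  flags <- logical(n_min)
  obs <- numeric(n_min)
  win <- config$window_len
  thr <- config$threshold
  cnt <- 0L
  last_emit <- -Inf
  trig_time <- numeric(0); trig_cnt <- integer(0)
  for (i in seq_len(n_min)) {
    obs[i] <- pmax(rmssd_floor, base_raw[i]) *
      exp(boost[i] + effects$smoking_effect * smoke[i])
    flags[i] <- obs[i] <= pred[i] - config$k * cal$sd
    cnt <- cnt + flags[i] - (if (i > win) flags[i - win] else FALSE)
    t_i <- dw[1] + 60 * i
    if (cnt >= thr && t_i - last_emit >= config$silence) {
      last_emit <- t_i
      trig_time <- c(trig_time, t_i)
      trig_cnt <- c(trig_cnt, cnt)
      dur_idx <- (i + 1):(i + 2)               # intervention minute + next
      post_idx <- (i + 3):(i + 12)             # 10 minutes thereafter
      dur_idx <- dur_idx[dur_idx <= n_min]
      post_idx <- post_idx[post_idx <= n_min]
      boost[dur_idx] <- boost[dur_idx] + effects$during_boost
      boost[post_idx] <- boost[post_idx] + effects$post_boost
    }
  }

  triggers <- rbind(
    data.frame(kind = rep("addhrvr", length(trig_time)), time = trig_time,
               window_flag_count = trig_cnt, stringsAsFactors = FALSE),
    randoms)
  triggers <- triggers[order(triggers$time), , drop = FALSE]
  minute_start <- seq(dw[1], dw[2] - 60, by = 60)
  minutes <- data.frame(
    person_id = person$id %||% NA, day = day_label,
    minute_start = minute_start, rmssd = obs, sdnn = NA_real_,
    hf = NA_real_, lf = NA_real_, met = met, valid = TRUE,
    n_beats = NA_integer_, flag = flags, in_episode = in_ep,
    smoking = smoke, stringsAsFactors = FALSE)
  prompt_min <- pmin(n_min, floor((triggers$time - dw[1]) / 60) + 1L)
  prompts <- data.frame(
    person_id = person$id %||% NA, day = day_label,
    time = triggers$time, trigger_kind = triggers$kind,
    window_flag_count = triggers$window_flag_count,
    in_episode = in_ep[prompt_min], smoking = smoke[prompt_min],
    stringsAsFactors = FALSE)
  list(minutes = minutes, triggers = triggers, prompts = prompts)
}

# Calibration day: same chain without episodes, prompts or boosts.
simulate_calibration_day <- function(person, config, day_label = "1",
                                     rmssd_floor = 1) {
  dw <- config$day_window
  n_min <- (dw[2] - dw[1]) %/% 60
  met <- generate_met_series(dw)
  obs <- pmax(rmssd_floor,
              person$intercept + person$slope * met +
                stats::rnorm(n_min, 0, person$noise_sd))
  data.frame(person_id = person$id %||% NA, day = day_label,
             minute_start = seq(dw[1], dw[2] - 60, by = 60), rmssd = obs,
             sdnn = NA_real_, hf = NA_real_, lf = NA_real_, met = met,
             valid = TRUE, n_beats = NA_integer_, flag = FALSE,
             in_episode = FALSE, smoking = FALSE, stringsAsFactors = FALSE)
}

#' Synthesize an IBI stream realizing per-minute RMSSD targets
#'
#' For each minute, a beat train is generated whose mean interval follows
#' heart rate modulated by movement (higher MET, shorter intervals) and
#' whose deviations — an optional band-limited respiratory sinus arrhythmia
#' sinusoid plus Gaussian increments — are rescaled so the realized minute
#' RMSSD matches the target exactly (RMSSD is linear in the deviations).
#' Beats stay inside their minute; the small residual gap at each minute
#' boundary is tolerated by [ibi_series()] as a marked gap.
#'
#' @param targets per-minute RMSSD targets, ms (length = minutes in window).
#' @param met per-minute MET values (same length).
#' @param person_id,day labels for the resulting series.
#' @param day_window `[start, end)` seconds since midnight.
#' @param hr_base,hr_slope heart rate model: `hr = hr_base + hr_slope *
#'   (met - 1)` beats/min.
#' @param rsa_freq respiratory sinus arrhythmia frequency, Hz (`NULL` for
#'   pure Gaussian increments).
#' @param rsa_frac fraction of deviation variance carried by the sinusoid.
#' @return an [ibi_series()].
#' @export
generate_ibis <- function(targets, met, person_id = "p1", day = "1",
                          day_window = c(9L, 21L) * 3600, hr_base = 65,
                          hr_slope = 11, rsa_freq = 0.25, rsa_frac = 0.3) {
  n_min <- length(targets)
  stopifnot(length(met) == n_min, all(targets > 0 | is.na(targets)))
  t_all <- numeric(0); ibi_all <- numeric(0)
  starts <- seq(day_window[1], by = 60, length.out = n_min)
  for (i in seq_len(n_min)) {
    if (is.na(targets[i])) next
    mean_ibi <- 60000 / (hr_base + hr_slope * (met[i] - 1))
    n <- max(4L, floor(60000 / mean_ibi))
    tk <- (seq_len(n) - 1) * mean_ibi / 1000
    d0 <- stats::rnorm(n)
    if (!is.null(rsa_freq) && rsa_frac > 0)
      d0 <- sqrt(1 - rsa_frac) * d0 +
        sqrt(2 * rsa_frac) * sin(2 * pi * rsa_freq * tk)
    r0 <- rmssd(d0)
    if (!is.na(r0) && r0 > 0) d0 <- d0 * targets[i] / r0 else d0 <- d0 * 0
    ibi <- mean_ibi + d0 - mean(d0)
    ibi <- pmax(ibi, 1)                     # never non-positive
    tt <- starts[i] + c(0, cumsum(ibi[-n])) / 1000
    keep <- tt < starts[i] + 60
    t_all <- c(t_all, tt[keep]); ibi_all <- c(ibi_all, ibi[keep])
  }
  ibi_series(person_id, day, t_all, ibi_all)
}

#' Generate pre/post self-reports for a prompt table
#'
#' Latent pre-intervention stress is baseline plus an in-episode lift plus
#' noise; it maps to four 1-5 items of which the first three are stored
#' reverse-coded (as collected).  Post-intervention stress shifts by the
#' configured time effect (plus an optional trigger interaction) before the
#' same mapping.  Rumination is a single analogous item.  A disposition
#' (answered / ignored / dismissed / incomplete) is sampled per prompt;
#' non-answered prompts have the corresponding items missing.
#'
#' Item values are continuous on the 1-5 scale by default (clipped), so
#' configured shifts are recovered exactly under zero noise; set
#' `discretize = TRUE` for integer Likert responses.
#'
#' @param prompts prompt table with columns `trigger_kind`, `in_episode`.
#' @param effects an [effect_params()].
#' @param baseline_stress,baseline_rumination latent scale baselines.
#' @param episode_lift latent stress/rumination lift while in an episode.
#' @param latent_sd,item_sd latent and per-item noise SDs.
#' @param disposition_probs named probabilities for
#'   answered/ignored/dismissed/incomplete.
#' @param discretize round items to integer Likert values.
#' @return the prompt table with item columns `stress_pre_1..4`,
#'   `stress_post_1..4`, `rumination_pre`, `rumination_post`, `disposition`.
#' @export
generate_selfreports <- function(prompts, effects = effect_params(),
                                 baseline_stress = 2.2,
                                 baseline_rumination = 2.0,
                                 episode_lift = 0.6, latent_sd = 0.4,
                                 item_sd = 0.3,
                                 disposition_probs = c(answered = 0.69,
                                                       ignored = 0.19,
                                                       dismissed = 0.04,
                                                       incomplete = 0.08),
                                 discretize = FALSE) {
  n <- nrow(prompts)
  stopifnot(abs(sum(disposition_probs) - 1) < 1e-8)
  trig <- as.integer(prompts$trigger_kind == "addhrvr")
  ep <- as.integer(prompts$in_episode %||% rep(0L, n))
  clipit <- function(x) {
    x <- pmin(5, pmax(1, x))
    if (discretize) round(x) else x
  }
  item <- function(latent, reverse = FALSE) {
    v <- clipit(latent + stats::rnorm(n, 0, item_sd))
    if (reverse) 6 - v else v
  }
  pre_s <- baseline_stress + episode_lift * ep + stats::rnorm(n, 0, latent_sd)
  post_s <- pre_s + effects$time_effect_stress +
    effects$trigger_time_stress * trig
  pre_r <- baseline_rumination + episode_lift * ep +
    stats::rnorm(n, 0, latent_sd)
  post_r <- pre_r + effects$time_effect_rumination +
    effects$trigger_time_rumination * trig
  out <- prompts
  for (j in 1:4) {
    out[[paste0("stress_pre_", j)]] <- item(pre_s, reverse = j <= 3)
    out[[paste0("stress_post_", j)]] <- item(post_s, reverse = j <= 3)
  }
  out$rumination_pre <- item(pre_r)
  out$rumination_post <- item(post_r)
  out$disposition <- sample(names(disposition_probs), n, replace = TRUE,
                            prob = disposition_probs)
  miss <- out$disposition != "answered"
  item_cols <- c(paste0("stress_pre_", 1:4), paste0("stress_post_", 1:4),
                 "rumination_pre", "rumination_post")
  post_cols <- c(paste0("stress_post_", 1:4), "rumination_post")
  out[out$disposition %in% c("ignored", "dismissed"), item_cols] <- NA_real_
  out[out$disposition == "incomplete", post_cols] <- NA_real_
  out
}

#' Simulate a full study cohort
#'
#' One calibration day plus `n_days` monitoring days per person, with
#' per-person calibration fits, real-time trigger detection, random prompt
#' schedules, intervention-contingent HRV boosts, and self-reports.  With
#' `fidelity = "ibi"` every person-day is additionally realized as a beat
#' stream and the per-minute records are recomputed from it through
#' [segment_minutes()]; the default `"minutes"` fidelity generates the
#' per-minute RMSSD directly (orders of magnitude faster, identical
#' statistical structure).
#'
#' Randomness is split per person: person `i` uses seed `seed + 1000 * i`,
#' so cohorts are reproducible and persons independent of ordering.
#'
#' @param n_persons number of persons.
#' @param n_days monitoring days per person (default 3).
#' @param effects an [effect_params()].
#' @param config a [trigger_config()].
#' @param persons optional list of [person_params()] (default: drawn from
#'   [sample_person_params()]).
#' @param design `"study1"` (one intervention) or `"study2"`
#'   (microrandomized mindful vs external intervention).
#' @param p_intervention probability of the mindful intervention under
#'   `"study2"`.
#' @param fidelity `"minutes"` or `"ibi"`.
#' @param seed master seed (integer) or `NULL` to use the current RNG state.
#' @param ... passed to [sample_person_params()] when `persons` is `NULL`.
#' @return list with `minutes`, `prompts`, `triggers`, `calibrations`
#'   (list of models), `calibration_table`, `persons`, `uncalibratable`
#'   (character ids of persons skipped for too few usable minutes or a
#'   non-negative slope).
#' @export
simulate_study <- function(n_persons, n_days = 3, effects = effect_params(),
                           config = trigger_config(), persons = NULL,
                           design = c("study1", "study2"),
                           p_intervention = 0.5,
                           fidelity = c("minutes", "ibi"), seed = NULL,
                           ...) {
  design <- match.arg(design)
  fidelity <- match.arg(fidelity)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(persons)) persons <- sample_person_params(n_persons, ...)
  stopifnot(length(persons) == n_persons, n_days >= 0)
  person_seeds <- if (is.null(seed)) sample.int(2^30, n_persons) else
    seed + 1000L * seq_len(n_persons)

  all_minutes <- list(); all_prompts <- list(); cals <- list()
  dropped <- character(0)
  for (i in seq_len(n_persons)) {
    set.seed(person_seeds[i])
    p <- persons[[i]]
    p$id <- sprintf("p%03d", i)
    cal_minutes <- simulate_calibration_day(p, config)
    cal <- tryCatch(fit_calibration(cal_minutes),
                    addhrvr_uncalibratable = function(e) NULL)
    if (is.null(cal) || !cal$eligible) {
      dropped <- c(dropped, p$id)
      next
    }
    days <- list(cal_minutes)
    prompts_i <- list()
    for (d in seq_len(n_days)) {
      sim <- simulate_monitoring_day(p, cal, effects, config,
                                     day_label = as.character(d + 1))
      days[[d + 1]] <- sim$minutes
      prompts_i[[d]] <- sim$prompts
    }
    minutes_i <- do.call(rbind, days)
    prompts_i <- if (length(prompts_i)) do.call(rbind, prompts_i) else NULL
    if (fidelity == "ibi") {
      redone <- lapply(unique(minutes_i$day), function(dl) {
        md <- minutes_i[minutes_i$day == dl, ]
        ser <- generate_ibis(md$rmssd, md$met, person_id = p$id, day = dl,
                             day_window = config$day_window)
        seg <- segment_minutes(ser, day_window = config$day_window,
                               met = md$met, bands = FALSE)
        seg$flag <- md$flag; seg$in_episode <- md$in_episode
        seg$smoking <- md$smoking
        seg
      })
      minutes_i <- do.call(rbind, redone)
    }
    if (!is.null(prompts_i) && nrow(prompts_i)) {
      prompts_i$intervention_kind <- if (design == "study1") "breathing"
        else ifelse(stats::runif(nrow(prompts_i)) < p_intervention,
                    "mindful", "external")
      prompts_i$prompt_id <- sprintf("%s_%s_%02d", p$id, prompts_i$day,
                                     seq_len(nrow(prompts_i)))
      prompts_i <- generate_selfreports(prompts_i, effects)
    }
    cals[[p$id]] <- cal
    all_minutes[[p$id]] <- minutes_i
    all_prompts[[p$id]] <- prompts_i
  }
  minutes <- do.call(rbind, all_minutes)
  all_prompts <- Filter(Negate(is.null), all_prompts)
  prompts <- if (length(all_prompts)) do.call(rbind, all_prompts) else NULL
  rownames(minutes) <- NULL
  if (!is.null(prompts)) rownames(prompts) <- NULL
  triggers <- if (!is.null(prompts) && nrow(prompts))
    prompts[c("person_id", "day", "trigger_kind", "time",
              "window_flag_count")] else NULL
  list(minutes = minutes, prompts = prompts, triggers = triggers,
       calibrations = cals, calibration_table = calibration_table(cals),
       persons = persons, uncalibratable = dropped)
}

#' Generate outcome windows directly from the multilevel model
#'
#' Bypasses the physiological chain and draws ln RMSSD window outcomes from
#' the mixed model the evaluation stage fits: random person intercepts
#' (variance `tau00`), fixed effects for movement, smoking, trigger kind,
#' time and their interactions (from [effect_params()]), and residual
#' variance `sigma2`.  This is the reference generator for estimator
#' calibration: type-I error, variance-component and interaction recovery
#' can be checked against exactly known values.
#'
#' @param n_persons persons.
#' @param prompts_per_person prompts per person.
#' @param effects an [effect_params()].
#' @param sigma2 within-person residual variance (ln scale).
#' @param tau00 between-person intercept variance (ln scale).
#' @param mu grand intercept (ln ms).
#' @param p_addhrvr probability a prompt is AddHRVr-triggered.
#' @param design `"study1"` or `"study2"` (adds intervention terms).
#' @param times which window rows to generate.
#' @return a windows data frame compatible with [fit_proximal_model()].
#' @export
simulate_windows <- function(n_persons = 30, prompts_per_person = 30,
                             effects = effect_params(), sigma2 = 0.23,
                             tau00 = 0.13, mu = 3.53, p_addhrvr = 0.3,
                             design = c("study1", "study2"),
                             times = c("pre", "during", "post")) {
  design <- match.arg(design)
  alpha <- stats::rnorm(n_persons, mu, sqrt(tau00))
  rows <- vector("list", n_persons)
  for (p in seq_len(n_persons)) {
    np <- prompts_per_person
    trig <- stats::runif(np) < p_addhrvr
    intv <- if (design == "study2") stats::runif(np) < 0.5 else
      rep(FALSE, np)
    smk <- stats::runif(np) < 0.1
    met <- pmax(0.9, stats::rnorm(np, 1.9, 0.6))
    g <- expand.grid(prompt = seq_len(np), time = times,
                     stringsAsFactors = FALSE)
    tr <- trig[g$prompt]; iv <- intv[g$prompt]
    dur <- g$time == "during"; pos <- g$time == "post"
    eta <- alpha[p] + effects$met_effect * (met[g$prompt] - 1.9) +
      effects$smoking_effect * smk[g$prompt] +
      effects$trigger_main * tr +
      effects$time_during * dur + effects$time_post * pos +
      effects$during_boost * tr * dur + effects$post_boost * tr * pos
    if (design == "study2")
      eta <- eta + effects$intervention_main * iv
    y <- eta + stats::rnorm(nrow(g), 0, sqrt(sigma2))
    rows[[p]] <- data.frame(
      person_id = sprintf("p%03d", p),
      prompt_id = sprintf("p%03d_%02d", p, g$prompt),
      trigger_kind = ifelse(tr, "addhrvr", "random"),
      intervention_kind = if (design == "study2")
        ifelse(iv, "mindful", "external") else "breathing",
      time = g$time, time_code = c(pre = -1, during = 0, post = 1)[g$time],
      ln_rmssd = y, met_mean = met[g$prompt], smoking = smk[g$prompt],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$time <- factor(out$time, levels = c("pre", "during", "post"))
  rownames(out) <- NULL
  out
}
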