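# Real-time trigger rule and prompt scheduling.
#
# Per-minute flags stream through a trailing-window rule: a prompt fires at
# the first minute whose trailing 28-minute window (current minute included)
# contains at least 13 flagged minutes, unless a previous trigger fired less
# than the silence period (60 min) ago.  Random prompts are scheduled
# independently.  An offline pass over the same flags finds "virtual"
# triggers: windows that satisfied the rule but never fired in real time
# (typically suppressed by silence), used as no-intervention controls.

#' Trigger-rule configuration
#'
#' @param window_len trailing-window length in minutes (default 28).
#' @param threshold flagged-minute count required in the window (default 13).
#' @param k SD multiplier for the per-minute flag (default 0.5).
#' @param silence refractory period after an emitted trigger, seconds
#'   (default 3600).
#' @param day_window monitoring window `[start, end)` in seconds since
#'   midnight (default 09:00-21:00).
#' @param random_rate random prompts per day (default 15).
#' @param random_min_gap minimal gap between random prompts, seconds
#'   (default 1200).
#' @param virtual_buffer exclusion zone around any real prompt when scanning
#'   for virtual triggers, seconds (default 600).
#' @return list of class `trigger_config`.
#' @export
trigger_config <- function(window_len = 28L, threshold = 13L, k = 0.5,
                           silence = 3600, day_window = c(9L, 21L) * 3600,
                           random_rate = 15L, random_min_gap = 1200,
                           virtual_buffer = 600) {
  stopifnot(is_count(window_len), window_len >= 1,
            is_count(threshold), length(day_window) == 2L,
            day_window[2] > day_window[1], silence >= 0,
            random_rate >= 0, random_min_gap >= 0, virtual_buffer >= 0)
  if (threshold < 1 || threshold > window_len)
    stop_addhrvr("threshold must satisfy 1 <= threshold <= window_len",
                 "addhrvr_bad_config")
  structure(list(window_len = as.integer(window_len),
                 threshold = as.integer(threshold), k = k,
                 silence = silence, day_window = day_window,
                 random_rate = random_rate, random_min_gap = random_min_gap,
                 virtual_buffer = virtual_buffer),
            class = "trigger_config")
}

# Trailing-window flagged-minute counts, window inclusive of current minute,
# clipped at the day start.  flags: logical vector, NA treated as FALSE.
trailing_counts <- function(flags, window_len) {
  f <- as.integer(!is.na(flags) & flags)
  cs <- cumsum(f)
  lag <- c(rep(0L, min(window_len, length(f))),
           cs[seq_len(max(0L, length(f) - window_len))])
  cs - lag
}

#' Detect AddHRVr triggers in real time
#'
#' Scans the day's per-minute flags in time order and emits a trigger at the
#' first minute whose trailing window (current minute included, clipped at
#' the day start) contains at least `threshold` flagged minutes, provided no
#' previous trigger fired within the silence period.  The emission timestamp
#' is the end of the qualifying minute — the earliest moment the rule can be
#' known to hold in real time.  Missing minutes must be passed as `FALSE`
#' (or `NA`, treated as not flagged).
#'
#' @param flags logical vector, one element per calendar minute of the day
#'   window.
#' @param config a [trigger_config()].
#' @param day_start first minute's start in seconds since midnight (default:
#'   the config's day window start).
#' @return data frame of events: `kind` (`"addhrvr"`), `time` (seconds since
#'   midnight), `window_flag_count`.
#' @export
detect_triggers <- function(flags, config = trigger_config(),
                            day_start = config$day_window[1]) {
  stopifnot(inherits(config, "trigger_config"))
  cnt <- trailing_counts(flags, config$window_len)
  qualifying <- which(cnt >= config$threshold)
  times <- numeric(0); counts <- integer(0)
  last <- -Inf
  for (i in qualifying) {
    t_i <- day_start + 60 * i            # end of minute i (1-based)
    if (t_i - last >= config$silence || !is.finite(last)) {
      times <- c(times, t_i); counts <- c(counts, cnt[i]); last <- t_i
    }
  }
  data.frame(kind = rep("addhrvr", length(times)), time = times,
             window_flag_count = counts, stringsAsFactors = FALSE)
}

#' Schedule random prompts over a day
#'
#' Draws prompt times uniformly over the day window conditional on all gaps
#' being at least `min_gap` (gap-shrinkage construction: uniform draws in the
#' window shortened by the total mandatory gap, then spread back out).
#' Reproducible under a fixed RNG state.
#'
#' @param config a [trigger_config()]; supplies defaults below.
#' @param rate number of prompts.
#' @param min_gap minimal separation in seconds.
#' @param day_window `[start, end)` seconds since midnight.
#' @return data frame of events: `kind` (`"random"`), `time`,
#'   `window_flag_count` (`NA`).
#' @export
schedule_random <- function(config = trigger_config(),
                            rate = config$random_rate,
                            min_gap = config$random_min_gap,
                            day_window = config$day_window) {
  stopifnot(rate >= 0, min_gap >= 0)
  rate <- as.integer(rate)
  empty <- data.frame(kind = character(0), time = numeric(0),
                      window_flag_count = numeric(0),
                      stringsAsFactors = FALSE)
  if (rate == 0L) return(empty)
  span <- day_window[2] - day_window[1]
  slack <- span - (rate - 1) * min_gap
  if (slack <= 0)
    stop_addhrvr("infeasible random schedule: rate * min_gap exceeds window",
                 "addhrvr_bad_config")
  u <- sort(stats::runif(rate, 0, slack))
  times <- day_window[1] + u + (seq_len(rate) - 1) * min_gap
  data.frame(kind = rep("random", rate), time = times,
             window_flag_count = rep(NA_real_, rate),
             stringsAsFactors = FALSE)
}

#' Scan offline for virtual triggers
#'
#' Replays the day's flags after the fact and collects minutes that satisfied
#' the trigger rule but where no real trigger fired — typically because the
#' silence period suppressed the prompt.  A virtual event must sit at least
#' one full trailing window after the previous real trigger (so the same
#' flagged-minute mass is not recounted as a new event), keeps the silence
#' spacing to other virtual events, and is excluded within a buffer around
#' any real prompt, so its pre/post windows are intervention-free and can
#' serve as spontaneous-recovery controls.
#'
#' @param flags per-minute flags as in [detect_triggers()].
#' @param emitted data frame of the person-day's real AddHRVr events
#'   ([detect_triggers()] output).
#' @param config a [trigger_config()].
#' @param prompt_times numeric vector of all real prompt times (AddHRVr and
#'   random) used for the exclusion buffer; defaults to the emitted AddHRVr
#'   times.
#' @param day_start first minute's start, seconds since midnight.
#' @return data frame of events: `kind` (`"virtual"`), `time`,
#'   `window_flag_count`.
#' @export
scan_virtual <- function(flags, emitted, config = trigger_config(),
                         prompt_times = NULL,
                         day_start = config$day_window[1]) {
  stopifnot(inherits(config, "trigger_config"))
  real_times <- if (is.data.frame(emitted)) emitted$time else as.numeric(emitted)
  prompt_times <- prompt_times %||% real_times
  cnt <- trailing_counts(flags, config$window_len)
  qualifying <- which(cnt >= config$threshold)
  times <- numeric(0); counts <- integer(0)
  last_virtual <- -Inf
  for (i in qualifying) {
    t_i <- day_start + 60 * i
    if (t_i %in% real_times) next
    if (length(prompt_times) &&
        min(abs(t_i - prompt_times)) < config$virtual_buffer) next
    prior <- real_times[real_times < t_i]
    if (length(prior) && t_i - max(prior) < 60 * config$window_len) next
    if (t_i - last_virtual < config$silence) next
    times <- c(times, t_i); counts <- c(counts, cnt[i])
    last_virtual <- t_i
  }
  data.frame(kind = rep("virtual", length(times)), time = times,
             window_flag_count = counts, stringsAsFactors = FALSE)
}

#' Write a trigger log to CSV
#' @param triggers data frame with at least `kind`, `time`,
#'   `window_flag_count` (plus optional `person_id`, `day`).
#' @param path file path.
#' @export
write_trigger_csv <- function(triggers, path) {
  utils::write.csv(triggers, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trigger log from CSV
#' @param path file path.
#' @return data frame.
#' @export
read_trigger_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a trigger configuration from YAML
#'
#' Any subset of the [trigger_config()] fields may be given; the rest keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a `trigger_config`.
#' @export
read_trigger_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(trigger_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_addhrvr(paste("unknown trigger config keys:",
                       paste(bad, collapse = ", ")), "addhrvr_bad_config")
  do.call(trigger_config, vals)
}
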