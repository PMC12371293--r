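# Independent brute-force references and small construction helpers.

# Plain replay of the trailing-window trigger rule: explicit window sum per
# minute plus a literal silence clock.  Deliberately naive; the engine under
# test uses cumulative counts instead.
oracle_detect <- function(flags, window_len = 28L, threshold = 13L,
                          silence = 3600, day_start = 9 * 3600) {
  flags <- !is.na(flags) & flags
  times <- numeric(0); counts <- integer(0)
  last <- -Inf
  for (i in seq_along(flags)) {
    cnt <- sum(flags[max(1L, i - window_len + 1L):i])
    t_i <- day_start + 60 * i
    if (cnt >= threshold && t_i - last >= silence) {
      times <- c(times, t_i); counts <- c(counts, cnt); last <- t_i
    }
  }
  data.frame(kind = rep("addhrvr", length(times)), time = times,
             window_flag_count = counts, stringsAsFactors = FALSE)
}

# Stationary distribution of a row-stochastic matrix via the eigen route
# (the package solves a linear system instead).
oracle_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Minute table with given RMSSD/MET vectors, all valid.
make_minutes <- function(rmssd, met, person_id = "p1", day = "1",
                         day_start = 9 * 3600) {
  n <- length(rmssd)
  data.frame(person_id = person_id, day = day,
             minute_start = seq(day_start, by = 60, length.out = n),
             rmssd = rmssd, sdnn = NA_real_, hf = NA_real_, lf = NA_real_,
             met = met, valid = TRUE, n_beats = 75L,
             stringsAsFactors = FALSE)
}

# Beat train with constant interval (ms) covering [from, to) seconds.
make_constant_beats <- function(from, to, ibi = 800) {
  t <- seq(from, to - ibi / 1000, by = ibi / 1000)
  list(t = t, ibi = rep(ibi, length(t)))
}

# Hand-built pre/post windows table for the virtual-trigger contrast:
# person intercepts + per-kind post shifts + iid noise.
make_virtual_windows <- function(n_persons = 20, per_kind = 6,
                                 post_shift = c(virtual = 0.05,
                                                random = 0.03,
                                                addhrvr = 0.17),
                                 sd = 0.15) {
  rows <- list()
  for (p in seq_len(n_persons)) {
    a <- stats::rnorm(1, 3.5, 0.3)
    for (kind in names(post_shift)) {
      for (r in seq_len(per_kind)) {
        pid <- sprintf("p%02d_%s_%d", p, kind, r)
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = sprintf("p%02d", p), prompt_id = pid,
          trigger_kind = kind, time = c("pre", "post"),
          ln_rmssd = a + c(0, post_shift[[kind]]) + stats::rnorm(2, 0, sd),
          met_mean = 1.9, smoking = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$time <- factor(out$time, levels = c("pre", "post"))
  out
}
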