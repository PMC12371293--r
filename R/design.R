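# Microrandomized-trial design helpers and worked-example arithmetic.

#' MRT design specification
#'
#' Inputs to the microrandomized-trial sample-size calculation for a
#' constant (standardized) proximal treatment effect with constant expected
#' availability.
#'
#' @param days trial duration in days.
#' @param occasions_per_day decision points per day.  Defaults to 10, the
#'   value recorded in the package's design-calibration note: with 10
#'   decision points per day the published sample-size methodology maps the
#'   default design to the reference sample sizes exactly.
#' @param p_rand randomization probability at a decision point.
#' @param availability expected availability (probability a decision point
#'   is usable).
#' @param effect standardized proximal effect size.
#' @param effect_shape only `"constant"` is implemented.
#' @param power target power.
#' @param alpha two-sided significance level.
#' @return list of class `mrt_design`.
#' @export
mrt_design <- function(days = 4, occasions_per_day = 10, p_rand = 0.40,
                       availability = 0.75, effect = 0.2,
                       effect_shape = "constant", power = 0.80,
                       alpha = 0.05) {
  stopifnot(is_count(days), days >= 1, is_count(occasions_per_day),
            occasions_per_day >= 1, p_rand > 0, p_rand < 1,
            availability > 0, availability <= 1, effect > 0,
            power > 0, power < 1, alpha > 0, alpha < 1)
  if (!identical(effect_shape, "constant"))
    stop_addhrvr("only the constant proximal-effect shape is implemented",
                 "addhrvr_bad_config")
  structure(as.list(environment()), class = "mrt_design")
}

#' Power of an MRT of size n
#'
#' Power of the Wald-type test of a constant proximal effect with the
#' small-sample F correction: the test statistic is referred to an
#' F(p, n - q - p) distribution (p = 1 effect parameter, q = 1 nuisance
#' parameter), with noncentrality
#' `n * T * availability * p_rand * (1 - p_rand) * effect^2` over the
#' T = days x occasions decision points.
#'
#' @param n number of participants.
#' @param design an [mrt_design()].
#' @return power in `[0, 1]`.
#' @export
mrt_power <- function(n, design = mrt_design()) {
  stopifnot(inherits(design, "mrt_design"))
  p <- 1L; q <- 1L
  df2 <- n - q - p
  if (df2 < 1) return(0)
  T_dp <- design$days * design$occasions_per_day
  ncp <- n * T_dp * design$availability * design$p_rand *
    (1 - design$p_rand) * design$effect^2
  crit <- stats::qf(1 - design$alpha, p, df2)
  1 - stats::pf(crit, p, df2, ncp = ncp)
}

#' Minimal MRT sample size
#'
#' Smallest integer number of participants whose [mrt_power()] reaches the
#' design's target power.  Nonincreasing in effect size, availability and
#' the number of decision points; nondecreasing in target power.
#'
#' @param design an [mrt_design()].
#' @param n_max search bound.
#' @return minimal N (integer), with the achieved power as attribute
#'   `"power"`.
#' @export
mrt_sample_size <- function(design = mrt_design(), n_max = 10000L) {
  stopifnot(inherits(design, "mrt_design"))
  for (n in 3:n_max) {
    pw <- mrt_power(n, design)
    if (pw >= design$power)
      return(structure(as.integer(n), power = pw))
  }
  stop_addhrvr(sprintf("target power %.2f not attainable with N <= %d",
                       design$power, n_max), "addhrvr_unattainable")
}

#' Summarize prompt dispositions
#'
#' Counts per disposition category (answered, dismissed, ignored,
#' incomplete) and their percentage of the total, rounded half-up to two
#' decimals as in printed compliance tables.
#'
#' @param x a prompt table with a `disposition` column, or a named count
#'   vector.
#' @param total denominator for the percentages; defaults to the sum of the
#'   counts (some published totals include undelivered prompts, in which
#'   case pass the printed total explicitly).
#' @return data frame `disposition`, `count`, `pct`.
#' @export
summarize_prompts <- function(x, total = NULL) {
  categories <- c("answered", "dismissed", "ignored", "incomplete")
  if (is.data.frame(x)) {
    if (is.null(x$disposition))
      stop_addhrvr("prompt table needs a disposition column",
                   "addhrvr_bad_input")
    bad <- setdiff(unique(x$disposition), categories)
    if (length(bad))
      stop_addhrvr(paste("unknown disposition categories:",
                         paste(bad, collapse = ", ")), "addhrvr_bad_input")
    counts <- table(factor(x$disposition, levels = categories))
    counts <- as.vector(counts); names(counts) <- categories
    counts <- counts[counts > 0 | categories %in% unique(x$disposition)]
  } else {
    counts <- x
    bad <- setdiff(names(counts), categories)
    if (length(bad))
      stop_addhrvr(paste("unknown disposition categories:",
                         paste(bad, collapse = ", ")), "addhrvr_bad_input")
  }
  total <- total %||% sum(counts)
  data.frame(disposition = names(counts), count = as.numeric(counts),
             pct = round_half_up(100 * as.numeric(counts) / total),
             stringsAsFactors = FALSE)
}

#' Paced-breathing pattern
#'
#' Inhale/exhale phase durations and the derived breathing-cycle frequency;
#' the 4 s / 6 s default gives the 0.1 Hz slow-paced breathing used to drive
#' low-frequency cardiac resonance (also the simulator's RSA input).
#'
#' @param inhale inhalation duration, seconds.
#' @param exhale exhalation duration, seconds.
#' @return list with `inhale`, `exhale`, `cycle` (s) and `freq` (Hz).
#' @export
breathing_pattern <- function(inhale = 4, exhale = 6) {
  stopifnot(inhale > 0, exhale > 0)
  cycle <- inhale + exhale
  list(inhale = inhale, exhale = exhale, cycle = cycle, freq = 1 / cycle)
}
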