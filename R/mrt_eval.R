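# Outcome-window construction and proximal-effect estimation.
#
# Each prompt contributes up to three observation windows on the ln HRV
# scale: the 10 minutes before the prompt (time code -1), the intervention
# phase (+/-2 minutes around the 1-minute intervention, code 0), and the 10
# minutes after it (code +1).  Multilevel models with a random person
# intercept estimate the proximal effect of AddHRVr-triggered versus random
# prompts as the trigger-by-time interaction (three-way with intervention
# type for two-intervention designs), and the virtual-trigger contrast
# separates the intervention effect from spontaneous HRV rebound.

#' Score the four-item perceived-stress scale
#'
#' Items are rated 1-5; reverse-coded items (by default the first three,
#' stored as collected) are reflected as `6 - raw` before averaging.  Any
#' missing item makes the score missing — no partial means.
#'
#' @param items numeric vector of 4 ratings, or an n-by-4 matrix/data frame.
#' @param reverse logical mask of reverse-coded items.
#' @return mean score(s) in `[1, 5]`.
#' @export
score_stress <- function(items, reverse = c(TRUE, TRUE, TRUE, FALSE)) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1) else as.matrix(items)
  stopifnot(ncol(m) == length(reverse))
  ok <- is.na(m) | (m >= 1 & m <= 5)
  if (!all(ok)) stop_addhrvr("item ratings must lie in [1, 5]",
                             "addhrvr_bad_input")
  m[, reverse] <- 6 - m[, reverse]
  out <- rowMeans(m)             # NA if any item missing
  if (is.null(dim(items))) out[[1]] else out
}

#' Score a prompt table's self-reports
#'
#' Applies [score_stress()] to the pre and post item sets and carries the
#' single rumination item through.
#'
#' @param prompts a prompt table with `stress_pre_1..4`, `stress_post_1..4`,
#'   `rumination_pre`, `rumination_post` (as from [generate_selfreports()]).
#' @return the table with `stress_pre`, `stress_post` score columns added.
#' @export
score_prompts <- function(prompts) {
  pre <- as.matrix(prompts[paste0("stress_pre_", 1:4)])
  post <- as.matrix(prompts[paste0("stress_post_", 1:4)])
  prompts$stress_pre <- score_stress(pre)
  prompts$stress_post <- score_stress(post)
  prompts
}

#' Reshape scored prompts to a pre/post analysis table
#'
#' @param prompts scored prompt table ([score_prompts()]).
#' @return long data frame with one row per prompt and time (`pre`/`post`),
#'   columns `stress` and `rumination`, compatible with
#'   [fit_proximal_model()].
#' @export
selfreport_long <- function(prompts) {
  base_cols <- intersect(c("person_id", "day", "prompt_id", "trigger_kind",
                           "intervention_kind", "smoking"), names(prompts))
  mk <- function(time, s, r) {
    d <- prompts[base_cols]
    d$time <- time; d$stress <- s; d$rumination <- r
    d
  }
  out <- rbind(mk("pre", prompts$stress_pre, prompts$rumination_pre),
               mk("post", prompts$stress_post, prompts$rumination_post))
  out$time <- factor(out$time, levels = c("pre", "post"))
  rownames(out) <- NULL
  out
}

# Aggregate ln-transformed minute HRV over a minute-start span.
# ln is applied per minute before averaging; only valid minutes count.
aggregate_span <- function(day_minutes, lo, hi, lo_open = FALSE,
                           hi_open = TRUE) {
  ms <- day_minutes$minute_start
  sel <- (if (lo_open) ms > lo else ms >= lo) &
         (if (hi_open) ms < hi else ms <= hi)
  d <- day_minutes[sel, , drop = FALSE]
  v <- d$valid & !is.na(d$rmssd)
  agg <- function(col) {
    x <- ln_hrv(d[[col]][v])
    if (!length(x) || all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  list(ln_rmssd = agg("rmssd"), ln_sdnn = agg("sdnn"), ln_hf = agg("hf"),
       ln_lf = agg("lf"),
       met_mean = if (nrow(d)) mean(d$met, na.rm = TRUE) else NA_real_,
       n_minutes = nrow(d), n_valid = sum(v))
}

#' Build pre/during/post outcome windows for a prompt table
#'
#' Per prompt: the pre window aggregates the 10 minutes before the prompt
#' (minute starts in `[t - pre_len, t)`, time code -1), the during window
#' the minutes whose start lies within `during_halfwidth` of the
#' intervention midpoint (code 0), and the post window the 10 minutes after
#' the intervention end (starts in `(end, end + post_len]`, code +1).
#' The intervention is taken to span `[t, t + intervention_len)`; virtual
#' triggers use the same offsets with no actual intervention.  ln transforms
#' are applied per minute before averaging; only valid minutes enter the HRV
#' aggregates, while the MET covariate averages over all span minutes.
#' Windows truncated by the day edge are flagged and kept only if at least
#' `min_minutes` minutes remain; windows with zero valid minutes have
#' missing outcomes.
#'
#' @param minutes per-minute records ([segment_minutes()] layout, any number
#'   of persons/days).
#' @param prompts prompt table with `person_id`, `day`, `time`,
#'   `trigger_kind` and optionally `intervention_kind`, `smoking`,
#'   `prompt_id`.
#' @param pre_len,post_len window lengths in seconds (default 600).
#' @param during_halfwidth half-width around the intervention midpoint,
#'   seconds (default 120).
#' @param intervention_len intervention length in seconds (default 60).
#' @param min_minutes minimal span minutes for a truncated window to be kept.
#' @return long data frame, one row per prompt and time code, with
#'   `ln_rmssd`, `ln_sdnn`, `ln_hf`, `ln_lf`, `met_mean`, `smoking`,
#'   `n_valid`, `truncated`.
#' @export
build_windows <- function(minutes, prompts, pre_len = 600, post_len = 600,
                          during_halfwidth = 120, intervention_len = 60,
                          min_minutes = 5L) {
  stopifnot(is.data.frame(minutes), is.data.frame(prompts))
  if (!nrow(prompts)) return(NULL)
  if (is.null(prompts$prompt_id))
    prompts$prompt_id <- sprintf("prompt_%04d", seq_len(nrow(prompts)))
  key <- paste(minutes$person_id, minutes$day)
  by_day <- split(minutes, key)
  rows <- vector("list", nrow(prompts) * 3L)
  k <- 0L
  for (j in seq_len(nrow(prompts))) {
    pr <- prompts[j, ]
    dm <- by_day[[paste(pr$person_id, pr$day)]]
    if (is.null(dm)) next
    t0 <- pr$time
    int_end <- t0 + intervention_len
    mid <- (t0 + int_end) / 2
    spans <- list(
      pre = list(-1, t0 - pre_len, t0, FALSE, TRUE, pre_len %/% 60),
      during = list(0, mid - during_halfwidth, mid + during_halfwidth,
                    FALSE, TRUE, 2 * during_halfwidth %/% 60),
      post = list(1, int_end, int_end + post_len, TRUE, FALSE,
                  post_len %/% 60))
    for (nm in names(spans)) {
      sp <- spans[[nm]]
      a <- aggregate_span(dm, sp[[2]], sp[[3]], sp[[4]], sp[[5]])
      truncated <- a$n_minutes < sp[[6]]
      if (truncated && a$n_minutes < min_minutes) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        person_id = pr$person_id, day = pr$day, prompt_id = pr$prompt_id,
        trigger_kind = pr$trigger_kind,
        intervention_kind = pr$intervention_kind %||% NA_character_,
        time = nm, time_code = sp[[1]], ln_rmssd = a$ln_rmssd,
        ln_sdnn = a$ln_sdnn, ln_hf = a$ln_hf, ln_lf = a$ln_lf,
        met_mean = a$met_mean,
        smoking = isTRUE(pr$smoking %||% FALSE),
        n_valid = a$n_valid, truncated = truncated,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (!is.null(out))
    out$time <- factor(out$time, levels = c("pre", "during", "post"))
  rownames(out) <- NULL
  out
}

# Wrap an lmer fit into the package's model-result container.
as_proximal_model <- function(fit, data, formula, key_term = NULL) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  z <- est / se
  co <- data.frame(term = rownames(sm), estimate = unname(est),
                   se = unname(se), z = unname(z),
                   p = 2 * stats::pnorm(-abs(unname(z))),
                   ci_lo = unname(est - stats::qnorm(0.975) * se),
                   ci_hi = unname(est + stats::qnorm(0.975) * se),
                   stringsAsFactors = FALSE)
  rownames(co) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "person_id" & vc$var1 == "(Intercept)" &
                     is.na(vc$var2)][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  structure(list(coefficients = co, sigma2 = sigma2, tau00 = tau00,
                 icc = tau00 / (tau00 + sigma2), n_obs = nrow(data),
                 n_persons = length(unique(data$person_id)),
                 formula = formula, key_term = key_term, fit = fit,
                 data = data),
            class = "proximal_model")
}

#' @export
print.proximal_model <- function(x, digits = 3, ...) {
  cat(sprintf("<proximal_model> %s\n", deparse(x$formula)))
  cat(sprintf("  %d observations, %d persons\n", x$n_obs, x$n_persons))
  co <- x$coefficients
  co[c("estimate", "se", "z")] <- lapply(co[c("estimate", "se", "z")],
                                         round, digits)
  co$p <- signif(co$p, 2)
  print(co[c("term", "estimate", "se", "z", "p")], row.names = FALSE)
  cat(sprintf("  sigma2 = %.3f, tau00 = %.3f, ICC = %.3f\n", x$sigma2,
              x$tau00, x$icc))
  if (!is.null(x$key_term)) {
    kt <- co[co$term == x$key_term, ]
    cat(sprintf("  key term %s: b = %.3f, p = %.3g\n", x$key_term,
                kt$estimate, kt$p))
  }
  invisible(x)
}

# Keep covariate terms whose column exists and actually varies (constant
# columns would only trigger rank-deficiency drops inside the fitter).
keep_covariates <- function(covariates, d) {
  covariates[vapply(covariates, function(cv)
    !is.null(d[[cv]]) && length(unique(d[[cv]])) > 1L, logical(1))]
}

# Shared preparation: filter, center, factorize.
prepare_model_frame <- function(windows, outcome, times, centered = TRUE,
                                reference_trigger = "random",
                                reference_intervention = "external") {
  d <- windows[windows$trigger_kind %in% c("addhrvr", "random") &
                 as.character(windows$time) %in% times, , drop = FALSE]
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  if (!nrow(d))
    stop_addhrvr("no usable rows for the requested model",
                 "addhrvr_bad_input")
  d$time <- factor(as.character(d$time), levels = times)
  trig <- as.numeric(d$trigger_kind == "addhrvr")
  if (centered) {
    d$trigger <- trig - stats::ave(trig, d$person_id)
  } else {
    d$trigger <- stats::relevel(
      factor(d$trigger_kind,
             levels = c("random", "addhrvr")), ref = reference_trigger)
  }
  if (!is.null(d$intervention_kind) &&
      any(d$intervention_kind %in% c("mindful", "external"))) {
    iv <- as.numeric(d$intervention_kind == "mindful")
    if (centered) {
      d$intervention <- iv - stats::ave(iv, d$person_id)
    } else {
      d$intervention <- stats::relevel(
        factor(d$intervention_kind, levels = c("external", "mindful")),
        ref = reference_intervention)
    }
  }
  if (!is.null(d$met_mean)) d$met_c <- d$met_mean - mean(d$met_mean)
  d
}

fit_lmm <- function(formula, data, key_term = NULL) {
  if (length(unique(data$person_id)) < 2L)
    stop_addhrvr("need at least 2 persons for a multilevel model",
                 "addhrvr_bad_input")
  fit <- lme4::lmer(formula, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  as_proximal_model(fit, data, formula, key_term)
}

#' Fit the proximal-effect multilevel model
#'
#' Linear mixed model with a random intercept per person.  The trigger
#' indicator (AddHRVr vs random) — and for two-intervention designs the
#' intervention indicator — is centered within person so its interactions
#' carry within-person proximal effects; MET is grand-mean centered; time
#' enters as a categorical factor with the pre window as reference, giving
#' one pre-to-during and one pre-to-post contrast.  Fixed-effect p-values
#' and confidence intervals use the large-sample normal approximation.
#'
#' @param windows a windows table ([build_windows()], [simulate_windows()]
#'   or [selfreport_long()]).
#' @param outcome outcome column name (e.g. `"ln_rmssd"`, `"stress"`).
#' @param design `"study1"` (trigger-by-time) or `"study2"`
#'   (trigger-by-intervention-by-time).
#' @param covariates covariate terms; entries whose column is absent from
#'   `windows` are dropped silently.
#' @param times window levels to model, pre first (reference).
#' @return a `proximal_model`: coefficient table (estimate, SE, z, p, CI),
#'   variance components `sigma2`/`tau00`, their intraclass correlation,
#'   sizes, and the underlying `lme4` fit.
#' @export
fit_proximal_model <- function(windows, outcome = "ln_rmssd",
                               design = c("study1", "study2"),
                               covariates = c("met_c", "smoking"),
                               times = c("pre", "during", "post")) {
  design <- match.arg(design)
  times <- intersect(times, unique(as.character(windows$time)))
  d <- prepare_model_frame(windows, outcome, times)
  if (all(d$trigger == 0))
    stop_addhrvr("no within-person trigger contrast", "addhrvr_bad_input")
  if (design == "study2" && is.null(d[["intervention"]]))
    stop_addhrvr("study2 design needs an intervention_kind column",
                 "addhrvr_bad_input")
  covariates <- keep_covariates(covariates, d)
  inter <- if (design == "study1") "trigger * time" else
    "trigger * intervention * time"
  fml <- stats::reformulate(c(covariates, inter, "(1 | person_id)"),
                            response = outcome)
  key <- if ("post" %in% times) "trigger:timepost" else NULL
  fit_lmm(fml, d, key_term = key)
}

#' Refit with a chosen reference level
#'
#' Dummy-codes trigger (and intervention) with the requested reference
#' levels instead of within-person centering, so lower-order terms become
#' simple effects at that reference — the standard way to probe a
#' significant three-way interaction.
#'
#' @inheritParams fit_proximal_model
#' @param reference_trigger `"random"` or `"addhrvr"`.
#' @param reference_intervention `"external"` or `"mindful"` (two-
#'   intervention designs).
#' @return a `proximal_model`.
#' @export
rescale_reference <- function(windows, outcome = "ln_rmssd",
                              design = c("study1", "study2"),
                              reference_trigger = "random",
                              reference_intervention = "external",
                              covariates = c("met_c", "smoking"),
                              times = c("pre", "during", "post")) {
  design <- match.arg(design)
  if (!reference_trigger %in% c("random", "addhrvr"))
    stop_addhrvr("unknown trigger reference level", "addhrvr_bad_input")
  if (!reference_intervention %in% c("external", "mindful"))
    stop_addhrvr("unknown intervention reference level",
                 "addhrvr_bad_input")
  times <- intersect(times, unique(as.character(windows$time)))
  d <- prepare_model_frame(windows, outcome, times, centered = FALSE,
                           reference_trigger = reference_trigger,
                           reference_intervention = reference_intervention)
  if (design == "study2" && is.null(d[["intervention"]]))
    stop_addhrvr("study2 design needs an intervention_kind column",
                 "addhrvr_bad_input")
  covariates <- keep_covariates(covariates, d)
  inter <- if (design == "study1") "trigger * time" else
    "trigger * intervention * time"
  fml <- stats::reformulate(c(covariates, inter, "(1 | person_id)"),
                            response = outcome)
  fit_lmm(fml, d)
}

#' Virtual-trigger rebound contrast
#'
#' Compares the pre-to-post HRV change after real AddHRVr-triggered
#' interventions with the spontaneous change after virtual triggers (rule-
#' qualifying windows that never prompted).  Three-level trigger factor
#' (virtual as reference, random, addhrvr) crossed with time (pre vs post);
#' the key term is the addhrvr-vs-virtual by time interaction: the
#' intervention effect net of spontaneous rebound.
#'
#' @param windows windows table containing `trigger_kind = "virtual"` rows.
#' @param outcome outcome column.
#' @param covariates covariate terms (absent columns dropped).
#' @return a `proximal_model` with `key_term = "kindaddhrvr:timepost"`.
#' @export
compare_virtual <- function(windows, outcome = "ln_rmssd",
                            covariates = c("met_c", "smoking")) {
  if (!any(windows$trigger_kind == "virtual"))
    stop_addhrvr(
      "no virtual triggers in the data; run scan_virtual() first",
      "addhrvr_no_virtual")
  d <- windows[as.character(windows$time) %in% c("pre", "post") &
                 !is.na(windows[[outcome]]), , drop = FALSE]
  d$time <- factor(as.character(d$time), levels = c("pre", "post"))
  d$kind <- factor(d$trigger_kind, levels = c("virtual", "random",
                                              "addhrvr"))
  if (!is.null(d$met_mean)) d$met_c <- d$met_mean - mean(d$met_mean)
  covariates <- keep_covariates(covariates, d)
  fml <- stats::reformulate(c(covariates, "kind * time", "(1 | person_id)"),
                            response = outcome)
  fit_lmm(fml, d, key_term = "kindaddhrvr:timepost")
}

#' Write a model result to CSV
#'
#' Coefficient rows followed by a variance-components block.
#' @param model a `proximal_model`.
#' @param path file path.
#' @export
write_model_csv <- function(model, path) {
  co <- model$coefficients
  vc <- data.frame(term = c("sigma2", "tau00", "icc", "n_obs", "n_persons"),
                   estimate = c(model$sigma2, model$tau00, model$icc,
                                model$n_obs, model$n_persons),
                   se = NA, z = NA, p = NA, ci_lo = NA, ci_hi = NA)
  utils::write.csv(rbind(co, vc), path, row.names = FALSE, na = "")
  invisible(path)
}
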