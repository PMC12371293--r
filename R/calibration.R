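# Person-specific calibration of RMSSD against bodily movement.
#
# A 12-hour calibration day yields per-minute (RMSSD, MET) pairs; ordinary
# least squares of RMSSD on MET gives the person's intercept and slope, and
# the dispersion of calibration-day RMSSD gives the SD used by the flag rule:
# a later minute shows an additional (nonmetabolic) HRV reduction when its
# observed RMSSD lies at least k = 0.5 SD below the movement-predicted value.

#' Fit the calibration-day regression for one person
#'
#' Ordinary least squares of per-minute RMSSD (ms) on movement (MET) over the
#' valid calibration-day minutes.  The dispersion attached to the model is,
#' by default, the sample SD of the valid calibration-day RMSSD values
#' (`sd_type = "marginal"`); the residual SD of the regression is available
#' as `sd_type = "residual"`.
#'
#' Persons with a non-negative fitted slope are flagged ineligible: a
#' positive movement-HRV coupling contradicts the physiology the flag rule
#' assumes, and such persons are excluded from triggering.
#'
#' @param minutes per-minute records ([segment_minutes()] layout) for the
#'   calibration day; only rows with `valid = TRUE` and non-missing `rmssd`
#'   and `met` enter the fit.
#' @param min_minutes minimal number of usable minutes (default 120 of a
#'   720-minute day); below this the person is reported uncalibratable.
#' @param sd_type `"marginal"` (SD of calibration-day RMSSD, default) or
#'   `"residual"` (regression residual SD).
#' @return an object of class `calibration_model`: `person_id`, `intercept`
#'   (ms), `slope` (ms/MET), `sd` (ms), `n_minutes_used`, `r` (Pearson
#'   correlation, diagnostic), `eligible`, `sd_type`.
#' @export
fit_calibration <- function(minutes, min_minutes = 120L,
                            sd_type = c("marginal", "residual")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.data.frame(minutes),
            all(c("rmssd", "met", "valid") %in% names(minutes)))
  use <- minutes$valid & !is.na(minutes$rmssd) & !is.na(minutes$met)
  d <- minutes[use, ]
  if (nrow(d) < min_minutes)
    stop_addhrvr(sprintf(
      "uncalibratable: %d usable minutes, need at least %d",
      nrow(d), min_minutes), "addhrvr_uncalibratable")
  fit <- stats::lm(rmssd ~ met, data = d)
  co <- stats::coef(fit)
  disp <- if (sd_type == "marginal") stats::sd(d$rmssd)
          else stats::sigma(fit)
  if (!is.finite(disp) || disp <= 0)
    stop_addhrvr("degenerate calibration: zero RMSSD dispersion",
                 "addhrvr_uncalibratable")
  structure(
    list(person_id = if ("person_id" %in% names(d)) d$person_id[1] else NA,
         intercept = unname(co[1]), slope = unname(co[2]), sd = disp,
         n_minutes_used = nrow(d),
         r = stats::cor(d$met, d$rmssd),
         eligible = unname(co[2]) < 0, sd_type = sd_type),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> person %s: RMSSD = %.2f %+.3f x MET (SD %.2f ms, %s)\n",
    x$person_id, x$intercept, x$slope, x$sd, x$sd_type))
  cat(sprintf("  n = %d minutes, r = %.3f, %s\n", x$n_minutes_used, x$r,
              if (x$eligible) "eligible" else
                "INELIGIBLE (non-negative slope)"))
  invisible(x)
}

#' Movement-predicted RMSSD
#'
#' `intercept + slope * met` for an eligible calibration model.
#'
#' @param model a [fit_calibration()] result.
#' @param met movement value(s) in MET.
#' @return predicted RMSSD in ms.
#' @export
predict_rmssd <- function(model, met) {
  stopifnot(inherits(model, "calibration_model"))
  if (!model$eligible)
    stop_addhrvr("calibration model is ineligible (non-negative slope)",
                 "addhrvr_ineligible")
  model$intercept + model$slope * met
}

#' Additional-HRV-reduction flag
#'
#' A minute is flagged when its observed RMSSD is at least `k` SD lower than
#' the movement-predicted value: `observed <= predicted - k * sd`.  The
#' boundary counts as flagged; missing observations never flag.
#'
#' @param observed observed minute RMSSD (ms); may contain `NA`.
#' @param predicted movement-predicted RMSSD (ms).
#' @param sd the person's calibration dispersion (ms), `> 0`.
#' @param k SD multiplier (default 0.5).
#' @return logical vector.
#' @export
addhrvr_flag <- function(observed, predicted, sd, k = 0.5) {
  stopifnot(all(sd > 0), k >= 0)
  out <- !is.na(observed) & observed <= predicted - k * sd
  out
}

#' Flag a day of minutes with a calibration model
#'
#' Convenience wrapper: predicted values from the minute METs, then
#' [addhrvr_flag()] per minute.  Minutes that are invalid or lack RMSSD or
#' MET never flag.
#'
#' @param model eligible [fit_calibration()] result.
#' @param minutes per-minute records for a monitoring day.
#' @param k SD multiplier.
#' @return logical vector, one element per minute row.
#' @export
flag_minutes <- function(model, minutes, k = 0.5) {
  obs <- ifelse(minutes$valid, minutes$rmssd, NA_real_)
  obs[is.na(minutes$met)] <- NA_real_
  pred <- predict_rmssd(model, ifelse(is.na(minutes$met), 0, minutes$met))
  addhrvr_flag(obs, pred, model$sd, k)
}

#' Tabulate calibration models
#'
#' @param models list of `calibration_model` objects.
#' @return data frame with one row per person: `person_id`, `intercept`,
#'   `slope`, `sd`, `n_minutes_used`, `r`, `eligible`.
#' @export
calibration_table <- function(models) {
  if (inherits(models, "calibration_model")) models <- list(models)
  do.call(rbind, lapply(models, function(m)
    data.frame(person_id = m$person_id, intercept = m$intercept,
               slope = m$slope, sd = m$sd,
               n_minutes_used = m$n_minutes_used, r = m$r,
               eligible = m$eligible, stringsAsFactors = FALSE)))
}

#' Write calibration parameters to CSV
#' @param models list of `calibration_model` objects.
#' @param path file path.
#' @export
write_calibration_csv <- function(models, path) {
  utils::write.csv(calibration_table(models), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
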