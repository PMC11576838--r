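# Dose regimens: weight-based IV infusions with an absolute cap (ADC dosing
# convention) and fixed oral/IV doses for perpetrators and probe substrates.

#' Construct a dose regimen
#'
#' @param route `"iv_infusion"`, `"iv_bolus"` or `"oral"`
#' @param dose_mg_kg per-kg dose (mg/kg); mutually exclusive with `dose_mg`
#' @param dose_cap_mg absolute cap (mg) on a per-kg dose, `Inf` for none
#' @param dose_mg fixed dose (mg)
#' @param infusion_h infusion duration (h), required > 0 for IV infusions
#' @param dosing_days days within the cycle on which doses are given
#'   (1 = first day of cycle)
#' @param cycle_days cycle length (days)
#' @param n_cycles number of cycles
#' @param offset_h start of the first cycle relative to simulation time 0 (h)
#' @return an object of class `dose_regimen`
#' @export
dose_regimen <- function(route = c("iv_infusion", "iv_bolus", "oral"),
                         dose_mg_kg = NULL, dose_cap_mg = Inf, dose_mg = NULL,
                         infusion_h = 0, dosing_days = 1, cycle_days = 28,
                         n_cycles = 1, offset_h = 0) {
  route <- match.arg(route)
  if (is.null(dose_mg_kg) == is.null(dose_mg))
    stop("give exactly one of dose_mg_kg or dose_mg", call. = FALSE)
  if (route == "iv_infusion" && infusion_h <= 0)
    stop("infusion duration must be > 0 for IV infusion", call. = FALSE)
  if (any(dosing_days < 1) || any(dosing_days > cycle_days))
    stop("dosing days must lie within [1, cycle length]", call. = FALSE)
  obj <- list(route = route, dose_mg_kg = dose_mg_kg,
              dose_cap_mg = dose_cap_mg, dose_mg = dose_mg,
              infusion_h = infusion_h, dosing_days = sort(dosing_days),
              cycle_days = cycle_days, n_cycles = n_cycles,
              offset_h = offset_h)
  class(obj) <- "dose_regimen"
  obj
}

#' Administered dose for a subject
#'
#' Per-kg regimens are capped at the absolute maximum
#' (`min(dose_mg_kg * weight, cap)`); fixed regimens ignore weight.
#'
#' @param regimen a [dose_regimen()]
#' @param weight_kg body weight (kg), > 0
#' @return dose in mg
#' @export
compute_dose <- function(regimen, weight_kg) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (!is.numeric(weight_kg) || any(weight_kg <= 0))
    stop("weight must be positive", call. = FALSE)
  if (!is.null(regimen$dose_mg))
    return(rep(regimen$dose_mg, length(weight_kg)))
  pmin(regimen$dose_mg_kg * weight_kg, regimen$dose_cap_mg)
}

#' Absolute dosing times of a regimen
#'
#' @param regimen a [dose_regimen()]
#' @return vector of dose start times (h from simulation start)
#' @export
dose_times <- function(regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  days <- as.vector(outer(regimen$dosing_days - 1,
                          (seq_len(regimen$n_cycles) - 1) * regimen$cycle_days,
                          "+"))
  sort(regimen$offset_h + days * 24)
}

#' Daily-repeat helper for perpetrator lead-in dosing
#'
#' Once-daily dosing from `start_h` for `n_days` days.
#'
#' @param start_h time of the first dose (h)
#' @param n_days number of daily doses
#' @param dose_mg dose (mg)
#' @param route `"oral"` by default
#' @return a [dose_regimen()]
#' @export
qd_regimen <- function(start_h, n_days, dose_mg, route = "oral") {
  dose_regimen(route = route, dose_mg = dose_mg, dosing_days = 1,
               cycle_days = 1, n_cycles = n_days, offset_h = start_h)
}
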