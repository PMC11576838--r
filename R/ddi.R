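# DDI engine: elementary interaction operations (competitive inhibition,
# mechanism-based inactivation, turnover induction, manual P-gp relative
# activity factor) and paired with/without-perpetrator trial execution.

#' Competitive (reversible) inhibition modifier
#'
#' Multiplier on an intrinsic clearance under reversible inhibition:
#' `1 / (1 + iu / ki)`.
#'
#' @param iu unbound inhibitor concentration (uM)
#' @param ki reversible inhibition constant (uM), > 0
#' @return clearance multiplier in `(0, 1]`
#' @export
competitive_modifier <- function(iu, ki) {
  if (any(ki <= 0)) stop("ki must be > 0", call. = FALSE)
  if (any(iu < 0)) stop("iu must be >= 0", call. = FALSE)
  1 / (1 + iu / ki)
}

#' Mechanism-based inactivation turnover derivative
#'
#' Relative active enzyme `E` obeys
#' `dE/dt = kdeg * (1 - E) - (kinact * iu / (kapp + iu)) * E`.
#'
#' @param e_rel relative enzyme level
#' @param iu unbound inactivator concentration (uM)
#' @param kinact maximal inactivation rate (1/h)
#' @param kapp concentration at half-maximal inactivation (uM)
#' @param kdeg enzyme degradation rate constant (1/h)
#' @return dE/dt (1/h)
#' @export
mbi_turnover <- function(e_rel, iu, kinact, kapp, kdeg) {
  lam <- ifelse(kapp + iu > 0, kinact * iu / (kapp + iu), 0)
  kdeg * (1 - e_rel) - lam * e_rel
}

#' Steady-state enzyme level under constant mechanism-based inactivation
#'
#' Closed form `E_ss = kdeg / (kdeg + lambda)` with
#' `lambda = kinact * iu / (kapp + iu)`.
#'
#' @inheritParams mbi_turnover
#' @return steady-state relative enzyme level
#' @export
mbi_steady_state <- function(iu, kinact, kapp, kdeg) {
  lam <- ifelse(kapp + iu > 0, kinact * iu / (kapp + iu), 0)
  kdeg / (kdeg + lam)
}

#' Enzyme-turnover induction derivative
#'
#' `dE/dt = kdeg * (1 + ind_max * iu / (ind_c50 + iu)) - kdeg * E`;
#' steady state `1 + ind_max * iu / (ind_c50 + iu)`.
#'
#' @param e_rel relative enzyme level
#' @param iu unbound inducer concentration (uM)
#' @param ind_max maximal fold-increase of synthesis minus one
#' @param ind_c50 unbound concentration at half-maximal induction (uM)
#' @param kdeg enzyme degradation rate constant (1/h)
#' @return dE/dt (1/h)
#' @export
induction_turnover <- function(e_rel, iu, ind_max, ind_c50, kdeg) {
  kdeg * (1 + ind_max * iu / (ind_c50 + iu)) - kdeg * e_rel
}

#' Static P-gp relative-activity-factor fold
#'
#' Manual transporter-induction handle: multiplies a P-gp intrinsic
#' clearance by a fold >= 1 in the with-perpetrator arm (the baseline arm
#' uses fold 1).
#'
#' @param clint_pgp P-gp intrinsic clearance (any clearance unit)
#' @param fold RAF fold, >= 1
#' @return modified clearance
#' @export
apply_pgp_raf <- function(clint_pgp, fold) {
  if (any(fold < 1)) stop("RAF fold must be >= 1", call. = FALSE)
  clint_pgp * fold
}

#' Analytic enzyme time course under constant inhibitor concentration
#'
#' Mono-exponential approach to steady state for the combined
#' MBI/induction turnover model; used as the closed-form oracle for the
#' integrated enzyme state.
#'
#' @param t time (h)
#' @param iu constant unbound perpetrator concentration (uM)
#' @param kinact,kapp MBI parameters (0 to disable)
#' @param ind_max,ind_c50 induction parameters (0 to disable)
#' @param kdeg degradation rate constant (1/h)
#' @param e0 initial relative enzyme level
#' @return E(t)
#' @export
enzyme_time_course <- function(t, iu, kinact = 0, kapp = 0, ind_max = 0,
                               ind_c50 = 1, kdeg = 0.0193, e0 = 1) {
  lam <- if (kapp + iu > 0) kinact * iu / (kapp + iu) else 0
  syn <- kdeg * (1 + if (ind_c50 + iu > 0)
    ind_max * iu / (ind_c50 + iu) else 0)
  kout <- kdeg + lam
  ess <- syn / kout
  ess + (e0 - ess) * exp(-kout * t)
}

#' Define a paired DDI scenario
#'
#' @param victim_analyte `"mmae"` (ADC payload is the victim) or `"victim"`
#'   (a probe substrate is the victim and the ADC is the perpetrator)
#' @param adc,adc_regimen ADC compound/regimen (`NULL` if absent)
#' @param mmae payload compound
#' @param perp,perp_regimen perpetrator compound/regimen (`NULL` when the
#'   ADC itself is the perpetrator)
#' @param victim,victim_regimen probe substrate compound/regimen
#' @param end_h simulation end (h)
#' @param nca_start_h start of the NCA window (victim dose time, h)
#' @param f_bile payload biliary-fraction override
#' @param label scenario label
#' @return a `ddi_scenario`
#' @export
ddi_scenario <- function(victim_analyte = c("mmae", "victim"),
                         adc = NULL, adc_regimen = NULL, mmae,
                         perp = NULL, perp_regimen = NULL,
                         victim = NULL, victim_regimen = NULL,
                         end_h = 672, nca_start_h = 0, f_bile = NULL,
                         label = "scenario") {
  victim_analyte <- match.arg(victim_analyte)
  if (victim_analyte == "victim" && is.null(victim))
    stop("victim compound required", call. = FALSE)
  obj <- list(victim_analyte = victim_analyte, adc = adc,
              adc_regimen = adc_regimen, mmae = mmae, perp = perp,
              perp_regimen = perp_regimen, victim = victim,
              victim_regimen = victim_regimen, end_h = end_h,
              nca_start_h = nca_start_h, f_bile = f_bile, label = label)
  class(obj) <- "ddi_scenario"
  obj
}

# simulate one subject in one arm of a scenario
.simulate_arm <- function(scenario, subject, with_perp) {
  phys <- subject_physiology(subject)
  adc_perp_mode <- scenario$victim_analyte == "victim"
  if (adc_perp_mode) {
    # ADC is the perpetrator: the without-arm omits the ADC dose
    simulate_subject(
      adc = scenario$adc,
      adc_regimen = if (with_perp) scenario$adc_regimen else NULL,
      mmae = scenario$mmae, physiology = phys,
      perp = scenario$perp,
      perp_regimen = if (with_perp) scenario$perp_regimen else NULL,
      victim = scenario$victim, victim_regimen = scenario$victim_regimen,
      end_h = scenario$end_h, weight_kg = subject$weight_kg,
      cyp_mult = subject$cyp3a4_mult, pgp_mult = subject$pgp_mult,
      apply_raf = FALSE, f_bile = scenario$f_bile)
  } else {
    simulate_subject(
      adc = scenario$adc, adc_regimen = scenario$adc_regimen,
      mmae = scenario$mmae, physiology = phys,
      perp = scenario$perp,
      perp_regimen = if (with_perp) scenario$perp_regimen else NULL,
      victim = scenario$victim, victim_regimen = scenario$victim_regimen,
      end_h = scenario$end_h, weight_kg = subject$weight_kg,
      cyp_mult = subject$cyp3a4_mult, pgp_mult = subject$pgp_mult,
      apply_raf = with_perp && !is.null(scenario$perp) &&
        scenario$perp$ind_max > 0,
      f_bile = scenario$f_bile)
  }
}

#' Run a paired with/without-perpetrator DDI trial
#'
#' Simulates every subject twice on identical physiology and seeds (the
#' only difference being the perpetrator doses and, for transporter
#' inducers, the static P-gp RAF fold), computes per-subject NCA for the
#' victim analyte and summarises geometric mean ratios with 90% CIs across
#' trial-level means.
#'
#' @param scenario a [ddi_scenario()]
#' @param subjects a `virtual_population`
#' @return a `ddi_result` list: `summary` (GMR table), `per_subject`
#'   (paired NCA parameters), `label`
#' @export
run_ddi_pair <- function(scenario, subjects) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  analyte <- if (scenario$victim_analyte == "mmae") "mmae" else "victim"
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    su <- subjects[i, ]
    sim1 <- .simulate_arm(scenario, su, with_perp = TRUE)
    sim0 <- .simulate_arm(scenario, su, with_perp = FALSE)
    n1 <- .nca_from_sim(sim1, analyte, scenario$nca_start_h)
    n0 <- .nca_from_sim(sim0, analyte, scenario$nca_start_h)
    rows[[i]] <- data.frame(
      trial = su$trial, subject = su$subject, analyte = analyte,
      cmax_with = n1$cmax, cmax_without = n0$cmax,
      auc_last_with = n1$auc_last, auc_last_without = n0$auc_last,
      auc_inf_with = n1$auc_inf, auc_inf_without = n0$auc_inf)
  }
  per_subject <- do.call(rbind, rows)
  summary <- rbind(
    cbind(parameter = "cmax",
          gmr_with_ci(per_subject$cmax_with, per_subject$cmax_without,
                      per_subject$trial)),
    cbind(parameter = "auc_last",
          gmr_with_ci(per_subject$auc_last_with,
                      per_subject$auc_last_without, per_subject$trial)))
  out <- list(label = scenario$label, summary = summary,
              per_subject = per_subject)
  class(out) <- "ddi_result"
  out
}

.nca_from_sim <- function(sim, analyte, start_h) {
  d <- sim[sim$analyte == analyte & sim$time_h >= start_h - 1e-9, ]
  nca_profile(d$time_h - start_h, d$conc)
}
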