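# ADC-level operations: quasi-equilibrium FcRn binding and the
# antibody-focused simulation wrapper.

#' Quasi-equilibrium FcRn-bound fraction
#'
#' 1:1 binding of total endosomal antibody to a shared FcRn pool at
#' quasi-equilibrium: solves the quadratic for free receptor `R` in
#' `R + A_tot * R / (kd + R) = R_tot`; the bound fraction `R / (kd + R)` is
#' identical across DAR species (a single dissociation constant).
#'
#' @param total_antibody_um total endosomal antibody concentration, summed
#'   over DAR species (uM)
#' @param fcrn_total_um total endosomal FcRn concentration (uM)
#' @param kd_um dissociation constant at endosomal pH (uM)
#' @return bound fraction in `[0, 1]`
#' @export
fcrn_bound_fraction <- function(total_antibody_um, fcrn_total_um, kd_um) {
  stopifnot(all(total_antibody_um >= 0), all(fcrn_total_um >= 0),
            all(kd_um >= 0))
  out <- numeric(length(total_antibody_um))
  for (i in seq_along(out)) {
    a <- total_antibody_um[i]; r_tot <- fcrn_total_um; kd <- kd_um
    if (r_tot <= 0) { out[i] <- 0; next }
    b <- kd + a - r_tot
    r_free <- 0.5 * (-b + sqrt(b^2 + 4 * r_tot * kd))
    out[i] <- if (kd + r_free > 0) r_free / (kd + r_free)
              else as.numeric(r_free > 0 || kd == 0)
  }
  out
}

#' Simulate the antibody (ADC) model for one subject
#'
#' Convenience wrapper over [simulate_subject()] returning the
#' antibody-side analytes: conjugated-antibody and total-antibody
#' concentrations (ug/mL), mean circulating DAR, and the payload release
#' flux handed to the small-molecule model.
#'
#' @param adc an [adc_compound()]
#' @param regimen the ADC [dose_regimen()]
#' @param physiology subject-scaled `physiology_set`
#' @param mmae payload compound (defaults to the shipped MMAE file; the
#'   payload model runs alongside and receives the release flux)
#' @param end_h simulation end (h)
#' @param ... passed to [simulate_subject()]
#' @return a `simulation_result` (see [simulate_subject()])
#' @export
simulate_adc <- function(adc, regimen, physiology,
                         mmae = load_compound(default_compound_file("mmae")),
                         end_h = 672, ...) {
  simulate_subject(adc = adc, adc_regimen = regimen, mmae = mmae,
                   physiology = physiology, end_h = end_h, ...)
}
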