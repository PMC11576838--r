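# Synthetic observed-like datasets: sparse-sampled concentration tables
# with lognormal residual error and below-limit flagging, plus the
# predicted/observed overlay statistics used in model verification.

#' Default phase-1-style PK sampling schedule (h)
#'
#' Dense early sampling (maximum antibody concentrations fall 30 min to 1 h
#' after the infusion) followed by daily samples through day 7, so the
#' payload Tmax (1-3 days) is resolvable.
#'
#' @return numeric vector of nominal sampling times (h)
#' @export
default_sampling_schedule <- function() {
  c(0.5, 1, 2, 6, 24 * (1:7))
}

#' Generate an observed-like dataset from a simulated truth
#'
#' Samples the simulated profile at the nominal schedule, applies
#' multiplicative lognormal residual error, and flags/blanks values below
#' the limit of quantification. Deterministic per seed.
#'
#' @param truth a `simulation_result` (single subject) or a data.frame with
#'   `time_h`, `analyte`, `conc`
#' @param schedule nominal sampling times (h), within the simulated span
#' @param error_cv residual coefficient of variation (fraction)
#' @param lloq named vector of lower limits of quantification per analyte
#'   (analyte units); analytes absent from `lloq` get 0
#' @param seed integer seed
#' @param analytes which analytes to sample
#' @param subject_id id stamped on the rows
#' @return an `observed_dataset` data.frame: `subject`, `analyte`,
#'   `time_h`, `conc` (NA when below limit), `blq` flag; metadata in
#'   attributes `lloq`, `error_cv`, `schedule`
#' @export
generate_observed <- function(truth, schedule = default_sampling_schedule(),
                              error_cv = 0.3, lloq = c(mmae = 0.01),
                              seed = 1,
                              analytes = c("adc_conjugated", "adc_total",
                                           "mmae"),
                              subject_id = 1L) {
  stopifnot(error_cv >= 0)
  span <- range(truth$time_h)
  if (any(schedule < span[1] - 1e-9) || any(schedule > span[2] + 1e-9))
    stop("sampling schedule outside the simulated span", call. = FALSE)
  set.seed(seed)
  rows <- list()
  sdlog <- sqrt(log(1 + error_cv^2))
  for (an in intersect(analytes, unique(truth$analyte))) {
    d <- truth[truth$analyte == an, ]
    tv <- vapply(schedule, function(tt) {
      i <- findInterval(tt, d$time_h)
      i <- max(min(i, nrow(d) - 1), 1)
      f <- (tt - d$time_h[i]) / (d$time_h[i + 1] - d$time_h[i])
      d$conc[i] + f * (d$conc[i + 1] - d$conc[i])
    }, numeric(1))
    err <- if (error_cv > 0) rlnorm(length(tv), -0.5 * sdlog^2, sdlog)
           else rep(1, length(tv))
    obs <- tv * err
    lim <- if (an %in% names(lloq)) lloq[[an]] else 0
    blq <- obs < lim | tv <= 0
    rows[[an]] <- data.frame(subject = subject_id, analyte = an,
                             time_h = schedule,
                             conc = ifelse(blq, NA_real_, obs), blq = blq)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lloq") <- lloq
  attr(out, "error_cv") <- error_cv
  attr(out, "schedule") <- schedule
  class(out) <- c("observed_dataset", class(out))
  out
}

#' Overlay coverage and predicted/observed statistics
#'
#' Compares an observed dataset against a simulated population: reports the
#' fraction of observed points inside the simulated 5th-95th percentile
#' band per analyte, and geometric-mean predicted/observed (P/O) ratios for
#' NCA parameters.
#'
#' @param observed an `observed_dataset` (possibly several subjects)
#' @param population_sims list of `simulation_result`s (one per simulated
#'   subject)
#' @return list with `coverage` (per-analyte fraction in band) and
#'   `po_table` (per analyte: observed GM, predicted GM and P/O ratio for
#'   Cmax and AUC over the observed span)
#' @export
overlay_check <- function(observed, population_sims) {
  stopifnot(inherits(observed, "observed_dataset"), length(population_sims) >= 1)
  analytes <- unique(observed$analyte)
  sim_an <- unique(population_sims[[1]]$analyte)
  if (!all(analytes %in% sim_an))
    stop("analyte mismatch between observed and simulated data",
         call. = FALSE)
  coverage <- numeric(0)
  po_rows <- list()
  for (an in analytes) {
    oan <- observed[observed$analyte == an & !observed$blq, ]
    if (!nrow(oan)) next
    tset <- sort(unique(oan$time_h))
    simmat <- vapply(population_sims, function(s) {
      d <- s[s$analyte == an, ]
      vapply(tset, function(tt) {
        i <- findInterval(tt, d$time_h)
        i <- max(min(i, nrow(d) - 1), 1)
        f <- (tt - d$time_h[i]) / (d$time_h[i + 1] - d$time_h[i])
        d$conc[i] + f * (d$conc[i + 1] - d$conc[i])
      }, numeric(1))
    }, numeric(length(tset)))
    simmat <- matrix(simmat, nrow = length(tset))
    lo <- apply(simmat, 1, quantile, 0.05)
    hi <- apply(simmat, 1, quantile, 0.95)
    idx <- match(oan$time_h, tset)
    coverage[an] <- mean(oan$conc >= lo[idx] & oan$conc <= hi[idx])

    # parameter-level P/O: observed NCA per subject vs simulated NCA
    obs_nca <- lapply(split(oan, oan$subject), function(d)
      if (sum(d$conc > 0, na.rm = TRUE) >= 3)
        nca_profile(d$time_h, d$conc) else NULL)
    obs_nca <- obs_nca[!vapply(obs_nca, is.null, logical(1))]
    sim_nca <- lapply(population_sims, function(s) {
      d <- s[s$analyte == an & s$time_h <= max(tset) + 1e-9, ]
      nca_profile(d$time_h, d$conc)
    })
    if (length(obs_nca)) {
      for (parm in c("cmax", "auc_last")) {
        og <- exp(mean(log(vapply(obs_nca, `[[`, numeric(1), parm))))
        pg <- exp(mean(log(vapply(sim_nca, `[[`, numeric(1), parm))))
        po_rows[[paste(an, parm)]] <-
          data.frame(analyte = an, parameter = parm, observed_gm = og,
                     predicted_gm = pg, po_ratio = pg / og)
      }
    }
  }
  list(coverage = coverage,
       po_table = if (length(po_rows)) do.call(rbind, po_rows) else NULL)
}

#' Predicted/observed ratio table from summary-level geometric means
#'
#' The P/O verification statistic computed directly from parameter-level
#' geometric means (for example a fixture table of reported clinical GMs
#' joined with simulated GMs).
#'
#' @param predicted_gm numeric vector of predicted geometric means
#' @param observed_gm numeric vector of observed geometric means
#' @return `predicted_gm / observed_gm`
#' @export
po_ratio <- function(predicted_gm, observed_gm) {
  stopifnot(length(predicted_gm) == length(observed_gm))
  if (any(observed_gm <= 0)) stop("observed GMs must be positive")
  predicted_gm / observed_gm
}
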