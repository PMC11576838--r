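# Noncompartmental analysis and trial-level summary statistics.

#' Noncompartmental analysis of a concentration-time profile
#'
#' Cmax/Tmax by maximum; AUC by the linear-up/log-down trapezoid (pure
#' linear by flag); terminal slope by log-linear regression over the
#' candidate terminal windows (>= 3 points strictly after Tmax, window with
#' the best adjusted R-squared wins); partial AUCs to day 7 and day 14 by
#' interpolation at exactly 168 h and 336 h.
#'
#' @param times_h sampling times (h), strictly increasing
#' @param conc concentrations (analyte units)
#' @param dose optional dose (for dose-normalised bookkeeping; not required)
#' @param method `"linear_up_log_down"` (default) or `"linear"`
#' @return a `pk_summary` list: `cmax`, `tmax_h`, `auc_last`, `auc_inf`,
#'   `auc_d7`, `auc_d14` (conc x day), `lambda_z_per_day`, `t_half_day`,
#'   `n_points_lambda_z`; `auc_inf`, `lambda_z` and `t_half` are `NA` when
#'   the terminal slope is not estimable
#' @export
nca_profile <- function(times_h, conc, dose = NA,
                        method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  stopifnot(length(times_h) == length(conc))
  ok <- !is.na(conc)
  times_h <- times_h[ok]; conc <- conc[ok]
  if (is.unsorted(times_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (sum(conc > 0) < 3)
    stop("need at least 3 positive concentrations", call. = FALSE)

  imax <- which.max(conc)
  cmax <- conc[imax]
  tmax <- times_h[imax]

  auc_cum <- .auc_cumulative(times_h, conc, method)  # conc*h
  auc_last_h <- auc_cum[length(auc_cum)]

  lz <- .lambda_z(times_h, conc, tmax)
  auc_inf_h <- if (!is.na(lz$lambda) && conc[length(conc)] > 0)
    auc_last_h + conc[length(conc)] / lz$lambda else NA_real_

  part <- function(t_cut) {
    if (times_h[length(times_h)] < t_cut - 1e-9) return(NA_real_)
    .auc_to(times_h, conc, auc_cum, t_cut, method)
  }
  res <- list(cmax = cmax, tmax_h = tmax,
              auc_last = auc_last_h / 24, auc_inf = auc_inf_h / 24,
              auc_d7 = part(168) / 24, auc_d14 = part(336) / 24,
              lambda_z_per_day = lz$lambda * 24,
              t_half_day = log(2) / (lz$lambda * 24),
              n_points_lambda_z = lz$n, dose = dose)
  class(res) <- "pk_summary"
  res
}

# cumulative AUC at each sampling time (conc * h)
.auc_cumulative <- function(t, c, method) {
  n <- length(t)
  dt <- diff(t)
  c1 <- c[-n]; c2 <- c[-1]
  lin <- dt * (c1 + c2) / 2
  if (method == "linear_up_log_down") {
    logd <- c2 < c1 & c2 > 0 & c1 > 0
    seg <- lin
    seg[logd] <- dt[logd] * (c1[logd] - c2[logd]) /
      log(c1[logd] / c2[logd])
    cumsum(c(0, seg))
  } else {
    cumsum(c(0, lin))
  }
}

# AUC from time 0 to t_cut, interpolating within the covering interval
.auc_to <- function(t, c, auc_cum, t_cut, method) {
  i <- findInterval(t_cut, t)
  if (abs(t[i] - t_cut) < 1e-9) return(auc_cum[i])
  c_cut <- .interp_conc(t, c, t_cut, method)
  dt <- t_cut - t[i]
  if (method == "linear_up_log_down" && c_cut < c[i] && c_cut > 0 &&
      c[i] > 0) {
    auc_cum[i] + dt * (c[i] - c_cut) / log(c[i] / c_cut)
  } else {
    auc_cum[i] + dt * (c[i] + c_cut) / 2
  }
}

.interp_conc <- function(t, c, t_cut, method) {
  i <- findInterval(t_cut, t)
  if (i >= length(t)) return(c[length(t)])
  f <- (t_cut - t[i]) / (t[i + 1] - t[i])
  if (method == "linear_up_log_down" && c[i + 1] < c[i] && c[i + 1] > 0 &&
      c[i] > 0) {
    exp(log(c[i]) + f * (log(c[i + 1]) - log(c[i])))
  } else {
    c[i] + f * (c[i + 1] - c[i])
  }
}

# terminal slope: best adjusted R^2 over candidate windows of >= 3 points
# strictly after Tmax, all concentrations positive
.lambda_z <- function(t, c, tmax) {
  sel <- which(t > tmax & c > 0)
  if (length(sel) < 3)
    return(list(lambda = NA_real_, n = 0L))
  x <- t[sel]; y <- log(c[sel])
  n <- length(x)
  # reversed cumulative sums: statistics of windows [k..n]
  rc <- function(v) rev(cumsum(rev(v)))
  sx <- rc(x); sy <- rc(y); sxx <- rc(x * x); sxy <- rc(x * y)
  syy <- rc(y * y)
  m <- n - seq_len(n) + 1
  ssxx <- sxx - sx^2 / m
  ssxy <- sxy - sx * sy / m
  ssyy <- syy - sy^2 / m
  slope <- ssxy / ssxx
  r2 <- ifelse(ssyy > 0, ssxy^2 / (ssxx * ssyy), 1)
  adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
  cand <- which(m >= 3 & slope < 0 & is.finite(adj))
  if (!length(cand))
    return(list(lambda = NA_real_, n = 0L))
  best <- cand[which.max(adj[cand])]
  list(lambda = -slope[best], n = as.integer(m[best]))
}

#' Summary statistics of a PK parameter across subjects
#'
#' @param values positive parameter values
#' @return list with `mean`, `sd`, `gm` (geometric mean) and `cv_pct`
#'   (100 * SD / mean)
#' @export
summarise_pk <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values", call. = FALSE)
  if (any(values <= 0))
    stop("geometric mean requires positive values", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) > 1) sd(values) else 0
  list(mean = m, sd = s, gm = exp(mean(log(values))),
       cv_pct = 100 * s / m, n = length(values))
}

#' Geometric mean ratio with a 90% confidence interval across trials
#'
#' Per-subject log ratios are averaged within trials; the overall GMR is
#' the exponential of the grand mean of trial-level log ratios and the 90%
#' CI uses the t-distribution over the trial-level values
#' (`n_trials - 1` degrees of freedom).
#'
#' @param with_values parameter values in the with-perpetrator arm
#' @param without_values paired values in the without-perpetrator arm
#'   (same subjects, same order)
#' @param trial trial index per subject
#' @return data.frame with `gmr`, `lo90`, `hi90`, `n_trials`, `n_subjects`
#' @export
gmr_with_ci <- function(with_values, without_values, trial) {
  stopifnot(length(with_values) == length(without_values),
            length(trial) == length(with_values))
  ok <- !is.na(with_values) & !is.na(without_values)
  if (!all(ok)) {
    with_values <- with_values[ok]; without_values <- without_values[ok]
    trial <- trial[ok]
  }
  if (any(with_values <= 0) || any(without_values <= 0))
    stop("GMR requires positive paired values", call. = FALSE)
  lr <- log(with_values / without_values)
  tl <- tapply(lr, trial, mean)
  k <- length(tl)
  gmr <- exp(mean(tl))
  if (k > 1) {
    se <- sd(tl) / sqrt(k)
    ci <- exp(mean(tl) + c(-1, 1) * qt(0.95, k - 1) * se)
  } else {
    ci <- c(gmr, gmr)
  }
  data.frame(gmr = gmr, lo90 = ci[1], hi90 = ci[2], n_trials = k,
             n_subjects = length(lr))
}

#' Run a virtual study from a validated configuration
#'
#' Executes the configured simulation trial-by-trial with logged seeds and
#' returns (optionally writes) the time-series, per-subject NCA summaries,
#' DDI summary and a reproducibility manifest.
#'
#' @param config a `study_config` from [validate_config()], or a path to a
#'   study YAML
#' @param out_dir optional output directory passed to [write_outputs()]
#' @param representative run the single representative subject instead of
#'   the sampled population
#' @return a `study_result` list with elements `timeseries`, `pk_summary`,
#'   `ddi_summary` (or `NULL`), `subjects`, `manifest`
#' @export
run_virtual_study <- function(config, out_dir = NULL,
                              representative = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "study_config"))
  cmp <- config$objects
  subjects <- if (representative)
    representative_subject(cmp$population)
  else sample_population(cmp$population)

  ts_rows <- list(); pk_rows <- list(); ddi <- NULL
  if (identical(config$scenario$type, "ddi")) {
    scen <- .scenario_from_config(config)
    ddi <- run_ddi_pair(scen, subjects)
    pk_rows <- list(ddi$per_subject)
  } else {
    for (i in seq_len(nrow(subjects))) {
      su <- subjects[i, ]
      sim <- .simulate_arm(.scenario_from_config(config), su,
                           with_perp = FALSE)
      keep <- sim$analyte %in% c("adc_conjugated", "adc_total", "mmae",
                                 "victim")
      ts <- sim[keep, ]
      ts$trial <- su$trial; ts$subject <- su$subject
      ts_rows[[i]] <- ts
      for (an in intersect(unique(ts$analyte),
                           c("adc_conjugated", "mmae", "victim"))) {
        d <- ts[ts$analyte == an, ]
        if (max(d$conc, na.rm = TRUE) <= 0) next
        s <- nca_profile(d$time_h, d$conc)
        pk_rows[[length(pk_rows) + 1]] <-
          data.frame(trial = su$trial, subject = su$subject, analyte = an,
                     cmax = s$cmax, tmax_h = s$tmax_h,
                     auc_last = s$auc_last, auc_inf = s$auc_inf,
                     auc_d7 = s$auc_d7, auc_d14 = s$auc_d14,
                     t_half_day = s$t_half_day)
      }
    }
  }
  res <- list(
    timeseries = if (length(ts_rows)) do.call(rbind, ts_rows) else NULL,
    pk_summary = if (length(pk_rows)) do.call(rbind, pk_rows) else NULL,
    ddi_summary = if (!is.null(ddi)) ddi$summary else NULL,
    subjects = subjects,
    manifest = list(label = config$label, seed = cmp$population$master_seed,
                    files = config$file_hashes,
                    representative = representative,
                    timestamp = format(Sys.time(), tz = "UTC")))
  class(res) <- "study_result"
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}
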