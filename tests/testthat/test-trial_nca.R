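test_that("NCA recovers the mono-exponential closed form", {
  lam_d <- 0.347  # 1/day -> half-life 2.0 days
  tt <- seq(0, 21 * 24, by = 2)
  cc <- 10 * exp(-lam_d * tt / 24)
  n <- nca_profile(tt, cc)
  expect_equal(n$cmax, 10)
  expect_equal(n$tmax_h, 0)
  expect_equal(n$t_half_day, log(2) / lam_d, tolerance = 1e-3)
  expect_equal(n$auc_inf, 10 / lam_d, tolerance = 1e-3)
  expect_equal(n$lambda_z_per_day, lam_d, tolerance = 1e-3)
  # log-down trapezoid is exact on an exponential; linear overestimates
  n_lin <- nca_profile(tt, cc, method = "linear")
  expect_gt(n_lin$auc_last, n$auc_last)
})

test_that("flat profiles integrate as rectangles", {
  n <- nca_profile(c(0, 12, 24), c(10, 10, 10))
  expect_equal(n$auc_last, 10)  # 10 conc * 1 day
})

test_that("partial AUCs interpolate at exactly day 7 and day 14", {
  lam <- 0.01
  tt <- c(seq(0, 150, by = 5), seq(155, 400, by = 7))  # 168 not on grid
  cc <- 5 * exp(-lam * tt)
  n <- nca_profile(tt, cc)
  expect_equal(n$auc_d7, 5 * (1 - exp(-lam * 168)) / lam / 24,
               tolerance = 1e-4)
  expect_equal(n$auc_d14, 5 * (1 - exp(-lam * 336)) / lam / 24,
               tolerance = 1e-4)
  expect_lte(n$auc_d7, n$auc_d14)
  expect_lte(n$auc_last, n$auc_inf)
})

test_that("NCA flags profiles without an estimable terminal slope", {
  # rising profile: no points after Tmax
  n <- nca_profile(c(0, 10, 20, 30), c(1, 2, 3, 4))
  expect_true(is.na(n$auc_inf))
  expect_equal(n$n_points_lambda_z, 0L)
  expect_error(nca_profile(c(0, 1, 2), c(0, 0, 1)), "positive")
})

test_that("summary statistics follow their definitions", {
  s <- summarise_pk(c(1, 4))
  expect_equal(s$gm, 2)
  expect_equal(summarise_pk(c(3, 3, 3))$cv_pct, 0)
  expect_equal(summarise_pk(c(1, 1, 8))$gm, 2)
  expect_error(summarise_pk(c(1, -1)), "positive")
})

test_that("GMR machinery handles degenerate and uniform ratios", {
  x <- c(1, 2, 3, 4)
  r <- gmr_with_ci(x, x, trial = c(1, 1, 2, 2))
  expect_equal(r$gmr, 1)
  expect_equal(r$lo90, 1)
  expect_equal(r$hi90, 1)
  r2 <- gmr_with_ci(2 * x, x, trial = c(1, 1, 2, 2))
  expect_equal(r2$gmr, 2)
  expect_equal(r2$hi90 - r2$lo90, 0)
  expect_error(gmr_with_ci(1:3, 1:2, 1:3), "length")
})

test_that("NCA agrees with the integrator's cumulative AUC to 0.5%", {
  sim <- ev_single_sim()
  st <- attr(sim, "states")
  mmae <- mmae_cmpd()
  m <- sim[sim$analyte == "mmae", ]
  auc_nca <- nca_profile(m$time_h, m$conc)$auc_last
  auc_int <- unname(st[nrow(st), "auc_mmae"]) * mmae$mw_da / 1000 / 24
  expect_equal(auc_nca, auc_int, tolerance = 0.005)
  a <- sim[sim$analyte == "adc_conjugated", ]
  expect_equal(nca_profile(a$time_h, a$conc)$auc_last,
               unname(st[nrow(st), "auc_adc"]) / 24, tolerance = 0.005)
})

test_that("a representative virtual study produces one row per analyte", {
  res <- run_virtual_study(shipped_config("ev_single_1p25"),
                           representative = TRUE)
  expect_equal(nrow(res$subjects), 1)
  expect_setequal(unique(res$pk_summary$analyte),
                  c("adc_conjugated", "mmae"))
  expect_equal(nrow(res$pk_summary), 2)
  expect_false(is.null(res$manifest$seed))
})

test_that("day-15 payload Cmax exceeds day-1 Cmax on the weekly regimen", {
  res <- fx("ev_multi_rep", run_virtual_study(
    shipped_config("ev_multiple_1p25"), representative = TRUE))
  ts <- res$timeseries
  m <- ts[ts$analyte == "mmae", ]
  cmax_d1 <- max(m$conc[m$time_h <= 7 * 24])
  cmax_d15 <- max(m$conc[m$time_h >= 14 * 24 & m$time_h <= 21 * 24])
  expect_gt(cmax_d15, cmax_d1)
})

test_that("biliary-fraction sensitivity has limited impact on the DDI", {
  sub <- rep_subject()
  for (nm in c("ev_ketoconazole", "ev_rifampin")) {
    base <- run_ddi_pair(rep_scenario(nm), sub)$summary
    g0 <- base$gmr[base$parameter == "auc_last"]
    for (fb in c(0.6, 0.8)) {
      scen <- rep_scenario(nm); scen$f_bile <- fb
      r <- run_ddi_pair(scen, sub)$summary
      dg <- abs(r$gmr[r$parameter == "auc_last"] - g0)
      expect_lt(dg, 0.15)
    }
  }
})
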