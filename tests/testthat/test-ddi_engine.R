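test_that("competitive inhibition follows its defining ratios", {
  expect_equal(competitive_modifier(0, 1), 1)
  expect_equal(competitive_modifier(2, 2), 0.5)
  expect_equal(competitive_modifier(3, 1), 0.25)
  expect_error(competitive_modifier(1, 0), "ki")
  expect_error(competitive_modifier(-1, 1), "iu")
})

test_that("turnover operations match their closed forms to 0.1%", {
  kdeg <- 0.0193
  # homeostasis
  expect_equal(mbi_turnover(1, 0, 6, 1.128, kdeg), 0)
  expect_equal(induction_turnover(1, 0, 8, 0.32, kdeg), 0)
  # steady states
  expect_equal(mbi_steady_state(0.001, 6, 1.128, kdeg), 0.7841,
               tolerance = 1e-3)
  iu <- 2
  ess_ind <- 1 + 8 * iu / (0.32 + iu)
  # integrate the turnover ODEs and compare with the analytic course
  for (case in c("mbi", "ind")) {
    rhs <- function(t, y, parms) {
      list(if (case == "mbi") mbi_turnover(y, iu = 0.5, 6, 1.128, kdeg)
           else induction_turnover(y, iu = iu, 8, 0.32, kdeg))
    }
    tt <- seq(0, 400, by = 1)
    num <- deSolve::lsoda(c(E = 1), tt, rhs, NULL, rtol = 1e-10,
                          atol = 1e-12)[, "E"]
    ana <- if (case == "mbi")
      enzyme_time_course(tt, iu = 0.5, kinact = 6, kapp = 1.128,
                         kdeg = kdeg)
    else enzyme_time_course(tt, iu = iu, ind_max = 8, ind_c50 = 0.32,
                            kdeg = kdeg)
    expect_lt(max(abs(num - ana) / ana), 1e-3)
  }
  expect_equal(enzyme_time_course(1e6, iu, ind_max = 8, ind_c50 = 0.32,
                                  kdeg = kdeg), ess_ind, tolerance = 1e-6)
})

test_that("the compiled enzyme pool follows the analytic time course", {
  # constant perpetrator exposure: bolus into the central compartment with
  # clearance and absorption switched off
  keto <- load_compound(default_compound_file("ketoconazole"))
  keto$cl_l_h <- 0; keto$ka_per_h <- 0
  p <- model_parameters(ev_adc(), mmae_cmpd(), rep_phys(), perp = keto,
                        mmae_mbi_self = FALSE)
  p["perp_kapp"] <- 1.128; p["perp_kinact"] <- 6
  conc_nM <- 0.5 / keto$fu_plasma * 1000  # unbound 0.5 uM
  st <- run_model(p, seq(0, 300, by = 1),
                  boluses = data.frame(time_h = 0, state = "perp_central",
                                       amount = conc_nM * keto$v1_l))
  ana <- enzyme_time_course(st[, "time"], iu = 0.5, kinact = 6,
                            kapp = 1.128, kdeg = p[["kdeg_cyp"]])
  expect_lt(max(abs(st[, "e_rel"] - ana) / ana), 1e-3)
})

test_that("the RAF fold multiplies and rejects sub-unity folds", {
  expect_equal(apply_pgp_raf(3, 1), 3)
  expect_equal(apply_pgp_raf(3, 2), 6)
  expect_error(apply_pgp_raf(3, 0.5), "fold")
})

test_that("GMR is exactly 1 when the perpetrator dose is 0", {
  scen <- rep_scenario("ev_ketoconazole")
  scen$perp_regimen <- qd_regimen(0, 31, 0)  # zero-dose perpetrator
  r <- run_ddi_pair(scen, small_pop()[1:2, ])
  expect_equal(r$summary$gmr, c(1, 1), tolerance = 1e-12)
  expect_equal(r$summary$lo90, c(1, 1), tolerance = 1e-12)
})

test_that("the baseline arm is identical to a standalone victim run", {
  scen <- rep_scenario("ev_ketoconazole")
  su <- rep_subject()[1, ]
  base <- adcpbpk:::.simulate_arm(scen, su, with_perp = FALSE)
  alone <- simulate_subject(
    adc = scen$adc, adc_regimen = scen$adc_regimen, mmae = scen$mmae,
    physiology = subject_physiology(su), perp = scen$perp,
    perp_regimen = NULL, end_h = scen$end_h, weight_kg = su$weight_kg,
    cyp_mult = su$cyp3a4_mult, pgp_mult = su$pgp_mult)
  expect_identical(base$conc[base$analyte == "mmae"],
                   alone$conc[alone$analyte == "mmae"])
})

test_that("MMAE exposure ratio is monotone in the inhibitor potency", {
  scen <- rep_scenario("ev_ketoconazole")
  sub <- rep_subject()
  gmrs <- sapply(c(0.25, 1, 4, 1e6), function(scale) {
    s <- scen
    s$perp$ki_cyp3a4_um <- scen$perp$ki_cyp3a4_um * scale
    s$perp$ki_pgp_um <- scen$perp$ki_pgp_um * scale
    r <- run_ddi_pair(s, sub)
    r$summary$gmr[r$summary$parameter == "auc_last"]
  })
  expect_true(all(diff(gmrs) < 0))       # weaker binding, weaker effect
  expect_equal(gmrs[4], 1, tolerance = 1e-4)  # Ki -> Inf recovers unity
})

test_that("inducer and inhibitor sit on opposite sides of unity", {
  sub <- rep_subject()
  keto <- run_ddi_pair(rep_scenario("ev_ketoconazole"), sub)$summary
  rif <- run_ddi_pair(rep_scenario("ev_rifampin"), sub)$summary
  a_keto <- keto$gmr[keto$parameter == "auc_last"]
  a_rif <- rif$gmr[rif$parameter == "auc_last"]
  expect_gt(a_keto, 1)
  expect_lt(a_rif, 1)
})
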