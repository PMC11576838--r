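test_that("without elimination the tissues equilibrate to Kp ratios", {
  mmae <- mmae_cmpd()
  phys <- rep_phys()
  p <- model_parameters(NULL, mmae, phys)
  p[c("mmae_cl_r", "clint_met", "clint_pgp")] <- 0
  st <- run_model(p, seq(0, 2000, by = 10),
                  boluses = data.frame(time_h = 0, state = "ven",
                                       amount = 1000))
  last <- st[nrow(st), ]
  cp <- (last[["ven"]] / p[["v_ven"]]) / mmae$bp_ratio  # plasma nM
  for (t in c("muscle", "kidney", "adipose", "brain")) {
    ct <- last[[t]] / p[[paste0("v_", t)]]
    expect_equal(ct / cp, p[[paste0("kp_", t)]], tolerance = 1e-3,
                 label = t)
  }
  # amounts conserved
  body <- sum(last[c("ven", "art", "lung", adcpbpk:::.pbpk_tissues,
                     "liv_ec", "liv_ic")])
  expect_equal(body, 1000, tolerance = 1e-6)
})

test_that("simulated terminal distribution reproduces the composition Vss", {
  mmae <- mmae_cmpd()
  phys <- rep_phys()
  p <- model_parameters(NULL, mmae, phys)
  p[c("mmae_cl_r", "clint_met", "clint_pgp")] <- 0
  st <- run_model(p, seq(0, 3000, by = 25),
                  boluses = data.frame(time_h = 0, state = "ven",
                                       amount = 1000))
  last <- st[nrow(st), ]
  cp <- (last[["ven"]] / p[["v_ven"]]) / mmae$bp_ratio
  vss_sim <- sum(last[c("ven", "art", "lung", adcpbpk:::.pbpk_tissues,
                        "liv_ec", "liv_ic")]) / cp / phys$body_weight_kg
  kps <- kp_rodgers_rowland(mmae, phys)
  expect_equal(vss_sim, vss_from_kp(kps, phys, mmae), tolerance = 0.02)
})

test_that("systemic payload clearance reproduces the reference value", {
  mmae <- mmae_cmpd()
  p <- model_parameters(NULL, mmae, rep_phys(), mmae_mbi_self = FALSE)
  dose_nmol <- 1e6 / mmae$mw_da  # 1 mg short infusion
  bol <- data.frame(time_h = seq(0, 0.95, by = 0.05), state = "ven",
                    amount = dose_nmol / 20)
  st <- run_model(p, sim_grid(1440, adc_dose_times = 0, infusion_h = 1),
                  boluses = bol)
  cp <- (st[, "ven"] / p[["v_ven"]]) / mmae$bp_ratio * mmae$mw_da / 1000
  n <- nca_profile(st[, "time"], cp)
  cl <- 1000 / (n$auc_inf * 24)  # mg / (ng/mL * day) -> L/h
  expect_equal(cl, mmae$cl_iv_reference_l_h, tolerance = 0.10)
  # renal share of total elimination follows CL_R / CL_iv
  led <- st[nrow(st), c("cum_met", "cum_bile", "cum_renal")]
  expect_equal(unname(led["cum_renal"] / sum(led)),
               mmae$cl_r_l_h / mmae$cl_iv_reference_l_h, tolerance = 0.10)
})

test_that("payload mass balance closes to 1e-6 in the coupled model", {
  sim <- ev_single_sim()
  st <- attr(sim, "states")
  body <- rowSums(st[, c("ven", "art", "lung", adcpbpk:::.pbpk_tissues,
                         "liv_ec", "liv_ic")])
  ledger <- st[, "cum_met"] + st[, "cum_bile"] + st[, "cum_renal"]
  input <- st[, "cum_released"]
  i <- input > 1e-3
  expect_lt(max(abs((body[i] + ledger[i] - input[i]) / input[i])), 1e-6)
})

test_that("perpetrator kinetics match the one-compartment closed form", {
  keto <- load_compound(default_compound_file("ketoconazole"))
  p <- model_parameters(ev_adc(), mmae_cmpd(), rep_phys(), perp = keto)
  dose_nmol <- 400 * 1e6 / keto$mw_da
  tt <- seq(0, 48, by = 0.25)
  st <- run_model(p, tt, boluses = data.frame(time_h = 0,
                                              state = "perp_gut",
                                              amount = dose_nmol))
  sim_c <- st[, "perp_central"] / keto$v1_l
  k <- keto$cl_l_h / keto$v1_l
  ka <- keto$ka_per_h
  bateman <- dose_nmol * keto$f_oral * ka / (keto$v1_l * (ka - k)) *
    (exp(-k * tt) - exp(-ka * tt))
  expect_equal(sim_c[-1], bateman[-1], tolerance = 1e-6)
})

test_that("once-daily perpetrator dosing accumulates by the superposition
           ratio", {
  keto <- load_compound(default_compound_file("ketoconazole"))
  p <- model_parameters(ev_adc(), mmae_cmpd(), rep_phys(), perp = keto)
  dose_nmol <- 400 * 1e6 / keto$mw_da
  doses <- data.frame(time_h = seq(0, 24 * 14, by = 24),
                      state = "perp_gut", amount = dose_nmol)
  tt <- sort(unique(c(seq(0, 24 * 15, by = 0.5), doses$time_h)))
  st <- run_model(p, tt, boluses = doses)
  conc <- st[, "perp_central"]
  trough1 <- conc[which.min(abs(tt - 24))]
  trough_ss <- conc[which.min(abs(tt - 24 * 14))]
  k <- keto$cl_l_h / keto$v1_l
  # absorption is essentially complete within a day, so trough
  # accumulation approaches the one-compartment superposition ratio
  expect_equal(trough_ss / trough1, 1 / (1 - exp(-k * 24)),
               tolerance = 0.02)
})
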