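test_that("FcRn bound fraction has the right limits", {
  expect_equal(fcrn_bound_fraction(1, 0, 7.28), 0)
  # trace antibody, receptor pool at the dissociation constant: half bound
  expect_equal(fcrn_bound_fraction(1e-12, 7.28, 7.28), 0.5,
               tolerance = 1e-6)
  # infinite affinity with receptor excess
  expect_equal(fcrn_bound_fraction(1, 50, 0), 1)
  # saturating antibody depresses the bound fraction
  fb <- fcrn_bound_fraction(c(0.01, 10, 100), 14, 7.28)
  expect_true(all(diff(fb) < 0))
})

test_that("the ADC right-hand side is zero when all rates are zero", {
  p <- model_parameters(ev_adc(), mmae_cmpd(), rep_phys())
  zero <- c("inf_rate", "k_up", "k_rc1", "cl_cat", "cl_add_slope",
            "kdec_p", "kdec_t", "k_rel")
  p[zero] <- 0
  y <- setNames(numeric(length(adcpbpk:::.state_names)),
                adcpbpk:::.state_names)
  y[paste0("adc_p", 0:8)] <- 10
  y["e_rel"] <- 1
  d <- adcpbpk:::pbpk_eval(0, y, p)
  expect_true(all(abs(d[paste0("adc_p", 0:8)]) < 1e-12))
  expect_true(all(abs(d[paste0("adc_e", 0:8)]) < 1e-12))
  expect_equal(unname(d["depot"]), 0)
})

test_that("deconjugation cascades one DAR step with payload bookkeeping", {
  adc <- ev_adc()
  p <- model_parameters(adc, mmae_cmpd(), rep_phys())
  p[c("k_up", "k_rc1", "cl_cat", "cl_add_slope", "k_rel")] <- 0
  p["kdec_p"] <- 0.001; p["kdec_t"] <- 0
  y <- setNames(numeric(length(adcpbpk:::.state_names)),
                adcpbpk:::.state_names)
  y["adc_p4"] <- 100; y["e_rel"] <- 1
  d <- adcpbpk:::pbpk_eval(0, y, p)
  # species-3 appearance rate equals species-4 loss rate
  expect_equal(unname(d["adc_p3"]), -unname(d["adc_p4"]))
  expect_equal(unname(d["adc_p4"]), -0.001 * 100)
  # exactly one payload per deconjugation event enters the depot
  expect_equal(unname(d["depot"]), 0.001 * 100)
  # DAR 0 cannot deconjugate
  y2 <- y; y2["adc_p4"] <- 0; y2["adc_p0"] <- 100
  d2 <- adcpbpk:::pbpk_eval(0, y2, p)
  expect_equal(unname(d2["adc_p0"]), 0)
})

test_that("DAR-proportional clearance vanishes for the naked antibody", {
  p <- model_parameters(ev_adc(), mmae_cmpd(), rep_phys())
  p[c("k_up", "k_rc1", "kdec_p", "kdec_t", "cl_cat", "k_rel")] <- 0
  y <- setNames(numeric(length(adcpbpk:::.state_names)),
                adcpbpk:::.state_names)
  y["adc_p0"] <- 50; y["e_rel"] <- 1
  d <- adcpbpk:::pbpk_eval(0, y, p)
  expect_equal(unname(d["adc_p0"]), 0)  # slope * j with j = 0
  y["adc_p0"] <- 0; y["adc_p4"] <- 50
  d <- adcpbpk:::pbpk_eval(0, y, p)
  expect_equal(unname(d["adc_p4"]),
               -p[["cl_add_slope"]] * 4 / p[["v_plasma"]] * 50)
})

test_that("zero dose gives identically zero profiles", {
  sim <- simulate_adc(ev_adc(),
                      dose_regimen("iv_infusion", dose_mg = 0,
                                   infusion_h = 0.5),
                      rep_phys(), mmae = mmae_cmpd(), end_h = 48)
  expect_true(all(sim$conc[sim$analyte %in%
                             c("adc_conjugated", "mmae")] == 0))
})

test_that("payload molar balance holds to 1e-6 along the trajectory", {
  sim <- ev_single_sim()
  dose_nmol <- compute_dose(ev_reg(), rep_subject()$weight_kg) * 1e6 /
    ev_adc()$mw_adc_da
  pb <- payload_balance(sim, ev_adc(), dose_nmol)
  post <- pb[pb$time_h >= 0.5, ]  # after the end of the infusion
  expect_lt(max(abs(post$rel_error)), 1e-6)
})

test_that("mean circulating DAR is non-increasing after the infusion", {
  sim <- ev_single_sim()
  md <- sim[sim$analyte == "mean_dar" & sim$time_h >= 0.5, "conc"]
  expect_true(all(diff(md) <= 1e-9))
})

test_that("total antibody is conserved without elimination pathways", {
  adc <- ev_adc()
  adc$cl_cat_l_h <- 0; adc$cl_add_slope_l_h_per_dar <- 0
  adc$k_dec_plasma_per_h <- 0; adc$k_dec_tissue_per_h <- 0
  sim <- simulate_adc(adc, ev_reg(), rep_phys(), mmae = mmae_cmpd(),
                      end_h = 240, weight_kg = rep_subject()$weight_kg)
  st <- attr(sim, "states")
  tot <- rowSums(st[, c(paste0("adc_p", 0:8), paste0("adc_e", 0:8))])
  post <- tot[st[, "time"] >= 0.5]
  expect_lt(max(abs(post / post[1] - 1)), 1e-7)
})

test_that("doubling the dose doubles concentrations in the linear regime", {
  w <- rep_subject()$weight_kg
  s1 <- simulate_adc(ev_adc(), ev_reg(), rep_phys(), mmae = mmae_cmpd(),
                     end_h = 336, weight_kg = w, mmae_mbi_self = FALSE)
  s2 <- simulate_adc(ev_adc(),
                     dose_regimen("iv_infusion", dose_mg_kg = 2.5,
                                  dose_cap_mg = 250, infusion_h = 0.5),
                     rep_phys(), mmae = mmae_cmpd(), end_h = 336,
                     weight_kg = w, mmae_mbi_self = FALSE)
  for (an in c("adc_conjugated", "mmae")) {
    i <- s1$analyte == an & s1$conc > 1e-6
    ratio <- s2$conc[i] / s1$conc[i]
    # quasi-equilibrium FcRn binding leaves a small saturation footprint
    expect_lt(max(abs(ratio / 2 - 1)), 0.02)
  }
})

test_that("a point-mass DAR at the mean releases similar payload totals", {
  adc <- ev_adc()
  sim_full <- ev_single_sim()
  point <- adc
  # nearest integer point mass bracketing the mean (3.735): mix of 3 and 4
  frac <- numeric(9); frac[4] <- 4 - 3.735; frac[5] <- 1 - frac[4]
  point$dar_fractions <- frac
  sim_pt <- simulate_adc(point, ev_reg(), rep_phys(), mmae = mmae_cmpd(),
                         end_h = 672, weight_kg = rep_subject()$weight_kg)
  rel_full <- max(attr(sim_full, "states")[, "cum_released"])
  rel_pt <- max(attr(sim_pt, "states")[, "cum_released"])
  expect_lt(abs(rel_pt / rel_full - 1), 0.15)
})

test_that("the conjugated-antibody analyte excludes the naked antibody", {
  sim <- ev_single_sim()
  st <- attr(sim, "states")
  i <- 200
  conj <- sim$conc[sim$analyte == "adc_conjugated"][i]
  tot <- sim$conc[sim$analyte == "adc_total"][i]
  expect_lt(conj, tot)
  naked <- st[i, "adc_p0"] * ev_adc()$mw_adc_da /
    (attr(sim, "parms")[["v_plasma"]] * 1e6)
  expect_equal(tot - conj, unname(naked), tolerance = 1e-9)
})
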