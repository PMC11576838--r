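test_that("zero residual error reproduces the interpolated truth", {
  sim <- ev_single_sim()
  obs <- generate_observed(sim, error_cv = 0, lloq = c(mmae = 0), seed = 1)
  m <- obs[obs$analyte == "mmae", ]
  truth <- sim[sim$analyte == "mmae", ]
  expected <- approx(truth$time_h, truth$conc, xout = m$time_h)$y
  expect_equal(m$conc, expected, tolerance = 1e-9)
  expect_false(any(obs$blq))
})

test_that("an all-zero truth is entirely below the limit", {
  sim <- simulate_adc(ev_adc(),
                      dose_regimen("iv_infusion", dose_mg = 0,
                                   infusion_h = 0.5),
                      rep_phys(), mmae = mmae_cmpd(), end_h = 192)
  obs <- generate_observed(sim, error_cv = 0.2,
                           lloq = c(adc_conjugated = 0.01, adc_total = 0.01,
                                    mmae = 0.01), seed = 2)
  expect_true(all(obs$blq))
  expect_true(all(is.na(obs$conc)))
})

test_that("residual error is reproducible per seed with the configured CV", {
  sim <- ev_single_sim()
  a <- generate_observed(sim, error_cv = 0.3, seed = 10)
  b <- generate_observed(sim, error_cv = 0.3, seed = 10)
  expect_identical(a, b)
  c2 <- generate_observed(sim, error_cv = 0.3, seed = 11)
  expect_false(isTRUE(all.equal(a$conc, c2$conc)))
  expect_identical(a$time_h, c2$time_h)
  expect_identical(a$analyte, c2$analyte)

  # empirical CV of sampled/truth ratios over many replicates
  truth <- sim[sim$analyte == "mmae", ]
  ratios <- unlist(lapply(1:50, function(s) {
    o <- generate_observed(sim, error_cv = 0.3, lloq = c(mmae = 0),
                           seed = s, analytes = "mmae")
    o$conc / approx(truth$time_h, truth$conc, xout = o$time_h)$y
  }))
  expect_equal(sd(ratios) / mean(ratios), 0.3, tolerance = 0.15)
})

test_that("schedules outside the simulated span are rejected", {
  sim <- simulate_adc(ev_adc(), ev_reg(), rep_phys(), mmae = mmae_cmpd(),
                      end_h = 48, weight_kg = rep_subject()$weight_kg)
  expect_error(generate_observed(sim, schedule = c(24, 96)), "span")
})

test_that("overlay statistics are exact when observed equals truth", {
  sim <- ev_single_sim()
  obs <- generate_observed(sim, error_cv = 0, lloq = c(mmae = 0), seed = 1,
                           analytes = "mmae")
  chk <- overlay_check(obs, list(sim))
  expect_equal(unname(chk$coverage["mmae"]), 1)
  # sparse-schedule NCA vs dense-grid NCA leaves a small quadrature gap
  expect_equal(chk$po_table$po_ratio, rep(1, 2), tolerance = 0.03)
  bad <- obs; bad$analyte <- "nonexistent"
  class(bad) <- class(obs)
  expect_error(overlay_check(bad, list(sim)), "mismatch")
})

test_that("noisy observations fall inside the population band", {
  pop <- fx("overlay_pop", {
    cfg <- population_config(n_trials = 4, n_per_trial = 5,
                             master_seed = 77)
    subs <- sample_population(cfg)
    lapply(seq_len(nrow(subs)), function(i)
      simulate_adc(ev_adc(), ev_reg(), subject_physiology(subs[i, ]),
                   mmae = mmae_cmpd(), end_h = 192,
                   weight_kg = subs$weight_kg[i]))
  })
  # sample the subject with the median payload peak, with residual error
  # small relative to the population band
  cmaxes <- vapply(pop, function(s) max(s$conc[s$analyte == "mmae"]),
                   numeric(1))
  truth <- pop[[order(cmaxes)[ceiling(length(cmaxes) / 2)]]]
  obs <- do.call(rbind, lapply(1:10, function(s)
    generate_observed(truth, error_cv = 0.05, lloq = c(mmae = 0), seed = s,
                      analytes = "mmae", subject_id = s)))
  class(obs) <- c("observed_dataset", "data.frame")
  chk <- overlay_check(obs, pop)
  expect_gte(unname(chk$coverage["mmae"]), 0.9)
})

test_that("the P/O statistic reproduces the published ratio columns", {
  fixture <- read.csv(system.file("extdata", "observed",
                                  "reported_pk_gm.csv",
                                  package = "adcpbpk"), comment.char = "#")
  po <- po_ratio(fixture$published_model_gm, fixture$observed_gm)
  ev_mmae_cmax <- po[fixture$adc == "enfortumab vedotin" &
                       fixture$dose_mg_kg == 1.25 &
                       fixture$analyte == "mmae" &
                       fixture$parameter == "cmax"]
  expect_equal(round(ev_mmae_cmax, 2), 1.08)
  ev_conj_auc <- po[fixture$adc == "enfortumab vedotin" &
                      fixture$dose_mg_kg == 1.25 &
                      fixture$analyte == "adc_conjugated" &
                      fixture$parameter == "auc"]
  expect_equal(round(ev_conj_auc, 3), 0.955)
})
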