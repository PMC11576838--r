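test_that("shipped compound files load with their printed parameters", {
  adc <- ev_adc()
  expect_s3_class(adc, "adc_compound")
  expect_equal(adc$kd_fcrn_um, 7.28)
  expect_equal(adc$mw_adc_da, 146664.1)
  expect_equal(sum(adc$dar_fractions), 1, tolerance = 1e-9)

  mmae <- mmae_cmpd()
  expect_equal(mmae$fu_plasma, 0.178)
  expect_equal(mmae$cl_iv_reference_l_h, 2.72)
  expect_equal(mmae$ki_pgp_um, 16.8)

  keto <- load_compound(default_compound_file("ketoconazole"))
  expect_equal(keto$ki_pgp_um, 0.67)
  rif <- load_compound(default_compound_file("rifampin"))
  expect_equal(rif$ki_pgp_um, 4.3)
})

test_that("schema validation rejects malformed files with named fields", {
  tmp <- tempfile(fileext = ".yaml")
  x <- yaml::read_yaml(default_compound_file("enfortumab_vedotin"))

  bad <- x; bad$dar_fractions <- c(0.5, rep(0.05, 8))  # sums to 0.9
  yaml::write_yaml(bad, tmp)
  expect_error(load_compound(tmp), "sum to 1")

  bad <- x; bad$mystery_field <- 1
  yaml::write_yaml(bad, tmp)
  expect_error(load_compound(tmp), "unknown field.*mystery_field")

  bad <- x; bad$k_up_per_h <- NULL
  yaml::write_yaml(bad, tmp)
  expect_error(load_compound(tmp), "missing field.*k_up_per_h")

  bad <- x; bad$f_rel_cat <- 1.4
  yaml::write_yaml(bad, tmp)
  expect_error(load_compound(tmp), "f_rel_cat")

  expect_error(load_compound(default_compound_file("mmae"), kind = "adc"),
               "does not match")
})

test_that("compound files round-trip numeric fields bit-exactly", {
  for (stem in c("enfortumab_vedotin", "mmae", "ketoconazole", "digoxin")) {
    orig <- load_compound(default_compound_file(stem))
    tmp <- tempfile(fileext = ".yaml")
    write_compound(orig, tmp)
    back <- load_compound(tmp)
    for (f in names(orig))
      if (is.numeric(orig[[f]]))
        expect_identical(back[[f]], orig[[f]], label = paste(stem, f))
  }
})

test_that("mean DAR is the probability-weighted species index", {
  expect_equal(mean_dar(c(1, rep(0, 8))), 0)
  expect_equal(mean_dar(rep(1 / 9, 9)), 4)
  # linearity in the fractions and bounds
  set.seed(7)
  for (i in 1:25) {
    p <- runif(9); p <- p / sum(p)
    m <- mean_dar(p)
    expect_gte(m, 0); expect_lte(m, 8)
    q <- runif(9); q <- q / sum(q)
    a <- runif(1)
    expect_equal(mean_dar(a * p + (1 - a) * q),
                 a * mean_dar(p) + (1 - a) * mean_dar(q))
  }
  expect_error(mean_dar(c(0.5, 0.4)), "sum to 1")
})

test_that("weight-based dosing honours the absolute cap", {
  reg <- ev_reg()
  expect_equal(compute_dose(reg, 80), 100)
  expect_equal(compute_dose(reg, 110), 125)
  fixed <- dose_regimen("oral", dose_mg = 400)
  expect_equal(compute_dose(fixed, 51), 400)
  expect_equal(compute_dose(fixed, 120), 400)
  expect_error(compute_dose(reg, -1), "positive")
  expect_error(dose_regimen("iv_infusion", dose_mg_kg = 1, infusion_h = 0),
               "infusion")
  expect_error(dose_regimen("oral", dose_mg = 1, dosing_days = 30,
                            cycle_days = 28), "within")
})

test_that("retrograde split matches the printed clearance decomposition", {
  s <- retrograde_split(2.72, 0.8, 0.70)
  expect_equal(s$cl_bile, 1.344)
  expect_equal(s$cl_met_cyp3a4, 0.576)
  expect_equal(retrograde_split(2.72, 0.8, 0)$cl_bile, 0)
  expect_equal(retrograde_split(2.72, 0.8, 0)$cl_met_cyp3a4, 1.92)
  expect_equal(retrograde_split(2.72, 0.8, 1)$cl_bile, 1.92)
  expect_equal(retrograde_split(2.72, 0.8, 1)$cl_met_cyp3a4, 0)
  # conservation property
  set.seed(11)
  for (i in 1:25) {
    cl_iv <- runif(1, 0.5, 50); cl_r <- runif(1, 0, cl_iv)
    fb <- runif(1)
    s <- retrograde_split(cl_iv, cl_r, fb)
    expect_equal(s$cl_bile + s$cl_met_cyp3a4 + cl_r, cl_iv)
  }
  expect_error(retrograde_split(1, 2, 0.5), "exceed")
})
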