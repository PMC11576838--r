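# Shared fixtures, built in code and cached for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

ev_adc <- function() fx("ev_adc",
  load_compound(default_compound_file("enfortumab_vedotin")))

mmae_cmpd <- function() fx("mmae",
  load_compound(default_compound_file("mmae")))

rep_subject <- function() fx("rep_subject",
  representative_subject(population_config()))

rep_phys <- function() fx("rep_phys", subject_physiology(rep_subject()[1, ]))

ev_reg <- function() dose_regimen("iv_infusion", dose_mg_kg = 1.25,
                                  dose_cap_mg = 125, infusion_h = 0.5)

# reference single-dose simulation of the representative subject
ev_single_sim <- function() fx("ev_single_sim",
  simulate_adc(ev_adc(), ev_reg(), rep_phys(), mmae = mmae_cmpd(),
               end_h = 672, weight_kg = rep_subject()$weight_kg))

shipped_config <- function(name) {
  validate_config(system.file("extdata", "configs", paste0(name, ".yaml"),
                              package = "adcpbpk"))
}

rep_scenario <- function(name) {
  adcpbpk:::.scenario_from_config(shipped_config(name))
}

# small population for paired-design tests (2 trials x 2 subjects)
small_pop <- function() fx("small_pop", {
  cfg <- population_config(n_trials = 2, n_per_trial = 2,
                           master_seed = 424242)
  sample_population(cfg)
})
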