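#!/usr/bin/env Rscript
# Step 4 - drug-drug interaction simulations.
# Paired 10x10 virtual trials of enfortumab vedotin 1.25 mg/kg with each
# perpetrator/probe: ketoconazole 400 mg QD (combined P-gp + strong CYP3A4
# inhibitor), rifampin 600 mg QD (combined P-gp + CYP3A4 inducer),
# midazolam 1 mg IV (CYP3A4 probe) and digoxin 0.5 mg oral (P-gp probe).
# GMRs with 90% CIs are computed across trial-level means.

library(adcpbpk)
dir.create("results", showWarnings = FALSE)

scenarios <- c("ev_ketoconazole", "ev_rifampin", "ev_midazolam",
               "ev_digoxin")
rows <- list()
for (nm in scenarios) {
  cfg <- validate_config(system.file("extdata", "configs",
                                     paste0(nm, ".yaml"),
                                     package = "adcpbpk"))
  subs <- sample_population(cfg$objects$population)
  t0 <- Sys.time()
  r <- run_ddi_pair(adcpbpk:::.scenario_from_config(cfg), subs)
  el <- as.numeric(Sys.time() - t0, units = "secs")
  s <- r$summary
  s$scenario <- nm
  rows[[nm]] <- s
  cat(sprintf("%-16s AUC GMR %.2f (%.2f-%.2f)  Cmax GMR %.2f (%.2f-%.2f)  [%.0f s]\n",
              nm,
              s$gmr[s$parameter == "auc_last"],
              s$lo90[s$parameter == "auc_last"],
              s$hi90[s$parameter == "auc_last"],
              s$gmr[s$parameter == "cmax"],
              s$lo90[s$parameter == "cmax"],
              s$hi90[s$parameter == "cmax"], el))
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/ddi_summary.csv", row.names = FALSE)
cat("\nReported simulation ratios for comparison: ketoconazole 1.38/1.15,",
    "rifampin 0.47/0.72, midazolam 1.14/1.00, digoxin 1.00/1.00",
    "(AUC/Cmax).\n")
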