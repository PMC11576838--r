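#!/usr/bin/env Rscript
# Step 3 - population exposures.
# Simulates the 10x10 cancer population for single doses of enfortumab
# vedotin 1.25 and 1.0 mg/kg and the weekly (days 1/8/15 of 28) multiple
# dose regimen, and summarises conjugated-antibody and MMAE exposure
# (GM, CV%) next to the reported clinical geometric means.

library(adcpbpk)
dir.create("results", showWarnings = FALSE)

summarise_run <- function(config_name) {
  res <- run_virtual_study(system.file("extdata", "configs",
                                       paste0(config_name, ".yaml"),
                                       package = "adcpbpk"))
  pk <- res$pk_summary
  do.call(rbind, lapply(split(pk, pk$analyte), function(d) {
    data.frame(run = config_name, analyte = d$analyte[1], n = nrow(d),
               gm_cmax = summarise_pk(d$cmax)$gm,
               cv_cmax = summarise_pk(d$cmax)$cv_pct,
               gm_auc_d7 = summarise_pk(d$auc_d7)$gm,
               gm_thalf_d = summarise_pk(
                 d$t_half_day[!is.na(d$t_half_day)])$gm)
  }))
}

tab <- rbind(summarise_run("ev_single_1p25"), summarise_run("ev_single_1p0"))
rownames(tab) <- NULL
write.csv(tab, "results/exposures_single_dose.csv", row.names = FALSE)
cat("Single-dose population exposure summary:\n")
print(tab, digits = 3)
cat("\nReported clinical GMs (1.25 mg/kg): conjugated Cmax 28.2 ug/mL,",
    "AUC0-7d 33.7 ug*day/mL; MMAE Cmax 3.03 ng/mL, AUC0-7d 16.0",
    "ng*day/mL\n\n")

# multiple dose: day-1 vs day-15 windows (accumulation of the payload)
res <- run_virtual_study(system.file("extdata", "configs",
                                     "ev_multiple_1p25.yaml",
                                     package = "adcpbpk"))
ts <- res$timeseries
win <- function(d, from, to) {
  dd <- d[d$time_h >= from & d$time_h <= to, ]
  nca_profile(dd$time_h - from, dd$conc)
}
rows <- list()
for (key in split(ts, list(ts$trial, ts$subject, ts$analyte), drop = TRUE)) {
  an <- key$analyte[1]
  if (!an %in% c("adc_conjugated", "mmae")) next
  d1 <- win(key, 0, 168); d15 <- win(key, 336, 504)
  rows[[length(rows) + 1]] <- data.frame(
    analyte = an, cmax_d1 = d1$cmax, cmax_d15 = d15$cmax,
    auc7_d1 = d1$auc_last, auc7_d15 = d15$auc_last)
}
md <- do.call(rbind, rows)
md_sum <- do.call(rbind, lapply(split(md, md$analyte), function(d)
  data.frame(analyte = d$analyte[1],
             gm_cmax_d1 = summarise_pk(d$cmax_d1)$gm,
             gm_cmax_d15 = summarise_pk(d$cmax_d15)$gm,
             gm_auc7_d1 = summarise_pk(d$auc7_d1)$gm,
             gm_auc7_d15 = summarise_pk(d$auc7_d15)$gm)))
write.csv(md_sum, "results/exposures_multiple_dose.csv", row.names = FALSE)
cat("Multiple-dose day-1 vs day-15 summary (weekly x3 regimen):\n")
print(md_sum, digits = 3)
cat("\nMMAE accumulates from day 1 to day 15 (reported direction:",
    "Cmax GM 3.19 -> 4.43 ng/mL).\n")
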