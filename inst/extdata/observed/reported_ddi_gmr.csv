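# Reported MMAE / probe-substrate interaction geometric mean ratios.
# observed_* are the clinical brentuximab vedotin DDI study results
# (Han et al., J Clin Pharmacol 2013; NCT01026415; AUCinf and Cmax ratios,
# with/without perpetrator); published_model_* are the corresponding
# previously published population-simulation ratios used as the
# calibration anchor for the perpetrator compound files (NA where no value
# was reported). victim_analyte "mmae": MMAE exposure ratio; "victim":
# probe-substrate exposure ratio.
adc,dose_mg_kg,perpetrator,victim_analyte,observed_auc_ratio,observed_cmax_ratio,published_model_auc_ratio,published_model_cmax_ratio
brentuximab vedotin,1.8,ketoconazole,mmae,1.34,1.25,1.37,1.15
brentuximab vedotin,1.8,rifampin,mmae,0.54,0.56,0.47,0.70
brentuximab vedotin,1.8,midazolam,victim,0.94,1.15,1.20,1.00
brentuximab vedotin,1.8,digoxin,victim,NA,NA,1.00,1.00
enfortumab vedotin,1.25,ketoconazole,mmae,NA,NA,1.38,1.15
enfortumab vedotin,1.25,rifampin,mmae,NA,NA,0.47,0.72
enfortumab vedotin,1.25,midazolam,victim,NA,NA,1.14,1.00
enfortumab vedotin,1.25,digoxin,victim,NA,NA,1.00,1.00
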