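# Reported clinical geometric means for vedotin ADCs (observed_gm) together
# with previously published population-simulation geometric means for the
# same regimens (published_model_gm), used by the verification workflow.
# Sources of the observed values: enfortumab vedotin phase 1 EV-101
# (Rosenberg et al., J Clin Oncol 2019; NCT02091999) and phase 2 EV-201
# (Rosenberg et al. 2019; NCT03219333); brentuximab vedotin clinical
# pharmacology review (US FDA BLA 125388) and its DDI study (Han et al.,
# J Clin Pharmacol 2013; NCT01026415).
# Units: conjugated antibody Cmax ug/mL, AUC ug*day/mL; MMAE Cmax ng/mL,
# AUC ng*day/mL. AUC is 0-7 day (single dose) for EV rows and AUC(0-inf)
# for BV rows, matching the published tables.
adc,dose_mg_kg,analyte,parameter,observed_gm,published_model_gm
brentuximab vedotin,1.8,adc_conjugated,cmax,32.0,30.9
brentuximab vedotin,1.8,adc_conjugated,auc,79.4,79.7
brentuximab vedotin,2.7,adc_conjugated,cmax,45.0,46.4
brentuximab vedotin,2.7,adc_conjugated,auc,126,120
enfortumab vedotin,1.25,adc_conjugated,cmax,28.2,24.9
enfortumab vedotin,1.25,adc_conjugated,auc,33.7,32.2
enfortumab vedotin,1.0,adc_conjugated,cmax,22.3,20.2
enfortumab vedotin,1.0,adc_conjugated,auc,27.9,25.7
brentuximab vedotin,1.8,mmae,cmax,4.67,4.28
brentuximab vedotin,1.8,mmae,auc,37.0,32.0
brentuximab vedotin,2.7,mmae,cmax,7.00,6.44
brentuximab vedotin,2.7,mmae,auc,53.2,48.6
enfortumab vedotin,1.25,mmae,cmax,3.03,3.28
enfortumab vedotin,1.25,mmae,auc,16.0,16.8
enfortumab vedotin,1.0,mmae,cmax,2.58,2.72
enfortumab vedotin,1.0,mmae,auc,15.1,14.0
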