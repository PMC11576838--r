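# Midazolam 1 mg single IV dose with vs without enfortumab vedotin
# 1.25 mg/kg. Midazolam is given 72 h after the ADC infusion (near the
# MMAE maximum; documented trial-design assumption).
schema: study_config/1
label: ev-midazolam
compounds: {adc: enfortumab_vedotin, mmae: mmae, victim: midazolam}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.25, dose_cap_mg: 125,
        infusion_h: 0.5}
  victim: {route: iv_bolus, dose_mg: 1, offset_h: 72}
scenario: {type: ddi, victim_analyte: victim, end_h: 168, nca_start_h: 72}
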