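# Brentuximab vedotin 1.8 mg/kg with rifampin 600 mg oral QD
# (calibration/verification scenario mirroring the clinical DDI study).
schema: study_config/1
label: bv-rifampin
compounds: {adc: brentuximab_vedotin, mmae: mmae, perpetrator: rifampin}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.8, infusion_h: 0.5, offset_h: 168}
  perpetrator: {qd: {start_h: 0, n_days: 35, dose_mg: 600}}
scenario: {type: ddi, victim_analyte: mmae, end_h: 840, nca_start_h: 168}
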