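# Enfortumab vedotin 1.25 mg/kg with ketoconazole 400 mg oral QD.
# Ketoconazole starts 3 days before the ADC dose (steady state before the
# victim dose; exact lead-in is a documented trial-design assumption) and
# continues through the MMAE washout.
schema: study_config/1
label: ev-ketoconazole
compounds: {adc: enfortumab_vedotin, mmae: mmae, perpetrator: ketoconazole}
population: {source: cancer, master_seed: 20230101}
regimens:
  adc: {route: iv_infusion, dose_mg_kg: 1.25, dose_cap_mg: 125,
        infusion_h: 0.5, offset_h: 72}
  perpetrator: {qd: {start_h: 0, n_days: 31, dose_mg: 400}}
scenario: {type: ddi, victim_analyte: mmae, end_h: 744, nca_start_h: 72}
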