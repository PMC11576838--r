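# Brentuximab vedotin: anti-CD30 IgG with the same valine-citrulline-MMAE
# linker/payload. Used as the clinically verified baseline for the DDI
# engine (its ketoconazole/rifampin/midazolam interaction study is the
# calibration anchor). The DAR distribution below is a SYNTHETIC stand-in:
# the classic cysteine-conjugation profile (even DAR species, mean 4),
# since the lot-level distribution is not public. Antibody elimination
# (FcRn affinity) reflects its longer half-life (~4-6 days) than
# enfortumab vedotin; linker-dependent rates are shared.
schema: adc_compound/1
name: brentuximab vedotin
mw_adc_da: 153000
max_dar: 8
dar_fractions: [0.05, 0.0, 0.25, 0.0, 0.35, 0.0, 0.25, 0.0, 0.10]
kd_fcrn_um: 2.0
k_up_per_h: 0.0298
k_rc1_per_h: 0.548
cl_cat_l_h: 0.0175
cl_add_slope_l_h_per_dar: 0.021
k_dec_plasma_per_h: 0.001
k_dec_tissue_per_h: 0.001
f_rel_deconj: 1.0
f_rel_cat: 1.0
k_rel_cat_per_h: 1.0
notes: >
  Synthetic DAR distribution (documented stand-in, mean DAR 4.0).
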