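# Enfortumab vedotin: anti-Nectin-4 IgG conjugated to MMAE via a
# valine-citrulline cleavable linker. DAR distribution and antibody mass per
# the sponsor's IND characterisation; FcRn affinity optimised to the
# clinical conjugated-antibody elimination profile; uptake/recycle/catabolism
# defaults from minimal-PBPK large-molecule practice.
schema: adc_compound/1
name: enfortumab vedotin
mw_adc_da: 146664.1
max_dar: 8
dar_fractions: [0.063, 0.004, 0.289, 0.008, 0.389, 0.019, 0.170, 0.006, 0.052]
kd_fcrn_um: 7.28
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
  Mean DAR of the distribution is 3.735. Additional systemic clearance is
  0.021 L/h per DAR unit (zero for unconjugated antibody). Deconjugation
  releases exactly one payload per event (DAR j -> j-1).
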