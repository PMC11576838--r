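# Monomethyl auristatin E (MMAE): microtubule-disrupting payload released
# from vedotin ADCs. CYP3A4 substrate and weak reversible CYP3A4 and P-gp
# inhibitor; hepatic elimination split between P-gp-mediated biliary efflux
# and CYP3A4 metabolism, anchored retrograde to the apparent systemic
# clearance (2.72 L/h, 70% of hepatic clearance biliary, remainder 100%
# CYP3A4, renal clearance 0.8 L/h).
schema: small_molecule_compound/1
name: MMAE
mw_da: 717.98
ionization_class: monoprotic base
log_p: 2.6
pka: 8.08
bp_ratio: 1.45
fu_plasma: 0.178
kp_scalar: 0.3
vss_reference_l_kg: 3.03
clint_cyp3a4_ul_min_pmol: 0.00597
cl_r_l_h: 0.8
clint_pgp_ul_min_10e6cells: 1.58
cl_pd_ml_min_10e6cells: 0.2
cl_iv_reference_l_h: 2.72
f_bile: 0.70
ki_cyp3a4_rev_um: 5.0
kapp_um: 1.128
kinact_per_h: 6.0
ki_pgp_um: 16.8
notes: >
  Tissue partitioning by the mechanistic monoprotic-base method with a
  global Kp scalar of 0.3 matching Vss 3.03 L/kg.
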