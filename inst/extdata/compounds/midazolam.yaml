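# Midazolam: sensitive CYP3A4 probe substrate (fraction metabolised by
# CYP3A4 ~0.94). Reduced two-compartment disposition with well-stirred
# hepatic CYP3A4 clearance; literature defaults (CL ~25 L/h, Vss ~80 L,
# fu 0.032, B/P 0.66). Dosed 1 mg IV in DDI scenarios.
schema: victim_compound/1
name: midazolam
mw_da: 325.77
ka_per_h: 2.0
v1_l: 35.0
v2_l: 45.0
q12_l_h: 25.0
fu_plasma: 0.032
bp_ratio: 0.66
clint_cyp3a4_u_l_h: 1260.0
cl_r_l_h: 1.5
cl_pgp_l_h: 0.0
f_oral: 1.0
fg_pgp_gain: 0.0
pgp_raf_fold: 1.0
notes: >
  clint chosen so the reference well-stirred hepatic clearance is ~24 L/h,
  i.e. fraction metabolised by CYP3A4 ~0.94 of total clearance.
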