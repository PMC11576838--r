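# Digoxin: narrow-therapeutic-index P-gp probe substrate. Negligible CYP
# metabolism; elimination split between glomerular filtration (non-P-gp
# renal) and a P-gp-mediated secretory/biliary pathway that interaction
# modifiers act on. Intestinal P-gp limits oral bioavailability (F ~0.7);
# inhibition of gut P-gp raises F through fg_pgp_gain. Literature defaults
# (CL ~12 L/h, Vss ~440 L, fu 0.71). Dosed 0.5 mg oral in DDI scenarios.
schema: victim_compound/1
name: digoxin
mw_da: 780.94
ka_per_h: 1.0
v1_l: 40.0
v2_l: 400.0
q12_l_h: 12.0
fu_plasma: 0.71
bp_ratio: 1.0
clint_cyp3a4_u_l_h: 0.0
cl_r_l_h: 7.0
cl_pgp_l_h: 5.0
f_oral: 0.7
fg_pgp_gain: 0.35
pgp_raf_fold: 1.0
notes: >
  cl_pgp lumps renal tubular secretion and biliary efflux (the
  transporter-mediated, inhibitable share of total clearance).
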