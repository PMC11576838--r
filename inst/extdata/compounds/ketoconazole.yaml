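# Ketoconazole: combined strong reversible CYP3A4 inhibitor and P-gp
# inhibitor. Base PK is a one-compartment first-order-absorption model with
# parameters from the published 400 mg multiple-dose literature (fu 0.029,
# unbound CYP3A4 Ki 0.015 uM are the widely used PBPK consensus values);
# the P-gp inhibition constant (0.67 uM) is the transporter-study value
# added to the interaction block. CL/V were fine-tuned once against the
# clinically verified MMAE interaction of the reference ADC (see
# analysis/02_calibration.R).
schema: perpetrator_compound/1
name: ketoconazole
mw_da: 531.43
model: one_compartment
ka_per_h: 0.8
v1_l: 34.0
v2_l: 0.0
q12_l_h: 0.0
cl_l_h: 4.2
fu_plasma: 0.029
f_oral: 1.0
ki_cyp3a4_um: 0.015
kapp_um: 0.0
kinact_per_h: 0.0
ind_max: 0.0
ind_c50_um: 1.0
ki_pgp_um: 0.67
pgp_raf_fold: 1.0
notes: 400 mg oral once daily in DDI scenarios.
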