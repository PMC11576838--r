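# Rifampin: combined CYP3A4 inducer (enzyme-turnover induction) and P-gp
# inducer/inhibitor. Base PK one-compartment oral (600 mg QD literature
# values); reversible P-gp Ki 4.3 uM added to the interaction block.
# Transporter induction is implemented manually as a static relative
# activity factor (pgp_raf_fold) applied to the victim's P-gp intrinsic
# clearance in the with-rifampin arm; the fold and the hepatic induction
# Emax are calibrated defaults (fine-tuned once against the clinically
# verified MMAE interaction of the reference ADC, see
# analysis/02_calibration.R) - they are not experimentally measured values.
schema: perpetrator_compound/1
name: rifampin
mw_da: 822.94
model: one_compartment
ka_per_h: 1.0
v1_l: 53.0
v2_l: 0.0
q12_l_h: 0.0
cl_l_h: 12.0
fu_plasma: 0.15
f_oral: 1.0
ki_cyp3a4_um: 0.0
kapp_um: 0.0
kinact_per_h: 0.0
ind_max: 8.0
ind_c50_um: 0.32
ki_pgp_um: 4.3
pgp_raf_fold: 2.2
notes: 600 mg oral once daily in DDI scenarios.
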