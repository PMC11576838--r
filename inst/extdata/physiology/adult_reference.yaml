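# Reference adult physiology for the whole-body PBPK model.
# All values are open-literature defaults:
#   organ volumes/flows: ICRP Publication 89 reference adult, as tabulated in
#     Davies & Morris (1993) and Jones & Rowland-Yeo (2013, CPT:PSP tutorial)
#   MPPGL 40 mg/g: Barter et al. (2007)
#   hepatocellularity 120e6 cells/g: Sohlenius-Sternbeck (2006)
#   hepatic CYP3A4 abundance 137 pmol/mg: Rowland-Yeo meta-analysis values
#   CYP3A4 degradation rate 0.0193 1/h (t1/2 ~36 h): Yang et al. (2008)
#   minimal-PBPK plasma volume and endosomal parameters: large-molecule
#     minimal PBPK literature; endosomal volume and FcRn concentration are
#     calibrated so the reference subject reproduces the conjugated-antibody
#     terminal half-life (see package vignette).
schema: physiology_set/1
body_weight_kg: 70
hematocrit: 0.45
plasma_albumin_g_l: 43
plasma_volume_l_kg: 0.050
endosomal_volume_l: 0.04
fcrn_um: 14.0
liver_weight_g: 1800
mppgl_mg_g: 40
hepatocellularity_10e6_g: 120
cyp3a4_abundance_pmol_mg: 137
cyp3a4_kdeg_per_h: 0.0193
volumes_l:
  lung: 0.53
  adipose: 14.0
  bone: 10.0
  brain: 1.45
  gut: 1.65
  heart: 0.33
  kidney: 0.31
  liver: 1.69
  muscle: 29.0
  skin: 3.4
  spleen: 0.19
  pancreas: 0.14
  venous_blood: 3.4
  arterial_blood: 1.8
flows_l_h:
  adipose: 19.5
  bone: 19.5
  brain: 46.8
  gut: 50.0
  heart: 15.6
  kidney: 74.1
  muscle: 66.3
  skin: 19.5
  spleen: 11.7
  pancreas: 3.9
  hepatic_artery: 25.4
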