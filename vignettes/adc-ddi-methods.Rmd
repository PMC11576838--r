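---
title: "Methods: a DAR-stratified PBPK model for MMAE ADC drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a DAR-stratified PBPK model for MMAE ADC drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the model equations
and their assumptions, the parameters that matter, the calibrated defaults
and why they were chosen, the numerical machinery, and what the shipped
tests do and do not demonstrate about real data.

## The problem

Enfortumab vedotin is an antibody-drug conjugate (ADC): an anti-Nectin-4
IgG carrying, on average, 3.7 molecules of the cytotoxic payload
monomethyl auristatin E (MMAE) on a protease-cleavable linker. Circulating
ADC is a mixture of drug-to-antibody-ratio (DAR) species 0-8. Free MMAE is
a CYP3A4 substrate and a P-glycoprotein (P-gp) substrate, so co-medication
with CYP3A4/P-gp inhibitors (ketoconazole) or inducers (rifampin) can move
MMAE exposure, and MMAE itself could perturb CYP3A4 (midazolam) or P-gp
(digoxin) probe substrates. No dedicated clinical DDI study exists for
enfortumab vedotin; the package reproduces, as open code, the
simulation-based interaction assessment: a large-molecule model of the
conjugated antibody feeding a whole-body small-molecule model of MMAE,
coupled to a DDI engine and virtual-trial statistics.

## Antibody model (DAR-stratified minimal PBPK)

Each DAR species $j \in 0..8$ has a plasma amount $A_{p,j}$ and an
endosomal amount $A_{e,j}$ (nmol antibody). With infusion input
$\mathrm{In}_j(t)$ split by the DAR distribution:

$$\frac{dA_{p,j}}{dt} = \mathrm{In}_j(t) - k_{up}A_{p,j}
  + k_{rc1}\,f_b\,A_{e,j} - \frac{CL_{add}\,j}{V_p}A_{p,j}
  - k_{dec}^{p}A_{p,j} + k_{dec}^{p}A_{p,j+1}$$

$$\frac{dA_{e,j}}{dt} = k_{up}A_{p,j} - k_{rc1}\,f_b\,A_{e,j}
  - \frac{CL_{cat}}{V_e}(1-f_b)A_{e,j}
  - k_{dec}^{t}A_{e,j} + k_{dec}^{t}A_{e,j+1}$$

FcRn binding is treated as quasi-equilibrium 1:1 binding to a shared
receptor pool (only a dissociation constant is available, no on/off
rates): the free receptor concentration solves
$R + A_{tot}R/(K_D + R) = R_{tot}$ and the bound (recycled, protected)
fraction $f_b = R/(K_D+R)$ is common to all DAR species. Deconjugation is
a single-step cascade $j \to j-1$ releasing exactly one payload per event;
catabolism and the DAR-proportional "additional" clearance destroy the
antibody and release $j$ payloads. All released payload passes through a
catabolite depot emptying at $k_{rel}$ into venous blood of the
small-molecule model. A payload ledger (conjugated + depot + released +
eliminated-without-release) is conserved to the integrator tolerance and
is tested at 1e-6 relative.

Key antibody parameters (units, defaults for enfortumab vedotin): DAR
fractions (mean 3.735), $K_D$ 7.28 uM at pH 6.0, $k_{up}$ 0.0298 1/h,
$k_{rc1}$ 0.548 1/h, $CL_{cat}$ 0.0175 L/h, $CL_{add}$ 0.021 L/h per DAR
unit, $k_{dec}$ 0.001 1/h, release fractions 1, $k_{rel}$ 1 1/h. The
uptake constant acts on an amount basis (1/h units as printed); whether
the upstream implementation used an amount or concentration basis is not
documented, and this choice is absorbed by the endosome calibration below.
The deconjugation rate is taken as DAR-independent per antibody molecule
(its "(DAR 1)" annotation is read as the parameterising species, not a
scaling rule). Lymphatic clearance is zero, so no lymph compartment is
implemented.

**Calibrated defaults.** The endosomal FcRn concentration, endosomal
volume and minimal-model plasma volume are not published. They were fixed
once so the reference subject reproduces the reported simulated
conjugated-antibody terminal half-life (~1.94 d) with the printed $K_D$:
FcRn 14 uM, endosomal volume 0.04 L per 70 kg, plasma (central) volume
0.050 L/kg x the population plasma scaling factor. These are within the
ranges used by published minimal-PBPK antibody models; the central volume
sits slightly above anatomical plasma because it absorbs the fast
early-distribution space the two-compartment architecture lacks (see
Limitations).

## Payload model (whole-body PBPK for MMAE)

Perfusion-limited tissues (adipose, bone, brain, gut, heart, kidney,
muscle, skin, spleen, pancreas, lung in series) with tissue:plasma
partition coefficients from the mechanistic tissue-composition method for
a monoprotic base (ionisation at intracellular pH, neutral lipid and
phospholipid partitioning, acidic-phospholipid association calibrated from
the blood-to-plasma ratio), each multiplied by the global Kp scalar 0.3.
With the shipped composition tables this Kp set yields Vss 3.07 L/kg
against the reference 3.03 L/kg.

The liver is permeability-limited - a deliberate worst case for
transporter-limited biliary excretion: an extracellular (plasma-like)
space exchanges with an intracellular space through the passive-diffusion
clearance (both directions, unbound), and intracellular unbound drug is
eliminated by CYP3A4 metabolism and P-gp canalicular efflux. The
whole-liver intrinsic clearances are anchored retrograde: hepatic plasma
clearance = apparent systemic clearance 2.72 L/h minus renal 0.8 L/h,
inverted through the well-stirred relation and split 70% biliary (P-gp) /
30% metabolic (100% CYP3A4). The biliary share is interpreted as a
fraction of *hepatic* (non-renal) clearance; the alternative reading
(fraction of total) would leave an implausibly small CYP3A4 contribution,
contradicting the ketoconazole interaction. The fraction is configurable
(`f_bile`) and is the subject of the sensitivity analysis. The printed
bottom-up per-unit CYP3A4 clearance (0.00597 uL/min/pmol), scaled with
abundance 137 pmol/mg, MPPGL 40 mg/g and liver weight, agrees with the
retrograde value to ~8%, which supports the anchoring. Clearance is
anchored per subject (the reference systemic clearance at each subject's
physiology); between-subject clearance variability enters only through
the CYP3A4/P-gp activity multipliers.

## DDI engine

Interaction terms act multiplicatively on intrinsic clearances:

* competitive inhibition: $1/(1 + I_u/K_i)$, with the unbound hepatic
  inlet concentration driving hepatic terms and systemic unbound driving
  renal/intestinal terms;
* mechanism-based inactivation and induction share one hepatic CYP3A4
  turnover pool: $dE/dt = k_{deg}(1 + E_{max} I_u/(EC_{50}+I_u))
  - k_{deg}E - \frac{k_{inact}I_u}{K_{app}+I_u}E$ with $k_{deg}$
  0.0193 1/h;
* P-gp induction is implemented manually as a static relative activity
  factor (RAF) fold on the victim's P-gp clearance in the
  with-perpetrator arm only (the baseline arm always uses fold 1).

MMAE carries both a mechanism-based CYP3A4 term (kinact 6.0 1/h, Kapp
1.128 uM) and a reversible constant (5 uM). Both are active by default
(switchable), since both are part of the compound characterisation and the
reversible term is numerically negligible at clinical MMAE concentrations;
MMAE auto-inactivation of its own metabolism is likewise on by default.
Ketoconazole carries reversible CYP3A4 (0.015 uM unbound) plus P-gp Ki
0.67 uM; rifampin carries turnover induction plus P-gp Ki 4.3 uM; MMAE
inhibits P-gp at 16.8 uM.

**Calibrated defaults.** Ketoconazole and rifampin base PK and the
rifampin induction/RAF magnitudes are not published in the source
parameter tables. Literature one-compartment models are shipped and were
fine-tuned *once* against the clinically verified reference-ADC
(brentuximab vedotin) interaction results - ketoconazole clearance 4.2 L/h
(within its published 400 mg multiple-dose range, where kinetics are
nonlinear); rifampin hepatic induction Emax 8 (EC50 0.32 uM unbound) and
P-gp RAF fold 2.2. The RAF fold is a calibrated engineering constant, not
a measurement. `analysis/02_calibration.R` re-runs the anchors and shows
the agreement; no further tuning happens anywhere.

Victim probes are reduced two-compartment models: midazolam with
well-stirred hepatic CYP3A4 clearance (fraction metabolised ~0.94) dosed
1 mg IV, digoxin with a P-gp pathway clearance (renal secretion + biliary,
inhibitable) and an intestinal P-gp bioavailability term, dosed 0.5 mg
orally. Trial-design details that are not published are encoded as
documented assumptions in the shipped configs: perpetrators reach steady
state before the ADC dose (3-day ketoconazole, 7-day rifampin lead-in);
probes are given 72 h after the ADC infusion, near the MMAE maximum.

## Virtual population and trial statistics

10 trials x 10 subjects. Demographics emulate the phase-1 cancer
population qualitatively (age ~67 +/- 9 y bounded 35-88, weight lognormal
GM 76 kg CV 20% bounded 45-130 - so the 125 mg cap binds for the ~10%
of subjects above 100 kg - albumin 40 +/- 4.5 g/L, hematocrit 0.38 +/-
0.04, 27% female); the supplementary demographics table was not available,
so only the structure, not the numbers, is reproduced. The cancer
modification sets the plasma tissue-volume scaling factor to 1.0 (from the
1.2 oncology default), raising conjugated-antibody Cmax; a healthy
population (scaling 1.2, younger) is used for digoxin. Between-subject
variability enters through body weight, a plasma-volume multiplier
(CV 15%) and lognormal CYP3A4 (CV 40%) and hepatic P-gp (CV 45%) activity
multipliers. The P-gp multiplier is one term beyond the minimal set
(weight, plasma volume, CYP3A4); without it the payload's dominant
clearance pathway had no variability at all. Even so the simulated MMAE
exposure CV% (~15-25%) undershoots the reported 40-50% - residual error
and unmodelled release variability dominate clinically - which is why the
paired GMR design, not absolute CV%, carries the interaction conclusions.
Subject draws come from per-(trial, subject) seeds, so changing one
subject never perturbs another.

NCA uses Cmax/Tmax by maximum, linear-up/log-down trapezoids (pure linear
by flag), terminal slope by best adjusted-R^2 log-linear regression over
all windows of >= 3 points strictly after Tmax, AUC extrapolation by
$C_{last}/\lambda_z$, and partial AUCs interpolated at exactly 168 h and
336 h. GMRs pair each subject with itself across arms; the 90% CI uses the
t-distribution over the 10 trial-level mean log-ratios (9 df) - the CI
convention across trials rather than across all subjects is a
documented choice, as the source convention is not stated.

## Synthetic observed data

`generate_observed()` emulates phase-1-style sparse sampling (0.5, 1, 2,
6 h, then daily to day 7) with multiplicative lognormal residual error and
LLOQ flagging; `overlay_check()` reports percentile-band coverage and
predicted/observed (P/O) GM ratios. The generator reproduces sampling
noise and censoring only - it does not emulate dropout, dosing-history
errors, assay bias, or the release-process variability mentioned above, so
overlay tests demonstrate self-consistency of the workflow, not clinical
validity. Reported clinical GMs ship as plain-CSV fixtures (sources cited
in the file headers) and anchor the P/O verification.

## Numerical choices

Stiff integration (`deSolve::lsoda`, compiled C right-hand side) at
rtol 1e-8 / atol 1e-9 nmol; the rate constants span four orders of
magnitude and the passive-diffusion liver exchange is fast, so a stiff
solver is required. The timeline is integrated piecewise between dose
events - infusions are constant rates within a segment, oral/IV doses are
state increments at segment starts - so the solver never steps across a
discontinuity, and a zero-dose arm is bit-identical to a no-dose arm (the
paired-design identity test relies on this). Output grids are tiered:
0.05 h through infusions and after probe doses, 0.25 h to 24 h post-dose,
1 h elsewhere, always containing the day-7/day-14 marks; a uniform 0.1 h
grid over 35 days added nothing but post-processing weight (the
NCA-vs-cumulative-integral agreement is tested at 0.5%). Degenerate
inputs fall to boundary values (zero receptor -> bound fraction 0; Ki = 0
is rejected; non-estimable terminal slopes flag AUCinf as missing rather
than guessing).

Problem sizes: all shipped analyses and tests use the 10x10 design (100
subjects, paired where applicable) or the single representative subject
for property checks and sensitivity runs; the population-moment test uses
2 000 sampled subjects without simulation.

## Known limitations

* **No interstitial compartment.** The two-pool antibody model lacks the
  fast plasma-to-interstitial distribution phase of a full minimal-PBPK
  mAb model. The calibration therefore trades a slightly depressed Cmax
  (-7%) and elevated AUC (+8%) around the correct terminal half-life, and
  MMAE absolute exposures run ~20% high. Interaction ratios are paired
  within subject and are insensitive to this (the shipped anchors agree to
  a few percent).
* **No target-mediated disposition.** Nectin-4 binding, tumour uptake and
  tumour MMAE exposure are out of scope.
* **Quasi-equilibrium FcRn binding** leaves a ~1% saturation footprint on
  dose-doubling at clinical doses; the strict linearity tests disable the
  (physically real) MMAE auto-inactivation feedback.
* **Victim models are reduced**, not whole-body; they are adequate for
  exposure-ratio endpoints only.
* The rifampin P-gp RAF fold and induction Emax are calibrated constants;
  conclusions about rifampin rest on the reference-ADC verification, not
  on independent measurement.
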