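---
title: "Methods: whole-body PBPK/PD modeling of osimertinib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK/PD modeling of osimertinib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osipbpk)
```

## Scope

`osipbpk` implements a whole-body physiologically based pharmacokinetic
(PBPK) model of osimertinib, a third-generation covalent EGFR tyrosine kinase
inhibitor used in EGFR-mutant non-small-cell lung cancer (NSCLC), coupled to
an irreversible target-occupancy pharmacodynamic (PD) model of the pulmonary
T790M and L858R mutant receptors. The package builds reference physiologies
for Caucasian, Japanese and Chinese healthy and NSCLC populations, samples
seeded virtual populations with log-normal inter-subject variability,
computes non-compartmental metrics and geometric summaries, runs local
sensitivity analyses, and evaluates dosing regimens against a plasma trough
window (328--677 nmol/L) and a pulmonary inhibition floor (80%).

## PK model structure

The PBPK model is a perfusion-limited, whole-body compartment system:
stomach and gut lumen (absorption), gut tissue, liver, lung, kidney, adipose,
muscle, skin, a lumped rest-of-body compartment, and arterial and venous
blood. Amounts are in nmol, time in hours, concentrations in nmol/L. Oral
doses are converted with the molecular weight (499.6 g/mol; 80 mg is
160128 nmol).

A perfusion-limited organ obeys

$$V_t \frac{dC_t}{dt} = Q_t \left(C_{art} - \frac{C_t\,R_{bp}}{K_{p,t}}\right),$$

with $Q_t$ the regional blood flow, $C_{art}$ arterial blood concentration,
$K_{p,t}$ the tissue:plasma partition coefficient and $R_{bp}$ the
blood:plasma ratio. Venous blood collects all organ outflows; the lung sits
in series between the venous and arterial pools and carries the whole cardiac
output. Regional flows and organ volumes are embedded constants for a ~70-kg
reference human (standard reference-tables compilation) and sum exactly to
cardiac output; they are argument-overridable. A perfusion-limited (rather
than permeability-limited) formulation was chosen because the
parameterization specifies only partition coefficients and a global partition
scale, not permeability-surface-area products.

### Absorption

The stomach empties first-order with half-life equal to the gastric emptying
time (GET; 15 min healthy, 120 min in NSCLC patients, where gastric emptying
is delayed). The gut lumen feeds gut tissue first-order with

$$k_a = \frac{2\,P_{eff}\,SEF}{r}, \qquad r = 1.25\ \mathrm{cm},\ SEF = 3.4,$$

where $P_{eff}$ = 0.187e-4 cm/s and $SEF$ is a plicae-circulares surface
enhancement factor; this gives $k_a \approx 0.37\ h^{-1}$ and an absorption
phase with time-to-peak around 5--9 h, consistent with clinical osimertinib.
Luminal degradation and solubility limitation are neglected (complete
absorption, $f_a = 1$): aqueous solubility (3.1 mg/mL) far exceeds the dose
dissolved in a glass of water. Oral bioavailability is therefore an emergent
property of gut-liver first pass, not a fitted input. Mechanistic
multi-segment gut models are out of scope.

### Tissue partitioning

Non-lung partition coefficients are Rodgers--Rowland mechanistic predictions
for a moderate-to-strong diprotic base (pKa 9.5, 4.4; logP 5.45):
intracellular pH trapping of the cation, electrostatic association with
acidic phospholipids (association constant derived from blood-cell
partitioning of unbound drug), and neutral lipid/phospholipid partitioning of
the neutral species, all multiplied by the fraction unbound and then by a
global scale factor of 1.5 (a literature calibration for tissue
distribution). The lung coefficient is overridden by the experimental value
$K_{lu,p} = 28.5$; the mechanistic prediction here is about 12.7, in line
with the commonly quoted mechanistic estimate of 14.3, and the override
matters for lung (hence PD) exposure while leaving plasma PK nearly unchanged
-- halving the lung coefficient roughly halves lung exposure at <10% plasma
change, which the test suite checks.

**Design choice: subject-invariant partitioning.** The partition set is
built once from the compound's healthy reference binding (fup 0.013,
Rbp 1.0, Hct 0.47) and is not rebuilt per subject when albumin sampling or
disease translation moves the subject's fraction unbound. Inter-individual
binding differences therefore act on clearance, not on the volume of
distribution. This keeps the partition set a compound-level constant
(matching its constructor signature) and reflects that the tissue-composition
terms, not plasma binding, dominate the mechanistic prediction for a compound
this lipophilic.

### Hepatic clearance and the CYP3A4 auto-effects

Six enzymes metabolize osimertinib (CYP1A2, 2A6, 2C9, 2E1, 3A4, 3A5).
Unbound intrinsic clearances (uL/min/pmol) times hepatic enzyme
concentrations (umol/L liver tissue, i.e. pmol/uL) give per-enzyme rate
constants in 1/min; multiplied by liver volume and 60 they become L/h of
unbound plasma-equivalent clearance. The metabolic rate is

$$v = \left(\sum_e CL_{int,u}^{(e)}\,[E_e]\,V_{liver} \cdot 60\right) C_{u,liver},
\qquad C_{u,liver} = f_{up}\,\frac{C_{liver}}{K_{p,liver}}.$$

The fraction metabolized by CYP3A4 at baseline healthy levels is ~0.44,
close to the commonly quoted ~0.48.

Osimertinib competitively inhibits CYP3A4/5 ($K_i$ 2.55 uM) and induces
CYP3A4 ($E_{max}$ 10.8, $EC_{50}$ 0.12 uM). Both are driven by the unbound
liver concentration ($K_i$ and $EC_{50}$ are in-vitro unbound-like
quantities). Inhibition divides the CYP3A4 and CYP3A5 terms by
$1 + C_u/K_i$; induction follows an indirect-response enzyme ODE

$$\frac{dE}{dt} = k_{deg}\left(1 + \frac{E_{max} C_u}{EC_{50} + C_u}\right) - k_{deg} E,$$

applied to CYP3A4 only, with $k_{deg} = 0.0158\ h^{-1}$ (canonical hepatic
CYP3A4 turnover half-life of ~44 h; an external literature constant,
argument-overridable). At therapeutic exposures the unbound liver
concentration is a few nmol/L -- three orders of magnitude below $K_i$ but
comparable to $EC_{50}$ -- so **auto-induction dominates auto-inhibition** in
this implementation: multiple dosing raises the CYP3A4 level to ~1.6x
baseline and the model is mildly sub-proportional in dose. See Limitations.

Renal clearance is filtration only: $CL_R = GFR \times f_{up}$ with GFR
120 mL/min and filtration fraction 1.0 for healthy subjects and patients
alike (transporter involvement is not established for this compound).

### Disease and ethnic translation

NSCLC patients differ from healthy subjects by: albumin 0.31 vs 0.45 g/dL
(carried on the printed g/dL scale; only the ratio enters the equations),
hematocrit 0.33 vs 0.47, gastric emptying 120 vs 15 min, and downregulated
hepatic enzyme concentrations (CYP1A2 by 26%, CYP2A6/2E1/3A5 to 0.7x, and
measured patient values for CYP2C9 and CYP3A4). The patient fraction unbound
follows from linear albumin binding with a fixed association constant,

$$f_{up,pat} = \frac{1}{1 + \dfrac{(1-f_{up,h})\,P_{pat}}{P_h\,f_{up,h}}} = 0.019,$$

and the patient blood:plasma ratio from the blood-cell affinity
$K_{puBC} = (Hct - 1 + R_{bp})/(Hct \cdot f_{up})$ evaluated on healthy
values (76.9) and held fixed: $R_{bp} = 1 + Hct(f_{up} K_{puBC} - 1) = 1.15$
(prints as 1.1). The linearized form was chosen as the only reading whose
healthy round trip returns exactly 1.0.

Ethnicity enters through liver volume (Caucasian 2.38 L, Japanese 1.91 L,
Chinese 2.16 L -- the tabulated assignment; the alternative Japanese/Chinese
swap found in some sources is available by overriding `liver_volumes`) and
through enzyme abundance ratios: the concentration of each enzyme is scaled
by abundance(ethnicity)/abundance(Caucasian). Abundances themselves
(pmol/mg protein) never enter absolutely -- the concentration and abundance
scales are dimensionally incompatible, so only ratios are meaningful.
Patient hematocrit 0.33 is applied to all three ethnicities. No other
anthropometrics differ across ethnicities.

## The virtual-population generator

The generator is the package's synthetic-data module: it emulates the
population conditions of the underlying study design. Variability is
log-normal with geometric mean equal to the reference value and
$\sigma^2 = \ln(1 + CV^2)$, applied to albumin (default CV 20% Caucasian,
30% Japanese/Chinese), optionally to the fraction unbound, and to per-enzyme
intrinsic-clearance multipliers. Albumin draws propagate to the fraction
unbound and blood:plasma ratio through the binding equations. Sampling is
seed-deterministic (identical seed, bit-identical population).

Anthropometric variability (body weight, organ volumes, flows) is
deliberately **not** sampled: the study design attributes the observed PK
dispersion to binding and enzyme factors, and adding unstated variability
sources would confound the attribution analyses. Consequently passing tests
demonstrate correct propagation of the three modeled variability channels,
not a full demographic population model; real cohorts carry additional
size-, age- and organ-function-related dispersion that this generator does
not emulate. Demographic fields on the population specification (age range,
proportion female) are reporting metadata only.

## PD: irreversible pulmonary target occupancy

The free lung concentration, taken as
$C_{lung,free} = f_{up} \times C_{lung,tissue}$, drives

$$\frac{dOEm}{dt} = k_{on} C_{lung} Em_{free} - k_{off}\,OEm - [k_{turn}\,OEm],$$
$$\frac{dEm_{free}}{dt} = (Em_0 - Em_{free})\,k_{turn} - k_{on} C_{lung} Em_{free} + k_{off}\,OEm,$$
$$\mathrm{Inhibition\%} = 100\,\frac{OEm}{Em_{free} + OEm},$$

with $k_{on}$ 0.91 (T790M) and 0.44 (L858R) uM$^{-1}$s$^{-1}$ (converted to
1/h internally), $k_{off} = 0$ (covalent), $k_{turn} = 0.025\ h^{-1}$ and
$Em_0 = 0.299$ uM. Coupling is one-way: receptor binding does not deplete
drug (receptor abundance is negligible against tissue drug amounts).

Two declared choices:

* **Free-lung convention.** Binding is driven by the unbound fraction of
  total lung tissue concentration rather than by unbound plasma. Only this
  convention lets the experimental lung partition coefficient influence the
  PD readout, which is the stated purpose of carrying it. The
  unbound-plasma-equivalent alternative can be obtained by feeding
  `simulate_occupancy()` a custom profile.
* **Complex degradation.** With the literal equations and $k_{off} = 0$ the
  complex only accumulates, so inhibition could never relax between doses
  and any dosing regimen would eventually approach 100% inhibition. By
  default the complex is therefore cleared at the receptor turnover rate
  (`complex_degradation = TRUE`), which conserves the total receptor pool
  and yields the fluctuating inhibition time-course expected of a
  turnover-limited covalent system; the accumulate-only literal form is
  available as a switch. The inhibition percentage is scale-free in $Em_0$
  under one-way coupling, so the ambiguity of the reference volume behind
  0.299 uM is immaterial.

At steady state under constant drug the closed form is
$k_{on}C/(k_{turn} + k_{on}C)$; the adaptive integrator is verified against
this and against a fixed-step Euler oracle at $10^{-4}$ h in the test suite.

## Metrics and summaries

AUC is trapezoidal on the dense solver grid (at least 10 output points per
hour by default; metrics change by well under 1% on refinement). The trough
is the concentration at the window end, i.e. the pre-dose concentration of
the final interval; steady state is asserted at day 14 of once-daily dosing.
Apparent clearance is dose/AUC over the final dosing interval at steady
state, or dose/AUC(0--inf) with a log-linear terminal tail (fitted over the
final three estimated half-lives) for single doses. Population summaries are
geometric: mean $\exp(\overline{\ln x})$, percent CV
$100\sqrt{e^{\mathrm{var}(\ln x)}-1}$, and a t-interval on the log scale.
Interval summaries are reported as 95% confidence intervals of the geometric
mean; min--max ranges are available from the per-subject tables.

## Sensitivity analysis

`run_sensitivity()` perturbs one parameter at a time by +/-20% on the
deterministic reference patient at 80 mg once daily for 14 days and reports
the normalized coefficient $SC = (\Delta Y/Y)/(\Delta P/P)$ for steady-state
AUC, peak and trough, as the mean of the two one-sided coefficients (the
combination rule is a package choice; both sides are available with
`verbose = TRUE`). The albumin perturbation is propagated to the fraction
unbound and the blood:plasma ratio through the binding equations -- without
that propagation albumin would have no pathway into the model. Perturbing an
enzyme's intrinsic clearance or its concentration gives identical
coefficients (they enter multiplicatively), a symmetry the tests assert. The
reference Caucasian patient is used because the individual behind the
published coefficient table is not identified.

## Scenario layer

`evaluate_regimen()` scores candidate regimens (defaults 20/40/80/160/240 mg
once daily for 14 days) on the geometric mean trough against the
328--677 nmol/L window and on minimal steady-state pulmonary inhibition
against the 80% floor. The efficacy bound is fixed at 328 nmol/L (the
commonly cited exposure-response cut); it is configurable. `factor_sweep()`
sweeps CYP3A4 intrinsic-clearance multipliers (enzyme variants are
user-supplied multipliers; only the wild-type 1.0 is built in), CYP1A2
intrinsic clearance (documented range 0.52--5.2 uL/min/pmol), the fraction
unbound (0.009--0.034), albumin (1.1--6.1 on the printed g/dL scale) and the
auto-effect on/off toggle; out-of-range values warn rather than error.
`variability_attribution()` varies one factor at a time and reports the
output percent CV of steady-state AUC and trough per input CV, on a default
grid of {0, 10, 20, 30, 40, 50}%. `compare_clf()` contrasts apparent
clearance between groups after single or multiple dosing.

## Numerical choices

* Stiff solver (`lsoda`) with relative tolerance 1e-8 and absolute tolerance
  1e-6 nmol; a 10x tightening changes steady-state AUC by <0.1% (tested).
  The right-hand side is compiled C; one 14-day simulation takes ~40 ms.
* Doses are instantaneous additions to the stomach (or venous blood for the
  analytic IV variant) via solver events aligned to the output grid.
* Occupancy integration interpolates the lung profile linearly and is run
  per mutant; initial state is the drug-free steady state.
* Degenerate inputs: zero dose yields identically zero concentrations; zero
  CV populations collapse to the reference subject; occupancy with an
  all-zero profile reports 0% inhibition; both-zero occupancy states are a
  domain error for the inhibition ratio.
* Mass balance (gut residual + body amounts + cumulative metabolized +
  excreted = administered dose) holds to ~1e-13 relative and is checked on
  every simulation; the tested contract is 0.1%.
* Default problem sizes: 10 subjects per population simulation (the study
  convention), 1000 subjects for variability attribution, dense output at
  10 points/h (2 points/h for large population sweeps, where the metrics are
  grid-stable).

## Known limitations

* **Binding-direction behavior.** In any thermodynamically consistent model
  of linear plasma binding, raising albumin lowers the free fraction, lowers
  clearance (hepatic clearance here is proportional to $f_{up}$), and
  *raises* total exposure: the albumin sensitivity coefficient on exposure is
  positive (~+1.0 to +1.2 here) and the fup coefficient negative (~-1.0 to
  -1.2), linked by the chain rule $d\ln f_{up}/d\ln P = -(1-f_{up})$. Some
  published coefficient tables for this compound print *both* as negative
  with larger magnitudes (up to -2.1); those two signs are mutually
  inconsistent under the stated binding equation, and this package
  reproduces the mechanistically consistent pair. For the same reason the
  higher total exposure observed in patients cannot, in this model, be
  produced by their higher free fraction: the patient/healthy exposure ratio
  here is ~0.9 (enzyme downregulation raising exposure ~1.35x, offset by the
  1.44x higher patient free fraction), whereas clinical cohorts report ~2x.
  The enzyme-only residual (~1.3x when binding is equalized) is reproduced.
* **Dose proportionality.** With the unbound-liver driver, auto-inhibition
  is negligible and auto-induction dominates, making simulated exposure
  mildly sub-proportional in dose. Clinical trough data are
  supra-proportional at low doses; capturing that would require driving the
  competitive inhibition with near-total liver concentrations, a convention
  this package deliberately does not adopt. Predictions at the clinical
  80 mg dose are within the standard 2-fold validation band; low-dose
  (20 mg) troughs are overpredicted.
* **Variability attribution.** Because the albumin-to-exposure elasticity is
  ~1, a 20% albumin CV yields ~20-25% output CV here, not the ~50%
  obtainable only with the larger (inconsistent) printed elasticities.
* Concentration-dependent plasma binding, active renal transport, the two
  active metabolites, enterohepatic recirculation, food effects and
  drug-drug interaction perpetrators are not modeled. Demographic physiology
  scaling (age, sex, weight) is out of scope.
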