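---
title: "A reduced-order cardiorenal model and virtual-population calibration for CCB therapy in hypertensive CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order cardiorenal model and virtual-population calibration for CCB therapy in hypertensive CKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

`virtualckd` simulates an in-silico clinical trial of calcium channel
blockade (amlodipine, 10 mg/day) in African Americans with hypertensive
chronic kidney disease, emulating the CCB arm of the AASK trial.  It has
three layers:

1. a **reduced-order whole-body cardiorenal model** — long-term blood
   pressure set by sodium balance (Guyton's pressure natriuresis), a renal
   vascular network that resolves glomerular capillary pressure, the
   renin–angiotensin–aldosterone axis, ANP, tubuloglomerular feedback (TGF),
   left-ventricular remodeling, and a delayed pressure-threshold
   glomerulosclerosis law;
2. **pharmacology** — one-compartment oral amlodipine kinetics with
   Emax-type preglomerular and systemic vasodilation and a direct tubular
   natriuretic action, plus renin–angiotensin system (RAS) blockade as a
   fractional scaling of every angiotensin-II effect channel;
3. a **virtual-population calibration algorithm** — random multiplicative
   perturbation of all model parameters, nearest-neighbour selection against
   patient-level clinical data in four dimensions (MAP and GFR, before and
   after three years of CCB), and iterative re-perturbation until the
   selected population is statistically indistinguishable from the cohort
   (two-sided Mann–Whitney p > 0.05 in all four dimensions).

In-silico trials of this kind are usually run on whole-body physiology
models with thousands of equations, whose published claims nevertheless live
in a modest set of reported operating points and signed couplings.  This
package implements the *system* at reduced order: roughly a dozen state
variables and ~100 parameters chosen so that the normal and CKD operating
points, the treatment responses, and the virtual-population calibration
algorithm are all reproduced.

## The model, state by state

**Sodium and volume.**  Body sodium is the master slow state:
`dNa/dt = intake − UNaV`.  Serum osmolarity is clamped (thirst follows
sodium), so extracellular volume is `ECFV = Na / 140 mEq/L`.  Urinary sodium
excretion is `UNaV = GFR × [Na] × FE`, with the fractional excretion FE
composed of a proximal fraction (default 0.70) and a distal factor modulated
by pressure natriuresis (`exp((MAP − 94)/s)`, e-fold scale `pn_slope`
= 18 mmHg), aldosterone, angiotensin II, ANP and the direct CCB natriuretic
term.  At any chronic steady state, excretion equals intake — the model's
long-term pressure level is whatever makes that true.

**Arterial pressure.**  MAP is algebraic:
`MAP = 94 × (ECFV/15)^g × tone`, with `g = gv_gain = 6` standing in for the
high long-term gain of whole-body autoregulation (small volume expansions
produce large chronic pressure changes), and `tone` collecting the
angiotensin-II pressor effect, the ANP depressor effect, baroreflex-scaled
sympathetic activity, the heart-rate set point and CCB systemic dilation.

**Renal network.**  Each of two identical kidneys is a series circuit:
renal/interlobar artery (0.004 mmHg/(mL/min)) → afferent arteriole →
glomerulus → efferent arteriole → vein (4 mmHg).  Glomerular pressure Pc
solves inflow = outflow + filtration; single-nephron GFR is a saturating
function of net filtration pressure, `snGFR = 150·x/(x + 42.67)` nL/min with
`x = max(0, Pc − 28)`, calibrated so the normal point (Pc 52 mmHg, snGFR
54 nL/min, GFR 129.6 mL/min at 2.4 M nephrons, RBF 1,100 mL/min) is exact.
Afferent tone is modulated by TGF, the myogenic response, angiotensin II and
CCB; efferent tone by angiotensin II (the dominant channel, which is what
makes RAS blockade glomerulo-protective).  As nephrons are lost, per-kidney
resistances scale with inverse functional nephron number; the afferent side
scales sublinearly (`exponent aff_scale_exp = 0.84`), expressing remnant
preglomerular vasodilation — this is what transmits systemic pressure into
glomerular hypertension in CKD and places the CKD operating point near the
published Pc of 68 mmHg.

**Hormones.**  Renin release falls with macula densa sodium delivery and
renal perfusion pressure and rises with sympathetic activity; angiotensin II
follows renin; aldosterone rises with angiotensin II and with a
potassium-retention proxy (falling GFR); ANP rises steeply with volume.
Hormones relax to their algebraic targets with a 0.25-day time constant
(quasi-steady at the daily step).  All couplings are four-parameter logistic
sigmoids `y = b + A/(1 + exp(∓(x − m)/s))` in "multiplier" form (equal to 1
at the normal operating point), so the normal state is an exact fixed point
by construction.

**TGF.**  The TGF signal is the product of an increasing sigmoid in total
macula densa sodium delivery and a weaker increasing sigmoid in effective
angiotensin II, normalized to 1 at the normal point, acting on afferent tone
with weight 0.6.  In CKD, whole-kidney distal delivery falls, so the signal
drops to ~0.76 — the "impaired TGF" regime described clinically.

**Glomerulosclerosis.**  Above `Pc = 70` mmHg, nephrons convert to
nonfiltering at `gain × (Pc − 70)` per day; each increment is realized after
an exact 120-day queue delay (not a first-order filter).  The gain is the
one deliberately tuned constant: `calibrate_damage_gain()` bisects it so
that the calibrated population's mean GFR slope between months 6 and 36
under CCB lands at −1.1 mL/min/yr (inside the reported −1 to −4 band).  The
threshold and delay are fixed protocol-level facts and are never perturbed.

**LV mass** relaxes first-order (τ = 100 days) toward a sigmoid target in
systolic pressure, with SBP = MAP + 2/3·PP and a fixed pulse pressure of
36 mmHg (the pulse-pressure model is only constrained by two reported blood-pressure points;
this is the simplest closure).

## Pharmacology

PK is one-compartment with first-order absorption.  Three clinical facts
constrain the fit: a 9.5 ng/mL steady-state trough at 10 mg/day, ~95%
accumulation within a week, and an elimination half-life inside the 30–50 h
literature band.  We fix t½ = 36 h (so seven days reach 96% of steady
state), ka = 0.3/h, bioavailability 0.64, and solve the apparent volume from
the trough superposition formula: V/F ≈ 1,914 L, CL/F ≈ 36.8 L/h (apparent
CL = 23.6 L/h at F = 0.64) — squarely in the clinical range for amlodipine.

PD has three channels, all Emax in concentration (EC50 = 12 ng/mL):
afferent dilation (Emax 0.45), systemic arteriolar dilation (Emax 0.35;
afferent ≥ systemic expresses dihydropyridine preglomerular selectivity),
and a direct tubular natriuretic action (Emax 2.2 on fractional excretion).
The natriuretic channel is what gives amlodipine its *chronic* pressure
effect in a Guyton-type model: a pure arteriolar dilator is neutralized at
steady state by renal sodium retention, whereas calcium-channel blockade of
tubular reabsorption shifts the renal function curve itself.  There is no
direct efferent drug effect; the efferent resistance rise seen under CCB
emerges from nephron loss and angiotensin II.

RAS blockade scales the *effective* angiotensin II seen by every effect
channel (vascular tone, TGF sensitization, reabsorption, aldosterone drive,
pressor effect) by `1 − fraction`; the trial arm uses 0.80.  Blockade is
deliberately drug-agnostic — no ACE-inhibitor kinetics are modeled.

## The synthetic cohort

Patient-level trial data are access-controlled, so `generate_cohort()`
produces a stand-in with the published marginal moments: MAP 107 ± 9 →
97 ± 8 mmHg (change −10 ± 11), GFR 48 ± 12 → 46 ± 20 mL/min (change
−2.6 ± 15), baseline GFR truncated to the 20–65 mL/min eligibility window by
rejection.  Pre/post pairs are bivariate normal with correlations derived
from the change-score identity (ρ ≈ 0.167 for MAP, ≈ 0.665 for GFR).  The
MAP and GFR blocks are independent because no cross-correlation is
published — a known limitation: the synthetic cohort cannot encode any real
MAP–GFR dependence, so a green calibration establishes that the algorithm
matches the stated marginals, not that it reproduces joint structure.
Visit-level measurement noise is likewise not modeled (the published values
are per-patient visit averages).  Real data can be supplied through the same
CSV schema.

## Calibration algorithm choices

The published procedure specifies the 1-SD box rule per dimension, k-nearest
neighbours, ×10 re-perturbation of selected parameter sets, and a
statistical-similarity stopping rule, but not every detail.  Decisions made
here (all in `knn_select()` / `calibrate_population()`):

* eligibility: a virtual record must lie within 1 clinical SD of **some**
  clinical patient in **all four** dimensions (Chebyshev ≤ 1 in standardized
  space);
* assignment: greedy 1-nearest-neighbour without replacement, in global
  order of increasing Euclidean distance in SD-standardized space, so the
  final population is one-to-one matched and has exactly the cohort's size;
* attrition: candidates whose steady-state solve fails, whose baseline is
  non-physiological (MAP outside 40–230 mmHg, GFR outside 2–200 mL/min), or
  whose trial run produces non-finite values are dropped and reported;
* stopping: full assignment plus all four Mann–Whitney p > 0.05; the
  generation budget (default 10) is an error, reporting per-dimension p.

The wide perturbation class covers exactly the named subset (renin and
aldosterone secretion, sympathetic activity, heart rate, baroreceptor
sensitivity, salt intake, amlodipine clearance, myogenic sensitivity, renal
vascular resistance, proximal and distal reabsorption): multipliers uniform
on [0.05, 2] ("up to 100%" above nominal, bounded below for positivity).
All other non-fixed parameters are narrow (±5%).  The reduced model has ~100
parameters rather than the original's 341; the algorithm, not the count, is
what this package reproduces.

## Protocols and numerical choices

* CKD induction: per-patient reduction fraction ~ Normal(0.70, 0.10)
  truncated to (0.3, 0.95), applied as a linear ramp of structural nephron
  number over 270 days, followed by a settle to steady state.  The damage
  law is disabled during induction — the ramp *is* the prescribed reduction,
  and double-counting pressure damage there would make the baseline a moving
  target; all arms (control included) accrue glomerulosclerosis from trial
  day 0.
* Integration: 1-day outer steps with 10 equal sub-steps; PK updated with
  the exact one-compartment solution per sub-step; hormones relaxed
  exponentially; a ±2%-of-body-sodium excursion cap per sub-step guards
  extreme parameter draws (the realized excretion is accounted from the
  actual sodium change, so daily mass balance is exact by construction).
* Steady state: damped iteration of the daily map until every tracked state
  drifts < 1e-6/day (contract: 0.1%/day), with per-patient convergence
  flags; non-convergence names the worst-residual variable.
* Glomerular pressure: safeguarded Newton on the strictly decreasing network
  residual, warm-started from the previous step, clamped to (venous
  pressure, MAP).
* Endpoints: "change" endpoints at day 365 point values (the table's
  footnote convention); chronic GFR decline as the per-patient OLS slope on
  the recorded series between months 6 and 36; damaged nephrons as the
  change in the nonfiltering count over the arm.  The windowed mean slope is
  monotone non-increasing in the damage gain throughout the −1 to −4
  mL/min/yr band that the gain calibration searches; at far larger gains it
  turns back up (kidneys that collapse before month 6 have nothing left to
  lose inside the window), which is why the bisection is run against the
  band rather than globally.
* Seeds: one root seed; derived streams for sampling, induction draws and
  refinement via a stable integer hash, so whole-pipeline runs are
  bitwise reproducible.

## What a green test establishes — and what it does not

The nominal normal operating point is reproduced *by construction* (it is
the anchor of the parameter table), so criterion-level agreement there
validates the wiring, not the physiology.  The CKD operating point, the
treatment responses and the population-level contrasts are emergent and are
the substantive checks.  Population SDs of treatment responses and purely
internal predictions of the original whole-body model (TGF change
magnitudes, ANP trajectories, damaged-nephron SDs) are reported and compared
qualitatively only — a reduced model cannot, and here does not, claim to
reproduce them exactly.  One known sign discrepancy: under CCB the original
model reports rising ANP while volume is roughly stable; here the CCB
natriuretic channel lets volume and ANP settle with a smaller rise.  Both
mechanisms deliver the same chronic pressure response; the ANP trajectory
itself is not a calibration target.

## Known limitations

* No proteinuria, potassium/acid–base physiology, pulsatile cardiac
  dynamics, dose titration, adherence, or advanced-CKD/dialysis extensions.
* The pulse-pressure closure (fixed 36 mmHg) is unconstrained beyond the
  two reported systolic/diastolic values.
* The damage law's form above threshold (linear in excess pressure) and its
  behaviour at very high pressure are assumptions; only the threshold,
  delay, and monotonicity are stated facts.
* Self-calibration and parameter-recovery tests run at desk scale; the
  full-scale configuration (pool 1,500, cohort 165) is supported but takes
  tens of minutes on one CPU.
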