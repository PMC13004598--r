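---
title: "Dual-timescale modelling of oral contraceptive dosing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-timescale modelling of oral contraceptive dosing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Combined oral contraceptives suppress ovulation by adding exogenous
estrogen (ethinyl estradiol, EE) and progestin (dienogest, DNG) to the
hypothalamic–pituitary–ovarian feedback loops. Both the endocrine system
and drug absorption operate on two timescales at once: the ~28-day
menstrual cycle and the 24-h circadian day. `chronOC` couples a
menstrual-cycle delay-differential model with circadian modulation of
hormone production to closed-form oral pharmacokinetics, and asks whether
the clock time of pill intake changes the dose needed to keep peak
progesterone (P4) below the 3 ng/mL anovulation threshold.

## The cycle model

The state is twelve-dimensional: pituitary LH and FSH in a synthesis
reserve pool (`RP_LH`, `RP_FSH`) and in blood (`LH`, `FSH`); a follicular
cascade of recruited, growing and dominant masses (`RcF`, `GrF`, `DomF`);
four luteal stages (`Lut1`–`Lut4`); and inhibin (`Inh`), which feeds back
on FSH synthesis with a transport/processing delay of `tau` days
(solved by the method of steps). Blood estradiol and progesterone are
algebraic outputs, linear in the stage masses:

```
E2 = (e0 + e1*GrF + e2*DomF + e3*Lut4) * (1 + theta5*cos(2*pi*(t - theta6))) + r1*E2exo
P4 = (p0 + p1*Lut3 + p2*Lut4)          * (1 + theta7*cos(2*pi*(t - theta8))) + r2*P4exo
```

LH synthesis carries the classic estradiol positive feedback (Hill
exponent 8 around `Km_LH`) divided by progesterone inhibition
(`1 + P4/Ki_LH_P`); FSH synthesis is inhibited by delayed inhibin and by
progesterone (`1 + Inh(t-tau)/Ki_FSH_Inh + P4/w`). Both synthesis terms are
multiplied by a daily cosine `1 + theta*cos(2*pi*(t - theta_acro))` —
circadian modulation enters *only* through these production terms
(reflecting the clock-gated hypothalamic drive) and through the E2/P4
output factors above. Ovulatory transfer from the dominant follicle to the
luteal chain is strongly supralinear in LH (`d2*LH^nu`, `nu = 6`), which
makes the LH surge an all-or-none trigger rather than a graded drain; time
is in days with `t = 0` at midnight of cycle day 0 (first day of menses),
so clock time `h` maps to `h/24`.

### Parameter provenance

No published parameter table was available to this project, so the
baseline parameter values shipped in
`inst/extdata/oc_params_v1.json` are a **synthetic reconstruction**: the
model family above was calibrated de novo to textbook cycle physiology — a
stable limit cycle of 27.95 days, E2 spanning ~65–310 pg/mL with a
pre-ovulatory peak, an LH surge on day 14 from the packaged day-0 state,
luteal P4 peaking near 7 ng/mL (well above the 3 ng/mL threshold), FSH
highest in the early follicular phase — and to the qualitative
contraceptive anchors of the study design (the market dose suppresses;
doses just below ~28 µg/day EE do not). The file is versioned and
checksummed; every simulation entry point refuses to run without a
provenance-carrying bundle. Quantities that depend on one specific
parameter realization (exact minimal-dose pairs, exact percent
reductions) are therefore not expected to reproduce numerically, and the
acceptance suite reports them honestly.

## Pharmacokinetics

Each oral dose contributes the standard two-compartment extravascular
tri-exponential

```
C(t) = N*exp(-ka*dt) + L*exp(-alpha1*dt) + M*exp(-beta1*dt),  dt = t - t_dose
```

with partial-fraction coefficients proportional to the dose; regimen
concentrations superpose all past doses exactly (a dose older than 40
elimination time constants contributes below machine precision and is
skipped). `F` and `Vc` enter only as `F/Vc`, so `F = 1` and `Vc` is the
apparent central volume. Rates must satisfy `beta1 < k21 < alpha1 < ka`;
coincident rates make the closed form singular and are rejected rather
than switched to a confluent limit. The packaged values use
literature-range kinetics (EE: half-life 13 h within the published 6–27 h
range, apparent clearance ~19 L/h; DNG: half-life 9.5 h, the value the
half-life sensitivity scenario scales by 2 and 4) with central volumes set
so that steady-state average concentrations at the market dose (30 µg EE,
2000 µg DNG) are ~65 pg/mL and ~40 ng/mL. A numerical
gut–central–peripheral ODE oracle validates the closed form in the test
suite; it is never used by the simulation path.

The relative binding affinities that couple drug concentration into the E2
and P4 observables are fixed at `r1 = 1.7` (EE) and `r2 = 0.01` (DNG) and
are not calibration knobs.

## Calibration

Daily hormone rhythms are fitted by **cosinor** on mean-normalized data —
an exact linear least-squares fit on the cos/sin basis, not an iterative
search. Circadian targets over a 28-day cycle are built by modulating the
rhythm-free model trajectory, `target(t) = H(t)*(1 + a*cos(2*pi*(t-b)))`,
and the eight model parameters `theta1..theta8` are estimated by
Nelder–Mead least squares between the circadian model and those targets.
Two modes exist: the joint default, and a staged per-hormone mode
(E2, P4, FSH, LH, two passes, then a restarted joint polish) that is much
better conditioned. On self-consistency tests (targets generated from the
model itself) the staged mode recovers injected parameters essentially
exactly.

An important structural finding: the pituitary reserve pools turn over
slowly (`k_LH` ≈ 0.56/day), so a daily modulation of the *synthesis* rate
is attenuated roughly tenfold before it reaches blood LH. Blood-level
cosinor data therefore cannot identify `theta1`–`theta4`. The packaged
bundle consequently fits the E2/P4 *output* rhythms from the synthetic
series but fixes the gonadotropin *production* rhythms a priori as study
conditions: `theta1 = 0.30` peaking at 13:12 and `theta3 = 0.15` at 13:55,
an early-afternoon production peak consistent with a clock-gated
hypothalamic drive. The dosing-time results inherit this choice: the
optimal intake window sits where the absorbed drug peak coincides with the
rising phase of LH production.

PK parameters are fitted to 24-h post-dose concentration series (seventh
daily dose) by Nelder–Mead least squares in log space with an ordering
barrier. A noiseless series is recovered exactly; with 3% multiplicative
noise the fitted *curve* (Cmax, profile) is recovered within a few
percent, but individual micro-rates trade off along sloppy directions and
can deviate far more — a known identifiability property of oral
two-compartment fits from a single dosing interval. The canonical file
therefore ships the generator's ground-truth kinetics; re-fitting is a
validation exercise. Least-squares AIC (`2k + n*log(RSS/n)`) selects the
two-compartment model over the one-compartment alternative on biphasic
data and reverses on mono-exponential data.

## Synthetic study inputs

Daily hormone rhythms and post-dose concentration profiles of the kind
usually digitized from published figures are emulated by seeded
generators with known ground truth:
`mean*(1 + a*cos(2*pi*(t-b)))*(1+eps)` hourly over 24 h post-wake (wake
07:00) with 5% multiplicative noise, and superposed closed-form
concentrations on a standard blood-draw grid with 3% noise. The chosen
rhythm conditions are: LH mean 8, amplitude 0.20, blood acrophase 20:00
(evening blood peak, consistent with midday production through the
reserve-pool lag); FSH 0.06 at 13:00; E2 0.10 at 10:00; P4 0.12 at 15:00.
Amplitudes are modest (4–20%), in line with reported diurnal variation of
reproductive hormones; they were chosen once and not revisited. What
passing tests show is that the *pipeline* recovers known truth under these
conditions — not that real digitized data would yield the same numbers.

## Screening and optimization

A regimen is 21 daily (EE, DNG) doses at one clock hour followed by a
7-day break, repeated per 28-day cycle; a verdict is anovulatory iff max
P4 over the horizon stays strictly below 3 ng/mL (equality counts as
ovulatory). The dose grid uses the canonical axes 0–30 µg EE by 0.6 and
0–2000 µg DNG by 40 (51×51); sensitivity scenarios use a coarse 6×6 grid.
Minimal doses are found by boundary search: per EE level the smallest
admissible DNG by bisection, with an explicit corner check because in this
reconstruction added DNG can *raise* measured peak P4 (its direct
RBA-weighted contribution outweighs its dynamic suppression), making the
admissible region non-monotone along the DNG axis. The default selection
rule minimizes the daily EE+DNG microgram sum with a low-DNG tie-break.

Nonconstant regimens are optimized by NSGA-II inside a two-population
coevolutionary constraint-handling scheme: the main population uses
constrained dominance (feasibility `J1 < 3` first), the helper population
ignores the constraint, and offspring of both enter both selection pools.
Operators are simulated binary crossover (eta 15, p 0.9) and polynomial
mutation (eta 20, p 1/42); stopping is a relative feasible-hypervolume
change below 1e-4 over 10 generations or an evaluation budget. Because
the feasible region is a narrow high-EE corner, the initial population is
warm-started with constant-dose heuristics — the standard practice when a
good engineering solution is known. Post-processing follows the
confirmation/zeroing/cross-validation pattern: front members are
re-simulated over 10 cycles (3-cycle winners that relapse are rejected),
sub-microgram doses are zeroed and re-verified, and the cheapest surviving
regimens are re-tested across all dosing hours.

## Numerical choices

The DDE integrator is an adaptive Dormand–Prince 5(4) scheme (compiled)
with maximum step 0.05 day so the daily cosine and absorption spikes are
resolved, cubic-Hermite dense output at 0.01-day resolution (max-P4
extraction error far below 0.5% of the threshold), and a cubic-Hermite
history of inhibin for the lagged term; the pre-history is constant at the
day-0 state. Default tolerances are `rtol = atol = 1e-8`; halving them
changes 3-cycle max P4 by under 1e-6 relative. Screening and optimization
use `1e-6` with 0.05-day output, which changes max P4 by ~1e-8 relative.
An independently written deSolve (`lsoda`) transcription of the equations
agrees with the compiled path to ~1e-8 relative over 84 days.

Problem sizes in the tests and acceptance runs are desk-scale by design:
3-cycle (84-day) objective horizons, 10-cycle (280-day) confirmations,
populations (40, 50) with a 5000-evaluation budget, coarse grids for the
sensitivity sweeps.

## What the reconstruction does and does not reproduce

Reproduced: a regular ovulatory 28-day cycle; daytime superiority of pill
timing (minimal EE-only dose 27 µg/day at 07:00–11:00 versus no
achievable dose within the market box at 19:00–24:00); the
second-cycle relapse of near-threshold regimens dosed in the evening
(e.g. 28.2 µg EE + 320 µg DNG suppresses all three cycles at 11:00 and
breaks through from cycle 2 at 22:00); the LH production rhythm as the
primary driver of the contrast (ablating it collapses the daytime/evening
difference); EE-only optimal nonconstant regimens with most of the dose in
the follicular phase.

Not reproduced, with the reason: minimal-dose pairs that place several
hundred µg of DNG on the frontier — in this reconstruction
exogenous DNG at RBA 0.01 contributes more to measured P4 directly than it
removes dynamically, so minimal doses sit at DNG = 0 and the DNG-specific
percent reductions and half-life totals have no analogue; and sparse
(8–11 intake day) optimal regimens — at the scaled-down evolutionary
budget the confirmed optima keep all 21 intake days, trimming dose level
rather than dosing days. Both are consequences of reconstructing the
baseline without the original parameter tables and are flagged red by the
acceptance suite rather than patched.

## Known limitations

Single representative cycle (no inter- or intra-individual variability
beyond the cycle-length scaling scenario); no enterohepatic recirculation,
SHBG binding or drug–drug PK interaction; anovulation is judged solely by
the P4 threshold; follicular-phase rhythm parameters are applied
cycle-wide; and the identifiability limits above mean the circadian
synthesis amplitudes should be read as model conditions, not estimates
from blood data.
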