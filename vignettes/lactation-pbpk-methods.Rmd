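---
title: "Lactation PBPK methods: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lactation PBPK methods: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactpbpk)
```

## What the package models

The pipeline predicts primaquine exposure in a breastfed infant from the
mother's dosing regimen, in five coupled stages: plasma protein binding,
milk-to-plasma partition, infant daily dose (IDD) arithmetic, a lumped PBPK
engine, and virtual-trial machinery. This vignette is the package's own
account of each stage: the equations, the defaults and why they were chosen,
the numerics, and what the results can and cannot claim.

## Protein binding

Primaquine binds α₁-acid glycoprotein (AAG). We use a single-site,
non-saturable model, bound/free = $K_a \cdot \mathrm{AAG}$, so

$$fu(\mathrm{AAG}) = \frac{1}{1 + K_a \,\mathrm{AAG}}, \qquad
K_a = \frac{1 - fu_\mathrm{ref}}{fu_\mathrm{ref}\,\mathrm{AAG}_\mathrm{ref}}.$$

The anchor is fu = 0.33 at the pregnancy AAG level of 0.6 g/L; the model then
gives fu ≈ 0.297 at the postpartum 0.7 g/L and ≈ 0.11 at a four-fold AAG
elevation. A saturable (Langmuir-type) model would add a capacity parameter
that no available observation constrains, so the linear form — which
reproduces the known fu/AAG pair pairs exactly — is the defensible choice.
Therapeutic primaquine concentrations (~0.3–0.5 µM at Cmax) sit far below
AAG's binding capacity (~10–20 µM), which is what makes non-saturable binding
physically reasonable here. Blood-basis unbound fraction is
$fu_b = fu/(B{:}P)$ with $B{:}P = 1$ by default.

## Milk-to-plasma partition

Milk transfer is passive. The unbound, un-ionized species is assumed to
equilibrate between plasma (pH 7.4) and the two phases of milk:

- **skim phase** — ion trapping of the base in the (more acidic) milk plus
  binding to milk proteins:
  $$S = fu_p \cdot \frac{1 + 10^{\,pK_a - \mathrm{pH}_\mathrm{milk}}}
  {\left(1 + 10^{\,pK_a - \mathrm{pH}_\mathrm{plasma}}\right) fu_\mathrm{skim}},$$
  where $fu_\mathrm{skim}$ rescales the plasma bound/free ratio by a
  milk/plasma binding-protein scalar;
- **fat phase** — partition of the neutral species into milk lipid with
  $K_\mathrm{fat} = 10^{0.99\,\log P - 0.88}$ (a standard olive-oil-type
  lipophilicity correlation):
  $$F = fu_p \cdot f_\mathrm{unionized}(\mathrm{pH}_\mathrm{plasma}) \cdot K_\mathrm{fat};$$
- **mixing** — $M/P = (1 - f_\mathrm{fat})\,S + f_\mathrm{fat}\,F$.

The binding-protein scalar is the single quantity the model cannot derive
from physicochemistry. It is calibrated **once**, against the predicted M/P
of 0.47 in mature milk (pH 7.2, 4% fat) at the postpartum unbound fraction,
and frozen at 0.0159 for every other composition (`primaquine_protein_ratio()`).
With pKa = 10.4 the drug is >99.9% ionized at physiologic pH, so the fat term
is small and the M/P is fat-insensitive but strongly pH-sensitive — the
behaviour the composition scans in `analysis/02_milk_transfer.R` quantify.

Primaquine's pKa and logP are not fixed by any observation inside this
pipeline; the shipped values (pKa 10.4 for the aliphatic amine, logP 3.0) are
literature-typical and exposed as tunable fields of `drug_parameters()`.
Absolute M/P predictions inherit their uncertainty; the pH/fat *sensitivities*
are more robust because the calibration absorbs level errors.

The maternal simulations use the observed M/P of 0.34 (`milk_mode =
"observed_mp"`); the predicted-M/P mode exists for prospective use where no
milk data are available.

## Dose arithmetic

Exact rational arithmetic, no modeling:
IDD = $M/P \cdot C_{avg} \cdot \mathrm{intake}/1000$ µg/kg/day (intake 150
mL/kg/day by convention, 200 for the conservative early-infancy case, a ratio
of exactly 4/3); RIDD = $100\,\mathrm{IDD}/\mathrm{maternal\ dose}$;
cumulative course dose = IDD × days / 1000 mg/kg; per-feed dose = IDD / 6 for
the default six feeds 4 h apart (feeding times in the underlying study were
not controlled, so an even q4h split is the neutral assumption and is
overridable in `feeding_regimen()`).

## The lumped PBPK engine

### Structure

A full multi-organ model is unnecessary for the quantities of interest
(Cmax, AUC, medians, ratios): once clearance, volume and absorption rate
reproduce the observed maternal exposure, those outputs are insensitive to
tissue-level resolution. The engine therefore uses:

- first-order absorption (ka = 1 h⁻¹, fa = 1 by default; absorption rate is
  unconstrained by the available observations, and 1 h⁻¹ puts tmax at 2–3 h,
  consistent with the 2–3.5 h sampling windows used in the pediatric studies);
- **well-stirred first-pass**: an absorbed dose enters the liver and only
  $F_h = Q_h/(Q_h + fu_b\,CL_{int})$ reaches the circulation. This makes oral
  AUC exactly $f_a D /(fu_b\,CL_{int})$, so exposure is monotone in $1/fu_b$
  — the behaviour that drives the AAG sensitivity scans;
- two-compartment disposition (central volume calibrated; peripheral volume
  1.2 L/kg and inter-compartmental clearance 0.15 L/h/kg fixed — they shape
  the terminal phase only weakly and are not identifiable from the two
  calibration targets);
- well-stirred systemic elimination
  $CL_h = Q_h\,fu_b\,CL_{int}/(Q_h + fu_b\,CL_{int})$.

### Subject scaling

Each pathway's intrinsic clearance scales as

$$CL_{int} = CL_{int}^{adult}\ (\mathrm{L/h\ per\ kg\ liver}) \times
\mathrm{liver\ mass} \times \mathrm{capacity}(age) \times
\mathrm{ontogeny}_p(age) \times \eta_{CL},$$

with $\eta_{CL}$ the subject's lognormal multiplier. The components:

- **Liver mass**: $LW = 0.07665\,WT^{0.70}$ kg — 1.5 kg for a 70-kg adult,
  ~5% of body weight at birth falling to ~2.2% in adults. The sublinear
  exponent encodes the well-known hepatic enrichment of infancy that makes
  per-kg clearance of hepatically eliminated drugs peak around 6 months to
  2 years.
- **Hepatic blood flow**: 66 L/h per kg liver (~1.1 mL/min/g), i.e. flow
  scales with liver mass.
- **Hepatic capacity maturation**: a system-level factor
  $0.35 + 0.65\,a^{1.6}/(a^{1.6} + 6^{1.6})$ ($a$ in postnatal weeks)
  multiplying *all* pathways. It represents the maturation of metabolically
  active tissue per gram of liver (microsomal and mitochondrial protein
  content). It is required for internal consistency: AAG is low at birth, so
  unbound fraction — and with it unbound clearance — would otherwise be
  *highest* in neonates, inverting the universally observed pattern that
  neonatal per-kg clearance is the lowest of childhood. The curve was fixed
  at design time so that the typical-subject exposure ordering (neonate >
  infant, both far below mother) matches the reported landscape, and is fully
  exposed in `physiology_config()`.
- **Enzyme ontogeny** per pathway,
  $f_{birth} + (1 - f_{birth})\,a^{h}/(a^{h} + a_{50}^{h})$:
  CYP2D6 default $f_{birth} = 0.05$, $a_{50} = 2$ weeks, $h = 1$ (fast
  postnatal maturation, consistent with the literature-shaped pattern of this
  enzyme). MAO-A has no published ontogeny, so two bounding presets are
  shipped: `maoa_none` (adult activity per gram liver at all ages — also the
  assumption used for infants ≥ 28 days) and `maoa_slow`
  ($f_{birth} = 0.2$, $a_{50} = 60$ weeks, $h = 1$), the conservative
  neonatal scenario chosen so that neonatal relative exposure stays below
  about 0.5%.
- **AAG maturation**: $0.7 \times (0.45 + 0.55\,a/(a + 35))$ g/L — ~0.32 g/L
  at birth, adult by about two years, within the reported ontogeny range.

### Calibration

The two free adult parameters — total $CL_{int}^{adult}$ and $V_c$/kg — are
pinned by the observed day-14 maternal medians (Cmax 129 ng/mL, AUC
988 ng/mL·h under 0.5 mg/kg q.d. × 14) using the reference postpartum mother
(29 y, 160 cm, 55 kg, AAG 0.7 g/L). Because steady-state oral AUC depends
only on $fu_b CL_{int}$ and Cmax mostly on $V_c$, damped alternating updates
(clearance ← clearance × AUC ratio; volume ← volume × Cmax ratio) converge in
a few iterations to a relative residual of 1e-6; calibration errors out if
residuals exceed 0.5%. The calibrated total is split 90/10 between MAO-A and
CYP2D6, and the resulting apparent oral clearance satisfies the identity
CL/F = daily dose / AUC = 500/988 ≈ 0.506 L/h/kg. The shipped
`primaquine_parameters()` carries these calibrated values; `calibrate_adult()`
recomputes them from scratch.

## Virtual populations

Height for age is the printed sex-specific polynomial (degree 7 boys,
degree 8 girls); weight combines a saturating age term, an exponential height
term and a linear age term. The weight equations are typeset ambiguously in
the source material (script fragments without parentheses); the adopted parse

$$W = A\,(1 - e^{-k\,\mathrm{age}}) + e^{c\,\mathrm{height}} + b\,\mathrm{age}$$

is the only grouping of the printed tokens that yields physiologic masses
across 0–18 years (2.5 kg at birth, ~21.6 kg at age 10), and it is frozen in
tests against an independently evaluated oracle. Adults use fixed
sex-specific means (160 cm/55 kg female, 172 cm/70 kg male — chosen for a
Southeast-Asian study population) since no adult demography equations are
printed; children get lognormal CVs of 4% (height) and 15% (weight), adults
10%/20%. Ages are uniform on the study range, sex is Bernoulli.

Between-subject variability enters as lognormal multipliers with median 1 on
intrinsic clearance (CV 35%) and volumes (CV 25%). These CVs are not printed
anywhere; they were chosen so the simulated maternal AUC spread spans roughly
the 3–4-fold range seen across the observed trial, and they are plain config
(`iiv_cv`).

## Virtual trials and study sizes

Every scenario runs as 10 trials × the clinical study's N (20 mothers, 20
infants, 20 neonates, 15 or ~21 children), with trial *i* seeded `seed + i`,
so any run is bit-reproducible from its config and seed. Pooled percentiles
(5th, median, 95th) use linear interpolation between order statistics
(`stats::quantile` type 7). Relative exposure is the percent ratio of pooled
medians. The shipped assessment window is the last dosing day
(312–336 h); children's single-dose study uses its 168-h span. The
deterministic property checks in the test suite (pediatric day-7 Cmax versus
the four reported cohort values) run on typical median-age subjects without
variability — a deliberate size reduction; the full 10-trial versions live in
`analysis/05_children_verification.R`.

## Numerical choices

- ODE integration: `deSolve::lsoda`, rtol 1e-8, atol 1e-10; doses are applied
  as additive events on the gut compartment, which keeps the concentration
  trace continuous and avoids integrating across discontinuities. Note that
  `lsoda` records the state at an event time *before* applying the event.
- Output grid 0.1 h; dose times are merged into the grid. Trapezoidal AUC on
  this grid is converged to well under 0.1% (tested by grid refinement).
- Cmax/tmax by grid maximum; `which.max` resolves ties to the earliest time.
- Degenerate inputs: a peripheral volume or inter-compartmental clearance of
  zero collapses cleanly to one compartment (the analytic-oracle test runs in
  exactly this configuration); zero enzyme activity gives zero hepatic
  clearance; AAG of zero gives fu = 1.
- Calibration starts from the steady-state identity
  $CL/F = \mathrm{dose}/\mathrm{AUC}$ and a 2 L/kg volume guess; it is
  locally unique because AUC is strictly decreasing in clearance and Cmax
  strictly decreasing in volume at fixed clearance.

## Synthetic data: what it does and does not emulate

`synth_observations()` reproduces the statistical structure the analysis has
to survive: sparse sampling (default pre-dose, 2, 4, 8, 12, 24 h around a
day-14 dose), combined proportional (CV 20%) plus additive (0.05 ng/mL)
residual error, and censoring at an LLOQ of 1 ng/mL — maternal plasma and
milk samples quantify, infant samples are essentially all BLQ, matching the
study's reported data pattern. The full-loop check
(`recovery_study()`, 200 replicates) generates milk data, recovers the IDD by
time-averaging, and re-simulates the infant; the median recovered IDD lands
within a few percent of truth, with a small negative bias from trapezoidal
averaging of a sparse grid over a peaked profile.

What the generator does **not** emulate: real assay error structure
(log-additive, heteroscedastic), irregular real-world sampling times, missed
feeds and variable milk intake, fore/hind-milk fat gradients and diurnal
composition changes, or active transport into milk. Passing the recovery test
therefore shows the *pipeline arithmetic* is sound under the assumed error
model — not that the error model matches any particular bioanalytical method.

## Known limitations

- The engine is a lumped reduction, not an organ-resolved model; it cannot
  resolve tissue concentrations or enterohepatic recirculation, and the
  carboxy metabolite is out of scope.
- MAO-A ontogeny is unknown; the two shipped presets bound the plausible
  range rather than estimate it, and neonatal predictions should be read as
  scenario bounds.
- The hepatic capacity maturation curve is a modeling construct constrained
  by qualitative ordering, not by direct enzyme-abundance data.
- pKa, logP, absorption rate, peripheral disposition and all variability CVs
  are defaults, not estimates; each is exposed in config and should be
  revisited for any drug other than primaquine.
- CYP2D6 polymorphism, G6PD-related pharmacodynamics and pregnancy physiology
  are not modeled.
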