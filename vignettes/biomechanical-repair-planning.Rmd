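---
title: "Biomechanically calculated incisional hernia repair: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanically calculated incisional hernia repair: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(griprepair)
```

## The problem

Incisional hernias — defects in the abdominal wall at the site of a previous
surgical incision — recur after roughly a quarter of conventional repairs,
and chronic pain is common. Biomechanically calculated reconstruction (BCR)
treats the repair as a structural engineering problem under cyclic load:
coughing, straining and a Valsalva maneuver repeatedly stress the
mesh–tissue composite, and a repair is durable only if the strength it
gains exceeds the strength the defect demands.

`griprepair` implements this calculus as a tested pipeline: the two
resistance scores and their inputs, a planner that iterates a mesh plan
until the gained resistance exceeds the critical one, a clinical complexity
score, a simplified abdominal-wall instability map, a synthetic registry
cohort generator, and the nonparametric statistics used to analyse such
cohorts.

## The resistance model

Two dimensionless scores summarise the mechanics.

**CRIP** (critical resistance to impacts related to pressure) is the
strength a durable repair must reach:

$$\mathrm{CRIP} = (0.5 \cdot \text{hernia size} + 15) \cdot \text{tissue distension}$$

where *hernia size* is the defect area in cm² and *tissue distension* the
maximum displacement of the wall (cm) under a Valsalva maneuver. The
additive constant means even a vanishingly small defect in lax tissue
demands strength proportional to its distension; the multiplicative
distension means perfectly stable tissue (distension 0) demands none.

**GRIP** (gained resistance) is the strength a planned repair achieves:

$$\mathrm{GRIP} = \mathrm{MDAR} \cdot c_{\text{adhesiveness}} \cdot
c_{\text{position}} \cdot c_{\text{fixation}}(\text{type}, \text{points})
+ f_{\text{peritoneal}} + f_{\text{fascial}}$$

with **MDAR** the mesh-defect area ratio (mesh area over defect area) and
the $c$'s multiplicative coefficients for mesh gripping class, position in
the wall, and fixation; closure credits are additive and applied after the
multiplicative chain (this ordering is a reading of how the factors are
described — multipliers *plus* factors — and is isolated in one function).
A repair is **durable** when GRIP strictly exceeds CRIP.

### Conventions and assumptions

- *Hernia size is an area.* The formula's "hernia size" is taken as the
  defect area under an elliptical model, $\pi/4 \cdot w \cdot \ell$ (cm²).
  Width alone cannot produce resistance scores in the hundreds for
  realistic distensions, while areas of large defects can; the convention
  is confined to `defect_size()` so it can be swapped. MDAR is unaffected
  because any fixed shape constant cancels in the ratio.
- *Distension is measured in cm.* The 1.5 cm stability limit and the 15 mm
  shift threshold of the instability map are then the same number, which is
  how the package treats them.
- *CRIP and GRIP are dimensionless scores.* No physical unit is asserted.
- *Coefficients are configuration.* The clinically validated multipliers
  are published separately and must be supplied as a JSON/YAML config. The
  package ships an identity placeholder (every multiplier 1 — GRIP
  reduces to MDAR), which `plan_repair()` and `assess_repair()` refuse
  unless explicitly allowed, and a clearly-labelled *synthetic* table whose
  values are calibrated only in order of magnitude, used by the cohort
  generator.
- *Fixation coefficients are banded.* The multiplier is looked up by
  fixation type and point-count band, because no functional form in the
  number of points is established; bands are part of the config.

### Measurement reliability

Manual measurement of hernia dimensions requires three observers taking at
least four readings each; the protocol is reliable only when the pooled
coefficient of variation is strictly below 5% (`interobserver_check()`).
This threshold is strict because the one recurrence observed in the study
population this package models occurred in a case whose interobserver
variation was 18% — a high-laxity wall that defeated manual measurement.

## The planner

`plan_repair()` implements the clinical iteration "design, compute GRIP,
compare to CRIP, escalate". The escalation path is linear and documented:

1. mesh overlap grows in 1 cm steps from the minimal overlap (default 5 cm)
   until both mesh dimensions hit the manufacturing cap (default 49 cm);
2. fixation points increase (default: steps of 10 up to 300, the largest
   count observed in practice);
3. the fixation type moves up an ordered escalation list;
4. the peritoneal and fascial closure credits are switched on.

Each step changes exactly one knob, so `escalation_trace()` is a readable
audit trail, and the returned plan is minimal *under this order*. The
order mirrors the clinical narrative (larger meshes for larger hernias
first, then more fixation) and is configurable via
`planner_constraints()`; no claim is made that it is optimal across
orders. GRIP is non-decreasing along the path whenever the coefficient
table is monotone in the escalation direction (banded multipliers
non-decreasing in points, types ordered by strength), which holds for the
shipped tables. If no candidate within the constraints is durable the
planner reports infeasibility together with the best achievable margin —
that is a clinically meaningful verdict (the case needs measures outside
the modelled grid), not a numerical failure.

## The complexity score

One point per triggered risk category: defect width > 10 cm, lateral site,
recurrent hernia, age > 80, BMI > 30, the comorbidity cluster, concomitant
stoma/bowel repair, and intensified surgery. All comorbidity-related
factors (metabolic disease, elevated intra-abdominal pressure, bleeding
risk, reduced wound healing, abnormal gait) collapse into a single point
however many are present — their shared biomechanical effect is increased
tissue laxity, so they are not additive. Thresholds are strict
(*above* 10 cm, *over* 80, *over* 30).

Whether age and BMI belong in the collapsible cluster is not settled; this
package treats them as standalone categories because they are listed as
distinct items rather than comorbidities. The maximum score is therefore 8,
while observed cohorts span 0–5. This partition is a documented assumption,
confined to `score_complexity()`.

## The instability map

The full image-analysis tool that produces displacement fields from CT at
rest and during Valsalva uses symmetric diffeomorphic registration; that
registration is out of scope here. This module consumes the *result* — a
2-D displacement field in mm on an isotropic pixel grid — and computes what
the clinic needs from it: the per-pixel shift magnitude, the unstable
region (shift > 15 mm), its area in cm², the maximum distension in cm, and
the strain map with its > 20% high-laxity flag. The shift and elasticity
criteria are computed and reported separately rather than OR-ed, since
their operational combination is not standardised.

`synth_field()` provides three phantom scenarios. The focal-laxity phantom
is a noise-free radial Gaussian bump, chosen because its unstable area has
a closed form ($2\pi\sigma^2\ln(A/T)$ for peak $A$ over threshold $T$),
giving the segmentation an analytic oracle. The phantoms emulate the
*pattern* of instability maps (a localised lax zone, diffuse laxity), not
the noise statistics, anisotropy or registration artefacts of real CT
data — tests passing on phantoms validate the arithmetic, not clinical
image handling.

## The synthetic cohort generator

No registry data are public, so the generator emulates the study
conditions: six complexity strata of sizes 18/44/45/31/34/18 (the 190
classified patients of 198 recruited, after 7 deaths and the single
recurrence, which is representable but excluded from stratified
summaries), with per-stratum marginals matched to the published cells.

Distribution choices, made once:

- **Hernia width and length**: scaled Beta on the printed [min, max] with
  the distribution's median placed exactly at the printed median
  (concentration fixed at 5). Bounded support honours the printed
  extremes; the family allows the strong right skew the data are stated to
  have. Width and length are generated independently — their
  within-stratum correlation is not reported.
- **Age, BMI, preoperative pain**: truncated normals matched to the
  printed mean, SD, min and max.
- **Tissue distension**: truncated normal on [0.2, 12] cm with location
  $0.9 + 0.45 \cdot \text{score}$ and SD $0.3 + 0.12 \cdot \text{score}$.
  This is an explicit calibration (distension rises with complexity), not
  a published marginal; published per-stratum CRIP summaries are *not*
  reproduced by it and are not claimed to be.
- **Outcomes**: Bernoulli at the printed per-stratum rates; length of stay
  from the bounded-skew family; pain scores Poisson with rate
  $\max(\text{median}, 0.2)$ clipped to the 0–10 scale, which reproduces
  the printed median trajectory (2 at discharge, 0–2 at one month, 0 from
  six months on).

Consistency between stratum label and risk flags is enforced by
construction: width is sampled first from its calibrated marginal (so the
width distribution is untouched), then the remaining point-bearing
categories are drawn so the recomputed complexity score equals the label,
with age/BMI sampled on the correct side of their thresholds. Mesh plans
are produced by running the planner (with the synthetic coefficient table)
on each sampled geometry; geometries infeasible within the default
constraints have their distension re-sampled up to five times and are
otherwise kept with the best plan and an infeasibility flag.

A single seed drives everything; per-stratum substreams are derived from
it, so generating one stratum alone reproduces its slice of the full
cohort.

What the generator does **not** emulate: joint distributions beyond the
enforced score–flag consistency (no width–length, width–BMI or
outcome–geometry correlations), centre effects, temporal trends, and the
real registry's missingness. Calibration tests passing on these cohorts
show the pipeline recovers the marginals it was given, not that it would
reproduce a real registry's joint structure.

## The statistics stage

The data are skewed, so the stage is nonparametric throughout:
`describe_strata()` (mean, SD, median, min, max per stratum, median by the
mean-of-middle-two convention), `trend_test()` (tie-corrected
Kruskal–Wallis omnibus, pairwise two-sided Mann–Whitney u-tests gated on
omnibus $p < 0.05$), and `rate_table()` (integer percents, half rounded
away from zero — the convention that reproduces the published contingency
rows from their printed counts). The u-test is exact for groups of at most
20 without ties, otherwise the tie-corrected normal approximation without
continuity correction, so the two-group case agrees asymptotically with
Kruskal–Wallis. No multiple-testing correction is applied by default,
matching the source analysis; Holm adjustment is available via `adjust`.

One published cell is knowingly not reproduced: the score-4
postoperative-complication rate prints 26% where its printed count and
stratum size (8 of 34) give 24% — 8 of 31, the neighbouring stratum size,
gives 26%, so this looks like a denominator slip in the source table. The
package reproduces the arithmetic, not the typo.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the generator at its
default 190-patient size for calibration checks, pool roughly 10,000
top-stratum draws for rate calibration (three standard errors of the
binomial), use 2,000 null replicates at 30 per group for the type-I-error
check of the omnibus test (two standard errors of $\alpha = 0.05$), 100
random geometries against an exhaustive-search oracle for the planner, and
a 201×201 phantom (5% tolerance against the analytic level-set area) for
the instability map. Median calibration uses the distribution-free
binomial order-statistic 99.9% band around each stratum's sample median.
The scaled-down trend check asserts $p < 0.001$ on a ×10 cohort — the
qualitative analogue of the much smaller p-values reported at registry
scale, which cannot be reproduced without the registry data.

Degenerate inputs are defined rather than accidental: zero distension gives
CRIP 0 (any plan durable), all-equal data give Kruskal–Wallis $H = 0$,
$p = 1$, an empty stratum is reported missing rather than zero, and
boundary cases are strict exactly where the prose is strict (stable *at*
1.5 cm; *less than* 5% CV reliable; GRIP must be strictly *above* CRIP).

## Known limitations

- The shipped coefficient tables are a placeholder and a synthetic
  illustration; clinical use requires the published coefficient sets as
  config.
- The planner's minimality is relative to its documented escalation order
  and grid; it does not optimise over materials or search all plan
  combinations.
- Composite repairs (a second intraperitoneal mesh in sandwich position)
  have no combined GRIP model here, as their coefficients are not
  established.
- The instability stage is 2-D and registration-free by design.
- The generator matches marginal cells only; see above.
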