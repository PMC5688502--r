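---
title: "Methods: modelling the mortality cost of coverage inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the mortality cost of coverage inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equilist)
```

## The question the package answers

In most low-income countries the richest fifth of households receives
markedly better maternal, newborn and child health (MNCH) intervention
coverage than the national average. `equilist` quantifies what that gap
costs in child lives: it raises each intervention's national coverage to
the level already enjoyed by the top wealth quintile (a level that is, by
construction, attainable within the country) and runs a deterministic
coverage-to-mortality model to count the deaths this would avert.

## Inequality ratios and scenarios

For an intervention with national coverage $c$ and top-quintile coverage
$q_5$, the *inequality ratio* is $\rho = q_5 / c$. Raw ratios are reported
unfloored — pro-poor interventions such as mass-distributed bednets
genuinely average below 1 — but the *applied* ratio used to build
scenarios is $\max(\rho, 1)$: the scale-up scenario never lowers
coverage. The target coverage is

$$c^\* = \min(c \cdot \max(\rho, 1),\; 1),$$

capped at 1 because a ratio estimated from an older survey multiplied
into a newer national rate can exceed 100%; the cap is the only coherent
choice for a proportion.

Household surveys measure only 18 of the catalog's indicators directly.
The remaining interventions are reached through the delivery structure:

* **Linked components** (antenatal-care and childbirth packages such as
  neonatal resuscitation or syphilis screening) are driven by their
  measured contact point: they inherit the parent's coverage pair in the
  engine, and hence its ratio.
* **Proxied interventions** (e.g. newer vaccines proxied by DPT, zinc
  proxied by ORS) borrow the resolved ratio of a co-delivered measured
  indicator, on the argument that co-delivered services share an access
  gradient.
* **Backups** cover surveys that lack a normally-measured indicator: the
  ratio of a single designated substitute is used. Backup chains resolve
  exactly one level deep — the catalog never specifies a chain — and
  flooring is applied *after* resolution, so a sub-1 source ratio
  propagates as sub-1 and is floored once at the end.

A *full* analysis scales all catalog interventions; a *limited* analysis
scales only directly measured indicators and their linked components,
excluding proxied items, and serves as the conservative lower bound. A
*single* scenario scales one intervention alone (the equity-tool view);
coverage-only parents are ranked as bundles that move their linked
children, because the engine always drives linked components from the
parent's coverage — a solo scenario for a linked child would be inert by
construction, so the ranking never builds one.

## The impact engine

Baseline deaths in each (age band, cause) cell are
$D_0 = B_0 \cdot m / 1000 \cdot f$, with $B_0$ annual live births, $m$
the band's mortality rate per 1000 live births (neonatal or 1–59 months)
and $f$ the cause fraction. Interventions affecting a cell combine
multiplicatively through the residual

$$R(\mathbf{c}) = \prod_i \left(1 - E_i \, A_i \, c_i\right),$$

where $E_i$ is effectiveness, $A_i$ the affected fraction and $c_i$
coverage. Because baseline deaths already embody baseline coverage, only
the *change* in the residual acts:

$$D_1 = D_0 \cdot \frac{B_1}{B_0} \cdot \frac{R(\mathbf{c}_1)}{R(\mathbf{c}_0)}.$$

This normalised multiplicative form is fixed explicitly here as the
standard convention for this family of cohort models; it makes
simultaneous scale-up free of double-counting and is the form all oracle
tests check against.

Scaling contraceptive prevalence from $u_0$ to $u_1$ with
use-effectiveness $e$ rescales the birth cohort,
$B_1 = B_0 (1 - u_1 e)/(1 - u_0 e)$ — the ratio of unprotected fecund
exposure — and is applied as a pure cohort scaling; no age-structured
projection is attempted over the two-point (baseline year, scale-up
year) horizon, which the scenario design fixes. Contraception is scaled
only where baseline fertility exceeds the replacement rate of 2.33
children per woman.

**Attribution.** Reported lives saved per intervention must sum to the
total. The cohort slice of each cell's savings, $D_0 (1 - B_1/B_0)$, is
attributed to contraceptive prevalence; the remainder is split across
the interventions affecting the cell in proportion to their solo
log-impacts

$$w_i = \log\frac{1 - E_i A_i c_{0i}}{1 - E_i A_i c_{1i}} \ge 0.$$

A proportional rule on log scale was chosen over sequential attribution
because it is order-independent (the residual is a product, so permuting
interventions cannot change any reported number — a testable property),
conserves the total exactly, and gives zero to interventions with
$E A = 0$ or unchanged coverage.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `fertility_gate` | children/woman | 2.33 | replacement fertility; below it, fewer births is not treated as lives saved |
| `cpr_effectiveness` | proportion | 0.9 | use-effectiveness of contraception in the cohort formula |
| effectiveness × affected fraction | proportions | catalog file | per cause and age band; shipped values are plausible defaults, **not** authoritative estimates — override with `read_catalog()` |
| `gradient_scale` | logit units | 0.4 | half-normal scale of the simulated wealth gradient; 0.4 reproduces the 1.1–1.8 range of ratios typical of survey compendia |
| `missingness_prob` | probability | 0.1 | share of indicators a simulated survey fails to measure |

The catalog requires $E_i A_i < 1 - 10^{-12}$: a product of 1 at full
coverage would eliminate a cause entirely and divide by zero in the
residual normalisation.

## What the synthetic generator does and does not emulate

The generator stands in for wealth-quintile tabulations of household
surveys. Per country and intervention it draws a logit-scale intercept
uniformly over the anchor coverage range and a half-normal wealth
gradient; quintile coverage is the inverse-logit of a line in quintile
rank, so it is monotone in wealth, and national coverage is the
unweighted quintile mean (quintiles are population fifths). Bednets are
sign-flipped pro-poor by default, mirroring the one indicator whose
ratio tends to fall below 1. With the stated probability an
intervention's five quintile values are blanked while the national value
is retained — the analogue of a survey lacking an indicator while
preloaded national data still exist — which is precisely the situation
backup resolution is for.

It does **not** simulate survey design (clustering, weights, sampling
error), correlation between intervention coverages within a country,
secular coverage trends, or any relation between coverage and the
mortality rates. Passing tests therefore demonstrate the correctness of
the pipeline's logic under controlled inequality structure, not the
accuracy of any country estimate; headline percentages computed on
synthetic compendia are expected to fall in the published 20–50% band
only directionally.

Problem sizes used in the shipped checks were chosen at desk scale: the
acceptance run uses a 98-country compendium (the size of a full survey
compendium analysis), property suites use 500–1000 randomized 2–4
intervention models, and the end-to-end determinism check uses 10
countries.

## Numerical and degenerate-input choices

* Missing coverage is a distinct state from zero everywhere upstream of
  scenario construction; only when a scenario is materialised does a
  missing national baseline become 0 (and is logged), which keeps the
  intervention inert rather than inventing coverage.
* A national coverage of exactly 0 leaves the ratio undefined (`NA` with
  a note), not infinite.
* Ratio resolution, scenarios and all outputs are deterministic
  functions of their inputs; ties in rankings and league tables break
  alphabetically by intervention id.
* Aggregate percentages are computed from summed deaths, so the
  under-five percentage is the death-weighted mean of the band
  percentages and always lies between them.

## Known limitations

Maternal deaths and stillbirths are outside the model's outcome set;
nutrition-status risk-factor pathways (stunting, wasting, breastfeeding
patterns) are not modelled; intervention interactions beyond the
multiplicative residual (herd effects, diminishing returns) are ignored;
and ratios estimated from older surveys are assumed still to apply at
baseline, which overstates impact where inequality has since narrowed —
the `min_survey_year` filter exists to probe that sensitivity.
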