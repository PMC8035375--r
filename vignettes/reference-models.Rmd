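---
title: "Modelling reference conditions of boreal forest age structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reference conditions of boreal forest age structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealNRV)
```

## The problem

Conservation and "closer-to-nature" forestry in the boreal zone need a
quantitative baseline: what mix of forest ages and disturbance dynamics would
a landscape carry under a natural disturbance regime? `borealNRV` implements
two contrasting answers for Fennoscandian conditions and the calculations
that hang off them — equilibrium age-class mathematics, a 3×3 reference
matrix, a site-type bottom-up estimator, reserve-need arithmetic, a
stochastic stand simulator used as an independent check, and a management
planner that projects a harvested landscape toward the reference.

## Equilibrium age-class mathematics

The classical view treats all disturbance as stand-replacing fire arriving
with constant hazard. If the mean return interval (fire cycle) is $\lambda$,
the equilibrium fraction of forest aged at least $t$ years is the
survivorship

$$S(t) = e^{-t/\lambda}
\qquad\text{(negative exponential)},$$

or, allowing a non-constant hazard,

$$S(t) = e^{-(t/b)^c}
\qquad\text{(Weibull, shape } c\text{)},$$

where the scale $b$ is always derived so that the interval distribution's
mean equals $\lambda$: $b = \lambda / \Gamma(1 + 1/c)$. A shape of 1
recovers the exponential exactly. Under a 50-year cycle only
$e^{-2} \approx 13.5\%$ of forest exceeds 100 years, and $1 - e^{-1}
\approx 63.2\%$ of intervals are shorter than the cycle itself — the
arithmetic behind the old belief that natural boreal landscapes are
young-forest landscapes.

```{r}
survivor_fraction(disturbance_regime("negative_exponential", 50), 100)
```

Bin shares over an age-class scheme are survivorship differences
(`age_class_shares()`), distributions can be mixed (`average_distributions()`)
and re-binned (`rebin()`). Re-binning assumes ages are uniform within each
bounded class; the unbounded "old" class cannot be split, and `rebin()`
refuses boundaries inside it rather than inventing information.

Two numerical notes. The Weibull shape used in earlier regional analyses is
not published; the package default is 2 (a moderately peaked interval
distribution), always configurable, and `asio_sensitivity_scan()` treats it
as a scan parameter rather than a known constant. Second, the fraction of
intervals below the mean does *not* tend to 0.5 as the Weibull concentrates:
the mean sits about $\gamma/c$ below the concentration point while the spread
shrinks as $1/c$, so the fraction tends to $1 - e^{-e^{-\gamma}} \approx
0.43$ — the package computes it exactly and the test suite checks that limit
against Monte-Carlo sampling of intervals.

## The revised reference matrix

Current evidence gives non-stand-replacing dynamics a far larger role than
the fire-cycle view did. The revised model is top-down: it fixes the
age-class marginals (young 0–74, mid-aged 75–149, old ≥ 150 years at
25 / 25 / 50% — old forest dominant) and equal thirds for the three dynamics
types — gap (GD), even-aged (ED) and cohort (CD) dynamics. Within each of
the GD and CD thirds, two thirds of the area sits in old forest; the
remainder is split between young and mid-aged classes in proportion to the
class age midpoints (37.5 : 112.5 = 1 : 3), which operationalises "increasing
linearly with age". ED takes each age class's residual, and therefore
declines with age. This is the only allocation rule we found that reproduces
all nine published cells:

```{r}
m <- build_revised_matrix()
m
```

The marginal identities (rows reproduce the age marginals, columns the
dynamics thirds), the monotone GD/CD-increase and ED-decrease, and
non-negativity (with an informative error when marginals make the residual
negative) are enforced and tested. The construction requires the old share
to be at least each non-old share — outside that regime the "old forests
dominate" premise no longer holds and the midpoint rule is not meaningful.

## The bottom-up (ASIO-style) estimate

The older bottom-up logic assumes one dynamics type per major site type:
even-aged dynamics on mesic–rich sites (73% of the case region), gap
dynamics on moist–wet (14%) and cohort dynamics on dry–poor sites (13%; only
the 27% sum is published — the 14/13 split is a package default). ED area
receives the average of the negative-exponential and mean-matched Weibull
equilibrium distributions at a 100-year return interval; GD/CD area receives
an old-leaning profile, by default 30 / 10 / 60% over 0–109 / 110–149 /
≥ 150 years. That profile is a declared assumption: the original appendix
parameterisation is not recoverable, which is why `asio_sensitivity_scan()`
reports the ≥ 110-year share across Weibull shapes 1.5–3 instead of a point
value.

```{r}
asio_bottom_up()
asio_sensitivity_scan()
```

A caveat worth stating plainly: with any old-leaning non-replacing profile,
the mesic ED block alone contributes about 24 points to the ≥ 110-year
share, so this reconstruction yields ~44–46% rather than the historically
reported 36% — the two published aggregates for this estimator are not
mutually consistent with its published construction, and the package
reports what the stated construction actually implies.

## Reserve need

Forest that conventional rotation forestry cannot reproduce is "management
incompatible": everything at or above the final-felling age (110 years,
inclusive), optionally plus younger forest maintained by gap or cohort
dynamics. The reserve need is a fixed fraction (20%) of that share. Under
the revised matrix the ≥ 110-year share is 63.3% (young 37%, mid-aged 13%,
old 50% after re-binning at 110), giving 12.7% ≈ 13%; including younger
GD/CD forest raises the incompatible share to 76.7% and the need to
15.3% ≈ 15%. Full precision is kept internally; rounding to whole percent
happens only at display.

```{r}
reserve_estimate(m, compatibility_rule())
reserve_estimate(m, compatibility_rule(include_gap_cohort_younger = TRUE))
```

## The stand-level simulator as an independent check

`simulate_landscape()` evolves independent stands with annual Bernoulli
events in three severity classes — stand-replacing (kills everything),
partial (killed fraction 0.25–0.75) and gap (< 0.25) — at most one event per
stand-year, highest severity first. Stand-replacing events reset the cohort
list; others add a cohort and scale the survivors. "Forest age" is the
dominant-cohort age; because survivors are scaled uniformly, their ranking
never changes, so dominance transfers exactly when a new cohort exceeds
every survivor. Cohorts below $10^{-4}$ are pruned and fractions
renormalised.

The simulator's purpose is oracle duty: with stand-replacing events alone at
hazard $1/\lambda$, the stationary dominant-age distribution must converge
to $e^{-t/\lambda}$, and `equilibrium_check()` scores the simulated shares
in binomial standard errors. At $10^4$ stands and a 1 000-year burn-in the
match is well within 3 SEs. A consequence of the dominance-transfer rule
worth knowing: partial events with killed fraction ≥ 0.5 always take
dominance, so dominant-cohort age turns over faster than time since stand
replacement; the stable indicator of old forest under mixed-severity
regimes is time since the last stand-replacing event, which the simulator
also records (`last_sr_year`).

Burn-in defaults to ten times the longest mean return interval; identical
seeds give bit-identical trajectories.

## The management planner

`build_plan()` expands the matrix into nine (age class × cutting method)
records via the fixed bijection GD→gap/selection cutting, ED→clear-cutting
with retention, CD→partial cutting, so each method covers its dynamics
third. Young records carry a 75-year rotation with a 40-year target mean
age; gap/partial records carry cutting cycles removing 20–30% of area every
20–30 years. The published table omits the mid- and old-class rotations; the
package defaults are 150 years (target mean 112) and continuous cover with a
300-year reference rotation, both configurable.

`project_managed()` schedules stand-replacing harvests as a landscape-level
conveyor rather than nine independent rotations, for a structural reason: an
area held on a 150-year rotation spends half its time young, so per-record
rotations cannot keep the 25/25/50 marginals in place. Instead, every stand
reaching the conveyor length (the old-class reference rotation, 300 years)
is felled, and when the young class drops below its target an additional
harvest restores it exactly, taken oldest-first while classes below their
target share are protected. A landscape with ages uniform over the conveyor
has exactly the 25/25/50 marginals and is a fixed point of this schedule up
to stand discretization (total-variation wobble below 0.02 at 5 000 stands).
Starting from the managed case-study state (78/13/9 over 0–109/110–149/
≥ 150), the distance to the reference declines steadily and reaches the
discretization floor within roughly two young rotations. Partial-cut cycles
are carried on the plan records but deliberately do not reset dominant age.
`disturbance_adjustment()` credits naturally disturbed area against the
matching cells (severity mapped through the method bijection), logging the
reduction.

## Synthetic inventory data

No stand-level inventory data are shipped; `generate_landscape()` draws a
stand table matching the case-study marginals — site types 73/14/13%, age
classes 78/13/9%, log-normal areas with a 10-ha median — with site type and
age drawn independently (the real joint site-by-age structure is not
published, so it is deliberately not emulated; tests that pass on these
tables say nothing about site-age correlation effects).
`generate_natural_landscape()` inverts the reference matrix for round-trip
tests (`estimate_reference_matrix()` recovers the cells to within one
point at $10^4$ stands); it uses equal stand areas because the matrix is an
area-share object. Where a concrete age inside the unbounded old class is
needed, ages are drawn uniformly on [150, 300], matching the conveyor
length so that reference-initialized landscapes are stationary under the
default plan.

## Problem sizes and determinism

The shipped tests run the simulator at 2 000–10 000 stands with burn-ins of
150–1 000 years, the projector at 2 000–5 000 stands over 150–300 years, and
the generators at up to 2 × 10^4 stands — sizes at which binomial error is
well below the tolerances being asserted while the whole suite stays fast.
Every stochastic path takes an explicit integer seed and is bit-reproducible.

## Limitations

* Equilibrium only: no transient age distributions under changing regimes,
  and no fitting of regime parameters to data.
* The simulator is non-spatial — no fire spread, contagion or stand-size
  dynamics; its role needs only marginal hazards.
* Severity-class hazards for the illustrative mixed regimes are not
  calibrated to any landscape.
* The bottom-up estimator's non-replacing profile and Weibull shape are
  assumptions, surfaced as scan parameters, not estimates.
* Economic outputs (timber volume, retention counts) are out of scope.
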