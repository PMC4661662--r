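---
title: "Variable-catchment floating catchment area accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-catchment floating catchment area accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchaccess)
```

## The measurement problem

A bare supply-to-demand ratio inside an administrative boundary hides
where people actually travel: demand crosses boundaries, and a facility
with 30 beds cannot serve the same radius as one with 500. Floating
catchment area (FCA) methods replace the boundary with a travel-time
window "floating" over every supply and demand point. The two-step
scheme first discounts each facility's capacity by the population able
to reach it, then sums those discounted ratios over the facilities each
population point can reach; the result $A_j$ is in beds per person.

Fixed-radius 2SFCA assigns every site the same window. That fails in
two directions this package addresses:

* **Catchment size should depend on capacity as well as density.** The
  V2SFCA baseline grows a facility's window until a fixed base
  population BP is reached — so a 30-bed home and a 500-bed complex in
  the same suburb get identical catchments. The enhanced method
  (EV2SFCA) grows the window until the facility-to-population ratio
  $S_i / \sum_{d_{ji} \le t} P_j$ *falls to* a threshold
  $\mathrm{FPRT}_1$: more beds or thinner population ⇒ a larger
  catchment.
* **Mismatched catchments over-count interaction.** With one-sided
  containment, a population point sits inside a distant facility's
  large catchment even when its own small catchment excludes that
  facility (it would not travel there), and vice versa. EV2SFCA scores
  only pairs with $d_{ji} \le C_i$ **and** $d_{ji} \le C_j$. The
  `generate_figure1_system()` fixtures encode both failure modes as
  testable micro-systems.

The four steps, with $\omega$ a distance-decay weight:

$$D_i = \frac{S_i}{\sum_{j \in \{d_{ji}\le C_i \,\cap\, d_{ji}\le C_j\}} P_j\,\omega_{ji}},
\qquad
A_j = \sum_{i \in \{d_{ij}\le C_i \,\cap\, d_{ij}\le C_j\}} D_i\,\omega_{ij}.$$

Steps 1–2 (the catchment searches) use **unweighted** sums; decay
enters only in steps 3–4, which is where the defining equations place
$\omega$.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `t0` | 5 min | first window of the search grid |
| `dt` | 1 min | grid increment |
| `t_max` | 120 min | travel cap; unreachable beyond, searches stop here |
| `fprt1` | 135/50 000 | step-1 stop: beds per reachable person |
| `fprt2` | 30/1000 | step-2 target: beds per person provision level |
| `base_population` (V2SFCA) | 50 000 | step-1 base population |
| `ppr` (V2SFCA) | 30/1000 | step-2 target ratio |
| `decay` | Gaussian $\beta = 1$ (EV2SFCA), stepwise (V2SFCA) | weight family |

The threshold defaults encode a concrete planning standard: an average
facility holds about 135 beds and draws on roughly 50 000 elders within
a 20-minute drive (hence 135/50 000 beds per person), and the
provision norm is 30 beds per 1 000 elders. `fprt1` and `fprt2` are
the two knobs an analyst should localise; `sensitivity_sweep()` makes
their effect visible — smaller `fprt1` grows facility catchments and
lowers scores, larger `fprt2` grows population catchments.

## Numerical conventions

These choices are deliberate, documented, and covered by tests:

* **Inclusive comparisons everywhere.** Distance eligibility is
  $d \le t$ and $d \le C$; the step-1 search stops at
  $\mathrm{FPR} \le \mathrm{FPRT}_1$ and step-2 at
  $\sum \mathrm{FPR} \ge \mathrm{FPRT}_2$. The prose formulations of
  such stopping rules are ambiguous at equality; equality here counts
  as attainment. `strict_thresholds = TRUE` flips all four to strict.
* **Cap rule.** A search that never meets its criterion stops at
  `t_max` with `capped = TRUE`; the site is kept, not dropped.
* **Empty windows.** A facility whose catchment contains no population
  has an undefined ratio, stored as the `Inf` sentinel: it always
  exceeds $\mathrm{FPRT}_1$ (the search keeps growing) and satisfies a
  population's target the moment it enters the window. A warning
  flags such degenerate facilities.
* **Grid discipline.** Every uncapped catchment lies on
  $\{t_0 + k\,\Delta t\}$; batch and per-site computations are
  verified equal, and the incremental search is tested against a
  brute-force scan of every grid point.
* **Deterministic order.** Sites are processed sorted by id; outputs
  are bit-reproducible.

### The decay weight

Only the *family* of the decay ("Gaussian") and $\beta = 1$ are fixed
by convention; a Gaussian on raw minutes with $\beta = 1$ would be
degenerate (it dies within a couple of minutes), so the package uses
the catchment-normalised truncated form standard in the FCA
literature:

$$\omega(d, C) = \left[\frac{e^{-d^2/(2C^2)} - e^{-1/2}}{1 - e^{-1/2}}\right]^\beta,$$

equal to 1 at the origin, continuously 0 at the catchment edge, 0
beyond, non-decreasing in $C$, and steeper for larger $\beta$. The
unnormalised kernel $e^{-d^2/\beta}$ is available as `form = "raw"`
for experimenting with impedance-coefficient conventions. The
stepwise scheme splits the catchment into equal zones with weights
(1.00, 0.42, 0.03); zone intervals are half-open $(lo, hi]$ so a
boundary time takes the inner zone's weight (a 45-min catchment puts
15 min in zone 1, 30 min in zone 2).

### Weight parametrisation and conservation

The defining equations write $\omega_{ji}$ and $\omega_{ij}$ without
fixing which catchment scales the weight. The default follows the
usual 2SFCA reading — step 3 uses the facility's $C_i$, step 4 the
population's $C_j$. The alternative `weight_param = "symmetric_min"`
uses $\min(C_i, C_j)$ in both. The distinction matters for the
bookkeeping identity
$\sum_j P_j A_j = \sum_{i\,\mathrm{served}} S_i$: substituting the
$D_i$ sum into the $A_j$ sum telescopes exactly when each pair carries
the same weight in both equations (pair-symmetric weights: `none`
decay under the mutual constraint, or `symmetric_min`). With
own-catchment weights and unequal catchments the identity fails by
design; `conservation_check()` reports the ratio as a diagnostic
rather than asserting it. One residual degeneracy is worth knowing: a
facility whose every eligible pair sits exactly at distance
$\min(C_i, C_j)$ has Gaussian weight 0 there, serves nobody
($D_i = 0$) while still counting as served, and shifts the ratio; the
positive-everywhere stepwise weights avoid this.

Under one-sided containment (the V2SFCA scoring), step 3 and step 4
run over *different* pair sets, so no conservation identity is
expected at all — one of the reasons mismatched catchments
systematically redistribute apparent supply.

## Travel times

`od_from_network()` stands in for a commercial OD-cost-matrix tool:
sites snap to their nearest network node (Euclidean, zero access
cost — the simplest defensible convention, stated so OD files are
reproducible), edge minutes are `length / speed` with class speeds
60/50/40/30 km/h, and Dijkstra shortest paths give one undirected time
per pair, truncated at `t_max`. No one-way streets, turn penalties or
congestion; if your travel times come from a richer router, feed them
in as the long-format `od.csv` instead.

## The synthetic city

`generate_city()` builds the test-bed the package validates itself on:
a monocentric city with population density
$\rho(r) = \rho_0 e^{-r/\tau}$ on a jittered grid clipped to a disk,
center-biased facility placement, truncated-Pareto capacities drawn
**independently of location**, and a square road grid whose class
improves toward the center. Exponential decay is the simplest
monocentric density model; capacity-location independence ensures the
capacity–catchment correlation test isolates the algorithm rather than
a generator artifact.

Defaults are scaled to the same planning standard as the thresholds:
200 demand points and 20 facilities in a 20 km radius,
$\rho_0 = 2700$ and $\tau = 8$ km giving ≈125 000 elders with ≈50 000
within 20 minutes of an average facility, and capacities 30–1000 beds
(Pareto shape 0.7, mean ≈140). On this city the expected qualitative
patterns emerge and are asserted in the test suite: facility
catchments rank-correlate with capacity (while V2SFCA supply
catchments are provably capacity-invariant), and both facility and
population catchments are smaller in the dense core than in the
periphery.

What the generator does *not* emulate: multi-centric density, real
street topology, capacity clustering by land price, unreachable
islands, demand heterogeneity beyond counts. Passing tests on this
city demonstrate algorithmic correctness and directionally right
behavior, not calibration to any real region.

A caveat on significance at this scale: with only 20 facilities a
rank-correlation test has limited power, and a single draw can place
its few largest facilities in the dense core where fast population
accumulation masks the capacity effect; the default seed-1 draw does
exactly that (rho ≈ 0.36, two-sided p ≈ 0.11, against p < 0.01 for
the large majority of seeds). The suite asserts the property at the
fixed default city rather than cherry-picking a seed, so that check
documents honest marginality instead of hiding it.

## Problem sizes used in validation

The test suite enumerates the worked 2×2 instance by hand, checks
stopping-rule bracketing on 500 randomized small instances, matches an
independent brute-force implementation on 100 instances up to 5×5 to
1e-12, and exercises the full pipeline plus conservation on the
default 20×200 city — sizes chosen so every algebraic property is
checked exhaustively where exhaustive checking is possible, while the
city run exercises the vectorised batch paths at realistic shape.

## Known limitations

* Accessibility scores are relative screening quantities; non-spatial
  access factors (fees, income, staffing) are out of scope.
* Demand competition refinements (three-step FCA, Huff-style choice
  probabilities, kernel-density decay) are not implemented.
* Step 2 sums saved facility ratios unweighted; whether those summands
  should themselves be distance-discounted is a genuine modelling
  fork, taken here on the side the step definitions state. A capped
  facility's ratio enters step 2 at its cap value.
* Coordinates are assumed projected planar meters; reproject before
  input.
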