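---
title: "Bio-economic modelling of beef production systems with beefsys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bio-economic modelling of beef production systems with beefsys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beefsys)
```

## The model

`beefsys` is an annual, single-farm bio-economic model for European beef
production. A farm is described declaratively (land endowments, stable
capacity, a herd specification, activity catalogues, prices, subsidies) and
solved as a linear programme: choose crop and grassland activity areas, the
herd scale, monthly rations per animal class, feed purchases and sales, and
mineral fertilizer, to maximise annual profit. On top of the optimum the
package computes four sustainability indicators — cradle-to-farm-gate
global warming potential (GWP) per kg beef carcass, net human-edible
protein (HEP) efficiency, work time per kg carcass, and farm profit — plus
the stocking rate on permanent grassland, and provides scenario transforms
(fast rotational grazing, FRG; system redesign with dairy-beef
crossbreeding and sexed semen, SR) and a Latin-Hypercube sensitivity
analysis.

The synthetic fixtures cover three stylised systems: a Belgian Blue
breeder/fattener pair (BE), a French suckler farm shipping weanlings to an
Italian fattener (FR-IT), and an integrated German dairy/cash-crop farm
fattening its own male calves (GE). Published endowments are carried
verbatim (155 cows and 78 male weanlings on 54 + 64 ha in BE; 79 cows, 38
weanlings, 96 ha grassland in FR-IT; 130 cows, 56 bulls, 198 + 27 ha in
GE; annual grazed yields of 8.0/4.0/9.0 t DM/ha rising to 9.0/4.4/9.9
under FRG with 1.9/0.9/2.1 t/ha crude protein; an FRG cost premium of
37.5 EUR/ha and 10 % more pasture work; redesign animals sold at 19 mo /
330 kg / 3.4 EUR per kg carcass in BE, 14 mo / 300 kg / 4.18 in FR-IT,
21 mo / 413 kg / 3.8 in GE). Everything else — feed composition,
requirement coefficients, emission factors, prices not published — is a
documented package default. Absolute profit and GWP levels are therefore
illustrative; the machinery, conservation laws and qualitative scenario
responses are the object of the tests.

## Herd demographics

The herd is an average-year, steady-state population: calvings and cohort
entries are spread uniformly over the calendar year, so monthly stocks are
constant, each month's entries equal its exits, and December closes onto
January exactly. Head counts are continuous, in the linear-programming
tradition — a herd is an activity level, not a set of integer animals —
which keeps the whole model linear and the dual values well defined.

One demographic convention deserves a note. The BE fixture sells 78 male
weanlings from 155 cows per year, which implies slightly more than one
weaned calf per cow place. The fixture therefore stores weaned output per
cow place directly (`calves_weaned_per_cow` ≈ 1.007), reading it as the
net productivity of the cow enterprise including calvings of first-calf
heifers that have not yet entered the mature herd. This makes
`cohort_progression()` reproduce the published sale counts exactly instead
of approximating them from a calving-rate chain whose components were not
published.

Requirements are linear in live weight: ME (MJ/d) =
0.105·W + 30·ADG + 5.3·milk, CP (g/d) = 0.6·W + 300·ADG + 85·milk, and an
intake capacity of 0.021·W + 0.32·milk fill units per day, with each feed
carrying a fill value per kg DM. These are deliberately simple,
configurable stand-ins for a full feed-evaluation system; linearity makes
the cohort-mean animal exactly representative, so the optimizer can work
with one requirement row per class and month. Suckler calves' requirements
are net of the milk received from their dam; the dam carries the
corresponding lactation requirement.

## The optimization model

The LP contains, per farm: land balances for arable land and permanent
grassland; a stable-capacity constraint in livestock-unit places; for
every class and month a fill-weighted intake ceiling, ME and CP balances
and a fibre floor (minimum forage share of ration DM); month-by-month
availability of grazed grass (growth not eaten in its month is lost, so
grazing is "use it or lose it", while cut forage and grains flow through
storable annual pools); an optional cap on the supply of purchased
animals; and a nitrogen balance in which nutrient removal by crops and by
consumed or harvested grass must be covered by stable manure (after
storage losses), the plant-available fraction of pasture-deposited
excreta, and purchased mineral N. Supplementary feeding on pasture is
always possible. Grassland nitrogen removal follows the grass actually
consumed or cut, not the area, so partially used swards do not demand
fertilizer for growth nobody harvested.

Distribution of conserved feed costs 12 EUR/t DM (machinery and diesel);
grazed grass is self-harvested. This term is what makes grazing the
cheapest feed in season and lets the model reproduce the economics of
rotational grazing adoption.

The solver is a dense two-phase primal simplex written for this package,
returning the dual value of every row. Vertex enumeration on small random
programmes serves as an independent correctness oracle in the test suite,
and dual values are validated against finite-difference sensitivities and
textbook identities (a binding purchase balance prices a commodity at its
market price). Tolerances: 1e-9 on pivoting, Dantzig pricing with a Bland
fallback for anti-cycling; solutions are reported through the objective,
with activity levels documented as possibly non-unique at degenerate
optima.

Labor is accounted for the work-time indicator but is not a constraint —
the study design treats work time as an indicator, not a limit.

## Emissions, allocation, and transfers

The inventory covers enteric CH4 (Tier-2 form, CH4 = GE·Ym/55.65 with Ym
= 6.5 %), manure-storage CH4 and N2O with distinct solid (BE, FR-IT) and
liquid (GE) factor sets, direct and indirect soil N2O at IPCC-style
default factors (1 % of applied or deposited N, with configurable
volatilisation and leaching fractions), on-farm diesel CO2, and upstream
CO2eq of purchased inputs from a small synthetic emission-factor table.
Gross energy intake rides on ration dry matter at a fixed 18.45 MJ/kg DM:
at equal energy supplied, a denser (higher-ME) ration means less DM and
therefore less methane, which is the mechanism by which better pasture
quality lowers enteric emissions. Characterization uses GWP100-style
factors (CH4 34, N2O 298), configurable.

Excreted nitrogen is intake minus retention (mass balance closed to
numerical precision) and splits between pasture and stable in proportion
to grazing days; grazing days are defined as days-in-month times the
grazed share of ration DM, which makes the standalone function and the
optimizer's per-feed attribution coincide exactly.

Farms that sell milk allocate their burden economically between milk and
beef (value shares, summing to one, shadow-priced when no market price
exists). Farms that sell live animals downstream pass the value share of
those animals as an embodied emission factor per kg live weight; the
receiving farm books it among purchased inputs. Summed over a
breeder–fattener chain this conserves the system total exactly — no double
counting, no loss — and the same construction carries embodied work time.
In the BE redesign the modelled 70-cow dairy supplies the calf type while
the growing-fattening farm may buy further calves of the same price and
origin profile on the market; only within-system heads are netted out of
the system total, so market calves keep their embodied burden like any
purchased input.

## Indicators

Net HEP efficiency is edible protein in beef output (carcass ×
0.138 kg protein/kg × 0.80 edible) divided by edible protein in the feed
used for beef (ration DM × CP × feed-specific edible fraction — 0.8 for
cereal grains, 0.65 for soymeal, 0.9 for milk powder, 0 for forages and
pressed beet pulp — times the beef allocation share on dairy farms). A
ration of grass and by-products has zero edible input; the indicator then
returns the sentinel `Inf`, a net contribution to human nutrition rather
than an error. Work time per kg sums feeding (0.8 h/t DM distributed),
caretaking, calving, pasture management (10 % dearer under FRG),
feed-related fieldwork and administration; the breakdown sums to the total
exactly. Profit is decomposed into the published revenue and cost lines
and must match the LP objective to 1e-6 relative — an identity check, not
a second model.

## Sensitivity analysis

`lhs_design()` draws 100 Latin-Hypercube samples (uniform, uncorrelated)
of three multipliers: stable capacity ±20 %, FRG grassland yield ±10 %,
bull slaughter age ±10 %. The slaughter-age multiplier is rounded to whole
months (the model's grid) with exit weight following the class's daily
gain; the yield multiplier touches only the FRG sward, leaving baseline
grassland alone (the ambiguity is resolved in favour of the
scenario-specific reading; the helper is configurable). Each draw re-runs
the full farm optimization; failed draws are flagged and counted, never
dropped silently. The HEP–stocking-rate relation is summarised by a
Spearman rank correlation; the package's fixture family with growing herd
size at fixed grassland (the integrated dairy farm under rising stable
capacity) reproduces the negative association: more animals per hectare
of grassland pull more human-edible feed into the ration while output
grows only proportionally.

## Problem sizes and numerical choices

The farm programmes have roughly 150–250 rows and 180–280 columns and
solve in well under a second each; the test suite re-optimizes a few dozen
farms and the acceptance script about fifty (including a 25-draw
sensitivity run), which keeps a full run in the tens of seconds on one
core. Conservation tests assert closure to 1e-9 relative error, LP
correctness to 1e-8 against enumeration, and the profit identity to 1e-6.
Degenerate inputs are handled explicitly: empty herds solve (crops-only
farms), zero carcass output makes work-time-per-kg an error and HEP a
sentinel, infeasible demography (selling more animals than flow through a
cohort) and missing prices or emission factors fail fast with named
culprits.

## What the fixtures do and do not show

The generator emulates the structure of the three systems — herd
architecture, land endowments, seasonal grass growth, scenario deltas —
with every published number carried exactly and the remainder set once to
field-plausible defaults. It does not emulate weather-driven grass growth,
multi-year dynamics (droughts, price cycles), genetic variation, or the
confidential accountancy data behind the original parameterization, and
its upstream emission factors are synthetic. Passing tests therefore
demonstrate that the machinery is correct and that the qualitative
scenario responses (FRG raises profit and work time; milk allocation
dilutes beef GWP; redesigns shift slaughter parameters as specified)
follow from the stated mechanisms — not that the absolute indicator levels
of any real farm are reproduced.

## A worked run

```{r, eval = FALSE}
res_base <- run_pipeline("BE", "base", seed = 1)
res_frg  <- run_pipeline("BE", "FRG",  seed = 1)
report_run(res_frg, baseline = res_base)$deltas
```
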