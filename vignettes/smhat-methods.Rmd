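---
title: "Scoring school food provision: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring school food provision: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smhat)
```

## The instrument

`smhat` audits school food provision with a content-analysis instrument:
a codebook of food-based items, each carrying a scoring rule, applied
week by week to a rotational menu cycle. The instrument deliberately
works at the level of foods named on a menu — "is fruit available every
day?", "is milk specified as semi-skimmed?" — not nutrients, so it needs
no dietary-analysis software and no cooperation from caterers beyond a
published menu.

Three design commitments shape everything else:

1. **The codebook is data.** Items, categories, rules, tags and maxima
   live in a YAML file (`inst/extdata/codebooks/`). The engine knows four
   rule *kinds* and nothing about any particular criterion, so a revised
   instrument — say, after a school-food-standards update — is a config
   change, not a code change.
2. **Absence is informative and distinct from failure.** A menu that
   never mentions red meat tells the coder nothing about red-meat
   frequency; the item rates `'A'`, not 0 and not 1. A menu that offers
   plain milk but never specifies the fat content *has* been observed to
   miss the lower-fat criterion and rates 0. Each item therefore carries
   two tag sets: `required_tags` (what the criterion demands) and
   `relevant_tags` (what makes the item "mentioned" at all).
3. **Fixed maxima.** `'A'` contributes 0 to week totals and the
   denominator never shrinks, so the primary instrument always scores out
   of 22 and the secondary out of 28. Completeness is reported alongside
   the score rather than folded into it.

### Rule kinds and their score sets

| kind | permitted scores | semantics |
|------|------------------|-----------|
| `binary` | A, 0, 1 | met at least once this week (optionally by `min_distinct` distinctly named offerings) |
| `per_day` | A, 0, 0.2, …, 1.0 | fraction of the 5 school days met |
| `limit` | A, 0, 1 | weekly occurrences ≤ `limit_max` |
| `frequency_per_period` | A, 0, 1 | cycle-wide count ≥ pro-rated threshold |

Two per-item switches extend the kinds where tags alone cannot express a
criterion:

* `absent_credit` (limit rules). For prohibitions — "no confectionery or
  crisps", "salt not freely available" — absence *is* compliance, so the
  item scores 1 rather than `'A'` when the class never appears. Without
  this, a flawless menu could never attain the instrument maximum. For
  consumption limits (red meat, processed meat) absence stays `'A'`:
  a menu dominated by chicken says nothing about red-meat frequency, and
  crediting it would inflate scores.
* `min_distinct` (binary rules). "At least three different fruits a
  week" counts distinct normalised offering names carrying the fruit
  tag; a tag set alone cannot count varieties.
* `slot`. Breakfast and break-time items inspect their own meal slot, so
  bacon at break does not count against the lunchtime processed-meat
  limit.

### Week coding and cycle averaging

Each week is coded separately against every item; the week total is the
sum of numeric ratings. The cycle's healthiness score is the *mean of
the week totals*, which makes 1-, 2-, 3- and 4-week cycles comparable.
Week totals are kept unrounded through the average and rounded once,
half-up to one decimal, at display — rounding per week first would bias
long cycles. Because all single-week ratings are exact tenths, week
totals are snapped to one decimal internally to keep floating-point
noise out of comparisons.

`frequency_per_period` items (oily fish: twice over a 4-week window)
are cycle-scoped: evidence is pooled across the whole cycle, the
required count is pro-rated as `ceiling(threshold × n_weeks /
period_weeks)` (a 3-week cycle needs `ceiling(2·3/4) = 2` occurrences;
a 2-week cycle needs 1), and the one rating is written into every week
sheet so week totals remain comparable.

```{r}
cb <- default_codebook("primary")
ideal <- generate_menu(menu_gen_params("primary", pass_prob = 1,
                                       absence_prob = 0, seed = 1))
score_menu(ideal, cb)
```

### Prices-only provisions

Some provisions publish only a price list. These are still audited — a
price list proves availability — by constructing a single-day
availability week from the entries and coding it normally: weekly
binaries can reach 1, per-day items at most 0.2, and the score lands far
below the maximum. The result is flagged as an **anomaly** and excluded
from subgroup means and SDs (while still being counted and listed), so
incomplete evidence cannot drag a subgroup average down.

## The default instruments

The shipped `smhat_primary_v1` (22 × 1-point items) splits as: breakfast
2; fruit & vegetables 4; meat, fish & alternatives 6; starchy
carbohydrates 3; dairy & alternatives 3; oils & spreads 1; HFSS 3.
`smhat_secondary_v1` (28) adds break-time 3, a two-item drinks block
(listing; free-sugar information) and a vegan-alternatives item,
reflecting the much wider secondary offering. Named criteria with fixed
parameters include oily fish twice per 4 weeks, a weekly wholegrain
item, red-meat and processed-meat limits of 2 occurrences per week, a
non-potato starch every day, lower-fat milk and lower-sugar yogurt
specification, and the three prohibitions listed above. Where a
published instrument leaves the item-by-item split unstated, the defaults
here were fixed once from the category structure and the named criteria,
and the totals pinned to 22/28; being config, they can be replaced
wholesale.

The break-time processed-meat limit is set at 4 occurrences per week so
that *daily* bacon provision (5/5 days) fails it while occasional
provision passes. The drinks items are filed under the `general` and
`hfss` categories of the ten-category scheme.

## Reliability statistics

Because `'A'` is non-numeric, agreement is computed on a **binary
recode**: `'A'` → 0, numeric ratings → 1 when they reach the cutpoint ×
item maximum (default cutpoint 1: only full marks count as "met"). The
cutpoint is configurable since other recodes are defensible.

* **Per-item SD** across coders (sample SD, n−1) locates ambiguous
  codebook items: unanimity gives 0, a 3–2 split among five coders gives
  √0.3 ≈ 0.548, the worst two-coder split gives √0.5 ≈ 0.707.
* **Mean pairwise agreement** pools multi-coder agreement without
  chance correction.
* **Cohen's κ** for two coders uses the standard marginal-product
  expected agreement. The unit of analysis is the pooled item-by-week
  ratings of the menus compared (one κ per menu in `icr_report()`);
  per-item κ is available by subsetting the ratings table. When both
  coders use a single identical class, κ is defined as 1; opposite
  unanimity yields expected agreement 0 and hence κ = 0.
* **McHugh bands**: below 0.60 below-moderate, 0.60–0.79 moderate,
  0.80–0.90 strong, over 0.90 almost perfect. The published edges leave
  the interval (0.79, 0.80) unassigned; such values are banded after
  half-up rounding to the two decimals the bands are stated in, while
  the stated edges elsewhere apply exactly (0.901 is already "over
  0.90").

```{r}
sheets <- generate_coders(rep(c(1, 0), 500),
                          coder_gen_params(2, flip_prob = 0.1, seed = 1))
cohens_kappa(sheets[1, ], sheets[2, ])
```

## Affordability

All money is integer pence; pounds exist only in formatting, so
disparities like 15p are exact. The meal-deal check uses the *cheapest*
meal-deal entry (the bundled main-meal-plus-drink price), reports
shortfall or residual, and lists what the residual still buys.
Price summaries report the mean rounded half-up to the penny, the sample
SD, and the mode with ties broken toward the lower price — the
conservative direction for "most commonly costs" claims about
affordability.

## The synthetic-data generator

The generator is the package's substitute for a non-deposited real
dataset, and it is built for *verifiability*, not realism: for every
codebook item it first draws the true rating (absent with
`absence_prob`; otherwise met with the item's pass probability) and then
plants offerings from a small name bank so that the engine must
reproduce exactly that rating. The name bank is wired to the shipped
lexicon, so auto-tagging round-trips; items whose tag classes overlap —
bacon is both processed and red meat, oily fish is fish, semi-skimmed
milk is milk — are planted jointly and their truths derived from the
planted counts. The truth table travels with the cycle as an attribute,
and the central cross-module test asserts that `score_menu()` recovers
every planted rating on every generated cycle.

What the generator emulates: 1–4-week × 5-day cycle structure, the four
provision subgroups, breakfast/break/lunch slots, per-item pass and
absence processes, and pence prices drawn from normal models truncated
at zero (defaults around 38p toast-like bread items, 49p fruit, 54p
vegetables, 92p HFSS snacks, 96p snack pots, £2.50 meal deals —
plausible magnitudes, not targets). What it does **not** emulate:
correlated menus across weeks (real cycles repeat dishes), seasonal
drift, coder idiosyncrasy beyond independent symmetric flips, Welsh
bilingual naming, or the messiness of real menu prose. A pass over the
synthetic suite therefore demonstrates that the engine implements the
instrument's semantics exactly; it does not demonstrate that the
instrument itself captures real-world menu healthiness.

Two generator edge cases are deliberate: a "fail" draw for a binary item
whose relevant and required classes coincide is realised as presence in
week 1 only (there is no way to be "mentioned but unmet" in every week),
which is impossible in a 1-week cycle, where the draw collapses to pass;
and prohibition items have no absence draw, since absence is their pass
state.

Coder sheets flip each true binary rating independently with probability
ε ∈ [0, 0.5]: ε = 0 reproduces the truth (κ = 1), ε = 0.5 is chance
(κ ≈ 0), and expected κ decreases monotonically in between (at ε = 0.25
on a balanced truth, P(agree) = 0.625 and κ ≈ 0.25).

## Numerical choices and degenerate inputs

* Reported scores and prices round **half-up** (2.25 → 2.3), matching
  how such instruments are conventionally reported; base R's
  round-half-even is not used for display.
* Week totals: sums of tenths are snapped to one decimal to keep binary
  floating-point representation out of equality checks.
* Empty provisions (no weeks, no price list) are a construction error;
  a menu-only cycle scored against price-dependent items is *not* an
  error (those items rate `'A'`).
* Degenerate κ marginals: see above; out-of-range κ or ratings are
  validation errors, as are negative or fractional pence.
* Mode ties → lower price; `'A'`-vs-0 distinctions never affect week
  totals, only interpretation.

## Problem sizes used in the checks

The test suite and the reproduction script work at deliberately modest
sizes chosen to exercise every code path many times over: sweeps of
1 000 generated cycles for boundedness/recovery properties, 1 000-unit
rating vectors for the κ noise curves, 2 000-draw price lists for the
law-of-large-numbers check, and exhaustive oracle comparison on 2-week ×
3-item cycles. These sizes are the package's own choice of a
comfortable statistical resolution (sampling error on κ at n = 1000 is
about ±0.03).

## Known limitations

* The default itemisation is one defensible realisation of the
  instrument's category structure; users with an authoritative codebook
  should load their own YAML rather than treat the defaults as
  canonical.
* Auto-tagging is keyword-based and assistive only; novel dish names
  (a "Buddha bowl") return an empty tag set with a warning and need
  manual tags.
* The binary recode at cutpoint 1 treats a 0.8 per-day rating as "not
  met", which is strict; the cutpoint is exposed for sensitivity
  analysis.
* Meal-deal composition rules (what counts as a main meal plus drink)
  are not modelled; the meal-deal price is taken as listed.
* Affordability says nothing about purchasing behaviour — only about
  what the allowance can arithmetically buy.
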