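# smhat — School Menu Healthiness Assessment and Affordability Auditing

`smhat` is an R implementation of a quick menu-auditing instrument for
school food provision. It is aimed at public-health nutritionists,
dietitians and researchers who need to judge how closely primary and
secondary school menus track food-based healthy-eating criteria — without
nutrient-level analysis software — and whether pupils on a free school
meal (FSM) allowance can actually afford the priced offering.

The package has four working parts:

* **A data-driven codebook.** The instrument is a YAML file, not code: an
  ordered list of items over ten provision categories (breakfast, break
  time, fruit & vegetables, meat/fish & alternatives, starchy
  carbohydrates, dairy & alternatives, oils & spreads, HFSS foods, prices,
  general observations), each with a scoring rule and a 1-point maximum.
  The shipped defaults sum to **22 points (primary)** and **28 points
  (secondary)**.
* **A scoring engine.** Each week of a rotational menu cycle is coded
  separately. An item rates `'A'` when its food class is never mentioned,
  `1`/`0` when the criterion is met/unmet, and incremental values
  `0.2–1.0` for "every day" criteria (fraction of the 5 school days met).
  Week totals are averaged over the weeks, giving a healthiness score
  comparable across 1–4-week cycles:

  `score = (1/W) * Σ_w Σ_items rating_w(item)`, with `'A'` contributing 0.

  Prices-only provisions are scored from availability alone and flagged
  as anomalies, which are excluded from subgroup means.
* **Intercoder reliability.** Ratings are binary-recoded (`'A'` → 0;
  numeric ratings thresholded at full marks), then compared by per-item
  sample SD, mean pairwise agreement, and Cohen's
  `κ = (p_o − p_e)/(1 − p_e)`, interpreted on McHugh's bands for health
  research (0.60–0.79 moderate, 0.80–0.90 strong, > 0.90 almost perfect).
* **Affordability analysis.** Integer-pence comparison of FSM allowances
  against price lists: meal-deal disparity/residual, the item set a
  residual still buys, outpriced items, and per-category price summaries
  (mean, sample SD, low-tie mode).

A synthetic-data module generates menus with *known* true ratings,
price lists, and noisy coder sheets, so the whole pipeline is testable
without any real menu data.

## Worked example

```r
library(smhat)

cb <- default_codebook("primary")
max_score(cb)
#> [1] 22

# a synthetic 3-week cycle in which every criterion is always met
ideal <- generate_menu(menu_gen_params("primary", pass_prob = 1,
                                       absence_prob = 0, seed = 7))
score_menu(ideal, cb)
#> <smhat score 'synthetic_LA_primary_seed7'> LA_primary
#>   healthiness score: 22 / 22 over 3 week(s)
#>   week totals: 22, 22, 22

# a realistic provision: criteria met ~60% of the time, 15% of food
# classes never mentioned
m <- generate_menu(menu_gen_params("primary", pass_prob = 0.6,
                                   absence_prob = 0.15, seed = 7))
score_menu(m, cb)
#> <smhat score 'synthetic_LA_primary_seed7'> LA_primary
#>   healthiness score: 12 / 22 over 3 week(s)
#>   week totals: 13.8, 11.2, 11.0

# reliability of two coders on 1000 binary rating units, 10% coding noise
sheets <- generate_coders(rep(c(1, 0), 500),
                          coder_gen_params(2, flip_prob = 0.1, seed = 7))
cohens_kappa(sheets[1, ], sheets[2, ])
#> Cohen's kappa: 0.6540  (p_o = 0.8270, p_e = 0.5000, n = 1000)
#>   agreement band: moderate

# can a 260p FSM allowance buy the meal deal?
pl <- price_list(c("meal deal", "salt sachet", "panini"),
                 c("meal_deal", "condiment", "bread"),
                 c(240L, 11L, 290L))
meal_deal_check(fsm_allowance("LA1", "secondary", 260L), pl)
#> <smhat affordability> LA LA1, allowance £2.60
#>   meal deal £2.40: AFFORDABLE, residual £0.20
#>   affordable extras: salt sachet
#>   outpriced items: panini
```

The healthiness score reads directly against the instrument maximum: the
ideal cycle attains exactly 22, the mixed provision reaches just over
half the ideal, and the affordability report shows a 20p
residual that covers only a condiment sachet while the panini is out of
reach.

Menus, codebooks, price lists, allowance tables and coder-rating sheets
all read/write from plain-text files (YAML/CSV); `exec/smhat` exposes the
same operations as a command-line tool
(`smhat score`, `aggregate`, `icr`, `afford`, `synth`).

## Scope

The instrument codes food-based criteria only (no nutrient analysis), and
the package does not source or scrape real menus; inputs are structured
files prepared by coders. Auto-tagging of offering names against the
shipped lexicon is assistive — coders' manual tags are authoritative.
See `vignettes/smhat-methods.Rmd` for the full account of the scoring
semantics, design choices and limitations.
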