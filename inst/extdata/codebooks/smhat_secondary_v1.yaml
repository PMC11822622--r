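# Default secondary-phase instrument. 28 items x 1 point = maximum 28.
# Extends the primary instrument with break-time, drinks and vegan-
# alternative items reflecting the wider secondary offering.
# The instrument is data: edit or replace this file to change the criteria
# without touching the scoring engine.
phase: secondary
version: smhat_secondary_v1
declared_max: 28
items:
- item_id: healthy_breakfast_daily
  category: breakfast
  rule: {kind: per_day}
  max_score: 1
  required_tags: [wholegrain]
  slot: breakfast
  description: A wholegrain breakfast option (e.g. porridge, wholegrain cereal) offered every school day.
- item_id: no_hfss_breakfast
  category: breakfast
  rule: {kind: limit, limit_max: 0, absent_credit: true}
  max_score: 1
  required_tags: [hfss_confectionery, hfss_savoury, hfss_sweet_snack]
  slot: breakfast
  description: No HFSS food offered at breakfast.
- item_id: fruit_daily
  category: fruit_and_vegetables
  rule: {kind: per_day}
  max_score: 1
  required_tags: [fruit]
  slot: lunch
  description: At least one portion of fruit available each day.
- item_id: vegetable_daily
  category: fruit_and_vegetables
  rule: {kind: per_day}
  max_score: 1
  required_tags: [vegetable]
  slot: lunch
  description: At least one portion of vegetables available each day.
- item_id: fruit_variety_weekly
  category: fruit_and_vegetables
  rule: {kind: binary, min_distinct: 3}
  max_score: 1
  required_tags: [fruit]
  slot: lunch
  description: At least three distinct fruits offered across the week.
- item_id: salad_available
  category: fruit_and_vegetables
  rule: {kind: binary}
  max_score: 1
  required_tags: [salad]
  slot: lunch
  description: A salad option available during the week.
- item_id: fish_weekly
  category: meat_fish_alternatives
  rule: {kind: binary}
  max_score: 1
  required_tags: [fish]
  slot: lunch
  description: Fish offered at least once a week.
- item_id: oily_fish_fortnightly
  category: meat_fish_alternatives
  rule: {kind: frequency_per_period, threshold: 2, period_weeks: 4}
  max_score: 1
  required_tags: [oily_fish]
  relevant_tags: [fish]
  slot: lunch
  description: Oily fish offered at least twice over a 4-week period (pro-rated to the cycle length).
- item_id: red_meat_limit
  category: meat_fish_alternatives
  rule: {kind: limit, limit_max: 2}
  max_score: 1
  required_tags: [red_meat]
  slot: lunch
  description: Red meat offered no more than twice a week.
- item_id: processed_meat_limit
  category: meat_fish_alternatives
  rule: {kind: limit, limit_max: 2}
  max_score: 1
  required_tags: [processed_meat]
  slot: lunch
  description: Meat products and processed meat (e.g. bacon) offered no more than twice a week.
- item_id: meat_cut_variety
  category: meat_fish_alternatives
  rule: {kind: binary}
  max_score: 1
  required_tags: [meat_cut]
  slot: lunch
  description: A recognisable cut of meat (not reformed or processed) offered during the week.
- item_id: non_meat_protein_weekly
  category: meat_fish_alternatives
  rule: {kind: binary}
  max_score: 1
  required_tags: [non_meat_protein]
  slot: lunch
  description: A non-meat protein source (pulses, eggs, meat-free dishes) offered weekly.
- item_id: non_potato_starch_daily
  category: starchy_carbohydrates
  rule: {kind: per_day}
  max_score: 1
  required_tags: [non_potato_starch]
  slot: lunch
  description: A starchy carbohydrate other than potato (pasta, rice, noodles, couscous) available each day.
- item_id: bread_available
  category: starchy_carbohydrates
  rule: {kind: binary}
  max_score: 1
  required_tags: [bread]
  slot: lunch
  description: Bread available during the week.
- item_id: wholegrain_weekly
  category: starchy_carbohydrates
  rule: {kind: binary}
  max_score: 1
  required_tags: [wholegrain]
  slot: lunch
  description: At least one wholegrain carbohydrate offered a week.
- item_id: milk_daily
  category: dairy_and_alternatives
  rule: {kind: per_day}
  max_score: 1
  required_tags: [milk]
  slot: lunch
  description: Milk available every day.
- item_id: lower_fat_milk
  category: dairy_and_alternatives
  rule: {kind: binary}
  max_score: 1
  required_tags: [lower_fat_milk]
  relevant_tags: [milk]
  slot: lunch
  description: Milk specified as semi-skimmed or skimmed.
- item_id: low_sugar_yogurt
  category: dairy_and_alternatives
  rule: {kind: binary}
  max_score: 1
  required_tags: [low_sugar_yogurt]
  relevant_tags: [yogurt]
  slot: lunch
  description: Yogurts offered are lower-sugar varieties.
- item_id: spread_specified
  category: oils_and_spreads
  rule: {kind: binary}
  max_score: 1
  required_tags: [condiment]
  slot: lunch
  description: Spreads/oils specified as lower-fat or unsaturated.
- item_id: no_confectionery_or_crisps
  category: hfss
  rule: {kind: limit, limit_max: 0, absent_credit: true}
  max_score: 1
  required_tags: [hfss_confectionery, hfss_savoury]
  slot: lunch
  description: No confectionery or non-compliant savoury snacks (e.g. crisps) on offer.
- item_id: compliant_sweet_snacks
  category: hfss
  rule: {kind: binary}
  max_score: 1
  required_tags: [compliant_snack]
  relevant_tags: [hfss_sweet_snack]
  slot: lunch
  description: Sweet/savoury snacks on offer comply with the healthiness criteria (e.g. oatcakes, cheese and biscuits).
- item_id: no_free_salt
  category: hfss
  rule: {kind: limit, limit_max: 0, absent_credit: true}
  max_score: 1
  required_tags: [salt_sachet]
  slot: lunch
  description: Salt not freely available to pupils.
- item_id: break_fruit_available
  category: break_time
  rule: {kind: binary}
  max_score: 1
  required_tags: [fruit]
  slot: break
  description: Fruit available at break time.
- item_id: break_processed_meat_limit
  category: break_time
  rule: {kind: limit, limit_max: 4}
  max_score: 1
  required_tags: [processed_meat]
  slot: break
  description: Processed meat (e.g. bacon) not provided daily at break time.
- item_id: break_compliant_snack
  category: break_time
  rule: {kind: binary}
  max_score: 1
  required_tags: [compliant_snack]
  slot: break
  description: A non-HFSS snack option available at break time.
- item_id: drinks_listed
  category: general
  rule: {kind: binary}
  max_score: 1
  required_tags: [drink]
  slot: lunch
  description: A drinks offering is listed on the menu or price list.
- item_id: drinks_sugar_compliant
  category: hfss
  rule: {kind: binary}
  max_score: 1
  required_tags: [drink, sugar_info_present]
  relevant_tags: [drink]
  slot: lunch
  description: Drinks state brand/quantity/sugar information and meet the free-sugar criteria.
- item_id: vegan_alternatives
  category: dairy_and_alternatives
  rule: {kind: binary}
  max_score: 1
  required_tags: [vegan_alternative]
  slot: lunch
  description: A vegan dairy or meat alternative offered during the week.
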