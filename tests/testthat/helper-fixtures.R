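# Fixture builders used across the suite. Everything is constructed in code;
# no stored data files.

off <- function(name, tags, slot = "lunch", price = NULL) {
  offering(name, slot = slot, tags = tags, price = price)
}

# days: a list indexed 1..5 of offering lists (missing entries = empty days)
wk <- function(week_index, days = list()) {
  menu_week(week_index, lapply(1:5, function(d) {
    menu_day(d, if (d <= length(days) && !is.null(days[[d]])) days[[d]] else list())
  }))
}

cycle_of <- function(weeks, subgroup = "LA_primary", pl = NULL, notes = "") {
  menu_cycle("fixture", subgroup, weeks = weeks, price_list = pl, notes = notes)
}

# A tiny 3-item codebook used where the full instrument would obscure the
# behaviour under test.
tiny_codebook <- function() {
  codebook(
    phase = "primary",
    items = list(
      codebook_item("veg_daily", "fruit_and_vegetables",
                    scoring_rule("per_day"), "vegetable"),
      codebook_item("fish_week", "meat_fish_alternatives",
                    scoring_rule("binary"), "fish"),
      codebook_item("red_limit", "meat_fish_alternatives",
                    scoring_rule("limit", limit_max = 2), "red_meat")
    ),
    declared_max = 3
  )
}
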