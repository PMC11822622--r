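veg_item <- function() codebook_item("veg", "fruit_and_vegetables",
                                     scoring_rule("per_day"), "vegetable")

test_that("per-day items score in increments of 0.2 per day met", {
  days_met <- function(k) {
    days <- lapply(seq_len(5), function(d) {
      if (d <= k) list(off("peas", "vegetable")) else NULL
    })
    cyc <- cycle_of(list(wk(1, days)))
    rate_item(cyc$weeks[[1]], veg_item(), cyc)$value
  }
  expect_equal(days_met(1), 0.2)
  expect_equal(days_met(3), 0.6)
  expect_equal(days_met(5), 1.0)
  # never mentioned anywhere: absent, not zero
  cyc <- cycle_of(list(wk(1)))
  expect_identical(rate_item(cyc$weeks[[1]], veg_item(), cyc)$value, "A")
  # mentioned in another week but not this one: 0, not 'A'
  cyc2 <- cycle_of(list(wk(1), wk(2, list(list(off("peas", "vegetable"))))))
  expect_identical(rate_item(cyc2$weeks[[1]], veg_item(), cyc2)$value, 0)
})

test_that("frequency items pool the whole cycle: oily fish twice per 4 weeks", {
  oily <- codebook_item("oily", "meat_fish_alternatives",
                        scoring_rule("frequency_per_period", threshold = 2,
                                     period_weeks = 4),
                        "oily_fish", relevant_tags = "fish")
  salmon_in <- function(weeks_with, n_weeks = 4) {
    weeks <- lapply(seq_len(n_weeks), function(w) {
      wk(w, if (w %in% weeks_with) list(list(off("salmon", c("fish", "oily_fish"))))
            else list(list(off("cod", "fish"))))
    })
    cyc <- cycle_of(weeks)
    rate_item(cyc$weeks[[1]], oily, cyc)$value
  }
  expect_equal(salmon_in(c(1, 3)), 1)   # twice over 4 weeks
  expect_equal(salmon_in(2), 0)         # once: below the standard
  # pro-rating: a 2-week cycle needs ceiling(2*2/4) = 1 occurrence
  expect_equal(salmon_in(1, n_weeks = 2), 1)
  # white fish only, cycle-wide: relevant class mentioned, criterion unmet
  expect_equal(salmon_in(integer(0)), 0)
  # no fish at all anywhere
  cyc <- cycle_of(list(wk(1)))
  expect_identical(rate_item(cyc$weeks[[1]], oily, cyc)$value, "A")
})

test_that("limit items score 1 within the cap, 0 above, and credit absence only when configured", {
  red <- codebook_item("red", "meat_fish_alternatives",
                       scoring_rule("limit", limit_max = 2), "red_meat")
  salt <- codebook_item("salt", "hfss",
                        scoring_rule("limit", limit_max = 0, absent_credit = TRUE),
                        "salt_sachet")
  n_red <- function(n) {
    days <- lapply(seq_len(5), function(d) {
      if (d <= n) list(off("beef stew", "red_meat")) else NULL
    })
    cyc <- cycle_of(list(wk(1, days)))
    rate_item(cyc$weeks[[1]], red, cyc)$value
  }
  expect_equal(n_red(2), 1)
  expect_equal(n_red(3), 0)
  # red meat never mentioned: uninformative absence rates 'A', not 1
  cyc <- cycle_of(list(wk(1)))
  expect_identical(rate_item(cyc$weeks[[1]], red, cyc)$value, "A")
  # prohibition with absent_credit: absence is compliance
  expect_equal(rate_item(cyc$weeks[[1]], salt, cyc)$value, 1)
  salty <- cycle_of(list(wk(1, list(list(off("salt sachet", "salt_sachet"))))))
  expect_equal(rate_item(salty$weeks[[1]], salt, salty)$value, 0)
})

test_that("binary items distinguish unmet (0) from absent ('A') via relevant tags", {
  lf_milk <- codebook_item("lf", "dairy_and_alternatives",
                           scoring_rule("binary"), "lower_fat_milk",
                           relevant_tags = "milk")
  plain <- cycle_of(list(wk(1, list(list(off("milk", "milk"))))))
  expect_equal(rate_item(plain$weeks[[1]], lf_milk, plain)$value, 0)
  semi <- cycle_of(list(wk(1, list(list(
    off("semi-skimmed milk", c("milk", "lower_fat_milk")))))))
  expect_equal(rate_item(semi$weeks[[1]], lf_milk, semi)$value, 1)
  none <- cycle_of(list(wk(1)))
  expect_identical(rate_item(none$weeks[[1]], lf_milk, none)$value, "A")
  # min_distinct: three distinct fruits needed
  variety <- codebook_item("var", "fruit_and_vegetables",
                           scoring_rule("binary", min_distinct = 3), "fruit")
  two <- cycle_of(list(wk(1, list(list(off("apple", "fruit"),
                                       off("banana", "fruit"))))))
  expect_equal(rate_item(two$weeks[[1]], variety, two)$value, 0)
  three <- cycle_of(list(wk(1, list(list(off("apple", "fruit"),
                                         off("banana", "fruit"),
                                         off("orange", "fruit"))))))
  expect_equal(rate_item(three$weeks[[1]], variety, three)$value, 1)
})

test_that("week totals sum numeric ratings with 'A' contributing zero", {
  cb <- tiny_codebook()
  cyc <- cycle_of(list(wk(1, list(
    list(off("peas", "vegetable"), off("cod", "fish")),
    list(off("peas", "vegetable"))
  ))))
  sheet <- score_week(cyc$weeks[[1]], cb, cyc)
  # veg on 2/5 days = 0.4; fish binary = 1; red meat absent = 'A' -> 0
  expect_equal(sheet$week_total, 1.4)
  expect_identical(sheet$ratings$red_limit$value, "A")
  empty <- cycle_of(list(wk(1)))
  expect_equal(score_week(empty$weeks[[1]], cb, empty)$week_total, 0)
})

test_that("a week meeting every criterion attains the instrument maximum", {
  for (phase in c("primary", "secondary")) {
    cb <- default_codebook(phase)
    m <- generate_menu(menu_gen_params(phase, pass_prob = 1, absence_prob = 0,
                                       seed = 11))
    sc <- score_menu(m, cb)
    expect_equal(sc$week_totals, rep(max_score(cb), 3))
    expect_equal(sc$healthiness_score, max_score(cb))
  }
})

test_that("the healthiness score is the mean of week totals", {
  cb <- tiny_codebook()
  # week veg-days: 2, 3, 1 -> totals 1.4, 1.6, 1.2 (fish rated each week)
  mk_week <- function(w, k) {
    wk(w, lapply(seq_len(5), function(d) {
      o <- list()
      if (d <= k) o <- c(o, list(off("peas", "vegetable")))
      if (d == 1) o <- c(o, list(off("cod", "fish")))
      if (length(o)) o else NULL
    }))
  }
  cyc <- cycle_of(list(mk_week(1, 2), mk_week(2, 3), mk_week(3, 1)))
  sc <- score_menu(cyc, cb)
  expect_equal(sc$week_totals, c(1.4, 1.6, 1.2))
  expect_equal(sc$healthiness_score, mean(c(1.4, 1.6, 1.2)))
  expect_false(sc$anomaly)
})

test_that("prices-only provisions are scored from availability and flagged anomalous", {
  cb <- default_codebook("secondary")
  pl <- price_list(
    c("slice of toast", "fruit pot", "whole fruit", "vegetables", "flapjack",
      "meal deal"),
    c("bread", "compliant_snack", "fruit", "vegetable", "hfss_sweet_snack",
      "meal_deal"),
    c(35L, 96L, 49L, 54L, 92L, 250L)
  )
  cyc <- menu_cycle("p", "school_secondary", price_list = pl)
  sc <- score_menu(cyc, cb)
  expect_true(sc$anomaly)
  # far below the 28 maximum, in the characteristic anomaly band
  expect_lt(sc$healthiness_score, 10)
  expect_gt(sc$healthiness_score, 0)
})

test_that("subgroup aggregation excludes anomalies from mean and SD", {
  mk_score <- function(id, subgroup, score, anomaly = FALSE) {
    structure(list(provision_id = id, subgroup = subgroup,
                   healthiness_score = score, week_totals = score,
                   week_sheets = list(), anomaly = anomaly,
                   completeness = if (anomaly) "prices_only" else "full",
                   max_score = 22, notes = ""),
              class = "smhat_score")
  }
  scores <- list(mk_score("a", "LA_primary", 10),
                 mk_score("b", "LA_primary", 12),
                 mk_score("c", "LA_primary", 3, anomaly = TRUE),
                 mk_score("d", "LA_secondary", 15),
                 mk_score("e", "school_primary", 10),
                 mk_score("f", "school_primary", 10),
                 mk_score("g", "school_primary", 10))
  summ <- aggregate_subgroup(scores)
  la_p <- summ[summ$subgroup == "LA_primary", ]
  expect_equal(la_p$mean, 11)
  expect_equal(la_p$n_included, 2L)
  expect_equal(la_p$n_anomalies, 1L)
  # single included score: SD undefined
  la_s <- summ[summ$subgroup == "LA_secondary", ]
  expect_equal(la_s$mean, 15)
  expect_true(is.na(la_s$sd))
  # identical scores: SD zero
  sp <- summ[summ$subgroup == "school_primary", ]
  expect_equal(sp$sd, 0)
  # all anomalous: mean reported as absent
  only_anom <- aggregate_subgroup(list(mk_score("z", "LA_secondary", 2.5,
                                                anomaly = TRUE)))
  expect_equal(only_anom$n_included, 0L)
  expect_true(is.na(only_anom$mean))
  expect_error(aggregate_subgroup(list()), "at least one")
})

test_that("scores are bounded by the codebook maximum across random menus", {
  for (seed in 1:25) {
    phase <- if (seed %% 2) "primary" else "secondary"
    p <- menu_gen_params(phase, n_weeks = 1L + seed %% 4,
                         pass_prob = runif(1), absence_prob = runif(1, 0, 0.5),
                         seed = seed)
    m <- withr::with_seed(seed, generate_menu(p))
    sc <- score_menu(m, default_codebook(phase))
    expect_gte(sc$healthiness_score, 0)
    expect_lte(sc$healthiness_score, max_score(default_codebook(phase)))
    expect_true(all(vapply(sc$week_sheets, `[[`, 0, "week_total") >= 0))
  }
})

test_that("adding a day that meets a per-day criterion never lowers the score", {
  cb <- tiny_codebook()
  base_days <- list(list(off("peas", "vegetable"), off("cod", "fish")))
  for (extra_day in 2:5) {
    cyc0 <- cycle_of(list(wk(1, base_days)))
    days1 <- base_days
    days1[[extra_day]] <- list(off("carrots", "vegetable"))
    cyc1 <- cycle_of(list(wk(1, days1)))
    s0 <- score_menu(cyc0, cb)$healthiness_score
    s1 <- score_menu(cyc1, cb)$healthiness_score
    expect_gte(s1, s0)
    base_days <- days1
  }
})

test_that("engine ratings match the brute-force oracle on small random cycles", {
  cb <- tiny_codebook()
  name_pool <- list(
    list("peas", "vegetable"), list("cod", "fish"),
    list("beef stew", "red_meat"), list("apple", "fruit")
  )
  for (seed in 1:40) {
    set.seed(seed)
    n_wk <- sample(1:2, 1)
    weeks <- lapply(seq_len(n_wk), function(w) {
      wk(w, lapply(1:5, function(d) {
        n_off <- sample(0:3, 1)
        if (!n_off) return(NULL)
        lapply(sample(name_pool, n_off, replace = TRUE),
               function(x) off(x[[1]], x[[2]]))
      }))
    })
    cyc <- cycle_of(weeks)
    for (item in cb$items) {
      for (w in seq_len(n_wk)) {
        got <- rating_chr(rate_item(cyc$weeks[[w]], item, cyc))
        expect_identical(got, oracle_rate(cyc, item, w),
                         label = sprintf("seed %d item %s week %d: %s",
                                         seed, item$item_id, w, got))
      }
    }
  }
})

test_that("full-instrument ratings match the oracle on generated menus", {
  for (seed in 1:6) {
    phase <- if (seed %% 2) "primary" else "secondary"
    cb <- default_codebook(phase)
    m <- generate_menu(menu_gen_params(phase, n_weeks = 2, pass_prob = 0.5,
                                       absence_prob = 0.2, seed = seed))
    for (item in cb$items) {
      for (w in 1:2) {
        expect_identical(rating_chr(rate_item(m$weeks[[w]], item, m)),
                         oracle_rate(m, item, w),
                         label = sprintf("seed %d %s w%d", seed, item$item_id, w))
      }
    }
  }
})
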