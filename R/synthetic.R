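#' Synthetic menus, price lists and coder ratings
#'
#' No real menu dataset is deposited, so every other module is exercised
#' against generated provision: rotational cycles (default 3 weeks of 5
#' school days) across the four catering subgroups, price lists with
#' realistic pence magnitudes, and multi-coder rating sheets with a
#' controllable error rate. The menu generator plants offerings so that
#' the true rating of every codebook item is known by construction; the
#' truth table travels with the generated cycle (attribute \code{"truth"})
#' and is the reference for the end-to-end recovery tests.
#'
#' @name synthetic_data
NULL

# Default price magnitudes (pence): plausible defaults echoing typical
# secondary price-list entries, not reproduction targets.
DEFAULT_PRICE_MODEL <- list(
  bread = c(mean = 38, sd = 7),        # slice of toast
  fruit = c(mean = 49, sd = 11),       # whole fruit piece
  vegetable = c(mean = 54, sd = 13),   # portion of vegetables
  compliant_snack = c(mean = 96, sd = 25),  # fruit pot
  hfss_sweet_snack = c(mean = 92, sd = 17),
  drink = c(mean = 85, sd = 15),
  condiment = c(mean = 11, sd = 3),
  meal_deal = c(mean = 250, sd = 30)
)

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
      } else {
        assign(".Random.seed", old, .GlobalEnv)
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Menu-generator parameters
#'
#' @param phase \code{"primary"} or \code{"secondary"}.
#' @param subgroup provision subgroup; defaults to the LA subgroup of the
#'   phase.
#' @param n_weeks cycle length in weeks (default 3, the typical rotational
#'   cycle).
#' @param pass_prob default probability that an item's criterion is met;
#'   may be overridden per item via \code{criterion_pass_prob}.
#' @param criterion_pass_prob named numeric vector item_id -> probability.
#'   Unknown ids are an error.
#' @param absence_prob probability that an item's tag class is never
#'   mentioned anywhere in the cycle (true rating 'A').
#' @param price_model named list category_tag -> c(mean, sd) pence; used
#'   for secondary-phase offerings. \code{NULL} disables prices.
#' @param seed integer RNG seed (reproducibility contract).
#' @return a \code{smhat_menu_gen_params} list.
#' @export
menu_gen_params <- function(phase = c("primary", "secondary"), subgroup = NULL,
                            n_weeks = 3L, pass_prob = 0.7,
                            criterion_pass_prob = NULL, absence_prob = 0.1,
                            price_model = DEFAULT_PRICE_MODEL, seed = 1L) {
  phase <- match.arg(phase)
  subgroup <- subgroup %||%
    if (phase == "primary") "LA_primary" else "LA_secondary"
  subgroup <- match.arg(subgroup, SUBGROUPS)
  if (phase_of(subgroup) != phase) {
    stop("subgroup '", subgroup, "' does not match phase '", phase, "'",
         call. = FALSE)
  }
  if (n_weeks < 1) stop("n_weeks must be >= 1", call. = FALSE)
  stopifnot(pass_prob >= 0, pass_prob <= 1, absence_prob >= 0, absence_prob <= 1)
  if (!is.null(criterion_pass_prob)) {
    stopifnot(all(criterion_pass_prob >= 0), all(criterion_pass_prob <= 1))
  }
  structure(list(phase = phase, subgroup = subgroup, n_weeks = as.integer(n_weeks),
                 pass_prob = pass_prob, criterion_pass_prob = criterion_pass_prob,
                 absence_prob = absence_prob, price_model = price_model,
                 seed = seed),
            class = "smhat_menu_gen_params")
}

# Name bank wired to the default lexicon, so tag_offering() on these names
# reproduces the tags exactly. One entry per planting role.
NAME_BANK <- list(
  porridge = c("wholegrain"),
  `chocolate muffin` = c("hfss_confectionery", "hfss_sweet_snack"),
  apple = c("fruit"), banana = c("fruit"), orange = c("fruit"),
  carrots = c("vegetable"),
  `side salad` = c("salad"),
  cod = c("fish"),
  salmon = c("fish", "oily_fish"),
  `savoury mince` = c("red_meat"),
  bacon = c("processed_meat", "red_meat"),
  `roast chicken` = c("meat_cut", "poultry"),
  `lentil curry` = c("non_meat_protein"),
  `tomato pasta` = c("non_potato_starch"),
  baguette = c("bread"),
  `wholemeal crackers` = c("wholegrain"),
  milk = c("milk"),
  `semi-skimmed milk` = c("lower_fat_milk", "milk"),
  yogurt = c("yogurt"),
  `low-sugar yogurt` = c("low_sugar_yogurt", "yogurt"),
  `low-fat spread` = c("condiment"),
  crisps = c("hfss_savoury"),
  flapjack = c("hfss_sweet_snack"),
  oatcakes = c("compliant_snack"),
  `salt sachet` = c("salt_sachet"),
  `bottled water` = c("drink"),
  `sugar-free squash` = c("drink", "sugar_info_present"),
  `vegan burger` = c("vegan_alternative")
)

# --- generator ---------------------------------------------------------------

#' Generate a synthetic menu cycle with known true ratings
#'
#' Plants offerings from the name bank so that, for every item of the
#' phase's default codebook, the true rating under the engine's rule
#' semantics is fixed by construction: with probability
#' \code{absence_prob} an item's tag class is omitted from the whole cycle
#' (true rating 'A'); otherwise the criterion is met with the item's pass
#' probability. Items whose tag classes overlap (e.g. bacon carries both
#' the processed-meat and red-meat tags, oily fish is also fish) are
#' planted jointly and their truths derived from the planted counts.
#' Deterministic given the seed.
#'
#' @param params a \code{\link{menu_gen_params}}.
#' @return an \code{smhat_menu} with attributes \code{"truth"} (data.frame
#'   item_id / week / rating, rating "A" or the numeric value as
#'   character) and \code{"expected_score"} (mean of the true week
#'   totals).
#' @export
#' @examples
#' p <- menu_gen_params("primary", pass_prob = 1, absence_prob = 0, seed = 7)
#' m <- generate_menu(p)
#' attr(m, "expected_score")  # 22: the ideal primary menu
generate_menu <- function(params) {
  stopifnot(inherits(params, "smhat_menu_gen_params"))
  cb <- default_codebook(params$phase)
  ids <- item_ids(cb)
  if (!is.null(params$criterion_pass_prob)) {
    bad <- setdiff(names(params$criterion_pass_prob), ids)
    if (length(bad)) {
      stop("unknown item_id(s) in criterion_pass_prob: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  with_seed(params$seed, build_cycle(params, cb))
}

build_cycle <- function(params, cb) {
  W <- params$n_weeks
  ids <- item_ids(cb)
  cp <- params$criterion_pass_prob
  p_of <- function(id) {
    if (!is.null(cp) && id %in% names(cp)) cp[[id]] else params$pass_prob
  }
  sample1 <- function(x) x[sample.int(length(x), 1L)]
  pass <- function(id) stats::runif(1) < p_of(id)
  absent <- function() stats::runif(1) < params$absence_prob

  # offerings[[w]][[d]]: list of offering()s being assembled
  offerings <- lapply(seq_len(W), function(w) lapply(1:5, function(d) list()))
  plant <- function(w, d, name, slot = "lunch") {
    offerings[[w]][[d]][[length(offerings[[w]][[d]]) + 1L]] <<-
      offering(name, slot = slot, tags = NAME_BANK[[name]])
  }
  truth <- stats::setNames(
    rep(list(rep(NA_character_, W)), length(ids)), ids)
  set_truth <- function(id, w, value) truth[[id]][w] <<- as.character(value)
  set_all <- function(id, value) truth[[id]] <<- rep(as.character(value), W)

  # week pattern for simple binary items: all weeks when pass, else week 1
  # only (collapses to pass for 1-week cycles)
  binary_weeks <- function(ok) if (ok || W == 1L) seq_len(W) else 1L

  # -- independent per_day items
  per_day_plan <- function(id, name, slot) {
    if (absent()) { set_all(id, "A"); return(invisible()) }
    for (w in seq_len(W)) {
      k <- if (pass(id)) 5L else sample(1:4, 1)
      for (d in sample(1:5, k)) plant(w, d, name, slot)
      set_truth(id, w, k / 5)
    }
  }
  per_day_plan("healthy_breakfast_daily", "porridge", "breakfast")
  per_day_plan("vegetable_daily", "carrots", "lunch")
  per_day_plan("non_potato_starch_daily", "tomato pasta", "lunch")

  # -- fruit: daily per_day coupled with the 3-distinct-varieties binary
  if (absent()) {
    set_all("fruit_daily", "A"); set_all("fruit_variety_weekly", "A")
  } else {
    for (w in seq_len(W)) {
      k <- if (pass("fruit_daily")) 5L else sample(1:4, 1)
      days <- sample(1:5, k)
      for (d in days) plant(w, d, "apple")
      set_truth("fruit_daily", w, k / 5)
      variety <- pass("fruit_variety_weekly")
      if (variety) {
        plant(w, days[1], "banana"); plant(w, days[1], "orange")
      }
      set_truth("fruit_variety_weekly", w, as.numeric(variety))
    }
  }

  # -- milk: daily per_day coupled with the lower-fat specification binary
  if (absent()) {
    set_all("milk_daily", "A"); set_all("lower_fat_milk", "A")
  } else {
    for (w in seq_len(W)) {
      k <- if (pass("milk_daily")) 5L else sample(1:4, 1)
      days <- sample(1:5, k)
      lf <- pass("lower_fat_milk")
      plant(w, days[1], if (lf) "semi-skimmed milk" else "milk")
      for (d in days[-1]) plant(w, d, "milk")
      set_truth("milk_daily", w, k / 5)
      set_truth("lower_fat_milk", w, as.numeric(lf))
    }
  }

  # -- simple weekly binaries (relevant class == required class)
  simple_binary <- function(id, name, slot = "lunch") {
    if (!id %in% ids) return(invisible())
    if (absent()) { set_all(id, "A"); return(invisible()) }
    wks <- binary_weeks(pass(id))
    for (w in seq_len(W)) {
      if (w %in% wks) plant(w, sample(1:5, 1), name, slot)
      set_truth(id, w, as.numeric(w %in% wks))
    }
  }
  simple_binary("salad_available", "side salad")
  simple_binary("meat_cut_variety", "roast chicken")
  simple_binary("non_meat_protein_weekly", "lentil curry")
  simple_binary("bread_available", "baguette")
  simple_binary("wholegrain_weekly", "wholemeal crackers")
  simple_binary("spread_specified", "low-fat spread")
  simple_binary("break_fruit_available", "apple", "break")
  simple_binary("break_compliant_snack", "oatcakes", "break")
  simple_binary("vegan_alternatives", "vegan burger")

  # -- binaries with contrasting "mentioned but unmet" evidence
  contrast_binary <- function(id, pass_name, fail_name) {
    if (!id %in% ids) return(invisible())
    if (absent()) { set_all(id, "A"); return(invisible()) }
    ok <- pass(id)
    for (w in seq_len(W)) {
      plant(w, sample(1:5, 1), if (ok) pass_name else fail_name)
      set_truth(id, w, as.numeric(ok))
    }
  }
  contrast_binary("low_sugar_yogurt", "low-sugar yogurt", "yogurt")
  contrast_binary("compliant_sweet_snacks", "oatcakes", "flapjack")

  # -- fish: weekly binary coupled with the cycle-scoped oily-fish count
  if (absent()) {
    set_all("fish_weekly", "A"); set_all("oily_fish_fortnightly", "A")
  } else {
    fish_wks <- binary_weeks(pass("fish_weekly"))
    for (w in seq_len(W)) {
      if (w %in% fish_wks) plant(w, sample(1:5, 1), "cod")
      set_truth("fish_weekly", w, as.numeric(w %in% fish_wks))
    }
    oily <- pass("oily_fish_fortnightly")
    if (oily) {
      it <- cb$items[[which(ids == "oily_fish_fortnightly")]]
      need <- ceiling(it$rule$threshold * W / it$rule$period_weeks)
      wk_cycle <- rep(fish_wks, length.out = need)
      used <- lapply(seq_len(W), function(w) integer())
      for (w in wk_cycle) {
        d <- sample1(setdiff(1:5, used[[w]]))
        used[[w]] <- c(used[[w]], d)
        plant(w, d, "salmon")
      }
    }
    set_all("oily_fish_fortnightly", as.numeric(oily))
  }

  # -- red and processed meat limits (bacon carries both tags, so truths
  #    are derived from the planted weekly counts)
  status <- function(id) {
    if (absent()) "absent" else if (pass(id)) "pass" else "fail"
  }
  s_p <- status("processed_meat_limit")
  s_r <- status("red_meat_limit")
  b <- switch(s_p, absent = 0L, pass = 1L, fail = 3L)
  e <- switch(s_r, absent = 0L,
              pass = if (b <= 1L) 1L else 0L,
              fail = max(0L, 3L - b))
  lim_truth <- function(count, limit_max) {
    if (count == 0L) "A" else if (count <= limit_max) "1" else "0"
  }
  for (w in seq_len(W)) {
    days <- sample(1:5, min(5L, b + e))
    for (d in days[seq_len(b)]) plant(w, d, "bacon")
    for (d in days[b + seq_len(e)]) plant(w, d, "savoury mince")
  }
  set_all("processed_meat_limit", lim_truth(b, 2L))
  set_all("red_meat_limit", lim_truth(b + e, 2L))

  # -- prohibition limits (absence is the compliant state; no 'A' draw)
  prohibition <- function(id, name, slot = "lunch") {
    if (!id %in% ids) return(invisible())
    ok <- pass(id)
    if (!ok) for (w in seq_len(W)) plant(w, sample(1:5, 1), name, slot)
    set_all(id, as.numeric(ok))
  }
  prohibition("no_hfss_breakfast", "chocolate muffin", "breakfast")
  prohibition("no_confectionery_or_crisps", "crisps")
  prohibition("no_free_salt", "salt sachet")

  # -- break-time processed meat (secondary): daily provision breaks the limit
  if ("break_processed_meat_limit" %in% ids) {
    st <- status("break_processed_meat_limit")
    n_day <- switch(st, absent = 0L, pass = 1L, fail = 5L)
    for (w in seq_len(W)) {
      for (d in seq_len(n_day)) plant(w, d, "bacon", "break")
    }
    set_all("break_processed_meat_limit",
            if (n_day == 0L) "A" else if (n_day <= 4L) "1" else "0")
  }

  # -- drinks (secondary): listing binary coupled with sugar-information
  if ("drinks_listed" %in% ids) {
    if (absent()) {
      set_all("drinks_listed", "A"); set_all("drinks_sugar_compliant", "A")
    } else {
      wks <- binary_weeks(pass("drinks_listed"))
      compliant <- pass("drinks_sugar_compliant")
      for (w in seq_len(W)) {
        listed <- w %in% wks
        if (listed) {
          plant(w, sample(1:5, 1), "bottled water")
          if (compliant) plant(w, sample(1:5, 1), "sugar-free squash")
        }
        set_truth("drinks_listed", w, as.numeric(listed))
        set_truth("drinks_sugar_compliant", w, as.numeric(compliant && listed))
      }
    }
  }

  # assemble menu, drawing prices for secondary offerings from the model
  weeks <- lapply(seq_len(W), function(w) {
    menu_week(w, lapply(1:5, function(d) {
      offs <- offerings[[w]][[d]]
      if (params$phase == "secondary" && !is.null(params$price_model)) {
        offs <- lapply(offs, function(o) {
          cat_tag <- intersect(o$tags, names(params$price_model))
          if (length(cat_tag)) {
            pm <- params$price_model[[cat_tag[1]]]
            o$price <- max(0L, as.integer(round(stats::rnorm(1, pm[1], pm[2]))))
          }
          o
        })
      }
      menu_day(d, offs)
    }))
  })
  pl <- NULL
  if (params$phase == "secondary" && !is.null(params$price_model)) {
    pl <- generate_price_list(params$price_model, n_per_category = 3L,
                              seed = NULL)
  }
  cycle <- menu_cycle(
    provision_id = sprintf("synthetic_%s_seed%s", params$subgroup,
                           format(params$seed)),
    subgroup = params$subgroup, weeks = weeks, price_list = pl,
    notes = "synthetic provision generated from the default name bank"
  )

  truth_df <- do.call(rbind, lapply(ids, function(id) {
    data.frame(item_id = id, week = seq_len(W), rating = truth[[id]],
               stringsAsFactors = FALSE)
  }))
  week_totals <- vapply(seq_len(W), function(w) {
    vals <- vapply(ids, function(id) {
      r <- truth[[id]][w]
      if (r == "A") 0 else as.numeric(r)
    }, 0)
    round(sum(vals) * 10) / 10
  }, 0)
  attr(cycle, "truth") <- truth_df
  attr(cycle, "expected_score") <- mean(week_totals)
  cycle
}

#' Generate a synthetic price list
#'
#' Draws \code{n_per_category} integer-pence prices per category from
#' normal price models (truncated at zero), plus a single meal-deal entry
#' when the model includes one.
#'
#' @param price_model named list category_tag -> c(mean, sd) in pence.
#' @param n_per_category entries drawn per category.
#' @param seed RNG seed (\code{NULL} to use the current RNG state).
#' @return an \code{\link{price_list}}.
#' @export
generate_price_list <- function(price_model = DEFAULT_PRICE_MODEL,
                                n_per_category = 5L, seed = 1L) {
  draw <- function() {
    nm <- character(); tg <- character(); pr <- integer()
    for (cat_tag in names(price_model)) {
      pm <- price_model[[cat_tag]]
      n <- if (cat_tag == "meal_deal") 1L else as.integer(n_per_category)
      p <- pmax(0L, as.integer(round(stats::rnorm(n, pm[1], pm[2]))))
      nm <- c(nm, sprintf("%s %d", gsub("_", " ", cat_tag), seq_len(n)))
      tg <- c(tg, rep(cat_tag, n))
      pr <- c(pr, p)
    }
    price_list(nm, tg, pr)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Coder-noise parameters
#'
#' @param n_coders number of coders (>= 2).
#' @param flip_prob probability a coder flips each true binary rating
#'   (in [0, 0.5]).
#' @param seed RNG seed.
#' @export
coder_gen_params <- function(n_coders = 2L, flip_prob = 0.1, seed = 1L) {
  if (n_coders < 2) stop("need at least two coders", call. = FALSE)
  if (flip_prob < 0 || flip_prob > 0.5) {
    stop("flip_prob must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(n_coders = as.integer(n_coders), flip_prob = flip_prob,
                 seed = seed),
            class = "smhat_coder_gen_params")
}

#' Generate noisy coder rating sheets
#'
#' Each coder independently flips each true binary rating with probability
#' \code{flip_prob}; at 0 all coders reproduce the truth, at 0.5 agreement
#' falls to chance level (kappa near 0). Reproducible given the seed.
#'
#' @param truth vector of true binary (0/1) ratings.
#' @param params a \code{\link{coder_gen_params}}.
#' @return integer matrix, one row per coder, one column per rating unit.
#' @export
generate_coders <- function(truth, params) {
  stopifnot(inherits(params, "smhat_coder_gen_params"),
            all(truth %in% c(0, 1)))
  with_seed(params$seed, {
    n <- length(truth)
    sheets <- vapply(seq_len(params$n_coders), function(i) {
      flips <- stats::runif(n) < params$flip_prob
      as.integer(xor(truth == 1L, flips))
    }, integer(n))
    t(matrix(sheets, nrow = n))
  })
}
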