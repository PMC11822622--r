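#' Round half away from zero
#'
#' Commercial rounding used for all reported scores and prices: exact halves
#' round up in magnitude (base \code{round()} rounds halves to even, which
#' would report a 0.25 mean as 0.2 rather than 0.3).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.25, 1)  # 2.3
#' round_half_up(36.6667)  # 37
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format integer pence as pounds
#'
#' @param pence integer pence.
#' @return character, e.g. \code{"£2.52"}.
#' @export
format_pence <- function(pence) {
  sprintf("£%d.%02d", pence %/% 100L, pence %% 100L)
}

# Sum ratings known to be exact tenths without floating drift.
sum_tenths <- function(x) round(sum(x) * 10) / 10

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sampling-frame coverage arithmetic
#'
#' An audit targeting every local authority's primary and secondary menu
#' plus all independently catered schools has a total population of
#' \code{2 * n_la + n_school_organised} provisions; those that cannot be
#' located online reduce the analysed sample. Coverage is the analysed
#' share of the population, reported as a whole percentage (half-up).
#'
#' @param n_la number of local authorities (each contributing a primary
#'   and a secondary provision).
#' @param n_school_organised number of school-organised provisions.
#' @param n_unlocatable provisions that could not be located.
#' @return list with \code{population}, \code{analysed} and
#'   \code{coverage_pct}.
#' @export
#' @examples
#' sample_coverage(22, 60, 22)  # population 104, analysed 82, coverage 79
sample_coverage <- function(n_la, n_school_organised, n_unlocatable = 0) {
  population <- 2L * as.integer(n_la) + as.integer(n_school_organised)
  analysed <- population - as.integer(n_unlocatable)
  if (analysed < 0) stop("more unlocatable provisions than the population",
                         call. = FALSE)
  list(population = population, analysed = analysed,
       coverage_pct = round_half_up(100 * analysed / population))
}

# Controlled food-tag vocabulary shared by menus, codebooks and price lists.
FOOD_TAGS <- c(
  "fruit", "vegetable", "salad", "fish", "oily_fish", "red_meat",
  "processed_meat", "meat_cut", "poultry", "non_meat_protein",
  "vegan_alternative", "potato", "non_potato_starch", "bread", "wholegrain",
  "milk", "lower_fat_milk", "yogurt", "low_sugar_yogurt", "non_dairy_milk",
  "hfss_confectionery", "hfss_savoury", "hfss_sweet_snack", "compliant_snack",
  "drink", "sugar_info_present", "salt_sachet", "condiment", "meal_of_day",
  "meal_deal"
)

MEAL_SLOTS <- c("breakfast", "break", "lunch")

SUBGROUPS <- c("LA_primary", "LA_secondary", "school_primary", "school_secondary")

CATEGORIES <- c(
  "breakfast", "break_time", "fruit_and_vegetables", "meat_fish_alternatives",
  "starchy_carbohydrates", "dairy_and_alternatives", "oils_and_spreads",
  "hfss", "prices", "general"
)

assert_tags <- function(tags, what = "tag") {
  bad <- setdiff(tags, FOOD_TAGS)
  if (length(bad)) {
    stop(sprintf(
      "unknown %s(s): %s. Permitted vocabulary: %s",
      what, paste(bad, collapse = ", "), paste(FOOD_TAGS, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(tags)
}
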