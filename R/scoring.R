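#' Scoring engine
#'
#' Applies a codebook to a menu cycle. Each week is coded separately: every
#' item receives either the non-numeric rating 'A' (absent — the item's tag
#' class is never mentioned anywhere in the cycle) or a numeric rating in
#' the rule's permitted set. Week totals sum the numeric ratings ('A'
#' contributes 0, keeping the instrument maximum fixed), and the cycle's
#' healthiness score is the mean of the week totals, so cycles of different
#' lengths remain comparable. Prices-only provisions are scored against a
#' one-day availability week built from the price list and flagged as
#' anomalies; anomalies are excluded from subgroup averages.
#'
#' @name scoring_engine
NULL

# Offerings of a week (or pseudo-week) relevant to an item: slot filter plus
# tag intersection with `tags`.
week_hits <- function(week, tags, slot = NULL) {
  hits <- list()
  for (d in week$days) {
    for (o in d$offerings) {
      if (!is.null(slot) && o$slot != slot) next
      if (length(intersect(o$tags, tags))) {
        hits[[length(hits) + 1L]] <- list(day = d$day_index, name = o$name,
                                          tags = o$tags)
      }
    }
  }
  hits
}

cycle_mentions <- function(cycle, tags, slot = NULL) {
  for (wk in cycle$weeks) if (length(week_hits(wk, tags, slot))) return(TRUE)
  FALSE
}

satisfies <- function(hit_tags, required) all(required %in% hit_tags)

new_rating <- function(item_id, value, evidence = list()) {
  structure(list(item_id = item_id, value = value, evidence = evidence),
            class = "smhat_rating")
}

is_absent <- function(rating) identical(rating$value, "A")

rating_points <- function(rating) if (is_absent(rating)) 0 else rating$value

#' Rate a single codebook item for one week
#'
#' Implements the 'A'/0/1 scheme with per-day increments: 'A' when the
#' item's relevant tag class is never mentioned in the cycle; otherwise a
#' numeric rating per the rule kind (see \code{\link{codebook}}).
#' Frequency-per-period items pool evidence across the whole cycle
#' (supplied as \code{context}) and write the same rating into every week
#' sheet, so week totals stay comparable.
#'
#' @param week an \code{smhat_week} (or \code{NULL} for prices-only
#'   context, in which case the pseudo-week inside \code{context} is used).
#' @param item an \code{smhat_item}.
#' @param context the enclosing \code{smhat_menu}.
#' @return an \code{smhat_rating}: item_id, value ('A' or points), and the
#'   evidence list of (week, day, offering name) supporting it.
#' @export
rate_item <- function(week, item, context) {
  rule <- item$rule
  rel <- item$relevant_tags
  req <- item$required_tags
  mentioned <- cycle_mentions(context, rel, item$slot)

  if (rule$kind == "frequency_per_period") {
    if (!mentioned) return(new_rating(item$item_id, "A"))
    count <- 0L
    evidence <- list()
    for (wk in context$weeks) {
      for (h in week_hits(wk, req, item$slot)) {
        if (satisfies(h$tags, req)) {
          count <- count + 1L
          evidence[[length(evidence) + 1L]] <-
            list(week = wk$week_index, day = h$day, name = h$name)
        }
      }
    }
    need <- ceiling(rule$threshold * n_weeks(context) / rule$period_weeks)
    return(new_rating(item$item_id, if (count >= need) 1 else 0, evidence))
  }

  hits <- week_hits(week, rel, item$slot)
  qualifying <- Filter(function(h) satisfies(h$tags, req), hits)
  evidence <- lapply(qualifying, function(h)
    list(week = week$week_index, day = h$day, name = h$name))

  if (rule$kind == "per_day") {
    if (!mentioned) return(new_rating(item$item_id, "A"))
    days_met <- unique(vapply(qualifying, `[[`, 0L, "day"))
    return(new_rating(item$item_id, length(days_met) / rule$days_per_week,
                      evidence))
  }

  if (rule$kind == "binary") {
    if (!mentioned) return(new_rating(item$item_id, "A"))
    distinct <- unique(normalise_name(vapply(qualifying, `[[`, "", "name")))
    met <- length(distinct) >= rule$min_distinct
    return(new_rating(item$item_id, as.numeric(met), evidence))
  }

  # limit: count this week's occurrences of the limited class; an offering
  # carrying any limited tag counts (the class is a union, e.g. "no
  # confectionery or crisps")
  limited <- week_hits(week, req, item$slot)
  evidence <- lapply(limited, function(h)
    list(week = week$week_index, day = h$day, name = h$name))
  if (!mentioned) {
    return(new_rating(item$item_id, if (rule$absent_credit) 1 else "A"))
  }
  new_rating(item$item_id, if (length(limited) <= rule$limit_max) 1 else 0,
             evidence)
}

#' Score one week of a menu cycle
#'
#' One rating per codebook item; the week total is the sum of numeric
#' ratings ('A' contributing 0) and is bounded by the codebook maximum.
#'
#' @param week an \code{smhat_week}.
#' @param cb an \code{smhat_codebook}.
#' @param context the enclosing \code{smhat_menu}.
#' @return an \code{smhat_week_sheet}: week_index, ratings, week_total.
#' @export
score_week <- function(week, cb, context) {
  ratings <- lapply(cb$items, function(it) rate_item(week, it, context))
  names(ratings) <- item_ids(cb)
  total <- sum_tenths(vapply(ratings, rating_points, 0))
  structure(list(week_index = week$week_index, ratings = ratings,
                 week_total = total),
            class = "smhat_week_sheet")
}

# Prices-only provisions: build a one-day availability pseudo-week from the
# price list so availability-type items can still be coded. Per-day items can
# then reach at most 0.2, reproducing the characteristically low anomaly
# scores of such provisions.
pricelist_pseudo_week <- function(pl) {
  offs <- lapply(seq_len(nrow(pl)), function(i) {
    offering(name = pl$name[i], slot = "lunch", tags = pl$category_tag[i],
             price = pl$price[i])
  })
  menu_week(1L, c(list(menu_day(1L, offs)),
                  lapply(2:5, function(d) menu_day(d, list()))))
}

#' Score a whole menu cycle
#'
#' Codes each week separately and divides the summed week totals by the
#' number of weeks, yielding a healthiness score comparable across cycle
#' lengths. The higher the score, the closer the provision sits to the
#' instrument's healthiness ideal (maximum 22 primary / 28 secondary for
#' the default instruments). Prices-only cycles are scored from a one-day
#' availability week and flagged \code{anomaly = TRUE}; scoring a
#' menu-only cycle is not an error (price-dependent items simply rate 'A').
#'
#' @param cycle an \code{smhat_menu}.
#' @param cb an \code{smhat_codebook}.
#' @return an \code{smhat_score}: provision_id, subgroup,
#'   healthiness_score, week_sheets, anomaly flag, notes.
#' @export
score_menu <- function(cycle, cb) {
  stopifnot(inherits(cycle, "smhat_menu"), inherits(cb, "smhat_codebook"))
  anomaly <- cycle$completeness == "prices_only"
  scoring_cycle <- cycle
  if (anomaly) {
    scoring_cycle$weeks <- list(pricelist_pseudo_week(cycle$price_list))
  }
  sheets <- lapply(scoring_cycle$weeks, score_week, cb = cb,
                   context = scoring_cycle)
  totals <- vapply(sheets, `[[`, 0, "week_total")
  structure(
    list(provision_id = cycle$provision_id, subgroup = cycle$subgroup,
         healthiness_score = mean(totals), week_totals = totals,
         week_sheets = sheets, anomaly = anomaly,
         completeness = cycle$completeness, max_score = max_score(cb),
         notes = cycle$notes),
    class = "smhat_score"
  )
}

#' @export
print.smhat_score <- function(x, ...) {
  cat(sprintf("<smhat score '%s'> %s\n", x$provision_id, x$subgroup))
  cat(sprintf("  healthiness score: %s / %s over %d week(s)%s\n",
              format(round_half_up(x$healthiness_score, 1)),
              format(x$max_score), length(x$week_totals),
              if (x$anomaly) "  [ANOMALY: prices only]" else ""))
  cat("  week totals:", paste(format(x$week_totals), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a menu score as a data frame
#'
#' One row per item per week: item_id, category, week, rating ('A' kept as
#' the string "A"), points, and collapsed evidence. The CSV report written
#' by the command-line tool is this table.
#'
#' @param x an \code{smhat_score}.
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.smhat_score <- function(x, ...) {
  rows <- list()
  for (sh in x$week_sheets) {
    for (r in sh$ratings) {
      rows[[length(rows) + 1L]] <- data.frame(
        provision_id = x$provision_id, week = sh$week_index,
        item_id = r$item_id,
        rating = if (is_absent(r)) "A" else format(r$value),
        points = rating_points(r),
        evidence = paste(vapply(r$evidence, function(e)
          sprintf("w%dd%d:%s", e$week, e$day, e$name), ""), collapse = "; "),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Summarise scores by provision subgroup
#'
#' Anomalous (prices-only) scores are excluded from the mean and SD so
#' they do not skew the subgroup averages, but they are counted and listed
#' separately. SD is the sample standard deviation (n - 1); with a single
#' included score it is reported as NA, as is the mean when every score in
#' a subgroup is anomalous.
#'
#' @param scores list of \code{smhat_score} objects.
#' @return an \code{smhat_subgroup_summary}: a data.frame with one row per
#'   subgroup (n_total, n_included, n_anomalies, mean, sd, min, max) and an
#'   \code{anomalies} attribute listing the excluded provisions.
#' @export
aggregate_subgroup <- function(scores) {
  if (!length(scores)) stop("need at least one score", call. = FALSE)
  stopifnot(all(vapply(scores, inherits, TRUE, "smhat_score")))
  df <- data.frame(
    subgroup = vapply(scores, `[[`, "", "subgroup"),
    provision_id = vapply(scores, `[[`, "", "provision_id"),
    score = vapply(scores, `[[`, 0, "healthiness_score"),
    anomaly = vapply(scores, `[[`, TRUE, "anomaly"),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(split(df, df$subgroup), function(g) {
    inc <- g$score[!g$anomaly]
    data.frame(
      subgroup = g$subgroup[1], n_total = nrow(g), n_included = length(inc),
      n_anomalies = sum(g$anomaly),
      mean = if (length(inc)) mean(inc) else NA_real_,
      sd = if (length(inc) >= 2) stats::sd(inc) else NA_real_,
      min = if (length(inc)) min(inc) else NA_real_,
      max = if (length(inc)) max(inc) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "anomalies") <- df[df$anomaly, c("subgroup", "provision_id", "score")]
  class(out) <- c("smhat_subgroup_summary", "data.frame")
  out
}

#' @export
print.smhat_subgroup_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean <- round_half_up(y$mean, 1)
  y$sd <- round_half_up(y$sd, 2)
  print.data.frame(y, row.names = FALSE)
  an <- attr(x, "anomalies")
  if (nrow(an)) {
    cat(sprintf("%d anomalous (prices-only) provision(s) excluded from mean/sd:\n",
                nrow(an)))
    print.data.frame(an, row.names = FALSE)
  }
  invisible(x)
}
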