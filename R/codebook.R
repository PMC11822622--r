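#' The codebook: the instrument definition as data
#'
#' A codebook is the auditing instrument itself: an ordered list of
#' food-based items, each with a scoring rule, grouped into the ten
#' provision categories (breakfast; break time; fruit and vegetables; meat,
#' fish and alternatives; starchy carbohydrates; dairy and alternatives;
#' oils and spreads; HFSS; prices; general). Item maxima sum to the
#' declared instrument maximum: 22 points for the primary-phase instrument
#' and 28 for the secondary phase. The codebook is data, not code — the
#' shipped defaults live under \code{inst/extdata/codebooks/} and can be
#' replaced wholesale without touching the engine.
#'
#' Four rule kinds exist:
#' \describe{
#'   \item{binary}{scores 'A', 0 or 1 per week: 1 when some offering that
#'     week carries every required tag (and, if \code{min_distinct} > 1, at
#'     least that many distinctly named offerings do), 0 when the item's
#'     relevant tag class is mentioned somewhere in the cycle but the
#'     criterion is unmet that week, 'A' when the class is never mentioned.}
#'   \item{per_day}{scores the fraction of the 5 school days on which the
#'     criterion is met: 0, 0.2, 0.4, 0.6, 0.8 or 1.0 (or 'A').}
#'   \item{limit}{scores 1 when weekly occurrences are at or below
#'     \code{limit_max}, 0 when exceeded; when the tag class never appears
#'     in the cycle the item scores 'A' unless \code{absent_credit} is set
#'     (prohibition items such as "no free salt", where absence is the
#'     compliant state, score 1).}
#'   \item{frequency_per_period}{cycle-scoped count rule: 1 when the
#'     cycle-wide occurrence count reaches the threshold pro-rated to the
#'     cycle length (\code{ceiling(threshold * n_weeks / period_weeks)}),
#'     0 when the class appears but falls short, 'A' when never mentioned.
#'     The oily-fish rule — twice over a 4-week window — is of this kind.}
#' }
#'
#' @name codebook
NULL

RULE_KINDS <- c("binary", "per_day", "frequency_per_period", "limit")

#' Construct a scoring rule
#'
#' @param kind one of \code{"binary"}, \code{"per_day"},
#'   \code{"frequency_per_period"}, \code{"limit"}.
#' @param threshold occurrences required over the reference window
#'   (frequency_per_period only).
#' @param period_weeks reference window in weeks (frequency_per_period only).
#' @param limit_max weekly occurrences above which a limit item scores 0.
#' @param min_distinct for binary rules, the number of distinctly named
#'   qualifying offerings required per week (default 1).
#' @param absent_credit for limit rules: score 1 rather than 'A' when the
#'   tag class never appears (absence is the compliant state).
#' @return an object of class \code{smhat_rule}.
#' @export
scoring_rule <- function(kind, threshold = NULL, period_weeks = NULL,
                         limit_max = NULL, min_distinct = 1L,
                         absent_credit = FALSE) {
  kind <- match.arg(kind, RULE_KINDS)
  if (kind == "frequency_per_period") {
    if (is.null(threshold) || is.null(period_weeks) ||
        threshold < 1 || period_weeks < 1) {
      stop("frequency_per_period rules need threshold >= 1 and period_weeks >= 1",
           call. = FALSE)
    }
  }
  if (kind == "limit" && (is.null(limit_max) || limit_max < 0)) {
    stop("limit rules need limit_max >= 0", call. = FALSE)
  }
  if (min_distinct < 1) stop("min_distinct must be >= 1", call. = FALSE)
  structure(
    list(
      kind = kind,
      threshold = if (!is.null(threshold)) as.integer(threshold),
      period_weeks = if (!is.null(period_weeks)) as.integer(period_weeks),
      limit_max = if (!is.null(limit_max)) as.integer(limit_max),
      min_distinct = as.integer(min_distinct),
      absent_credit = isTRUE(absent_credit),
      days_per_week = 5L
    ),
    class = "smhat_rule"
  )
}

#' Construct a codebook item
#'
#' @param item_id unique identifier.
#' @param category one of the ten provision categories.
#' @param rule a \code{\link{scoring_rule}}.
#' @param required_tags food-tag vocabulary terms the rule inspects.
#' @param max_score points awarded at full marks (default 1).
#' @param relevant_tags tags whose presence anywhere in the cycle makes the
#'   item "mentioned" (so an unmet criterion rates 0, not 'A'); defaults to
#'   \code{required_tags}. E.g. the lower-fat-milk item requires
#'   \code{lower_fat_milk} but any \code{milk} offering makes it relevant.
#' @param slot restrict the rule to one meal slot (\code{"breakfast"},
#'   \code{"break"}, \code{"lunch"}); \code{NULL} inspects all slots.
#' @param description free text shown in reports.
#' @return an object of class \code{smhat_item}.
#' @export
codebook_item <- function(item_id, category, rule, required_tags,
                          max_score = 1, relevant_tags = NULL, slot = NULL,
                          description = "") {
  stopifnot(is.character(item_id), nchar(item_id) > 0)
  category <- match.arg(category, CATEGORIES)
  if (!inherits(rule, "smhat_rule")) stop("rule must be a scoring_rule", call. = FALSE)
  if (max_score <= 0) stop("max_score must be > 0", call. = FALSE)
  assert_tags(required_tags, "required_tag")
  relevant_tags <- unique(c(required_tags, relevant_tags %||% character()))
  assert_tags(relevant_tags, "relevant_tag")
  if (!is.null(slot)) slot <- match.arg(slot, MEAL_SLOTS)
  structure(
    list(
      item_id = item_id, category = category, rule = rule,
      required_tags = sort(required_tags), relevant_tags = sort(relevant_tags),
      max_score = as.numeric(max_score), slot = slot,
      description = description
    ),
    class = "smhat_item"
  )
}

#' Construct and validate a codebook
#'
#' @param phase \code{"primary"} or \code{"secondary"}.
#' @param items list of \code{\link{codebook_item}}s.
#' @param declared_max the instrument maximum the item maxima must sum to
#'   (22 primary, 28 secondary for the shipped defaults).
#' @param version free-text version tag.
#' @return an object of class \code{smhat_codebook}.
#' @export
codebook <- function(phase = c("primary", "secondary"), items, declared_max,
                     version = "custom") {
  phase <- match.arg(phase)
  if (!length(items) || !all(vapply(items, inherits, TRUE, "smhat_item"))) {
    stop("items must be a non-empty list of codebook_item objects", call. = FALSE)
  }
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids)) {
    stop("validation error: item_ids must be unique (duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), ")", call. = FALSE)
  }
  total <- sum(vapply(items, `[[`, 0, "max_score"))
  if (!isTRUE(all.equal(total, declared_max))) {
    stop(sprintf(
      "validation error: item max_scores sum to %s but declared_max is %s",
      format(total), format(declared_max)), call. = FALSE)
  }
  structure(
    list(phase = phase, items = items, declared_max = as.numeric(declared_max),
         version = version),
    class = "smhat_codebook"
  )
}

#' Maximum attainable score of a codebook
#'
#' The higher a provision scores, the closer it sits to the instrument's
#' healthiness ideal; this is the ceiling, equal to the sum of item maxima
#' and to the declared maximum (22 for the default primary instrument, 28
#' for secondary).
#'
#' @param cb an \code{smhat_codebook}.
#' @return numeric points.
#' @export
max_score <- function(cb) {
  stopifnot(inherits(cb, "smhat_codebook"))
  sum(vapply(cb$items, `[[`, 0, "max_score"))
}

item_ids <- function(cb) vapply(cb$items, `[[`, "", "item_id")

#' Load a codebook from a YAML configuration file
#'
#' Parses and fully validates an instrument definition. Files with a
#' malformed structure raise a parse error naming the offending field;
#' files violating an instrument invariant (duplicate ids, maxima not
#' summing to \code{declared_max}, unknown tags or categories) raise a
#' validation error naming the invariant.
#'
#' @param path path to a codebook YAML file, or one of the shipped
#'   defaults \code{"smhat_primary_v1"} / \code{"smhat_secondary_v1"}.
#' @return an \code{smhat_codebook}.
#' @seealso \code{\link{default_codebook}}, \code{\link{write_codebook}}
#' @export
load_codebook <- function(path) {
  if (path %in% c("smhat_primary_v1", "smhat_secondary_v1")) {
    path <- system.file("extdata", "codebooks", paste0(path, ".yaml"),
                        package = "smhat", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("codebook file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in codebook file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  for (f in c("phase", "declared_max", "items")) {
    if (is.null(raw[[f]])) stop("parse error: missing field '", f, "'", call. = FALSE)
  }
  items <- lapply(seq_along(raw$items), function(i) {
    it <- raw$items[[i]]
    for (f in c("item_id", "category", "rule", "required_tags")) {
      if (is.null(it[[f]])) {
        stop(sprintf("parse error: item %d is missing field '%s'", i, f),
             call. = FALSE)
      }
    }
    r <- it$rule
    if (is.null(r$kind)) {
      stop(sprintf("parse error: item '%s' rule is missing 'kind'", it$item_id),
           call. = FALSE)
    }
    rule <- scoring_rule(
      kind = r$kind, threshold = r$threshold, period_weeks = r$period_weeks,
      limit_max = r$limit_max, min_distinct = r$min_distinct %||% 1L,
      absent_credit = r$absent_credit %||% FALSE
    )
    codebook_item(
      item_id = it$item_id, category = it$category, rule = rule,
      required_tags = unlist(it$required_tags),
      max_score = it$max_score %||% 1,
      relevant_tags = unlist(it$relevant_tags),
      slot = it$slot, description = it$description %||% ""
    )
  })
  codebook(phase = raw$phase, items = items, declared_max = raw$declared_max,
           version = raw$version %||% "unversioned")
}

#' Write a codebook to a YAML file
#'
#' Inverse of \code{\link{load_codebook}}: reloading the written file gives
#' a field-by-field identical instrument.
#'
#' @param cb an \code{smhat_codebook}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "smhat_codebook"))
  items <- lapply(cb$items, function(it) {
    r <- it$rule
    rule <- list(kind = r$kind)
    if (!is.null(r$threshold)) rule$threshold <- r$threshold
    if (!is.null(r$period_weeks)) rule$period_weeks <- r$period_weeks
    if (!is.null(r$limit_max)) rule$limit_max <- r$limit_max
    if (r$min_distinct != 1L) rule$min_distinct <- r$min_distinct
    if (r$absent_credit) rule$absent_credit <- TRUE
    out <- list(item_id = it$item_id, category = it$category, rule = rule,
                max_score = it$max_score, required_tags = as.list(it$required_tags))
    extra <- setdiff(it$relevant_tags, it$required_tags)
    if (length(extra)) out$relevant_tags <- as.list(extra)
    if (!is.null(it$slot)) out$slot <- it$slot
    if (nchar(it$description)) out$description <- it$description
    out
  })
  yaml::write_yaml(
    list(phase = cb$phase, version = cb$version, declared_max = cb$declared_max,
         items = items),
    path
  )
  invisible(path)
}

#' Shipped default instruments
#'
#' Convenience wrapper around \code{\link{load_codebook}} for the two
#' instruments shipped with the package: \code{smhat_primary_v1}
#' (maximum 22) and \code{smhat_secondary_v1} (maximum 28). The secondary
#' instrument extends the primary with break-time, drinks and vegan
#' alternative items reflecting the wider secondary offering.
#'
#' @param phase \code{"primary"} or \code{"secondary"}.
#' @return an \code{smhat_codebook}.
#' @export
#' @examples
#' cb <- default_codebook("primary")
#' max_score(cb)  # 22
default_codebook <- function(phase = c("primary", "secondary")) {
  phase <- match.arg(phase)
  load_codebook(paste0("smhat_", phase, "_v1"))
}

#' @export
print.smhat_codebook <- function(x, ...) {
  cat(sprintf("<smhat codebook: %s phase, version %s>\n", x$phase, x$version))
  cat(sprintf("  %d items, maximum score %s\n", length(x$items),
              format(max_score(x))))
  cats <- vapply(x$items, `[[`, "", "category")
  for (ct in unique(cats)) {
    n <- sum(cats == ct)
    pts <- sum(vapply(x$items[cats == ct], `[[`, 0, "max_score"))
    cat(sprintf("  - %-24s %d item%s, %s pt%s\n", ct, n,
                if (n > 1) "s" else "", format(pts), if (pts != 1) "s" else ""))
  }
  invisible(x)
}

#' @export
print.smhat_item <- function(x, ...) {
  cat(sprintf("<smhat item '%s'> %s rule on {%s}%s, max %s\n",
              x$item_id, x$rule$kind, paste(x$required_tags, collapse = ", "),
              if (!is.null(x$slot)) paste0(" [", x$slot, "]") else "",
              format(x$max_score)))
  invisible(x)
}
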