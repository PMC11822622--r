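#' Menu-cycle data model
#'
#' School food provision is audited as a rotational menu cycle: 1--4 weeks
#' of 5 school days, each day carrying offerings in the breakfast, break or
#' lunch slot. Offerings carry controlled-vocabulary food tags (assigned by
#' coders, optionally assisted by \code{\link{tag_offering}}) and, where a
#' price list exists, integer-pence prices. Some provisions publish only a
#' price list; these are represented with \code{completeness =
#' "prices_only"} and are flagged as anomalies at scoring time.
#'
#' @name menu_model
NULL

#' Construct an offering
#'
#' @param name free-text offering name as printed on the menu.
#' @param slot meal slot: \code{"breakfast"}, \code{"break"} or \code{"lunch"}.
#' @param tags character vector from the food-tag vocabulary.
#' @param price integer pence, or \code{NULL} when unpriced.
#' @return an \code{smhat_offering}.
#' @export
offering <- function(name, slot = "lunch", tags = character(), price = NULL) {
  slot <- match.arg(slot, MEAL_SLOTS)
  assert_tags(tags)
  if (!is.null(price)) {
    if (length(price) != 1 || is.na(price) || price < 0 || price != round(price)) {
      stop("price must be a single non-negative integer (pence)", call. = FALSE)
    }
    price <- as.integer(price)
  }
  structure(list(name = name, slot = slot, tags = sort(unique(tags)),
                 price = price),
            class = "smhat_offering")
}

#' Construct a menu day
#' @param day_index school day 1--5.
#' @param offerings list of \code{\link{offering}}s.
#' @export
menu_day <- function(day_index, offerings = list()) {
  day_index <- as.integer(day_index)
  if (day_index < 1L || day_index > 5L) {
    stop("day_index must be within the 5-day school week (1..5)", call. = FALSE)
  }
  stopifnot(all(vapply(offerings, inherits, TRUE, "smhat_offering")))
  structure(list(day_index = day_index, offerings = offerings),
            class = "smhat_day")
}

#' Construct a menu week
#'
#' A week is exactly five school days, day indices 1..5 each once.
#'
#' @param week_index position in the rotational cycle.
#' @param days list of five \code{\link{menu_day}}s.
#' @export
menu_week <- function(week_index, days) {
  stopifnot(all(vapply(days, inherits, TRUE, "smhat_day")))
  idx <- vapply(days, `[[`, 0L, "day_index")
  if (length(days) != 5L || !setequal(idx, 1:5) || anyDuplicated(idx)) {
    stop("schema error: a menu week must contain exactly 5 days, day_index 1..5 each once (got ",
         length(days), " days)", call. = FALSE)
  }
  structure(list(week_index = as.integer(week_index),
                 days = days[order(idx)]),
            class = "smhat_week")
}

#' Construct a price list
#'
#' @param name character vector of entry names.
#' @param category_tag vocabulary term per entry.
#' @param price integer pence per entry.
#' @return an \code{smhat_pricelist} (a data frame).
#' @export
price_list <- function(name = character(), category_tag = character(),
                       price = integer()) {
  stopifnot(length(name) == length(category_tag), length(name) == length(price))
  assert_tags(category_tag, "category_tag")
  if (any(price < 0) || any(price != round(price))) {
    stop("prices must be non-negative integer pence", call. = FALSE)
  }
  structure(
    data.frame(name = as.character(name), category_tag = as.character(category_tag),
               price = as.integer(price), stringsAsFactors = FALSE),
    class = c("smhat_pricelist", "data.frame")
  )
}

#' Construct a menu cycle
#'
#' @param provision_id identifier for the provision under audit.
#' @param subgroup one of \code{"LA_primary"}, \code{"LA_secondary"},
#'   \code{"school_primary"}, \code{"school_secondary"}.
#' @param weeks list of \code{\link{menu_week}}s (may be empty for a
#'   prices-only provision).
#' @param price_list an \code{\link{price_list}} or \code{NULL}.
#' @param notes free text (the qualitative comment box).
#' @return an \code{smhat_menu} with \code{completeness} inferred:
#'   \code{"full"} (weeks and prices), \code{"menu_only"} or
#'   \code{"prices_only"}.
#' @export
menu_cycle <- function(provision_id, subgroup, weeks = list(),
                       price_list = NULL, notes = "") {
  subgroup <- match.arg(subgroup, SUBGROUPS)
  stopifnot(all(vapply(weeks, inherits, TRUE, "smhat_week")))
  if (!is.null(price_list) && !inherits(price_list, "smhat_pricelist")) {
    stop("price_list must be created with price_list()", call. = FALSE)
  }
  completeness <- if (length(weeks) == 0L) {
    if (is.null(price_list)) {
      stop("empty provision: a menu cycle needs weeks and/or a price list",
           call. = FALSE)
    }
    "prices_only"
  } else if (is.null(price_list)) "menu_only" else "full"
  structure(
    list(provision_id = provision_id, subgroup = subgroup, weeks = weeks,
         price_list = price_list, completeness = completeness,
         notes = notes),
    class = "smhat_menu"
  )
}

n_weeks <- function(cycle) length(cycle$weeks)

phase_of <- function(subgroup) {
  if (grepl("primary$", subgroup)) "primary" else "secondary"
}

#' @export
print.smhat_menu <- function(x, ...) {
  cat(sprintf("<smhat menu cycle '%s'> subgroup %s, %d week(s), completeness=%s\n",
              x$provision_id, x$subgroup, n_weeks(x), x$completeness))
  if (!is.null(x$price_list)) {
    cat(sprintf("  price list: %d entr%s\n", nrow(x$price_list),
                if (nrow(x$price_list) == 1) "y" else "ies"))
  }
  if (nchar(x$notes)) cat("  notes: ", substr(x$notes, 1, 60), "\n", sep = "")
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a menu cycle from a YAML file
#'
#' The schema mirrors the data model: top-level \code{provision_id},
#' \code{subgroup}, optional \code{notes}, optional \code{weeks} (each week
#' a list of exactly five days of offerings) and optional \code{price_list}
#' (entries of name / category_tag / price_pence). Unknown tags raise an
#' error listing the permitted vocabulary; a week with other than five days
#' raises a schema error.
#'
#' @param path path to a menu YAML file.
#' @return an \code{smhat_menu}.
#' @export
read_menu <- function(path) {
  if (!file.exists(path)) stop("menu file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in menu file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  for (f in c("provision_id", "subgroup")) {
    if (is.null(raw[[f]])) stop("parse error: missing field '", f, "'", call. = FALSE)
  }
  weeks <- lapply(seq_along(raw$weeks %||% list()), function(w) {
    wk <- raw$weeks[[w]]
    days <- lapply(wk$days %||% list(), function(d) {
      offs <- lapply(d$offerings %||% list(), function(o) {
        offering(name = o$name %||% "", slot = o$slot %||% "lunch",
                 tags = as.character(unlist(o$tags %||% list())),
                 price = o$price_pence)
      })
      menu_day(d$day, offs)
    })
    menu_week(wk$week %||% w, days)
  })
  pl <- NULL
  if (!is.null(raw$price_list)) {
    pl <- price_list(
      name = vapply(raw$price_list, function(e) as.character(e$name), ""),
      category_tag = vapply(raw$price_list, function(e) as.character(e$category_tag), ""),
      price = vapply(raw$price_list, function(e) as.integer(e$price_pence), 0L)
    )
  }
  menu_cycle(provision_id = raw$provision_id, subgroup = raw$subgroup,
             weeks = weeks, price_list = pl, notes = raw$notes %||% "")
}

#' Write a menu cycle to a YAML file
#'
#' Inverse of \code{\link{read_menu}}: \code{read_menu(write_menu(m))} is
#' identical to \code{m}, including notes text and completeness.
#'
#' @param cycle an \code{smhat_menu}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_menu <- function(cycle, path) {
  stopifnot(inherits(cycle, "smhat_menu"))
  out <- list(provision_id = cycle$provision_id, subgroup = cycle$subgroup)
  if (nchar(cycle$notes)) out$notes <- cycle$notes
  if (n_weeks(cycle) > 0) {
    out$weeks <- lapply(cycle$weeks, function(wk) {
      list(week = wk$week_index, days = lapply(wk$days, function(d) {
        list(day = d$day_index, offerings = lapply(d$offerings, function(o) {
          e <- list(name = o$name, slot = o$slot, tags = as.list(o$tags))
          if (!is.null(o$price)) e$price_pence <- o$price
          e
        }))
      }))
    })
  }
  if (!is.null(cycle$price_list)) {
    out$price_list <- lapply(seq_len(nrow(cycle$price_list)), function(i) {
      list(name = cycle$price_list$name[i],
           category_tag = cycle$price_list$category_tag[i],
           price_pence = cycle$price_list$price[i])
    })
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a price list from a CSV file
#'
#' Columns: \code{name}, \code{category_tag}, \code{price_pence}.
#'
#' @param path CSV path.
#' @return an \code{smhat_pricelist}.
#' @export
read_price_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "category_tag", "price_pence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("price list is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  price_list(df$name, df$category_tag, df$price_pence)
}

# ---- lexicon ----------------------------------------------------------------

#' Load the keyword-to-tag lexicon
#'
#' A two-column CSV (\code{keyword}, \code{tags}; tags separated by
#' semicolons) mapping menu vocabulary to food tags. \code{path = NULL}
#' loads the shipped default lexicon.
#'
#' @param path CSV path or \code{NULL} for the default.
#' @return named list keyword -> character vector of tags.
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon.csv", package = "smhat",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("keyword", "tags") %in% names(df))) {
    stop("lexicon needs columns 'keyword' and 'tags'", call. = FALSE)
  }
  lex <- lapply(strsplit(df$tags, ";", fixed = TRUE), function(tg) {
    assert_tags(trimws(tg))
  })
  names(lex) <- tolower(trimws(df$keyword))
  lex
}

normalise_name <- function(name) {
  tolower(gsub("\\s+", " ", trimws(name)))
}

#' Auto-tag an offering name against a lexicon
#'
#' Matches lexicon keywords as whole words, case-insensitively, against
#' the offering name and returns the union of their tags. Assistive only:
#' coders remain free to override tags in the menu file. A name matching
#' no keyword (e.g. a novel dish such as a Buddha bowl) returns the empty
#' set with a warning, signalling that manual tagging is needed.
#'
#' @param name free-text offering name.
#' @param lexicon named list keyword -> tags, e.g. from
#'   \code{\link{load_lexicon}}.
#' @return character vector of tags (possibly empty).
#' @export
#' @examples
#' tag_offering("Grilled salmon", list(salmon = c("fish", "oily_fish")))
tag_offering <- function(name, lexicon) {
  if (!length(lexicon)) stop("lexicon must be non-empty", call. = FALSE)
  nm <- normalise_name(name)
  hits <- vapply(names(lexicon), function(kw) {
    grepl(paste0("\\b", kw, "\\b"), nm, perl = TRUE)
  }, TRUE)
  tags <- sort(unique(unlist(lexicon[hits], use.names = FALSE)))
  if (!length(tags)) {
    warning("no lexicon match for offering '", name,
            "'; tag it manually in the menu file", call. = FALSE)
    tags <- character()
  }
  tags
}
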