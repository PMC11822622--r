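# Brute-force rating oracle: re-derives every rating from first principles
# on a flat (week, day, slot, name, tags) table, independently of the
# engine's traversal. Used to cross-check rate_item on small cycles.

flatten_cycle <- function(cycle) {
  rows <- list()
  for (w in cycle$weeks) {
    for (d in w$days) {
      for (o in d$offerings) {
        rows[[length(rows) + 1L]] <- data.frame(
          week = w$week_index, day = d$day_index, slot = o$slot,
          name = o$name, tags = I(list(o$tags)), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(week = integer(), day = integer(), slot = character(),
                      name = character(), tags = I(list())))
  }
  do.call(rbind, rows)
}

oracle_rate <- function(cycle, item, week_index) {
  tab <- flatten_cycle(cycle)
  if (!is.null(item$slot)) tab <- tab[tab$slot == item$slot, , drop = FALSE]
  has_any <- function(tags, set) length(intersect(tags, set)) > 0
  has_all <- function(tags, set) all(set %in% tags)

  mentioned <- any(vapply(tab$tags, has_any, TRUE, set = item$relevant_tags))
  rule <- item$rule
  wtab <- tab[tab$week == week_index, , drop = FALSE]

  if (rule$kind == "frequency_per_period") {
    if (!mentioned) return("A")
    count <- sum(vapply(tab$tags, has_all, TRUE, set = item$required_tags))
    need <- ceiling(rule$threshold * length(cycle$weeks) / rule$period_weeks)
    return(as.character(as.numeric(count >= need)))
  }
  if (rule$kind == "per_day") {
    if (!mentioned) return("A")
    ok <- vapply(wtab$tags, has_all, TRUE, set = item$required_tags)
    return(as.character(length(unique(wtab$day[ok])) / 5))
  }
  if (rule$kind == "binary") {
    if (!mentioned) return("A")
    ok <- vapply(wtab$tags, has_all, TRUE, set = item$required_tags)
    distinct <- unique(tolower(gsub("\\s+", " ", trimws(wtab$name[ok]))))
    return(as.character(as.numeric(length(distinct) >= rule$min_distinct)))
  }
  # limit
  count <- sum(vapply(wtab$tags, has_any, TRUE, set = item$required_tags))
  if (!mentioned) return(if (rule$absent_credit) "1" else "A")
  as.character(as.numeric(count <= rule$limit_max))
}

rating_chr <- function(r) if (identical(r$value, "A")) "A" else as.character(r$value)
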