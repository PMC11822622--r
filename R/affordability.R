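#' Free-school-meal affordability analysis
#'
#' Compares a local authority's free-school-meal (FSM) allowance with a
#' provision's price list: can an FSM pupil buy the meal deal (main meal
#' plus drink), how large is the shortfall or the residual allowance, what
#' else could the residual buy, and which items are outpriced altogether.
#' All arithmetic is in integer pence; pounds appear only in display.
#'
#' @name affordability
NULL

#' Construct an FSM allowance
#'
#' @param la_id local-authority identifier.
#' @param phase \code{"primary"} or \code{"secondary"}.
#' @param amount daily allowance in integer pence (> 0).
#' @export
fsm_allowance <- function(la_id, phase = c("primary", "secondary"), amount) {
  phase <- match.arg(phase)
  if (length(amount) != 1 || amount <= 0 || amount != round(amount)) {
    stop("allowance amount must be a positive integer (pence)", call. = FALSE)
  }
  structure(list(la_id = la_id, phase = phase, amount = as.integer(amount)),
            class = "smhat_allowance")
}

#' Read an FSM allowance table from CSV
#'
#' Columns: \code{la_id}, \code{phase}, \code{amount_pence}.
#'
#' @param path CSV path.
#' @return list of \code{smhat_allowance} objects.
#' @export
read_allowances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("la_id", "phase", "amount_pence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allowance table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    fsm_allowance(df$la_id[i], df$phase[i], df$amount_pence[i])
  })
}

#' Meal-deal affordability check
#'
#' Uses the cheapest \code{meal_deal} entry on the price list. The
#' disparity is price minus allowance (positive = shortfall, the pupil
#' cannot buy the meal deal); when affordable, the residual is the spare
#' allowance and \code{affordable_items} lists the entries the residual
#' still covers (e.g. an inexpensive condiment sachet). Without any
#' meal-deal entry the report is item-level only: \code{affordable_items}
#' are entries within the full allowance.
#'
#' @param allowance an \code{\link{fsm_allowance}}.
#' @param pl an \code{\link{price_list}}.
#' @return an \code{smhat_affordability}: provision fields
#'   \code{meal_deal_price}, \code{affordable}, \code{disparity},
#'   \code{residual}, \code{affordable_items}, \code{outpriced_items}.
#' @export
#' @examples
#' pl <- price_list(c("meal deal", "salt sachet", "panini"),
#'                  c("meal_deal", "condiment", "bread"),
#'                  c(240L, 11L, 290L))
#' meal_deal_check(fsm_allowance("LA1", "secondary", 260L), pl)
meal_deal_check <- function(allowance, pl) {
  stopifnot(inherits(allowance, "smhat_allowance"),
            inherits(pl, "smhat_pricelist"))
  deals <- pl[pl$category_tag == "meal_deal", , drop = FALSE]
  others <- pl[pl$category_tag != "meal_deal", , drop = FALSE]
  if (nrow(deals) == 0) {
    res <- list(meal_deal_price = NULL, affordable = NA, disparity = NULL,
                residual = NULL,
                affordable_items = others$name[others$price <= allowance$amount])
  } else {
    price <- min(deals$price)
    disparity <- price - allowance$amount
    affordable <- disparity <= 0L
    residual <- if (affordable) -disparity else NULL
    budget <- if (affordable) residual else allowance$amount
    res <- list(meal_deal_price = price, affordable = affordable,
                disparity = disparity, residual = residual,
                affordable_items = others$name[others$price <= budget])
  }
  res$outpriced_items <- outpriced_items(allowance, pl)
  res$allowance <- allowance$amount
  res$la_id <- allowance$la_id
  structure(res, class = "smhat_affordability")
}

#' Items priced above the allowance
#'
#' Price-list entries an FSM pupil cannot buy at all (price strictly above
#' the allowance), sorted most expensive first.
#'
#' @inheritParams meal_deal_check
#' @return character vector of entry names (possibly empty).
#' @export
outpriced_items <- function(allowance, pl) {
  stopifnot(inherits(allowance, "smhat_allowance"),
            inherits(pl, "smhat_pricelist"))
  out <- pl[pl$price > allowance$amount, , drop = FALSE]
  out$name[order(out$price, decreasing = TRUE)]
}

#' Per-category price summary
#'
#' For each category tag on a price list: n, mean price (rounded half-up
#' to the penny), sample SD (n - 1; NA for a single entry) and mode (most
#' frequent price, ties broken toward the lower price — conservative for
#' affordability claims). Empty categories are simply absent.
#'
#' @param pl an \code{\link{price_list}}.
#' @return data.frame with columns category_tag, n, mean, sd, mode.
#' @export
#' @examples
#' price_summary(price_list(c("toast", "toast", "toast"),
#'                          rep("bread", 3), c(35L, 35L, 40L)))
price_summary <- function(pl) {
  stopifnot(inherits(pl, "smhat_pricelist"))
  if (nrow(pl) == 0) {
    return(data.frame(category_tag = character(), n = integer(),
                      mean = numeric(), sd = numeric(), mode = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(pl$price, pl$category_tag), function(p) {
    tab <- table(p)
    modes <- as.integer(names(tab)[tab == max(tab)])
    data.frame(n = length(p),
               mean = round_half_up(mean(p)),
               sd = if (length(p) >= 2) stats::sd(p) else NA_real_,
               mode = min(modes))
  }))
  out <- cbind(data.frame(category_tag = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' @export
print.smhat_affordability <- function(x, ...) {
  cat(sprintf("<smhat affordability> LA %s, allowance %s\n",
              x$la_id, format_pence(x$allowance)))
  if (is.null(x$meal_deal_price)) {
    cat("  no meal deal on the price list; item-level analysis only\n")
  } else if (x$affordable) {
    cat(sprintf("  meal deal %s: AFFORDABLE, residual %s\n",
                format_pence(x$meal_deal_price), format_pence(x$residual)))
  } else {
    cat(sprintf("  meal deal %s: NOT affordable, shortfall %s\n",
                format_pence(x$meal_deal_price), format_pence(x$disparity)))
  }
  if (length(x$affordable_items)) {
    cat("  affordable extras:", paste(x$affordable_items, collapse = ", "), "\n")
  }
  if (length(x$outpriced_items)) {
    cat("  outpriced items:", paste(x$outpriced_items, collapse = ", "), "\n")
  }
  invisible(x)
}
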