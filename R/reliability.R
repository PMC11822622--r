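#' Intercoder reliability
#'
#' Two-stage reliability workflow for content-analysis coding. Stage one:
#' several coders rate the same menus; ratings are binary-recoded (the
#' non-numeric 'A' cannot enter numeric agreement statistics) and per-item
#' dispersion (sample SD) plus mean pairwise agreement quantify where the
#' codebook is ambiguous. Stage two: two coders' recoded ratings are
#' compared with Cohen's kappa, interpreted on McHugh's bands for health
#' research (0.60--0.79 moderate, 0.80--0.90 strong, above 0.90 almost
#' perfect).
#'
#' @name reliability
NULL

#' Binary-recode a rating
#'
#' 'A' is a non-numerical rating, so agreement statistics operate on a
#' binary recode: 1 when the numeric rating reaches \code{cutpoint} times
#' the item maximum ("criterion met"), else 0; 'A' recodes to 0. The
#' default cutpoint of 1 counts only full marks as met.
#'
#' @param rating \code{"A"} or a numeric rating.
#' @param item_max the item's maximum score (default 1).
#' @param cutpoint proportion of \code{item_max} at or above which the
#'   recode is 1.
#' @return 0 or 1 (integer).
#' @export
#' @examples
#' binary_recode("A")          # 0
#' binary_recode(0.6)          # 0
#' binary_recode(0.6, cutpoint = 0.5)  # 1
binary_recode <- function(rating, item_max = 1, cutpoint = 1) {
  if (identical(rating, "A")) return(0L)
  rating <- as.numeric(rating)
  if (is.na(rating) || rating < 0 || rating > item_max) {
    stop("validation error: rating must be 'A' or numeric in [0, item_max]",
         call. = FALSE)
  }
  as.integer(rating >= cutpoint * item_max - 1e-9)
}

recode_vector <- function(ratings, item_max = 1, cutpoint = 1) {
  vapply(ratings, binary_recode, 0L, item_max = item_max, cutpoint = cutpoint)
}

#' Per-item dispersion across coders
#'
#' Sample standard deviation (n - 1 denominator) of the binary-recoded
#' ratings that multiple coders gave the same item of the same menu. Low
#' SD marks items coders apply consistently; high SD flags codebook
#' ambiguity. Averaging SDs across menus is left to the caller.
#'
#' @param ratings vector of ratings ('A' or numeric), one per coder.
#' @param item_max,cutpoint passed to \code{\link{binary_recode}}.
#' @return the sample SD of the recoded ratings.
#' @export
item_sd <- function(ratings, item_max = 1, cutpoint = 1) {
  if (length(ratings) < 2) stop("item_sd needs at least two coders", call. = FALSE)
  stats::sd(recode_vector(ratings, item_max, cutpoint))
}

#' Mean pairwise agreement across coders
#'
#' The mean, over all coder pairs, of the indicator that their
#' binary-recoded ratings match; 1 means unanimity.
#'
#' @inheritParams item_sd
#' @return proportion in [0, 1].
#' @export
pairwise_agreement <- function(ratings, item_max = 1, cutpoint = 1) {
  if (length(ratings) < 2) {
    stop("pairwise_agreement needs at least two coders", call. = FALSE)
  }
  x <- recode_vector(ratings, item_max, cutpoint)
  pairs <- utils::combn(length(x), 2)
  mean(x[pairs[1, ]] == x[pairs[2, ]])
}

#' Cohen's kappa for two coders
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} on
#' aligned binary rating vectors: \eqn{p_o} is the fraction of units the
#' coders rate identically and \eqn{p_e = \sum_c P_a(c) P_b(c)} the
#' agreement expected from each coder's marginal proportions over the
#' classes \{0, 1\}. When both coders use a single class (\eqn{p_e = 1}),
#' kappa is defined as 1 for unanimous identical ratings and is otherwise
#' an error (degenerate marginals).
#'
#' @param coder_a,coder_b equal-length vectors of 0/1 ratings (length >= 2).
#' @return an \code{smhat_kappa}: kappa, p_o, p_e, McHugh band, n_units.
#' @seealso \code{\link{mchugh_band}}, \code{\link{kappa_from_scores}}
#' @export
#' @examples
#' cohens_kappa(c(1,1,1,1,0,0,1,0,1,1), c(1,1,0,1,0,1,1,0,1,1))
cohens_kappa <- function(coder_a, coder_b) {
  if (length(coder_a) != length(coder_b)) {
    stop("coder vectors must be aligned and of equal length", call. = FALSE)
  }
  n <- length(coder_a)
  if (n < 2) stop("kappa needs at least two rating units", call. = FALSE)
  if (!all(coder_a %in% c(0, 1)) || !all(coder_b %in% c(0, 1))) {
    stop("ratings must be binary-recoded 0/1 (see binary_recode)", call. = FALSE)
  }
  p_o <- mean(coder_a == coder_b)
  pa1 <- mean(coder_a); pb1 <- mean(coder_b)
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) {
      kappa <- 1
    } else {
      stop("degenerate marginals: both coders used a single class but disagree; kappa undefined",
           call. = FALSE)
    }
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(
    list(kappa = kappa, p_o = p_o, p_e = p_e, band = mchugh_band(kappa),
         n_units = n),
    class = "smhat_kappa"
  )
}

#' Interpret kappa on McHugh's bands
#'
#' Bands for health research: below 0.60 is below moderate; 0.60--0.79
#' moderate; 0.80--0.90 strong; above 0.90 almost perfect. The published
#' edges leave a gap between 0.79 and 0.80; values falling in it are
#' assigned by rounding half-up to the two decimals the bands are stated
#' in (0.795 therefore bands as 0.80, strong; 0.792 as 0.79, moderate).
#' Outside the gap the stated edges apply exactly, so 0.901 is already
#' "over 0.90" and bands as almost perfect.
#'
#' @param kappa value in [-1, 1].
#' @return one of \code{"below_moderate"}, \code{"moderate"},
#'   \code{"strong"}, \code{"almost_perfect"}.
#' @export
#' @examples
#' mchugh_band(0.60)   # "moderate"
#' mchugh_band(0.901)  # "almost_perfect"
mchugh_band <- function(kappa) {
  if (is.na(kappa) || kappa < -1 - 1e-9 || kappa > 1 + 1e-9) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  in_gap <- kappa > 0.79 && kappa < 0.80
  k <- if (in_gap) round_half_up(kappa, 2) else kappa
  if (k < 0.60) "below_moderate"
  else if (k <= 0.79) "moderate"
  else if (k <= 0.90) "strong"
  else "almost_perfect"
}

#' @export
print.smhat_kappa <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa: %.4f  (p_o = %.4f, p_e = %.4f, n = %d)\n  agreement band: %s\n",
    x$kappa, x$p_o, x$p_e, x$n_units, gsub("_", " ", x$band)))
  invisible(x)
}

#' Kappa from two coders' raw score sheets
#'
#' Convenience wrapper mirroring the study workflow: takes two aligned
#' vectors of raw ratings ('A' or numeric) over the pooled item-by-week
#' units of one or more menus, binary-recodes both, and returns Cohen's
#' kappa.
#'
#' @param ratings_a,ratings_b aligned raw rating vectors.
#' @param item_max,cutpoint passed to \code{\link{binary_recode}}.
#' @return an \code{smhat_kappa}.
#' @export
kappa_from_scores <- function(ratings_a, ratings_b, item_max = 1, cutpoint = 1) {
  cohens_kappa(recode_vector(ratings_a, item_max, cutpoint),
               recode_vector(ratings_b, item_max, cutpoint))
}

#' Intercoder-reliability report from a ratings table
#'
#' Takes a long-format ratings table (columns \code{menu_id},
#' \code{item_id}, \code{week}, \code{coder_id}, \code{rating}) such as
#' the CSV consumed by the command-line tool, and returns per-item SD
#' (averaged over menus and weeks) plus, when exactly two coders are
#' present or a pair is named, per-menu Cohen's kappa over the pooled
#' item-by-week units.
#'
#' @param df a data.frame of ratings; \code{rating} may contain "A".
#' @param pair optional character vector of two coder_ids.
#' @param cutpoint recode cutpoint, see \code{\link{binary_recode}}.
#' @return list with elements \code{item_sd} (data.frame) and
#'   \code{kappa} (data.frame, possibly empty).
#' @export
icr_report <- function(df, pair = NULL, cutpoint = 1) {
  need <- c("menu_id", "item_id", "week", "coder_id", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ratings table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$recoded <- vapply(seq_len(nrow(df)), function(i) {
    r <- df$rating[i]
    binary_recode(if (identical(as.character(r), "A")) "A" else as.numeric(r),
                  cutpoint = cutpoint)
  }, 0L)

  unit <- paste(df$menu_id, df$item_id, df$week, sep = "\r")
  sds <- tapply(df$recoded, unit, function(x) if (length(x) >= 2) stats::sd(x) else NA_real_)
  key <- do.call(rbind, strsplit(names(sds), "\r", fixed = TRUE))
  per_unit <- data.frame(menu_id = key[, 1], item_id = key[, 2],
                         week = key[, 3], sd = as.numeric(sds),
                         stringsAsFactors = FALSE)
  item_sd_tab <- stats::aggregate(sd ~ item_id, data = per_unit, FUN = mean,
                                  na.rm = TRUE)

  coders <- pair %||% sort(unique(df$coder_id))
  kap <- data.frame()
  if (length(coders) == 2) {
    wide_rows <- lapply(split(df, df$menu_id), function(g) {
      a <- g[g$coder_id == coders[1], ]
      b <- g[g$coder_id == coders[2], ]
      keyed <- merge(a[, c("item_id", "week", "recoded")],
                     b[, c("item_id", "week", "recoded")],
                     by = c("item_id", "week"))
      if (nrow(keyed) < 2) return(NULL)
      kr <- tryCatch(cohens_kappa(keyed$recoded.x, keyed$recoded.y),
                     error = function(e) NULL)
      if (is.null(kr)) return(NULL)
      data.frame(menu_id = g$menu_id[1], n_units = kr$n_units,
                 p_o = kr$p_o, p_e = kr$p_e, kappa = kr$kappa,
                 band = kr$band, stringsAsFactors = FALSE)
    })
    kap <- do.call(rbind, wide_rows)
    if (is.null(kap)) kap <- data.frame()
    rownames(kap) <- NULL
  }
  list(item_sd = item_sd_tab, kappa = kap)
}
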