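test_that("binary recoding maps 'A' to 0 and thresholds numeric ratings", {
  expect_identical(binary_recode("A"), 0L)
  expect_identical(binary_recode(1.0), 1L)
  expect_identical(binary_recode(0.6), 0L)
  expect_identical(binary_recode(0.6, cutpoint = 0.5), 1L)
  expect_identical(binary_recode(0), 0L)
  expect_error(binary_recode(1.4), "validation error")
  expect_error(binary_recode(-0.2), "validation error")
})

test_that("per-item dispersion is the sample SD of recoded ratings", {
  expect_equal(item_sd(c(1, 1, 1, 1, 1)), 0)
  # hand computation: var = 1.2/4 = 0.3, sd = sqrt(0.3)
  expect_equal(item_sd(c(1, 1, 1, 0, 0)), sqrt(0.3), tolerance = 1e-12)
  expect_equal(round(item_sd(c(1, 1, 1, 0, 0)), 4), 0.5477)
  expect_equal(round(item_sd(c(1, 0)), 4), 0.7071)  # sqrt(0.5)
  # 'A' enters as 0
  expect_equal(item_sd(c("A", 1)), item_sd(c(0, 1)))
  expect_error(item_sd(1), "two coders")
})

test_that("pairwise agreement enumerates coder pairs", {
  expect_equal(pairwise_agreement(c(1, 1, 1)), 1)
  expect_equal(pairwise_agreement(c(1, 1, 0)), 1 / 3)
  expect_equal(pairwise_agreement(c(1, 0)), 0)
  # unanimity for any number of coders
  for (k in 2:6) expect_equal(pairwise_agreement(rep(1, k)), 1)
  # 'A' recodes to 0, agreeing with a rating of 0
  expect_equal(pairwise_agreement(c("A", 0)), 1)
  expect_error(pairwise_agreement(1), "two coders")
})

test_that("Cohen's kappa reproduces hand-computed contingency values", {
  a <- c(1, 1, 1, 1, 0, 0, 1, 0, 1, 1)
  b <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  k <- cohens_kappa(a, b)
  # oracle by hand: p_o = 8/10; marginals 0.7/0.7 -> p_e = 0.49 + 0.09
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.58)
  expect_equal(k$kappa, (0.8 - 0.58) / (1 - 0.58), tolerance = 1e-12)
  expect_equal(round(k$kappa, 4), 0.5238)
  expect_equal(k$n_units, 10L)

  expect_equal(cohens_kappa(b, b)$kappa, 1)
  expect_equal(cohens_kappa(c(1, 0), c(0, 1))$kappa, -1)
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(cohens_kappa(c(1), c(1)), "at least two")
  # degenerate unanimity: shared single class is perfect agreement
  expect_equal(cohens_kappa(c(1, 1, 1), c(1, 1, 1))$kappa, 1)
  expect_identical(cohens_kappa(c(0, 0), c(0, 0))$band, "almost_perfect")
  # opposite unanimity has p_e = 0, so kappa is simply (0 - 0)/(1 - 0) = 0
  expect_equal(cohens_kappa(c(1, 1), c(0, 0))$kappa, 0)
})

test_that("kappa is symmetric and never exceeds observed agreement", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:40, 1)
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    kab <- tryCatch(cohens_kappa(a, b), error = function(e) NULL)
    if (is.null(kab)) next
    kba <- cohens_kappa(b, a)
    expect_equal(kab$kappa, kba$kappa)
    expect_lte(kab$kappa, kab$p_o + 1e-12)
    # kappa == 1 iff perfect agreement
    expect_identical(isTRUE(all.equal(kab$kappa, 1)), kab$p_o == 1)
  }
})

test_that("McHugh bands reproduce the published edges", {
  expect_identical(mchugh_band(0.60), "moderate")
  expect_identical(mchugh_band(0.79), "moderate")
  expect_identical(mchugh_band(0.80), "strong")
  expect_identical(mchugh_band(0.85), "strong")
  expect_identical(mchugh_band(0.90), "strong")
  expect_identical(mchugh_band(0.901), "almost_perfect")
  expect_identical(mchugh_band(0.59), "below_moderate")
  expect_identical(mchugh_band(-1), "below_moderate")
  # the 0.79-0.80 gap resolves by half-up rounding to two decimals
  expect_identical(mchugh_band(0.792), "moderate")
  expect_identical(mchugh_band(0.795), "strong")
  expect_error(mchugh_band(1.2), "\\[-1, 1\\]")
  # band stored on the kappa object agrees with the banding function
  k <- cohens_kappa(c(1, 1, 1, 1, 0, 0, 1, 0, 1, 1),
                    c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1))
  expect_identical(k$band, mchugh_band(k$kappa))
})

test_that("kappa_from_scores recodes raw sheets before comparing", {
  a <- c("A", 1, 0.6, 1, 0)
  b <- c(0, 1, 0, 1, "A")
  k <- kappa_from_scores(a, b)
  expect_equal(k$p_o, 1)  # recodes agree everywhere at cutpoint 1
  expect_equal(k$kappa, 1)
})

test_that("icr_report produces per-item SD and per-menu kappa from a long table", {
  df <- expand.grid(menu_id = c("m1", "m2"), item_id = c("veg", "fish"),
                    week = 1:2, coder_id = c("c1", "c2"),
                    stringsAsFactors = FALSE)
  set.seed(42)
  df$rating <- sample(c("A", "0", "1"), nrow(df), replace = TRUE)
  rep <- icr_report(df)
  expect_setequal(rep$item_sd$item_id, c("veg", "fish"))
  expect_true(all(rep$item_sd$sd >= 0 & rep$item_sd$sd <= sqrt(0.5) + 1e-9))
  expect_true(all(rep$kappa$menu_id %in% c("m1", "m2")))
  expect_true(all(rep$kappa$kappa <= 1))
  expect_error(icr_report(df[, -1]), "missing column")
})
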