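# Lab-based adoption classification and belief-vs-lab misclassification.

test_that("classification follows the strip and threshold rules", {
  expect_equal(classify_lab_adoption(c(0, 0), 0.5)$label, "non_bt")
  expect_equal(classify_lab_adoption(c(1, 0), 0.9)$label, "weak_bt")
  expect_equal(classify_lab_adoption(c(1, 1), 3.09)$label, "true_bt")
  expect_equal(classify_lab_adoption(c(1, 1), 1.90)$label, "true_bt")
  expect_equal(classify_lab_adoption(c(0, 0), 5.0)$label, "non_bt")
  expect_error(classify_lab_adoption(numeric(0), 1.0), "strip")
  expect_error(classify_lab_adoption(c(1, 0), -0.1), "expression")
})

test_that("classification partitions and is monotone in the threshold", {
  set.seed(4)
  for (i in 1:200) {
    strips <- rbinom(sample(1:5, 1), 1, 0.5)
    expr <- rexp(1, 1 / 1.5)
    lo <- classify_lab_adoption(strips, expr, threshold = 1.0)$label
    hi <- classify_lab_adoption(strips, expr, threshold = 2.5)$label
    expect_true(lo %in% c("non_bt", "weak_bt", "true_bt"))
    # raising the threshold can only move true_bt -> weak_bt, never back
    if (lo == "weak_bt") expect_true(hi != "true_bt")
    if (hi == "true_bt") expect_equal(lo, "true_bt")
    if (lo == "non_bt") expect_equal(hi, "non_bt")
  }
})

test_that("published cross-tab counts reproduce the published rates", {
  xt <- published_crosstab()
  expect_equal(sum(xt$n), 564)
  r <- misclassification_rates(xt)
  pj <- r[r$province == "punjab", ]
  sd_ <- r[r$province == "sindh", ]
  expect_equal(pj$n, 435)
  expect_equal(pj$type1, 61 / 353)
  expect_equal(pj$type2, 17 / 30)
  expect_equal(pj$self_reported_adoption, 353 / 435)
  expect_equal(pj$lab_adoption, 355 / 435)
  expect_equal(pj$incorrect_or_uncertain, 129 / 435)
  expect_equal(sd_$lab_adoption, 97 / 129)
  expect_equal(sd_$incorrect_or_uncertain, 66 / 129)
})

test_that("degenerate cross-tabs give zero or undefined rates, never fake zeros", {
  xt <- data.frame(province = "p",
                   belief = c("bt", "non_bt"),
                   strip_outcome = c("at_least_one_positive", "all_negative"),
                   n = c(10, 5))
  r <- misclassification_rates(xt)
  expect_equal(r$type1, 0)
  expect_equal(r$type2, 0)
  # empty denominator: no non-Bt believers at all
  xt2 <- data.frame(province = "p", belief = "bt",
                    strip_outcome = "at_least_one_positive", n = 10)
  r2 <- misclassification_rates(xt2)
  expect_true(is.na(r2$type2))
  expect_equal(r2$type1, 0)
})

test_that("a single record produces exactly one non-zero cell", {
  rec <- data.frame(province = "punjab", belief = "bt", strip_1 = 1,
                    strip_2 = 0, bt_expression = 2.5, pesticide_qty = 2.0)
  xt <- cross_tabulate(rec)
  expect_equal(sum(xt$n > 0), 1L)
  expect_equal(sum(xt$n), 1L)
  expect_equal(xt$mean_bt_expression[xt$n > 0], 2.5)
})

test_that("unknown belief codes are excluded and counted", {
  rec <- data.frame(province = "punjab",
                    belief = c("bt", "banana"), strip_1 = c(1, 1),
                    bt_expression = c(2, 2), pesticide_qty = c(1, 1))
  expect_message(xt <- cross_tabulate(rec), "unknown belief")
  expect_equal(sum(xt$n), 1L)
  expect_equal(attr(xt, "n_excluded"), 1L)
})

test_that("simulated cross-tab reproduces belief-conditional target rates", {
  # calibrate the generator to the Punjab belief-conditional errors
  p <- 355 / 435
  cal <- calibrate_misclassification(p, 61 / 353, 17 / 30,
                                     dontknow_rate = 51 / 435)
  cfg <- dgp_config(n_farmers = 10000, seed = 31,
                    province_share_punjab = 1,
                    category_probs = c(non_bt = 80 / 435,
                                       weak_bt = 259 / 435,
                                       true_bt = 96 / 435),
                    misclass = list(type1_rate = cal$type1_rate,
                                    type2_rate = cal$type2_rate,
                                    dontknow_rate = 51 / 435))
  s <- generate_survey(cfg)
  r <- misclassification_rates(cross_tabulate(s))
  n_bt <- sum(s$belief == "bt")
  n_nbt <- sum(s$belief == "non_bt")
  expect_lt(abs(r$type1 - 61 / 353),
            3 * sqrt(0.1728 * (1 - 0.1728) / n_bt))
  expect_lt(abs(r$type2 - 17 / 30),
            3 * sqrt(0.5667 * (1 - 0.5667) / n_nbt))
})

test_that("rates recovered from synthetic data track the configuration", {
  cfg <- dgp_config(n_farmers = 8000, seed = 12)
  s <- generate_survey(cfg)
  # truth-conditional checks straight against the configured rates
  lab_neg <- s$true_category == "non_bt"
  a_hat <- mean(s$belief[lab_neg] == "bt")
  expect_lt(abs(a_hat - cfg$misclass$type1_rate),
            3 * sqrt(0.55 * 0.45 / sum(lab_neg)))
  dk_hat <- mean(s$belief == "dont_know")
  expect_lt(abs(dk_hat - cfg$misclass$dontknow_rate),
            3 * sqrt(0.18 * 0.82 / nrow(s)))
})
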