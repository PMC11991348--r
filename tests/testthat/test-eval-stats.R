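test_that("accuracy and kappa follow their closed forms and invariances", {
  cm <- confusion_2x2(2620, 148, 74, 2832)
  expect_equal(accuracy(cm), (2620 + 2832) / 5674)
  expect_equal(accuracy(confusion_2x2(5, 0, 0, 0)), 1)
  expect_error(accuracy(confusion_2x2(0, 0, 0, 0)), "empty")

  # perfect diagonal
  expect_equal(cohen_kappa(confusion_2x2(3, 0, 0, 7)), 1)
  # degenerate marginals are undefined, not a number
  expect_warning(k <- cohen_kappa(confusion_2x2(5, 0, 0, 0)), "degenerate")
  expect_true(is.na(k))

  # range and swap invariance over random tables
  withr::with_seed(42, {
    for (i in 1:50) {
      x <- sample(0:40, 4, replace = TRUE)
      if (sum(x) == 0) next
      cm1 <- confusion_2x2(x[1], x[2], x[3], x[4])
      cm2 <- confusion_2x2(x[4], x[3], x[2], x[1]) # a<->d, b<->c
      k1 <- suppressWarnings(cohen_kappa(cm1))
      expect_equal(accuracy(cm1), accuracy(cm2))
      if (!is.na(k1)) {
        expect_true(k1 >= -1 && k1 <= 1)
        expect_equal(k1, suppressWarnings(cohen_kappa(cm2)))
      }
    }
  })
})

test_that("uncorrected McNemar matches its closed form and an independent oracle", {
  m <- mcnemar_test(confusion_2x2(2620, 148, 74, 2832))
  expect_equal(m$statistic, 74^2 / 222)
  # cross-check statistic and p against stats::mcnemar.test without correction
  tab <- matrix(c(2620, 74, 148, 2832), 2)
  ref <- stats::mcnemar.test(tab, correct = FALSE)
  expect_equal(m$statistic, unname(ref$statistic))
  expect_equal(m$p_value, ref$p.value)

  # symmetric discordance and degenerate cases
  expect_equal(mcnemar_test(confusion_2x2(5, 9, 9, 5))$statistic, 0)
  deg <- mcnemar_test(confusion_2x2(5, 0, 0, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)

  # Edwards correction reduces the statistic
  expect_lt(
    mcnemar_test(confusion_2x2(10, 20, 10, 10), correct = TRUE)$statistic,
    mcnemar_test(confusion_2x2(10, 20, 10, 10))$statistic
  )
})

test_that("Pearson chi-square matches chisq.test without Yates correction", {
  ct <- pearson_chi2(c(3638, 2459), c(557, 470))
  ref <- stats::chisq.test(matrix(c(3638, 557, 2459, 470), 2), correct = FALSE)
  expect_equal(ct$statistic, unname(ref$statistic))
  expect_equal(ct$p_value, ref$p.value)

  # proportional table -> independence
  expect_equal(pearson_chi2(c(20, 10), c(40, 20))$statistic, 0)
  expect_error(pearson_chi2(c(0, 0), c(3, 4)), "marginal")
})

test_that("Wald margin and sample-size formulas behave as stated", {
  expect_equal(wald_ci_margin(0.5, 100), qnorm(0.975) * 0.05)
  expect_equal(wald_ci_margin(0, 500), 0)
  expect_equal(required_sample_size(0.5, 0.05), 385)
  expect_equal(required_sample_size(0.8, 10), 1) # vanishing requirement

  # non-increasing in half-width, maximised at p = 0.5
  hw <- c(0.01, 0.02, 0.05, 0.1, 0.25)
  ns <- vapply(hw, function(h) required_sample_size(0.7, h), integer(1))
  expect_true(all(diff(ns) <= 0))
  ps <- seq(0.05, 0.95, by = 0.05)
  np <- vapply(ps, function(p) required_sample_size(p, 0.05), integer(1))
  expect_equal(ps[which.max(np)], 0.5)

  # Wilson half-width shrinks toward the score interval at p = 0.5
  expect_lt(wald_ci_margin(0.5, 100, method = "wilson"), wald_ci_margin(0.5, 100))
})

test_that("chi-square survival function is the upper tail", {
  expect_equal(chi2_survival(0), 1)
  expect_equal(chi2_survival(qnorm(0.975)^2), 0.05, tolerance = 1e-10)
  expect_error(chi2_survival(-1), "non-negative")
  for (x in c(0.92, 3.3, 24.67, 151.51)) {
    expect_equal(chi2_survival(x), chi2_tail_oracle(x), tolerance = 1e-9)
  }
})

test_that("table summaries compute per-row statistics and reporting labels", {
  tbl <- item_stats_table(published_item_counts())
  expect_equal(nrow(tbl), 6)
  expect_equal(tbl$n, c(5674, 1784, 10836, 3280, 7029, 2205))
  expect_equal(tbl$p_label[tbl$item == "gloves" & tbl$split == "live"], "0.339")
  expect_true(all(tbl$p_label[tbl$split == "training"] == "<0.001"))

  ov <- overall_accuracy_table(read_count_fixture("overall_counts"))
  expect_equal(ov$n[1:2], c(7124, 7124))
  expect_equal(ov$accuracy, ov$correct / (ov$correct + ov$incorrect))

  st <- strata_chi2_table(read_count_fixture("strata_counts"))
  expect_equal(nrow(st), 4)
  expect_true(all(c("clothing", "height", "scenery", "sex") %in% st$confounder))
  expect_error(
    strata_chi2_table(tibble::tibble(
      confounder = "x", group = "only", correct = 1, incorrect = 1
    )),
    "two groups"
  )
})

test_that("p-value formatting matches the reporting style", {
  expect_equal(format_p(c(0.3387, 0.0009, 0.011)), c("0.339", "<0.001", "0.011"))
})
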