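# Agreement statistics on paired 2x2 tables. Cell naming follows the
# ground-truth-on-rows / prediction-on-columns orientation:
#   a = true & predicted true (TP),  b = true & predicted false (FN),
#   c = false & predicted true (FP), d = false & predicted false (TN).
# McNemar is the uncorrected (b-c)^2/(b+c) form and the Pearson statistic is
# uncorrected n(ad-bc)^2 / (row x column marginals): these are the exact
# variants the published tables were computed with; continuity-corrected
# versions sit behind flags.

#' A 2x2 prediction-vs-ground-truth confusion matrix
#'
#' @param a True positives (ground truth TRUE, predicted TRUE).
#' @param b False negatives (ground truth TRUE, predicted FALSE).
#' @param c False positives (ground truth FALSE, predicted TRUE).
#' @param d True negatives (ground truth FALSE, predicted FALSE).
#' @return A `ppe_cm2x2` object.
#' @examples
#' cm <- confusion_2x2(2620, 148, 74, 2832)
#' accuracy(cm)
#' cohen_kappa(cm)
#' @export
confusion_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "ppe_cm2x2")
}

#' @export
print.ppe_cm2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
    dimnames = list(truth = c("TRUE", "FALSE"), prediction = c("TRUE", "FALSE"))
  )
  print(m)
  invisible(x)
}

cm_n <- function(cm) cm$a + cm$b + cm$c + cm$d

as_cm <- function(cm) {
  if (inherits(cm, "ppe_cm2x2")) {
    return(cm)
  }
  if (is.numeric(cm) && length(cm) == 4) {
    return(confusion_2x2(cm[1], cm[2], cm[3], cm[4]))
  }
  abort("expected a ppe_cm2x2 or a numeric (a, b, c, d) quadruple")
}

#' Classification accuracy
#'
#' `(a + d) / n`, the observed agreement proportion.
#'
#' @param cm A [confusion_2x2()] or numeric `(a, b, c, d)`.
#' @return Proportion in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- as_cm(cm)
  n <- cm_n(cm)
  if (n == 0) abort("empty confusion matrix")
  (cm$a + cm$d) / n
}

#' Cohen's kappa for a paired 2x2 table
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with observed agreement
#' `po = (a + d)/n` and chance agreement `pe` from the row/column marginals.
#' Degenerate marginals with `pe = 1` have no chance-corrected agreement and
#' return `NA` with a warning.
#'
#' @inheritParams accuracy
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(cm) {
  cm <- as_cm(cm)
  n <- cm_n(cm)
  if (n == 0) abort("empty confusion matrix")
  po <- (cm$a + cm$d) / n
  pe <- ((cm$a + cm$b) * (cm$a + cm$c) + (cm$c + cm$d) * (cm$b + cm$d)) / n^2
  if (pe >= 1) {
    warn("kappa undefined: degenerate marginals (pe = 1)")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' McNemar test on the discordant cells
#'
#' Tests marginal homogeneity (whether prediction and truth disagree
#' systematically) via `(b - c)^2 / (b + c)` on the discordant cells, with
#' the p-value as the upper tail of a chi-square with 1 df (one minus its
#' cumulative distribution function). No continuity correction by default.
#'
#' @inheritParams accuracy
#' @param correct Apply the Edwards continuity correction
#'   `(|b - c| - 1)^2 / (b + c)` (default FALSE).
#' @return Tibble with `statistic`, `p_value`, `df`, `degenerate`.
#' @examples
#' mcnemar_test(confusion_2x2(2620, 148, 74, 2832)) # statistic 24.67
#' @export
mcnemar_test <- function(cm, correct = FALSE) {
  cm <- as_cm(cm)
  b <- cm$b
  c <- cm$c
  if (b + c == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, df = 1L, degenerate = TRUE))
  }
  num <- if (correct) (abs(b - c) - 1)^2 else (b - c)^2
  stat <- num / (b + c)
  tibble::tibble(
    statistic = stat, p_value = chi2_survival(stat, df = 1),
    df = 1L, degenerate = FALSE
  )
}

#' Pearson chi-square on a 2x2 correct/incorrect-by-group table
#'
#' Association test between classification correctness and a binary
#' confounder (clothing, sex, height class, scenery):
#' `n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, 1 df, no Yates correction by
#' default.
#'
#' @param correct Length-2 counts of correct classifications per group.
#' @param incorrect Length-2 counts of incorrect classifications per group.
#' @param yates Apply the Yates continuity correction (default FALSE).
#' @return Tibble with `statistic`, `p_value`, `df`.
#' @examples
#' pearson_chi2(c(3638, 2459), c(557, 470)) # statistic 10.71
#' @export
pearson_chi2 <- function(correct, incorrect, yates = FALSE) {
  stopifnot(length(correct) == 2, length(incorrect) == 2)
  a <- correct[1]
  b <- correct[2]
  c <- incorrect[1]
  d <- incorrect[2]
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) abort("chi-square undefined: zero marginal")
  num <- if (yates) n * (max(0, abs(a * d - b * c) - n / 2))^2 else n * (a * d - b * c)^2
  stat <- num / prod(marg)
  tibble::tibble(statistic = stat, p_value = chi2_survival(stat, df = 1), df = 1L)
}

#' Upper-tail chi-square probability
#'
#' One minus the chi-square cumulative distribution function, used for every
#' chi-square-distributed statistic in the package.
#'
#' @param x Non-negative statistic value.
#' @param df Degrees of freedom (default 1).
#' @return Upper-tail probability.
#' @export
chi2_survival <- function(x, df = 1) {
  if (any(x < 0)) abort("chi-square statistic must be non-negative")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Wald margin of error for a proportion
#'
#' Half-width of the normal-approximation confidence interval,
#' `z * sqrt(p (1 - p) / n)`. A Wilson-interval half-width is available for
#' comparison.
#'
#' @param p Observed proportion.
#' @param n Sample size.
#' @param confidence Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Margin on the proportion scale.
#' @examples
#' wald_ci_margin(0.8558, 7124) # ~0.0082
#' @export
wald_ci_margin <- function(p, n, confidence = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  stopifnot(p >= 0, p <= 1, n > 0, confidence > 0, confidence < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  if (method == "wald") {
    return(z * sqrt(p * (1 - p) / n))
  }
  # Wilson: half-width of the score interval
  denom <- 1 + z^2 / n
  z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
}

#' Sample size for a proportion confidence interval
#'
#' Smallest n for which the Wald interval at the assumed proportion has at
#' most the requested half-width: `ceil(z^2 p (1 - p) / half_width^2)`.
#'
#' @param p Assumed proportion.
#' @param half_width Target CI half-width on the proportion scale.
#' @param confidence Confidence level (default 0.95).
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.8, 0.05) # 246
#' @export
required_sample_size <- function(p, half_width, confidence = 0.95) {
  stopifnot(p > 0, p < 1, half_width > 0)
  z <- qnorm(1 - (1 - confidence) / 2)
  max(1L, as.integer(ceiling(z^2 * p * (1 - p) / half_width^2)))
}

#' Format a p-value in reporting style
#'
#' Three decimals, `"<0.001"` below that.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", round(p, 3)))
}

# -- table-level summaries ---------------------------------------------------

#' Per-item agreement statistics from confusion-matrix counts
#'
#' Computes accuracy, Cohen's kappa, the McNemar statistic and its p-value
#' for each row of a counts table -- the layout of a per-item
#' training/live-deployment results table.
#'
#' @param counts Data frame with columns `item`, `split`, `a`, `b`, `c`,
#'   `d`.
#' @return Tibble with the input keys plus `n`, `accuracy`, `kappa`,
#'   `mcnemar`, `p_value`, `p_label`.
#' @export
item_stats_table <- function(counts) {
  stopifnot(all(c("item", "split", "a", "b", "c", "d") %in% names(counts)))
  counts |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n = .data$a + .data$b + .data$c + .data$d,
      accuracy = accuracy(c(.data$a, .data$b, .data$c, .data$d)),
      kappa = cohen_kappa(c(.data$a, .data$b, .data$c, .data$d)),
      mcnemar = mcnemar_test(c(.data$a, .data$b, .data$c, .data$d))$statistic,
      p_value = mcnemar_test(c(.data$a, .data$b, .data$c, .data$d))$p_value
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_label = format_p(.data$p_value)) |>
    tibble::as_tibble()
}

#' Overall accuracies from correct/incorrect counts
#'
#' @param counts Data frame with columns `split`, `definition`, `correct`,
#'   `incorrect`.
#' @param confidence Confidence level for the Wald margin.
#' @return Tibble with `n`, `accuracy` and the Wald `margin` added.
#' @export
overall_accuracy_table <- function(counts, confidence = 0.95) {
  stopifnot(all(c("split", "definition", "correct", "incorrect") %in% names(counts)))
  counts |>
    dplyr::mutate(
      n = .data$correct + .data$incorrect,
      accuracy = .data$correct / .data$n,
      margin = purrr::map2_dbl(
        .data$accuracy, .data$n,
        ~ wald_ci_margin(.x, .y, confidence)
      )
    ) |>
    tibble::as_tibble()
}

#' Confounder chi-square table from stratified correct/incorrect counts
#'
#' One chi-square association test per confounder, on the 2x2
#' correct/incorrect-by-group table.
#'
#' @param strata Data frame with columns `confounder`, `group`, `correct`,
#'   `incorrect` (two groups per confounder).
#' @return Tibble with one row per confounder: group accuracies,
#'   `statistic`, `p_value`, `p_label`.
#' @export
strata_chi2_table <- function(strata) {
  stopifnot(all(c("confounder", "group", "correct", "incorrect") %in% names(strata)))
  strata |>
    dplyr::group_by(.data$confounder) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) != 2) abort("each confounder needs exactly two groups")
      ct <- pearson_chi2(df$correct, df$incorrect)
      tibble::tibble(
        group_1 = df$group[1], accuracy_1 = df$correct[1] / (df$correct[1] + df$incorrect[1]),
        group_2 = df$group[2], accuracy_2 = df$correct[2] / (df$correct[2] + df$incorrect[2]),
        statistic = ct$statistic, p_value = ct$p_value
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_label = format_p(.data$p_value))
}

#' Read the shipped printed-count fixtures
#'
#' The package ships CSV fixtures with the published per-item confusion
#' counts, overall correct/incorrect counts, and stratified confounder
#' counts, so the full statistics protocol can be exercised without any
#' image data.
#'
#' @param which `"item_counts"`, `"overall_counts"` or `"strata_counts"`.
#' @return Tibble.
#' @export
read_count_fixture <- function(which = c("item_counts", "overall_counts", "strata_counts")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "ppemonitor")
  if (path == "") abort("fixture not found; is ppemonitor installed?")
  readr::read_csv(path, show_col_types = FALSE)
}
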