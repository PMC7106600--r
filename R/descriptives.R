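# Group-comparison statistics for cohort description: Pearson chi-squared
# tests on contingency tables (Yates-corrected for 2x2) and two-sample t
# tests recomputed from summary statistics.

#' Pearson chi-squared test of independence
#'
#' Computes the Pearson statistic on an r x c contingency table via
#' [stats::chisq.test()]. For 2x2 tables the Yates continuity correction is
#' applied by default, which is the convention that reproduces published
#' 2x2 statistics computed from these instruments' group tables; larger
#' tables are never corrected. An expected count below 5 is reported as a
#' warning attribute, not an error.
#'
#' @param table Matrix of non-negative integer counts (r, c >= 2).
#' @param correct Apply the Yates correction for 2x2 tables (default TRUE).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `min_expected`.
#' @export
#' @examples
#' chi_squared_test(rbind(c(257, 260), c(67, 66)))
chi_squared_test <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    rlang::abort("contingency table must be at least 2x2",
                 class = "pvq_descriptive_error")
  }
  if (any(table < 0) || sum(table) == 0) {
    rlang::abort("counts must be non-negative with a positive total",
                 class = "pvq_descriptive_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("all-zero row or column", class = "pvq_descriptive_error")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  expected <- ht$expected
  if (any(expected < 5)) {
    rlang::warn(sprintf("minimum expected count %.2f is below 5",
                        min(expected)))
  }
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    method = if (correct && all(dim(table) == 2)) "pearson_yates" else "pearson",
    min_expected = min(expected)
  )
}

#' Two-sample t test from summary statistics
#'
#' Recomputes the t statistic from group means, standard deviations and
#' sizes, either with a pooled variance (df = n1 + n2 - 2) or with the
#' Welch-Satterthwaite approximation (real-valued df). Two-sided p value.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' t_test_from_summary(42.13, 14.8, 324, 37.42, 14.91, 326)
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2 || sd1 <= 0 || sd2 <= 0) {
    rlang::abort("need n >= 2 and positive sd in both groups",
                 class = "pvq_descriptive_error")
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  tibble::tibble(
    statistic = t, df = df,
    p_value = 2 * stats::pt(-abs(t), df),
    method = paste0("t_", variant)
  )
}

#' Group-comparison report for a labeled cohort
#'
#' For every categorical variable: per-group counts and percentages plus a
#' chi-squared test of independence against the binary suicidal-behavior
#' group (Yates-corrected when the variable is binary in the observed
#' data). Categories unobserved in the whole cohort are dropped from the
#' table before testing. Deterministic.
#'
#' @param cohort Validated cohort tibble.
#' @param variables Demographic columns to compare (default: all eight).
#' @param schema Schema from [pvq_schema()].
#' @return A list of class `pvq_descriptives`: `counts` (long tibble:
#'   variable, level, group, n, pct) and `tests` (one row per variable).
#' @export
group_comparison_report <- function(cohort,
                                    variables = names(pvq_schema()$demographics),
                                    schema = pvq_schema()) {
  cohort <- tibble::as_tibble(cohort)
  group <- derive_sb_group(cohort$sb_status)
  if (length(unique(group)) < 2) {
    rlang::abort("both groups must be present", class = "pvq_descriptive_error")
  }
  counts <- list(); tests <- list()
  for (v in variables) {
    lv <- schema$demographics[[v]] %||% sort(unique(as.character(cohort[[v]])))
    tab <- table(factor(as.character(cohort[[v]]), levels = lv),
                 factor(group, levels = c("without_sb", "with_sb")))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    long <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(long) <- c("level", "group", "n")
    long <- dplyr::group_by(long, .data$group) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = v, .before = 1)
    counts[[v]] <- long
    tt <- chi_squared_test(unclass(tab))
    tests[[v]] <- dplyr::mutate(tt, variable = v, .before = 1)
  }
  structure(list(counts = dplyr::bind_rows(counts),
                 tests = dplyr::bind_rows(tests)),
            class = "pvq_descriptives")
}

#' @export
print.pvq_descriptives <- function(x, ...) {
  cat("Group comparison report\n")
  print(as.data.frame(x$tests))
  invisible(x)
}
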