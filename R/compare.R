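# Hot-spot vs cold-spot comparative statistics: mean age compared with the
# Wilcoxon rank-sum test, length of stay summarised as median and IQR, and
# every categorical variable compared with per-category 2x2 chi-square tests
# (each with 1 degree of freedom, no omnibus test).

#' Wilcoxon rank-sum test
#'
#' Mid-ranks for ties; exact enumeration when the combined sample size is
#' below 20 and there are no ties, otherwise the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (rank-sum W) and two-sided `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) < 20 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = min(wt$p.value, 1), exact = exact)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction by default (switchable). Cells with expected
#' counts below 5 are flagged in the output rather than silently accepted.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply Yates continuity correction.
#' @return List with `statistic`, `df = 1`, `p`, `expected`, `low_expected`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0)) stop("cell counts must be >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-square test undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = 1L, p = ct$p.value,
       expected = ct$expected, low_expected = any(ct$expected < 5))
}

#' Median and interquartile range of length of stay
#'
#' Quartiles use the lower/upper-half (Tukey hinge) convention: the hinges are
#' the medians of the lower and upper halves of the sorted data, with the
#' overall median included in both halves when n is odd.
#'
#' @param los_values Non-empty numeric vector of lengths of stay (days).
#' @return List with `median`, `q1`, `q3`, `n`.
#' @export
los_summary <- function(los_values) {
  if (length(los_values) == 0L) stop("length-of-stay input is empty")
  fn <- stats::fivenum(los_values)
  list(median = fn[3], q1 = fn[2], q3 = fn[4], n = length(los_values))
}

#' @noRd
format_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))

#' Compare patients in hot spots vs cold spots
#'
#' Pools patients across all hot-spot (HH) regions and all cold-spot (LL)
#' regions and produces the comparison report: mean age with a Wilcoxon
#' rank-sum p-value, median/IQR length of stay per group, and for each
#' categorical variable per-category 2x2 chi-square tests (hot/cold x
#' category/other, df = 1 each). Missing category values are excluded from
#' that variable's tests and tallied separately. P-values are reported to two
#' decimals with "<0.01" flooring.
#'
#' @param cohort Cohort data frame (must carry `region_id`, `age`, `los` and
#'   the requested variables).
#' @param labels A [lisa()] result, or a named character vector of cluster
#'   labels per region id.
#' @param variables Categorical variables to compare.
#' @return A `comparison_report` list: group sizes, `age`, `los`,
#'   `categorical` (one row per variable x category) and `missing` tallies.
#' @export
compare_clusters <- function(cohort, labels,
                             variables = c("sex", "race_ethnicity", "setting",
                                           "disposition", "died")) {
  if (inherits(labels, "lisa")) {
    labels <- stats::setNames(labels$label, labels$region_id)
  }
  hot_ids <- names(labels)[labels == "HH"]
  cold_ids <- names(labels)[labels == "LL"]
  if (length(hot_ids) == 0L || length(cold_ids) == 0L) {
    stop("no comparison possible: need at least one hot-spot and one cold-spot region")
  }
  hot <- cohort[cohort$region_id %in% hot_ids, , drop = FALSE]
  cold <- cohort[cohort$region_id %in% cold_ids, , drop = FALSE]
  if (nrow(hot) == 0L || nrow(cold) == 0L) {
    stop("no comparison possible: a cluster group contains no patients")
  }

  age_test <- wilcoxon_rank_sum(hot$age, cold$age)
  age <- list(mean_hot = mean(hot$age), mean_cold = mean(cold$age),
              statistic = age_test$statistic, p = age_test$p,
              p_label = format_p(age_test$p))
  los <- list(hot = los_summary(hot$los), cold = los_summary(cold$los))

  cat_rows <- list()
  miss_rows <- list()
  for (v in variables) {
    hv <- hot[[v]]; cv <- cold[[v]]
    if (is.logical(hv)) {
      hv <- ifelse(hv, "yes", "no"); cv <- ifelse(cv, "yes", "no")
    }
    hv <- as.character(hv); cv <- as.character(cv)
    h_miss <- is.na(hv) | !nzchar(hv)
    c_miss <- is.na(cv) | !nzchar(cv)
    miss_rows[[v]] <- data.frame(variable = v, hot_missing = sum(h_miss),
                                 cold_missing = sum(c_miss),
                                 stringsAsFactors = FALSE)
    hv <- hv[!h_miss]; cv <- cv[!c_miss]
    hn <- length(hv); cn <- length(cv)
    cats <- sort(union(unique(hv), unique(cv)))
    if (length(cats) < 2L) {
      warning(sprintf("variable '%s' has a single category; chi-square undefined, skipped", v))
      next
    }
    for (cat in cats) {
      a <- sum(hv == cat); b <- sum(cv == cat)
      tab <- matrix(c(a, hn - a, b, cn - b), nrow = 2,
                    dimnames = list(c("hot", "cold"), c(cat, "other")),
                    byrow = TRUE)
      test <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
      if (is.null(test)) {
        warning(sprintf("category '%s' of '%s' has a zero margin; skipped", cat, v))
        next
      }
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        variable = v, category = cat,
        hot_n = a, hot_pct = round_half_up(100 * a / hn, 1),
        cold_n = b, cold_pct = round_half_up(100 * b / cn, 1),
        chi_sq = test$statistic, df = 1L, p = test$p,
        p_label = format_p(test$p), low_expected = test$low_expected,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(
    n_hot = nrow(hot), n_cold = nrow(cold),
    hot_regions = hot_ids, cold_regions = cold_ids,
    age = age, los = los,
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
    missing = do.call(rbind, miss_rows)
  )
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Hot vs cold spot comparison: %d hot-spot patients (%d regions), %d cold-spot patients (%d regions)\n",
              x$n_hot, length(x$hot_regions), x$n_cold, length(x$cold_regions)))
  cat(sprintf("mean age: hot %.1f vs cold %.1f (rank-sum p %s)\n",
              x$age$mean_hot, x$age$mean_cold, x$age$p_label))
  cat(sprintf("LOS median (IQR): hot %.1f (%.1f-%.1f) vs cold %.1f (%.1f-%.1f) days\n",
              x$los$hot$median, x$los$hot$q1, x$los$hot$q3,
              x$los$cold$median, x$los$cold$q1, x$los$cold$q3))
  if (!is.null(x$categorical)) {
    print.data.frame(x$categorical[, c("variable", "category", "hot_n",
                                       "hot_pct", "cold_n", "cold_pct",
                                       "chi_sq", "df", "p_label")],
                     digits = 4, row.names = FALSE)
  }
  invisible(x)
}
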