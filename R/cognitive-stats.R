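# Cohort statistics: group summaries, Fisher LSD pairwise comparisons from a
# one-way ANOVA, and covariate-adjusted (partial Pearson) correlation of WMH
# volume with neuropsychological scores.

wmh_score_names <- function() {
  c("mmse", "moca", "tmt_a", "tmt_b", "stroop", "vft",
    "avlt4", "avlt5", "rey_o", "bnt")
}

drop_incomplete <- function(records, cols) {
  keep <- stats::complete.cases(records[, cols, drop = FALSE])
  if (any(!keep))
    rlang::inform(paste0("dropping ", sum(!keep),
                         " record(s) with missing values (listwise deletion)"))
  records[keep, , drop = FALSE]
}

#' Per-group mean and SD summaries
#'
#' Sample mean and sample SD (n - 1 denominator) of each variable within
#' each group. SD is reported as `NA` for single-record groups.
#'
#' @param records cohort data frame with a `group` column.
#' @param variables variable columns to summarise; defaults to all numeric
#'   columns except identifiers.
#' @return tibble with `group`, `variable`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(records, variables = NULL) {
  records <- tibble::as_tibble(records)
  if (!"group" %in% names(records))
    stop_wmh("records need a 'group' column", class = "wmh_grouping_error")
  if (any(table(records$group) == 0) || nrow(records) == 0)
    stop_wmh("every group needs at least one record",
             class = "wmh_grouping_error")
  if (is.null(variables)) {
    num <- vapply(records, is.numeric, logical(1))
    variables <- setdiff(names(records)[num], c("id", "case_id"))
  }
  records <- drop_incomplete(records, c("group", variables))
  records |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable") |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
                     .groups = "drop")
}

#' Fisher's LSD pairwise comparisons
#'
#' One-way ANOVA pooled error variance `MSE = sum((n_g - 1) s_g^2) / (N - G)`
#' followed by unadjusted pairwise t-tests: for groups I, J the difference is
#' `mean_I - mean_J`, its standard error `sqrt(MSE (1/n_I + 1/n_J))`, and the
#' two-sided p-value comes from the t distribution on `N - G` degrees of
#' freedom. No multiplicity correction is applied (that is the LSD). Both
#' orderings of every pair are reported, as SPSS prints them, so differences
#' are antisymmetric and standard errors symmetric by construction.
#'
#' @param records cohort data frame with a `group` column.
#' @param variable name of the response column.
#' @param alpha significance level for the `significant` flag.
#' @return tibble of class `wmh_lsd` with one row per ordered group pair.
#' @export
lsd_pairwise <- function(records, variable, alpha = 0.05) {
  records <- tibble::as_tibble(records)
  records <- drop_incomplete(records, c("group", variable))
  y <- records[[variable]]
  g <- factor(records$group)
  if (nlevels(g) < 2)
    stop_wmh("need at least two groups", class = "wmh_grouping_error")
  ns <- tapply(y, g, length)
  if (any(ns < 2))
    stop_wmh("every group needs n >= 2 for a pooled variance (got n = ",
             paste(ns, collapse = ", "), ")",
             class = "wmh_degenerate_error")
  means <- tapply(y, g, mean)
  vars <- tapply(y, g, stats::var)
  N <- length(y); G <- nlevels(g)
  mse <- sum((ns - 1) * vars) / (N - G)
  df <- N - G
  pairs <- expand.grid(j = levels(g), i = levels(g),
                       stringsAsFactors = FALSE)[, c("i", "j")]
  pairs <- pairs[pairs$i != pairs$j, ]
  diff <- as.numeric(means[pairs$i] - means[pairs$j])
  se <- as.numeric(sqrt(mse * (1 / ns[pairs$i] + 1 / ns[pairs$j])))
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- as.numeric(2 * stats::pt(-abs(tstat), df))
  out <- tibble::tibble(variable = variable,
                        group_i = pairs$i, group_j = pairs$j,
                        difference = as.numeric(diff), std_error = as.numeric(se),
                        df = df, statistic = as.numeric(tstat), p_value = p,
                        significant = p < alpha)
  class(out) <- c("wmh_lsd", class(out))
  out
}

#' Partial correlation with covariate adjustment
#'
#' Residualizes both variables on an intercept plus the covariates by least
#' squares and reports the Pearson correlation of the residuals, with
#' `t = r sqrt((n - k - 2) / (1 - r^2))` on `n - k - 2` degrees of freedom
#' (`k` covariates), two-sided. With no covariates this reduces to the plain
#' Pearson correlation test. Binary sex is expected coded 0/1 (female = 1).
#'
#' @param records cohort data frame.
#' @param score response column name.
#' @param x volume column name.
#' @param covariates covariate column names (may be empty).
#' @return one-row tibble of class `wmh_pcor`: `score`, `n`, `r`, `df`,
#'   `statistic`, `p_value`.
#' @export
partial_correlation <- function(records, score, x = "wmh_volume",
                                covariates = c("sex", "age", "education")) {
  records <- tibble::as_tibble(records)
  records <- drop_incomplete(records, c(x, score, covariates))
  n <- nrow(records)
  k <- length(covariates)
  if (n <= k + 2)
    stop_wmh("need n > ", k + 2, " complete records, got ", n,
             class = "wmh_degenerate_error")
  if (k > 0) {
    M <- cbind(`(intercept)` = 1,
               as.matrix(records[, covariates, drop = FALSE]))
    qd <- qr(M)
    if (qd$rank < ncol(M)) {
      bad <- colnames(M)[qd$pivot[(qd$rank + 1):ncol(M)]]
      stop_wmh("collinear covariate column(s): ", paste(bad, collapse = ", "),
               class = "wmh_rank_error")
    }
    rx <- qr.resid(qd, records[[x]])
    ry <- qr.resid(qd, records[[score]])
  } else {
    rx <- records[[x]] - mean(records[[x]])
    ry <- records[[score]] - mean(records[[score]])
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- tibble::tibble(score = score, n = n, r = r, df = df,
                        statistic = tstat, p_value = p)
  class(out) <- c("wmh_pcor", class(out))
  out
}

#' Full cohort analysis
#'
#' Bundles the three analyses run on a subject table: per-group summaries,
#' the LSD pairwise grid over all ten neuropsychological scores (plus WMH
#' volume), and the covariate-adjusted correlation of WMH volume with each
#' score.
#'
#' @param records subject table: `group`, `sex` (0/1, female = 1), `age`,
#'   `education`, `wmh_volume`, and the ten score columns
#'   (`mmse`, `moca`, `tmt_a`, `tmt_b`, `stroop`, `vft`, `avlt4`, `avlt5`,
#'   `rey_o`, `bnt`).
#' @param covariates covariates for the correlation analysis.
#' @return list of class `wmh_cohort_report` with elements `summary`,
#'   `lsd`, `correlations`, and `covariates`.
#' @export
analyze_cohort <- function(records,
                           covariates = c("sex", "age", "education")) {
  scores <- intersect(wmh_score_names(), names(records))
  if (length(scores) == 0)
    stop_wmh("no recognised score columns found", class = "wmh_config_error")
  lsd <- dplyr::bind_rows(lapply(c(scores, "wmh_volume"), function(v)
    lsd_pairwise(records, v)))
  cors <- dplyr::bind_rows(lapply(scores, function(v)
    partial_correlation(records, v, covariates = covariates)))
  structure(list(summary = group_summary(records),
                 lsd = lsd, correlations = cors,
                 covariates = covariates,
                 sex_coding = c(female = 1, male = 0)),
            class = "wmh_cohort_report")
}

report_group_sizes <- function(x) {
  x$summary |> dplyr::group_by(.data$group) |>
    dplyr::summarise(n = max(.data$n), .groups = "drop")
}

#' @export
print.wmh_cohort_report <- function(x, ...) {
  cat("<wmh_cohort_report>\n")
  cat("Group sizes:\n")
  print(report_group_sizes(x), n = Inf)
  cat("\nPartial correlations of WMH volume with each score (covariates: ",
      paste(x$covariates, collapse = ", "), "):\n", sep = "")
  print(x$correlations, n = Inf)
  invisible(x)
}

#' @export
tidy.wmh_cohort_report <- function(x, ...) x$correlations

#' @export
glance.wmh_cohort_report <- function(x, ...) {
  tibble::tibble(
    n = sum(report_group_sizes(x)$n),
    n_groups = length(unique(x$summary$group)),
    n_scores = nrow(x$correlations),
    min_p_correlation = min(x$correlations$p_value))
}

#' Write a cohort report to CSV + text
#'
#' @param report a `wmh_cohort_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$lsd, file.path(dir, "lsd_pairwise.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations,
                   file.path(dir, "partial_correlations.csv"),
                   row.names = FALSE)
  txt <- c("Cohort analysis report",
           paste0("covariates: ", paste(report$covariates, collapse = ", ")),
           "sex coding: female = 1, male = 0", "",
           utils::capture.output(print(report$correlations, n = Inf)))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
autoplot.wmh_pcor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score, y = .data$r)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = "partial correlation with WMH volume", x = NULL)
}
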