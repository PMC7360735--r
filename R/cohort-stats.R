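# Donor-level statistics: reference-enzyme normalization, z-standardization,
# age trends, one-sided two-sample t-tests (raw and summary-statistic forms),
# group summaries and the young/old comparison of per-cell PAS indices.

activity_columns <- function(table) {
  setdiff(names(table), c("id", "age", "sex"))
}

resolve_column <- function(table, column) {
  cols <- activity_columns(table)
  if (is.numeric(column)) {
    if (column < 1 || column > length(cols))
      stop("activity column index out of range", call. = FALSE)
    cols[column]
  } else {
    if (!column %in% cols) stop("unknown activity column: ", column, call. = FALSE)
    column
  }
}

#' Bundled enzyme-activity table
#'
#' Activities of glycolytic-pathway enzymes (aldolase, adenylate kinase,
#' triose-phosphate isomerase, hexokinase) in CD34+ cells from nine human
#' donors aged 19 to 71 years, each normalized within-donor to the pyruvate
#' kinase "high affinity" activity to absorb donor-to-donor variation in
#' overall glycolytic flux. Columns: `id`, `age`, `sex`, then the activity
#' columns in assay order (`pk_ref`, `aldolase`, `adenylate_kinase`, `tpi`,
#' `hexokinase`).
#'
#' @return a data frame with 9 rows.
#' @export
enzyme_activities <- function() {
  utils::read.csv(system.file("extdata", "enzyme_activities.csv",
                              package = "pasquant"),
                  stringsAsFactors = FALSE)
}

#' Bundled glucose-uptake fraction summary
#'
#' Group-level summary statistics (mean percent, SD percent, group size) of
#' the fractions of CD34+ cells with high, intermediate and low glucose
#' uptake in young (3 donors) versus older (7 donors) subjects, as measured
#' by 2-NBDG flow sorting.
#'
#' @return a data frame with columns `subset`, `group`, `mean_pct`,
#'   `sd_pct`, `n`.
#' @export
gu_fractions <- function() {
  utils::read.csv(system.file("extdata", "gu_fractions.csv", package = "pasquant"),
                  stringsAsFactors = FALSE)
}

#' Normalize activities by a per-subject reference column
#'
#' Divides every non-reference activity by the same subject's reference
#' value, which cancels subject-level multiplicative factors (overall
#' glycolytic state, input cell number); the reference column itself is kept
#' unchanged.
#'
#' @param table activity data frame (`id`, `age`, `sex`, activity columns).
#' @param reference name of the reference column; must be strictly positive.
#' @return the normalized table, same shape and column order.
#' @export
normalize_by_reference <- function(table, reference = "pk_ref") {
  reference <- resolve_column(table, reference)
  ref <- table[[reference]]
  bad <- which(!is.finite(ref) | ref <= 0)
  if (length(bad))
    stop("non-positive reference activity for subject(s): ",
         paste(table$id[bad], collapse = ", "), call. = FALSE)
  for (col in setdiff(activity_columns(table), reference))
    table[[col]] <- table[[col]] / ref
  table
}

#' Z-standardize a numeric vector
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation.
#'
#' @param x numeric vector, length at least 2, non-zero SD.
#' @return standardized vector with mean 0 and SD 1.
#' @export
z_standardize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to standardize", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize: zero standard deviation", call. = FALSE)
  (x - mean(x)) / s
}

#' Linear age trend of an activity column
#'
#' Ordinary least squares of activity on age; reports slope, intercept,
#' Pearson r and r-squared (both invariant to z-standardization or any
#' affine rescaling of the activity values).
#'
#' @param table activity data frame.
#' @param column activity column, by name or by position among the activity
#'   columns.
#' @param exclude_ids subject ids to drop before fitting.
#' @return an object of class `trend_result`.
#' @export
age_trend_r2 <- function(table, column, exclude_ids = NULL) {
  column <- resolve_column(table, column)
  keep <- !(table$id %in% exclude_ids)
  d <- table[keep, ]
  if (nrow(d) < 3) stop("need at least 3 subjects after exclusions", call. = FALSE)
  if (stats::sd(d[[column]]) == 0)
    stop("activity column is constant; trend undefined", call. = FALSE)
  fit <- stats::lm(d[[column]] ~ d$age)
  r <- stats::cor(d$age, d[[column]])
  structure(
    list(column = column, slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), r = r, r2 = r^2,
         n = nrow(d), excluded = exclude_ids),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Age trend of %s: slope %.4g, r = %.3f, r^2 = %.3f (n = %d%s)\n",
              x$column, x$slope, x$r, x$r2, x$n,
              if (length(x$excluded)) paste0(", excluded: ",
                                             paste(x$excluded, collapse = ",")) else ""))
  invisible(x)
}

new_ttest_result <- function(statistic, df, p_value, variant, alternative,
                             means = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 variant = variant, alternative = alternative, means = means),
            class = "ttest_result")
}

#' One-sided two-sample t-test
#'
#' Pooled-variance (`df = n_x + n_y - 2`) or Welch (Welch-Satterthwaite df)
#' two-sample t-test with a one-sided alternative about
#' `mean(x) - mean(y)`. A thin wrapper around [stats::t.test()] that fixes
#' the one-sided conventions used throughout the package.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @param variant `"pooled"` or `"welch"`.
#' @param alternative `"greater"` (mean of `x` hypothesized larger) or
#'   `"less"`.
#' @return an object of class `ttest_result` with `statistic`, `df`,
#'   `p_value`, `variant`, `alternative`.
#' @export
one_sided_t_test <- function(x, y, variant = c("pooled", "welch"),
                             alternative = c("greater", "less")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(x, y, alternative = alternative,
                      var.equal = variant == "pooled")
  new_ttest_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                   variant, alternative, means = c(mean(x), mean(y)))
}

#' One-sided two-sample t-test from summary statistics
#'
#' Same hypotheses and formulas as [one_sided_t_test()] but computed from
#' sufficient statistics (group means, SDs and sizes) — as needed when only
#' a published summary table is available.
#'
#' @param mean_x,sd_x,n_x first group's mean, sample SD and size.
#' @param mean_y,sd_y,n_y second group's summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @param alternative `"greater"` (first group hypothesized larger) or
#'   `"less"`.
#' @return an object of class `ttest_result`.
#' @examples
#' # high-glucose-uptake fraction, old (n = 7) vs young (n = 3) donors:
#' t_test_from_summary(5.4, 3.5, 7, 1.7, 1.5, 3, variant = "welch")
#' @export
t_test_from_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                                variant = c("pooled", "welch"),
                                alternative = c("greater", "less")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (n_x < 2 || n_y < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd_x < 0 || sd_y < 0) stop("standard deviations must be non-negative", call. = FALSE)
  if (sd_x == 0 && sd_y == 0 && mean_x == mean_y)
    stop("both groups constant and equal; test undefined", call. = FALSE)
  if (variant == "pooled") {
    df <- n_x + n_y - 2
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
  } else {
    vx <- sd_x^2 / n_x
    vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  }
  t <- (mean_x - mean_y) / se
  p <- stats::pt(t, df, lower.tail = alternative == "less")
  new_ttest_result(t, df, p, variant, alternative, means = c(mean_x, mean_y))
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("One-sided %s t-test (%s): t = %.4f, df = %.3f, p = %.4g\n",
              x$variant, x$alternative, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Young/old group summary of an activity table
#'
#' Per activity column: overall mean and sample SD over all subjects, plus
#' the young-group (`age < young_max_age`) and old-group
#' (`age > old_min_age`) means after dropping `exclude_ids` from the groups.
#' The default cutoffs leave middle-aged subjects out of both groups;
#' median-valued subjects can additionally be excluded explicitly.
#'
#' @param table activity data frame.
#' @param young_max_age,old_min_age group cutoffs in years.
#' @param exclude_ids ids excluded from the young/old groups (overall
#'   mean/SD still use all subjects).
#' @return an object of class `group_summary` with a `stats` data frame
#'   (`column`, `mean`, `sd`, `mean_young`, `mean_old`), the group id lists
#'   and the settings used.
#' @export
summarize_groups <- function(table, young_max_age = 40, old_min_age = 50,
                             exclude_ids = NULL) {
  cols <- activity_columns(table)
  in_group <- !(table$id %in% exclude_ids)
  young <- in_group & table$age < young_max_age
  old <- in_group & table$age > old_min_age
  if (!any(young) || !any(old)) stop("empty young or old group", call. = FALSE)
  stats_df <- data.frame(
    column = cols,
    mean = vapply(cols, function(cl) mean(table[[cl]]), 0),
    sd = vapply(cols, function(cl) stats::sd(table[[cl]]), 0),
    mean_young = vapply(cols, function(cl) mean(table[[cl]][young]), 0),
    mean_old = vapply(cols, function(cl) mean(table[[cl]][old]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(stats = stats_df,
                 young_ids = table$id[young], old_ids = table$id[old],
                 excluded = exclude_ids,
                 cutoffs = c(young_max_age = young_max_age, old_min_age = old_min_age)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Group summary (young: age < %g, n = %d; old: age > %g, n = %d%s)\n",
              x$cutoffs[1], length(x$young_ids), x$cutoffs[2], length(x$old_ids),
              if (length(x$excluded)) paste0("; excluded: ",
                                             paste(x$excluded, collapse = ",")) else ""))
  out <- x$stats
  out[-1] <- lapply(out[-1], round, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' One-sided old-vs-young t-tests for every activity column
#'
#' Convenience layer over [one_sided_t_test()]: for each activity column,
#' tests whether the old group's activities are larger than the young
#' group's.
#'
#' @inheritParams summarize_groups
#' @param variant `"pooled"` or `"welch"`.
#' @return a data frame `column`, `statistic`, `df`, `p_value`.
#' @export
activity_group_tests <- function(table, young_max_age = 40, old_min_age = 50,
                                 exclude_ids = NULL, variant = "pooled") {
  in_group <- !(table$id %in% exclude_ids)
  young <- in_group & table$age < young_max_age
  old <- in_group & table$age > old_min_age
  cols <- activity_columns(table)
  rows <- lapply(cols, function(cl) {
    tt <- one_sided_t_test(table[[cl]][old], table[[cl]][young], variant = variant)
    data.frame(column = cl, statistic = tt$statistic, df = tt$df,
               p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-cell PAS indices between young and old groups
#'
#' Fold change of group means (old over young), a one-sided pooled t-test of
#' the hypothesis that old cells carry more glycogen, and the outlier
#' fraction: the share of old cells whose index exceeds the young group's
#' maximum — the heterogeneity signature of aged samples.
#'
#' @param young,old numeric vectors of per-cell PAS indices (each length at
#'   least 2).
#' @param variant t-test variant, default pooled.
#' @return an object of class `index_comparison`: `fold_change`,
#'   `statistic`, `df`, `p_value`, `outlier_fraction`, group sizes and means.
#' @export
compare_pas_indices <- function(young, old, variant = "pooled") {
  if (length(young) < 2 || length(old) < 2)
    stop("each group needs at least 2 cells", call. = FALSE)
  my <- mean(young)
  if (my == 0) stop("young group mean is zero; fold change undefined", call. = FALSE)
  # degenerate (constant) inputs still have a well-defined fold change
  tt <- tryCatch(one_sided_t_test(old, young, variant = variant),
                 error = function(e) new_ttest_result(NA_real_, NA_real_,
                                                      NA_real_, variant, "greater"))
  structure(
    list(fold_change = mean(old) / my, statistic = tt$statistic, df = tt$df,
         p_value = tt$p_value, outlier_fraction = mean(old > max(young)),
         n_young = length(young), n_old = length(old),
         mean_young = my, mean_old = mean(old)),
    class = "index_comparison"
  )
}

#' @export
print.index_comparison <- function(x, ...) {
  cat(sprintf("PAS index comparison: old/young fold change %.2f (means %.4f / %.4f)\n",
              x$fold_change, x$mean_old, x$mean_young))
  cat(sprintf("  one-sided t = %.3f (df %.2f), p = %.3g; %.0f%% of old cells above young maximum\n",
              x$statistic, x$df, x$p_value, 100 * x$outlier_fraction))
  invisible(x)
}
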