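# Donor-level statistics: normalization, standardization, trends, one-sided
# tests, group summaries and the young/old index comparison.

test_that("reference normalization divides by the subject's reference value", {
  tab <- data.frame(id = 1:2, age = c(20, 60), sex = c("f", "m"),
                    pk_ref = c(0.5, 2.0), enz_a = c(2.0, 2.0), enz_b = c(0.5, 4.0))
  out <- normalize_by_reference(tab, "pk_ref")
  expect_equal(out$enz_a, c(4.0, 1.0))
  expect_equal(out$enz_b, c(1.0, 2.0))
  expect_equal(out$pk_ref, tab$pk_ref)  # reference kept unchanged
  same <- normalize_by_reference(transform(tab, enz_a = pk_ref, enz_b = pk_ref))
  expect_true(all(same$enz_a == 1 & same$enz_b == 1))
})

test_that("normalization cancels subject-level multiplicative factors", {
  tab <- data.frame(id = 1:4, age = c(20, 30, 60, 70), sex = "f",
                    pk_ref = c(0.3, 0.4, 0.6, 0.5),
                    enz_a = c(1.1, 0.9, 2.0, 1.7), enz_b = c(5, 4, 9, 8))
  f <- c(1, 2.5, 0.4, 10)  # per-subject overall-activity factor
  scaled <- tab
  for (cl in c("pk_ref", "enz_a", "enz_b")) scaled[[cl]] <- tab[[cl]] * f
  a <- normalize_by_reference(tab)
  b <- normalize_by_reference(scaled)
  expect_equal(a[c("enz_a", "enz_b")], b[c("enz_a", "enz_b")])
})

test_that("normalization rejects non-positive reference values by subject", {
  tab <- data.frame(id = c(7, 8), age = c(20, 60), sex = "f",
                    pk_ref = c(0.5, 0), enz_a = c(1, 1))
  expect_error(normalize_by_reference(tab), "8")
})

test_that("z-standardization has the closed form and exact moments", {
  expect_equal(z_standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(61)
  x <- rnorm(50, 10, 4)
  z <- z_standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(z_standardize(rep(2, 5)), "zero")
  expect_error(z_standardize(3), "at least 2")
})

test_that("t statistics and r2 are invariant under affine rescaling", {
  set.seed(62)
  a <- rnorm(6, 5); b <- rnorm(7, 6)
  for (variant in c("pooled", "welch")) {
    t_raw <- one_sided_t_test(a, b, variant)$statistic
    t_aff <- one_sided_t_test(3 * a - 2, 3 * b - 2, variant)$statistic
    expect_equal(t_raw, t_aff, tolerance = 1e-10)
    # standardizing both groups with the combined mean/SD is an affine map
    z <- z_standardize(c(a, b))
    t_z <- one_sided_t_test(z[1:6], z[-(1:6)], variant)$statistic
    expect_equal(t_raw, t_z, tolerance = 1e-10)
  }
  tab <- enzyme_activities()
  r2_raw <- age_trend_r2(tab, "adenylate_kinase")$r2
  tab$adenylate_kinase <- -4 * tab$adenylate_kinase + 100
  expect_equal(abs(age_trend_r2(tab, "adenylate_kinase")$r2), r2_raw,
               tolerance = 1e-10)
})

test_that("age trends of the bundled table match the recomputed values", {
  tab <- enzyme_activities()
  # frozen from an independent cor(age, x)^2 computation on the table
  expect_equal(age_trend_r2(tab, 1)$r2, 0.2150, tolerance = 5e-4)
  expect_equal(age_trend_r2(tab, 2)$r2, 0.4294, tolerance = 5e-4)
  expect_equal(age_trend_r2(tab, 3)$r2, 0.4203, tolerance = 5e-4)
  expect_equal(age_trend_r2(tab, 4, exclude_ids = 307)$r2, 0.3334, tolerance = 5e-4)
  lin <- data.frame(id = 1:5, age = c(20, 30, 40, 50, 60), sex = "f",
                    enz = c(1, 2, 3, 4, 5))
  expect_equal(age_trend_r2(lin, "enz")$r2, 1)
  expect_error(age_trend_r2(transform(lin, enz = 2), "enz"), "constant")
  expect_error(age_trend_r2(lin[1:2, ], "enz"), "3 subjects")
})

test_that("one-sided t-tests reproduce the bundled-table reference p-values", {
  tab <- enzyme_activities()
  young <- tab$age < 40
  old <- tab$age > 50
  p1 <- one_sided_t_test(tab$pk_ref[old], tab$pk_ref[young], "pooled")$p_value
  expect_lt(abs(p1 - 0.07), 0.01)
  p3 <- one_sided_t_test(tab$adenylate_kinase[old], tab$adenylate_kinase[young],
                         "pooled")$p_value
  expect_equal(p3, 0.0149, tolerance = 5e-4)  # frozen recomputed value
})

test_that("identical groups give t = 0 and one-sided p = 1/2", {
  x <- c(1, 2, 3, 4)
  tt <- one_sided_t_test(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 0.5)
  ts <- t_test_from_summary(2, 1, 5, 2, 1, 5)
  expect_equal(ts$p_value, 0.5)
})

test_that("pooled and Welch agree exactly for balanced equal-variance groups", {
  a <- c(1, 2, 3, 4, 5)
  b <- a + 1.3  # same n, same sample SD
  tp <- one_sided_t_test(a, b, "pooled")
  tw <- one_sided_t_test(a, b, "welch")
  expect_equal(tp$statistic, tw$statistic)
  expect_equal(tp$df, tw$df)
  expect_equal(tp$p_value, tw$p_value)
})

test_that("summary-statistic tests equal raw-data tests on matching data", {
  set.seed(63)
  for (variant in c("pooled", "welch")) {
    x <- vector_with_moments(5.4, 3.5, 7)
    y <- vector_with_moments(1.7, 1.5, 3)
    raw <- one_sided_t_test(x, y, variant)
    summ <- t_test_from_summary(5.4, 3.5, 7, 1.7, 1.5, 3, variant)
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
    expect_equal(raw$df, summ$df, tolerance = 1e-10)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
  }
})

test_that("the Welch summary test reproduces the glucose-uptake comparison", {
  gu <- gu_fractions()
  hi <- gu[gu$subset == "high", ]
  old <- hi[hi$group == "old", ]
  young <- hi[hi$group == "young", ]
  tt <- t_test_from_summary(old$mean_pct, old$sd_pct, old$n,
                            young$mean_pct, young$sd_pct, young$n,
                            variant = "welch")
  expect_lt(abs(tt$p_value - 0.02), 0.01)
  expect_equal(tt$statistic, 2.34, tolerance = 0.005)
  expect_equal(tt$df, 7.9, tolerance = 0.05)
})

test_that("t_test_from_summary validates its inputs", {
  expect_error(t_test_from_summary(1, 0, 5, 1, 0, 5), "undefined")
  expect_error(t_test_from_summary(1, -1, 5, 2, 1, 5), "non-negative")
  expect_error(t_test_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("group summaries reproduce the recomputed reference cells", {
  gs <- summarize_groups(enzyme_activities())
  st <- gs$stats
  adk <- st[st$column == "adenylate_kinase", ]
  expect_equal(adk$mean_old, 16.64, tolerance = 0.005)
  expect_equal(adk$mean, 10.63, tolerance = 0.005)
  expect_equal(adk$sd, 7.53, tolerance = 0.005)
  expect_equal(st$mean_young[st$column == "hexokinase"], 13.77, tolerance = 0.005)
  expect_lt(abs(st$mean_old[st$column == "pk_ref"] - 0.76), 0.0055)
  expect_equal(sort(gs$young_ids), c(214, 219, 308, 309))
  expect_equal(sort(gs$old_ids), c(221, 302, 303, 305))
  expect_error(summarize_groups(enzyme_activities()[1:4, ]), "empty")
})

test_that("PAS index comparison computes fold change, test and outliers", {
  cmp <- compare_pas_indices(rep(0.1, 5), rep(0.35, 5))
  expect_equal(cmp$fold_change, 3.5)
  expect_true(is.na(cmp$p_value))  # constant groups: no t-test, fold still defined
  young <- c(0.08, 0.1, 0.12, 0.11)
  old <- c(0.3, 0.42, 0.09, 0.5)
  cmp2 <- compare_pas_indices(young, old)
  expect_equal(cmp2$outlier_fraction, 0.75)  # 3 of 4 above max(young)
  null <- compare_pas_indices(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(null$fold_change, 1)
  expect_equal(null$p_value, 0.5)
  expect_error(compare_pas_indices(c(0, 0), c(0.1, 0.2)), "zero")
})
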