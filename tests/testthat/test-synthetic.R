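# Generators: determinism, conservation, dye model, cohort and table
# statistics of the planted ground truth.

test_that("rendering is deterministic given the seed", {
  sc <- function() image_scene(demo_cells(c(0.2, 0.7), size = 200, a = 30, b = 26),
                               width = 200, height = 200, seed = 31)
  a <- render_scene(sc())
  b <- render_scene(sc())
  expect_identical(a$specimen, b$specimen)
  expect_identical(a$bright, b$bright)
  expect_identical(a$mask, b$mask)
  c <- render_scene(image_scene(demo_cells(c(0.2, 0.7), size = 200, a = 30, b = 26),
                                width = 200, height = 200, seed = 32))
  expect_false(identical(a$specimen, c$specimen))
})

test_that("mask labels and truth rows match the cell count", {
  r <- render_scene(image_scene(demo_cells(c(0, 0.5, 1)), seed = 33))
  expect_equal(sort(unique(r$mask[r$mask > 0])), 1:3)
  expect_equal(nrow(r$truth), 3)
  expect_equal(r$truth$n_pixels, as.vector(table(r$mask[r$mask > 0])))
})

test_that("degenerate dye fractions give single-population hues", {
  r <- render_scene(image_scene(demo_cells(c(0, 1), size = 300, a = 45, b = 40),
                                width = 300, height = 300, noise_sd = 0,
                                illumination = flat_field(), seed = 34))
  hsb <- rgb_to_hsb(correct_background(r$specimen, r$bright, r$dark))
  h0 <- hsb$h[r$mask == 1]  # pure hematoxylin
  h1 <- hsb$h[r$mask == 2]  # pure PAS
  expect_gt(mean(h0 > 235 & h0 < 265), 0.99)
  expect_gt(mean(h1 > 255 & h1 < 285), 0.99)
  expect_equal(mean(h0), 250, tolerance = 1)
  expect_equal(mean(h1), 270, tolerance = 1)
})

test_that("overlapping cells error unless explicitly allowed", {
  cells <- data.frame(x = c(50, 60), y = c(50, 55), a = 20, b = 18,
                      angle = 0, p_pas = 0.5)
  expect_error(render_scene(image_scene(cells, width = 120, height = 120)),
               "overlap")
  r <- render_scene(image_scene(cells, width = 120, height = 120,
                                allow_overlap = TRUE))
  expect_equal(max(r$mask), 2L)
})

test_that("scene validation rejects bad fractions, hues and placements", {
  base <- demo_cells(0.5, size = 100, a = 20, b = 18)
  expect_error(image_scene(transform(base, p_pas = 1.2), width = 100, height = 100),
               "p_pas")
  expect_error(image_scene(base, width = 100, height = 100, hues = c(250, 370)),
               "360")
  expect_error(image_scene(transform(base, x = 5), width = 100, height = 100),
               "canvas")
})

test_that("cohort truth reproduces the designed fold change at scale", {
  # law-of-large-numbers check on the planted per-cell fractions
  spec <- cohort_spec(cells_per_subject = 400, young_sd = 0.02, old_sd = 0.02,
                      subject_sd = 0.005, seed = 41)
  truth <- pasquant:::draw_cohort_truth(spec)
  ratio <- mean(truth$p_pas[truth$group == "old"]) /
    mean(truth$p_pas[truth$group == "young"])
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 3.8)
})

test_that("a unit fold change leaves the groups indistinguishable", {
  ps <- sapply(1:40, function(s) {
    spec <- cohort_spec(fold_change = 1, cells_per_subject = 20, seed = 500 + s,
                        young_sd = 0.04, old_sd = 0.04, subject_sd = 0.01)
    truth <- pasquant:::draw_cohort_truth(spec)
    one_sided_t_test(truth$p_pas[truth$group == "old"],
                     truth$p_pas[truth$group == "young"])$p_value
  })
  expect_gt(mean(ps), 0.3)   # one-sided p should hover around 1/2 under the null
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("one cell per subject gives one truth row per subject", {
  spec <- cohort_spec(n_young = 4, n_old = 5, cells_per_subject = 1, seed = 42)
  truth <- pasquant:::draw_cohort_truth(spec)
  expect_equal(nrow(truth), 9)
  expect_equal(length(unique(truth$subject)), 9)
})

test_that("activity simulation honours degenerate noise and slope settings", {
  flat <- activity_sim_spec(slopes = c(pk_ref = 0, aldolase = 0,
                                       adenylate_kinase = 0, tpi = 0,
                                       hexokinase = 0),
                            noise_sd = 0, seed = 43)
  tab <- simulate_activity_table(flat)
  expect_true(all(vapply(tab[-(1:3)], function(x) diff(range(x)) == 0, TRUE)))

  lin <- activity_sim_spec(noise_sd = 0, seed = 44)
  tab2 <- simulate_activity_table(lin)
  expect_equal(age_trend_r2(tab2, "aldolase")$r2, 1, tolerance = 1e-10)
  expect_true(all(tab2$adenylate_kinase > 0))
  expect_identical(tab2, simulate_activity_table(lin))  # determinism
})

test_that("a slope designed for population r2 = 0.4 is recovered", {
  # independent oracle: under y = (b + s*age) * exp(e), e ~ N(0, sg^2), with
  # ages uniform on [lo, hi], the population squared correlation of y with
  # age is r2(s) = s^2 m^2 V / (s^2 m^2 V + w * E[(b + s*age)^2]) where
  # m = exp(sg^2/2), w = exp(sg^2) * (exp(sg^2) - 1), V = var(age);
  # solve r2(s) = 0.4 for the slope
  b <- 10; sg <- 0.1; lo <- 20; hi <- 70
  V <- (hi - lo)^2 / 12
  m2 <- exp(sg^2)
  w <- exp(sg^2) * (exp(sg^2) - 1)
  mean_a <- (lo + hi) / 2
  ea2 <- V + mean_a^2
  pop_r2 <- function(s) {
    between <- s^2 * m2 * V
    within <- w * (b^2 + 2 * b * s * mean_a + s^2 * ea2)
    between / (between + within)
  }
  slope <- uniroot(function(s) pop_r2(s) - 0.4, c(1e-4, 1))$root
  r2s <- sapply(1:40, function(s) {
    spec <- activity_sim_spec(n_subjects = 100, age_range = c(20, 70),
                              baselines = c(pk_ref = 10, enz = 10),
                              slopes = c(pk_ref = 0, enz = slope),
                              noise_sd = 0.1, seed = 600 + s)
    age_trend_r2(simulate_activity_table(spec), "enz")$r2
  })
  expect_gt(mean(r2s), 0.3)
  expect_lt(mean(r2s), 0.5)
})

test_that("expression simulation is deterministic and plants its effects", {
  spec <- expression_sim_spec(seed = 45)
  a <- simulate_expression_matrix(spec)
  b <- simulate_expression_matrix(spec)
  expect_identical(a$counts, b$counts)
  mk <- spec$markers
  ann <- a$annotations
  old_mye <- ann$cell_id[ann$lineage == "myeloid" & ann$age_group == "old"]
  young_mye <- ann$cell_id[ann$lineage == "myeloid" & ann$age_group == "young"]
  # proliferation elevation confined to old myeloid cells
  expect_gt(mean(a$counts[mk$proliferation, old_mye]),
            2.5 * mean(a$counts[mk$proliferation, young_mye]))
  lym <- ann$cell_id[ann$lineage == "lymphoid"]
  expect_equal(mean(a$counts[mk$proliferation, lym]),
               mean(a$counts[mk$proliferation, young_mye]), tolerance = 0.4)
})

test_that("expression spec validates multipliers and dispersion", {
  expect_error(expression_sim_spec(marker_multiplier = 0.5), "at least 1")
  expect_error(expression_sim_spec(dispersion = -1), "non-negative")
  pois <- simulate_expression_matrix(expression_sim_spec(dispersion = 0, seed = 46))
  expect_true(all(pois$counts >= 0))
})
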