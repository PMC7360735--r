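# Cohort-level image simulation: young and old donor groups whose cells
# differ in mean PAS dye fraction (default 3.5-fold) and heterogeneity.

#' Specify a synthetic young/old imaging cohort
#'
#' Per-cell true PAS fractions are drawn from Beta distributions: each donor
#' gets a mean shifted by a donor-level random effect around the group mean
#' (`young_mean`, and `young_mean * fold_change` for the old group), and each
#' cell draws its fraction from a Beta with that donor mean and the group's
#' cell-level SD. The old group's larger default dispersion reproduces the
#' hallmark heterogeneity of aged samples, where a subset of cells carries
#' far more glycogen than anything seen in young donors.
#'
#' @param n_young,n_old number of donors per group.
#' @param cells_per_subject cells imaged per donor (at least 1).
#' @param young_mean mean true PAS fraction of young-donor cells.
#' @param fold_change old/young ratio of group mean fractions (default 3.5).
#' @param young_sd,old_sd cell-level SD of the true fraction per group.
#' @param subject_sd donor-level SD of the mean fraction.
#' @param cells_per_image cells rendered per image (layout grid holds 4).
#' @param image_size canvas side in pixels.
#' @param cell_axes nominal ellipse semi-axes in pixels (jittered per cell).
#' @param noise_sd sensor noise SD passed to the renderer.
#' @param illumination an [illumination_field()] shared by all renders.
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 3, n_old = 3, cells_per_subject = 15,
                        young_mean = 0.10, fold_change = 3.5,
                        young_sd = 0.03, old_sd = 0.10, subject_sd = 0.005,
                        cells_per_image = 4, image_size = 512,
                        cell_axes = c(60, 52), noise_sd = 2,
                        illumination = illumination_field(), seed = 1L) {
  if (fold_change <= 0) stop("`fold_change` must be positive", call. = FALSE)
  if (cells_per_subject < 1) stop("`cells_per_subject` must be at least 1", call. = FALSE)
  old_mean <- young_mean * fold_change
  if (young_mean <= 0 || old_mean >= 1)
    stop("group means must lie strictly inside (0, 1)", call. = FALSE)
  structure(
    list(n_young = n_young, n_old = n_old, cells_per_subject = cells_per_subject,
         young_mean = young_mean, old_mean = old_mean, fold_change = fold_change,
         young_sd = young_sd, old_sd = old_sd, subject_sd = subject_sd,
         cells_per_image = cells_per_image, image_size = image_size,
         cell_axes = cell_axes, noise_sd = noise_sd,
         illumination = illumination, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Beta draws with a given mean and SD; the SD is shrunk if it exceeds what a
# Beta on (0, 1) with that mean can carry.
rbeta_ms <- function(n, mean, sd) {
  vmax <- mean * (1 - mean)
  v <- min(sd^2, 0.81 * vmax)
  if (v <= 0) return(rep(mean, n))
  k <- vmax / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

# Draw the cohort's ground truth (donor means and per-cell true fractions)
# without rendering any pixels. Used by simulate_cohort_images() and directly
# testable for its statistical properties.
draw_cohort_truth <- function(spec) {
  subjects <- data.frame(
    subject = c(sprintf("Y%02d", seq_len(spec$n_young)),
                sprintf("O%02d", seq_len(spec$n_old))),
    group = rep(c("young", "old"), c(spec$n_young, spec$n_old)),
    stringsAsFactors = FALSE
  )
  gmean <- ifelse(subjects$group == "young", spec$young_mean, spec$old_mean)
  gsd <- ifelse(subjects$group == "young", spec$young_sd, spec$old_sd)
  smean <- pmin(pmax(gmean + stats::rnorm(nrow(subjects), 0, spec$subject_sd), 0.02), 0.95)
  cells <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    data.frame(
      subject = subjects$subject[i], group = subjects$group[i],
      cell = seq_len(spec$cells_per_subject),
      p_pas = rbeta_ms(spec$cells_per_subject, smean[i], gsd[i]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(cells) <- NULL
  cells
}

#' Simulate a young/old cohort of rendered smear images
#'
#' Draws the cohort ground truth (see [cohort_spec()]), then renders each
#' donor's cells in batches of `cells_per_image` as full synthetic image sets
#' (specimen plus calibration frames plus label mask). Deterministic given
#' the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort_sim`: `truth` (data frame `subject`,
#'   `group`, `cell`, `p_pas` across all donors) and `subjects`, a list with
#'   one entry per donor holding its `renders` (list of [render_scene()]
#'   outputs) and the row indices of its cells in `truth`.
#' @export
simulate_cohort_images <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(spec$seed, {
    truth <- draw_cohort_truth(spec)
    subjects <- list()
    for (sid in unique(truth$subject)) {
      rows <- which(truth$subject == sid)
      batches <- split(rows, ceiling(seq_along(rows) / spec$cells_per_image))
      renders <- lapply(batches, function(b) {
        lay <- layout_cells(length(b), spec$image_size, spec$image_size,
                            spec$cell_axes[1], spec$cell_axes[2])
        lay$p_pas <- truth$p_pas[b]
        scene <- image_scene(lay, width = spec$image_size, height = spec$image_size,
                             illumination = spec$illumination,
                             noise_sd = spec$noise_sd,
                             seed = sample.int(.Machine$integer.max, 1))
        render_scene(scene)
      })
      subjects[[sid]] <- list(subject = sid, group = truth$group[rows[1]],
                              renders = renders, truth_rows = rows)
    }
    structure(list(truth = truth, subjects = subjects, spec = spec),
              class = "cohort_sim")
  })
}

#' Quantify every cell of a simulated cohort
#'
#' Runs [quantify_image_set()] over all renders of a [simulate_cohort_images()]
#' result, using each render's ground-truth mask, and joins the estimated PAS
#' index to the true per-cell fraction.
#'
#' @param sim a `cohort_sim`.
#' @param ... passed on to [quantify_image_set()].
#' @return a data frame with one row per cell: `subject`, `group`, `cell`,
#'   `p_pas` (truth), and the measurement columns of [quantify_image_set()].
#' @export
quantify_cohort <- function(sim, ...) {
  stopifnot(inherits(sim, "cohort_sim"))
  out <- list()
  for (sub in sim$subjects) {
    rows <- sub$truth_rows
    done <- 0L
    for (r in sub$renders) {
      meas <- quantify_image_set(r$specimen, r$bright, r$dark, mask = r$mask, ...)
      b <- rows[done + seq_len(nrow(meas))]
      out[[length(out) + 1L]] <- cbind(sim$truth[b, ], meas[, -1, drop = FALSE])
      done <- done + nrow(meas)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
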