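# Table-level generators: donor enzyme-activity tables with linear age
# trends and multiplicative noise, and gene-by-cell count matrices with
# planted lineage priming and proliferation effects.

#' Specify a synthetic enzyme-activity cohort
#'
#' Each enzyme's expected activity is linear in age,
#' `baseline + slope * age`, with multiplicative log-normal noise, keeping
#' simulated activities strictly positive as enzyme assays are.
#'
#' @param n_subjects number of donors.
#' @param age_range length-2 range of ages (years); ages are drawn uniformly
#'   and sorted.
#' @param baselines named numeric vector of per-enzyme baselines (activity
#'   at age 0); names define the activity columns.
#' @param slopes named numeric vector of per-enzyme slopes vs age, same
#'   names as `baselines`.
#' @param noise_sd SD of the log-normal noise on the log scale.
#' @param reference name of the reference column (kept for
#'   [normalize_by_reference()]).
#' @param seed integer seed.
#' @return an object of class `activity_sim_spec`.
#' @export
activity_sim_spec <- function(n_subjects = 9, age_range = c(19, 71),
                              baselines = c(pk_ref = 0.30, aldolase = 0.20,
                                            adenylate_kinase = 2.5, tpi = 0.05,
                                            hexokinase = 12),
                              slopes = c(pk_ref = 0.004, aldolase = 0.012,
                                         adenylate_kinase = 0.18, tpi = 0.0025,
                                         hexokinase = 0),
                              noise_sd = 0.25, reference = "pk_ref", seed = 1L) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            identical(names(baselines), names(slopes)))
  lo <- baselines + slopes * ifelse(slopes < 0, age_range[2], age_range[1])
  if (any(lo <= 0))
    stop("baseline + slope * age must stay positive over the age range", call. = FALSE)
  if (!reference %in% names(baselines))
    stop("`reference` must name one of the enzymes", call. = FALSE)
  structure(list(n_subjects = n_subjects, age_range = age_range,
                 baselines = baselines, slopes = slopes, noise_sd = noise_sd,
                 reference = reference, seed = as.integer(seed)),
            class = "activity_sim_spec")
}

#' Simulate a donor enzyme-activity table
#'
#' @param spec an [activity_sim_spec()].
#' @return a data frame shaped like [enzyme_activities()]: `id`, `age`,
#'   `sex`, then one column per enzyme.
#' @export
simulate_activity_table <- function(spec) {
  stopifnot(inherits(spec, "activity_sim_spec"))
  local_seed(spec$seed, {
    # stratified ages: evenly spaced across the range with jitter, as in a
    # designed age-span cohort (guarantees both ends are represented)
    step <- diff(spec$age_range) / max(spec$n_subjects - 1, 1)
    ages <- seq(spec$age_range[1], spec$age_range[2], length.out = spec$n_subjects) +
      stats::runif(spec$n_subjects, -step / 3, step / 3)
    ages <- sort(round(pmin(pmax(ages, spec$age_range[1]), spec$age_range[2])))
    out <- data.frame(id = 100 + seq_len(spec$n_subjects), age = ages,
                      sex = rep_len(c("f", "m"), spec$n_subjects),
                      stringsAsFactors = FALSE)
    for (enz in names(spec$baselines)) {
      mu <- spec$baselines[[enz]] + spec$slopes[[enz]] * ages
      out[[enz]] <- mu * exp(stats::rnorm(spec$n_subjects, 0, spec$noise_sd))
    }
    out
  })
}

#' Specify a synthetic lineage-primed expression cohort
#'
#' Gene-by-cell negative-binomial counts with planted structure: myeloid
#' marker genes are elevated (`marker_multiplier`) in myeloid-primed cells
#' and lymphoid markers in lymphoid-primed cells; proliferation genes are
#' elevated (`proliferation_multiplier`) only in old myeloid-primed cells,
#' the configuration the enrichment stage is meant to detect.
#'
#' @param n_background_genes unstructured genes in addition to the marker
#'   sets.
#' @param n_lineage_markers myeloid and lymphoid marker genes each.
#' @param n_proliferation proliferation-set genes.
#' @param cells_per_group cells per (age group x lineage) combination;
#'   lineages are myeloid, lymphoid and unprimed.
#' @param donors_per_age donors per age group (cells assigned round-robin).
#' @param baseline_mean negative-binomial mean of unaffected genes.
#' @param marker_multiplier fold elevation of a lineage's own markers
#'   (at least 1).
#' @param proliferation_multiplier fold elevation of proliferation genes in
#'   old myeloid-primed cells (at least 1).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param seed integer seed.
#' @return an object of class `expression_sim_spec`; its `markers` element
#'   is the matching [marker_set()].
#' @export
expression_sim_spec <- function(n_background_genes = 160, n_lineage_markers = 10,
                                n_proliferation = 20, cells_per_group = 60,
                                donors_per_age = 2, baseline_mean = 2,
                                marker_multiplier = 10,
                                proliferation_multiplier = 3,
                                dispersion = 0.5, seed = 1L) {
  if (marker_multiplier < 1 || proliferation_multiplier < 1)
    stop("effect multipliers must be at least 1", call. = FALSE)
  if (dispersion < 0) stop("`dispersion` must be non-negative", call. = FALSE)
  markers <- marker_set(
    myeloid = sprintf("MYE%02d", seq_len(n_lineage_markers)),
    lymphoid = sprintf("LYM%02d", seq_len(n_lineage_markers)),
    proliferation = sprintf("PRO%02d", seq_len(n_proliferation))
  )
  genes <- c(markers$myeloid, markers$lymphoid, markers$proliferation,
             sprintf("BG%03d", seq_len(n_background_genes)))
  structure(list(genes = genes, markers = markers,
                 cells_per_group = cells_per_group, donors_per_age = donors_per_age,
                 baseline_mean = baseline_mean, marker_multiplier = marker_multiplier,
                 proliferation_multiplier = proliferation_multiplier,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Simulate a gene-by-cell count matrix with planted priming
#'
#' @param spec an [expression_sim_spec()].
#' @return a list: `counts` (genes x cells integer matrix) and `annotations`
#'   (data frame `cell_id`, `donor`, `age_group`, `lineage` — the planted
#'   truth).
#' @export
simulate_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  local_seed(spec$seed, {
    lineages <- c("myeloid", "lymphoid", "unprimed")
    ages <- c("young", "old")
    ann <- expand.grid(cell = seq_len(spec$cells_per_group), lineage = lineages,
                       age_group = ages, stringsAsFactors = FALSE)
    n_cells <- nrow(ann)
    ann$donor <- paste0(substr(ann$age_group, 1, 1),
                        (ann$cell - 1L) %% spec$donors_per_age + 1L)
    ann$cell_id <- sprintf("c%04d", seq_len(n_cells))

    genes <- spec$genes
    mu <- matrix(spec$baseline_mean, length(genes), n_cells,
                 dimnames = list(genes, ann$cell_id))
    mk <- spec$markers
    mu[mk$myeloid, ann$lineage == "myeloid"] <-
      spec$baseline_mean * spec$marker_multiplier
    mu[mk$lymphoid, ann$lineage == "lymphoid"] <-
      spec$baseline_mean * spec$marker_multiplier
    old_mye <- ann$lineage == "myeloid" & ann$age_group == "old"
    mu[mk$proliferation, old_mye] <-
      spec$baseline_mean * spec$proliferation_multiplier

    counts <- if (spec$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu), dimnames = dimnames(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    }
    list(counts = counts,
         annotations = ann[, c("cell_id", "donor", "age_group", "lineage")])
  })
}
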