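# Lineage priming of single cells from marker-gene abundance, and
# proliferation-gene enrichment per lineage and age group.

#' Define marker gene sets
#'
#' @param myeloid,lymphoid character vectors of lineage marker genes; must
#'   be disjoint.
#' @param proliferation character vector of proliferation-associated genes.
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(myeloid, lymphoid, proliferation = character()) {
  if (length(intersect(myeloid, lymphoid)))
    stop("myeloid and lymphoid marker sets must be disjoint", call. = FALSE)
  structure(list(myeloid = unique(myeloid), lymphoid = unique(lymphoid),
                 proliferation = unique(proliferation)),
            class = "marker_set")
}

# Per-cell log1p expression after scaling each cell to a common total count.
# Total-count scaling makes all marker scores invariant to per-cell depth.
normalize_log_counts <- function(counts, target_total = 1e4) {
  tot <- colSums(counts)
  scale <- ifelse(tot > 0, target_total / tot, 0)
  log1p(sweep(counts, 2, scale, `*`))
}

present_genes <- function(counts, genes, what) {
  found <- intersect(genes, rownames(counts))
  if (length(found) == 0)
    stop("none of the ", what, " genes are present in the matrix", call. = FALSE)
  if (length(found) < length(genes))
    warning(sprintf("%d of %d %s genes missing from the matrix",
                    length(genes) - length(found), length(genes), what), call. = FALSE)
  found
}

#' Classify cells as myeloid-primed, lymphoid-primed or unprimed
#'
#' Scores each cell by the mean log1p total-count-normalized expression over
#' the myeloid and over the lymphoid marker set; a cell is called
#' myeloid-primed when its myeloid score exceeds its lymphoid score by more
#' than `margin` (on the log scale), lymphoid-primed in the opposite case,
#' and unprimed when the scores are within the margin of each other.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param markers a [marker_set()]; at least one gene per lineage must be
#'   present in the matrix.
#' @param margin score difference required to call priming.
#' @param target_total per-cell total count after normalization.
#' @return a data frame `cell_id`, `lineage`, `myeloid_score`,
#'   `lymphoid_score`.
#' @export
classify_lineage <- function(counts, markers, margin = 0.25, target_total = 1e4) {
  stopifnot(inherits(markers, "marker_set"))
  if (!is_count_matrix(counts))
    stop("`counts` must be a named non-negative genes x cells matrix", call. = FALSE)
  mye <- present_genes(counts, markers$myeloid, "myeloid marker")
  lym <- present_genes(counts, markers$lymphoid, "lymphoid marker")
  ln <- normalize_log_counts(counts, target_total)
  score_m <- colMeans(ln[mye, , drop = FALSE])
  score_l <- colMeans(ln[lym, , drop = FALSE])
  lineage <- ifelse(score_m - score_l > margin, "myeloid",
                    ifelse(score_l - score_m > margin, "lymphoid", "unprimed"))
  data.frame(cell_id = colnames(counts), lineage = lineage,
             myeloid_score = unname(score_m), lymphoid_score = unname(score_l),
             stringsAsFactors = FALSE)
}

merge_annotations <- function(counts, annotations) {
  need <- c("cell_id", "lineage", "age_group")
  if (!all(need %in% names(annotations)))
    stop("`annotations` must have columns cell_id, lineage, age_group", call. = FALSE)
  if (!all(colnames(counts) %in% annotations$cell_id))
    stop("annotations must cover every cell in the matrix", call. = FALSE)
  annotations[match(colnames(counts), annotations$cell_id), need]
}

#' Count detected proliferation genes per lineage and age group
#'
#' A gene counts as detected in a group when at least `detection_fraction`
#' of the group's cells express it at `detection_threshold` counts or more —
#' a rule robust to the dropout typical of sparse single-cell counts.
#'
#' @param counts genes x cells count matrix.
#' @param annotations data frame with `cell_id`, `lineage`, `age_group`
#'   covering all cells (e.g. [classify_lineage()] output joined with cell
#'   metadata, or a generator's planted truth).
#' @param markers a [marker_set()] whose `proliferation` genes are counted.
#' @param detection_threshold minimum count for a cell to express a gene.
#' @param detection_fraction minimum fraction of group cells expressing.
#' @return a data frame `age_group`, `lineage`, `n_cells`, `n_detected`.
#'   Empty groups are kept with a warning and zero counts.
#' @export
proliferation_counts <- function(counts, annotations, markers,
                                 detection_threshold = 1,
                                 detection_fraction = 0.25) {
  stopifnot(inherits(markers, "marker_set"))
  ann <- merge_annotations(counts, annotations)
  genes <- if (length(markers$proliferation))
    intersect(markers$proliferation, rownames(counts)) else character()
  grid <- expand.grid(age_group = unique(ann$age_group),
                      lineage = unique(ann$lineage),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- ann$age_group == grid$age_group[i] & ann$lineage == grid$lineage[i]
    n_cells <- sum(sel)
    if (n_cells == 0) {
      warning(sprintf("empty group: %s/%s", grid$age_group[i], grid$lineage[i]),
              call. = FALSE)
      n_det <- 0L
    } else if (length(genes) == 0) {
      n_det <- 0L
    } else {
      expr_frac <- rowMeans(counts[genes, sel, drop = FALSE] >= detection_threshold)
      n_det <- sum(expr_frac >= detection_fraction)
    }
    data.frame(age_group = grid$age_group[i], lineage = grid$lineage[i],
               n_cells = n_cells, n_detected = n_det, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Hypergeometric one-sided test (alternative "greater" on the [1,1] cell)
#' with the conditional maximum-likelihood odds ratio, via
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts with at least one
#'   positive margin.
#' @return a list `odds_ratio`, `p_value`, `table`.
#' @examples
#' fisher_exact_one_sided(matrix(c(3, 1, 1, 3), 2))$p_value  # 17/70
#' @export
fisher_exact_one_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integer counts", call. = FALSE)
  if (sum(table) == 0) stop("all-zero contingency table", call. = FALSE)
  ft <- stats::fisher.test(table, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = table)
}

#' Proliferation-gene enrichment in myeloid- vs lymphoid-primed cells
#'
#' Builds the 2x2 table of proliferation genes detected / not detected
#' (rule of [proliferation_counts()], applied to all cells of each lineage
#' pooled over age groups) in myeloid-primed versus lymphoid-primed cells,
#' and tests myeloid enrichment with the one-sided Fisher exact test.
#'
#' @inheritParams proliferation_counts
#' @return an object of class `enrichment_result`: `table` (2x2, rows
#'   myeloid/lymphoid, columns detected/not detected), `odds_ratio`,
#'   `p_value`, `per_group` (the [proliferation_counts()] breakdown).
#' @export
proliferation_enrichment <- function(counts, annotations, markers,
                                     detection_threshold = 1,
                                     detection_fraction = 0.25) {
  ann <- merge_annotations(counts, annotations)
  genes <- present_genes(counts, markers$proliferation, "proliferation")
  detected_in <- function(lin) {
    sel <- ann$lineage == lin
    if (!any(sel)) stop("no cells of lineage ", lin, call. = FALSE)
    frac <- rowMeans(counts[genes, sel, drop = FALSE] >= detection_threshold)
    sum(frac >= detection_fraction)
  }
  d_m <- detected_in("myeloid")
  d_l <- detected_in("lymphoid")
  tab <- matrix(c(d_m, d_l, length(genes) - d_m, length(genes) - d_l), 2,
                dimnames = list(c("myeloid", "lymphoid"),
                                c("detected", "not_detected")))
  ft <- fisher_exact_one_sided(tab)
  per_group <- proliferation_counts(counts, annotations, markers,
                                    detection_threshold, detection_fraction)
  structure(list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 per_group = per_group),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Proliferation-gene enrichment (myeloid vs lymphoid primed cells)\n")
  print(x$table)
  cat(sprintf("  one-sided Fisher exact: odds ratio %.3g, p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Young-vs-old expression of a gene set, per lineage
#'
#' For each lineage present in the annotations, scores every cell by its
#' mean log1p-normalized expression over `gene_set` and tests whether old
#' cells score higher than young cells with a one-sided t-test
#' ([one_sided_t_test()]). Lineages lacking one of the age groups are
#' skipped with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param annotations data frame `cell_id`, `lineage`, `age_group`.
#' @param gene_set character vector of genes; at least one must be in the
#'   matrix.
#' @param variant t-test variant (default Welch).
#' @param target_total per-cell total for normalization.
#' @return a data frame `lineage`, `n_young`, `n_old`, `mean_young`,
#'   `mean_old`, `statistic`, `df`, `p_value`.
#' @export
compare_age_by_lineage <- function(counts, annotations, gene_set,
                                   variant = "welch", target_total = 1e4) {
  ann <- merge_annotations(counts, annotations)
  genes <- present_genes(counts, gene_set, "gene-set")
  ln <- normalize_log_counts(counts, target_total)
  score <- colMeans(ln[genes, , drop = FALSE])
  rows <- list()
  for (lin in unique(ann$lineage)) {
    sel <- ann$lineage == lin
    young <- score[sel & ann$age_group == "young"]
    old <- score[sel & ann$age_group == "old"]
    if (length(young) < 2 || length(old) < 2) {
      warning("lineage ", lin, " lacks one of the age groups; skipped", call. = FALSE)
      next
    }
    tt <- one_sided_t_test(old, young, variant = variant)
    rows[[length(rows) + 1L]] <- data.frame(
      lineage = lin, n_young = length(young), n_old = length(old),
      mean_young = mean(young), mean_old = mean(old),
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
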