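# Cell segmentation on background-corrected smear images. Stained (cell)
# pixels are chromatic and darker than the near-white background, so a
# saturation/brightness gate followed by connected-component labelling is
# enough for well-separated smear preparations.

#' Segment stained cells by saturation/brightness gating
#'
#' Foreground pixels are those with saturation at least `s_min` and
#' brightness inside `b_window`; 8-connected components of the foreground
#' with at least `min_area` pixels become cells, labelled `1..N` in raster
#' order of their first pixel. Intended to run on a background-corrected
#' image (see [correct_background()]); a user-supplied mask can bypass this
#' step entirely in [quantify_image_set()].
#'
#' @param img a height x width x 3 RGB array in `[0, 255]`, or an
#'   `hsb_image`.
#' @param s_min minimum saturation for foreground.
#' @param b_window length-2 brightness window `[lo, hi]` for foreground.
#' @param min_area minimum component size in pixels.
#' @return an integer label matrix (0 = background, `k` = cell `k`). A
#'   warning is issued when no cells are found.
#' @export
segment_cells <- function(img, s_min = 0.08, b_window = c(0.05, 0.98), min_area = 50) {
  hsb <- if (inherits(img, "hsb_image")) img else rgb_to_hsb(img)
  fg <- hsb$s >= s_min & hsb$b >= b_window[1] & hsb$b <= b_window[2]
  label_components(fg, min_area = min_area)
}

# 8-connected component labelling of a logical matrix via an explicit pixel
# adjacency graph. Labels are assigned in raster (column-major) order of each
# component's first pixel, so results are deterministic.
label_components <- function(fg, min_area = 1) {
  stopifnot(is.matrix(fg), is.logical(fg))
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0) {
    warning("no foreground pixels: returning an empty mask", call. = FALSE)
    return(out)
  }
  rank <- integer(nr * nc)
  rank[idx] <- seq_along(idx)

  edges <- list()
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  # offsets covering half the 8-neighbourhood (the rest arrive symmetrically)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- rank[nb] > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(rank[idx[ok][hit]], rank[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership

  keep <- which(tabulate(memb) >= min_area)
  if (length(keep) == 0) {
    warning("no components reach `min_area`: returning an empty mask", call. = FALSE)
    return(out)
  }
  # relabel surviving components by first appearance in raster order
  # (idx is ascending, so unique() sees components in raster order)
  ord <- unique(memb)
  ord <- ord[ord %in% keep]
  relab <- integer(max(memb))
  relab[ord] <- seq_along(ord)
  out[idx] <- relab[memb]
  out
}
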