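# Hue histograms: the binned representation that the EMG deconvolution fits.

#' Build a hue histogram from hue values
#'
#' Counts hue values into uniform bins over `[0, 360)`. The bin width must
#' divide 360.
#'
#' @param hues numeric vector of hue values in degrees (wrapped into
#'   `[0, 360)`).
#' @param bin_width bin width in degrees; must divide 360. Default 1 degree,
#'   which resolves the 20-degree separated stain peaks comfortably.
#' @param n_total total pixel count the hues were drawn from (defaults to
#'   `length(hues)`); used for the conservation bookkeeping.
#' @param n_excluded number of pixels removed by filters before binning.
#' @param filters list recording the filter settings used.
#' @return an object of class `hue_histogram`: `counts`, `breaks`, `mids`,
#'   `bin_width`, `n_total`, `n_excluded`, `filters`.
#' @export
hue_histogram <- function(hues, bin_width = 1, n_total = length(hues),
                          n_excluded = 0L, filters = list()) {
  if (bin_width <= 0 || abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop("`bin_width` must be a positive divisor of 360", call. = FALSE)
  nbin <- as.integer(round(360 / bin_width))
  hues <- hues %% 360
  counts <- tabulate(pmin.int(nbin, floor(hues / bin_width) + 1L), nbin)
  breaks <- seq(0, 360, by = bin_width)
  structure(
    list(counts = counts, breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
         bin_width = bin_width, n_total = n_total, n_excluded = as.integer(n_excluded),
         filters = filters),
    class = "hue_histogram"
  )
}

#' Extract the hue histogram of one cell
#'
#' Collects the hue values of the pixels belonging to cell `cell_id` in
#' `mask` that pass the saturation/brightness filters, and bins them. The
#' filters remove near-white background bleed (low saturation) and
#' sensor-saturated or near-black pixels (brightness outside the window);
#' excluded pixels are counted so that `sum(counts) + n_excluded` always
#' equals the cell's pixel count.
#'
#' @param hsb an `hsb_image` (see [rgb_to_hsb()]).
#' @param mask integer label matrix of the same dimensions.
#' @param cell_id positive integer label to extract.
#' @param bin_width hue bin width in degrees (divisor of 360).
#' @param s_min minimum saturation.
#' @param b_window brightness window `[lo, hi]`.
#' @return a [hue_histogram()] with `n_total` the cell pixel count and
#'   `n_excluded` the number filtered out.
#' @export
extract_hue_histogram <- function(hsb, mask, cell_id, bin_width = 1,
                                  s_min = 0.08, b_window = c(0.05, 0.98)) {
  stopifnot(inherits(hsb, "hsb_image"))
  if (!identical(dim(hsb$h), dim(mask)))
    stop("mask dimensions must match the image", call. = FALSE)
  sel <- mask == cell_id
  n_cell <- sum(sel)
  if (n_cell == 0)
    stop(sprintf("cell id %s is not present in the mask", cell_id), call. = FALSE)
  pass <- sel & hsb$s >= s_min & hsb$b >= b_window[1] & hsb$b <= b_window[2]
  n_pass <- sum(pass)
  if (n_pass == 0)
    stop("empty histogram: no pixels of this cell pass the saturation/brightness filters",
         call. = FALSE)
  hue_histogram(hsb$h[pass], bin_width = bin_width, n_total = n_cell,
                n_excluded = n_cell - n_pass,
                filters = list(s_min = s_min, b_window = b_window))
}

#' @export
print.hue_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("Hue histogram: %d counts in %d bins (width %g deg), %d excluded\n",
              sum(x$counts), length(x$counts), x$bin_width, x$n_excluded))
  if (length(nz))
    cat(sprintf("  occupied hue range: [%g, %g) deg\n",
                x$breaks[min(nz)], x$breaks[max(nz) + 1]))
  invisible(x)
}

#' @export
plot.hue_histogram <- function(x, xlim = NULL, ...) {
  nz <- which(x$counts > 0)
  if (is.null(xlim) && length(nz)) xlim <- range(x$mids[nz]) + c(-10, 10)
  graphics::plot(x$mids, x$counts, type = "h", xlab = "hue (degrees)",
                 ylab = "pixel count", xlim = xlim, ...)
  invisible(x)
}
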