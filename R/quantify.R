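# The end-to-end per-cell quantification: correction -> HSB -> (segmentation)
# -> per-cell hue histogram -> EMG deconvolution -> PAS index. Also the small
# amount of image IO the pipeline needs.

#' Quantify per-cell glycogen from one image set
#'
#' Runs the full measurement chain on a specimen image and its calibration
#' pair: [correct_background()], [rgb_to_hsb()], [segment_cells()] (skipped
#' when a label mask is supplied), then per cell [extract_hue_histogram()],
#' [fit_emg_mixture()] and [pas_index()]. Cells whose histogram or fit fails
#' are kept in the output with `NA` index and the error message in the
#' `error` column — failures are flagged, never silently dropped.
#'
#' @param specimen,bright,dark 8-bit RGB arrays (see [correct_background()]).
#' @param mask optional integer label matrix; when supplied, segmentation is
#'   bypassed and the mask's labels are measured as-is.
#' @param bin_width hue bin width in degrees.
#' @param s_min,b_window pixel filters (see [extract_hue_histogram()]); also
#'   used for segmentation when no mask is given.
#' @param min_area minimum segment area in pixels (segmentation only).
#' @param per_cell fit one histogram per cell (default). With
#'   `per_cell = FALSE` all cell pixels are pooled into one histogram and one
#'   row (`cell_id = 0`) is returned — a coarser per-image mode.
#' @param fit_args list of extra arguments for [fit_emg_mixture()].
#' @return a data frame with one row per cell: `cell_id`, `n_pixels`,
#'   `pas_index`, component parameters (`mu1`, `mu2`, `sigma1`, `sigma2`,
#'   `tau1`, `tau2`, `A1`, `A2`), `rss`, `converged`, `fallback_used`,
#'   `error`.
#' @examples
#' sc <- image_scene(data.frame(x = 60, y = 60, a = 40, b = 34, angle = 0, p_pas = 0.4),
#'                   width = 120, height = 120, noise_sd = 0,
#'                   illumination = flat_field())
#' r <- render_scene(sc)
#' quantify_image_set(r$specimen, r$bright, r$dark, mask = r$mask)
#' @export
quantify_image_set <- function(specimen, bright, dark, mask = NULL,
                               bin_width = 1, s_min = 0.08,
                               b_window = c(0.05, 0.98), min_area = 50,
                               per_cell = TRUE, fit_args = list()) {
  corrected <- correct_background(specimen, bright, dark)
  hsb <- rgb_to_hsb(corrected)
  if (is.null(mask)) {
    mask <- segment_cells(hsb, s_min = s_min, b_window = b_window, min_area = min_area)
  } else if (!identical(dim(mask), dim(hsb$h))) {
    stop("supplied mask dimensions do not match the image", call. = FALSE)
  }

  ids <- sort(unique(mask[mask > 0]))
  if (!per_cell && length(ids)) {
    mask <- (mask > 0) * 1L
    ids <- if (any(mask > 0)) 1L else integer()
  }

  empty <- data.frame(cell_id = integer(), n_pixels = integer(), pas_index = double(),
                      mu1 = double(), mu2 = double(), sigma1 = double(), sigma2 = double(),
                      tau1 = double(), tau2 = double(), A1 = double(), A2 = double(),
                      rss = double(), converged = logical(), fallback_used = logical(),
                      error = character(), stringsAsFactors = FALSE)
  if (length(ids) == 0) return(empty)

  rows <- lapply(ids, function(id) {
    n_pix <- sum(mask == id)
    row <- data.frame(cell_id = if (per_cell) id else 0L, n_pixels = n_pix,
                      pas_index = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
                      sigma1 = NA_real_, sigma2 = NA_real_, tau1 = NA_real_,
                      tau2 = NA_real_, A1 = NA_real_, A2 = NA_real_,
                      rss = NA_real_, converged = NA, fallback_used = NA,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- try({
      hist <- extract_hue_histogram(hsb, mask, id, bin_width = bin_width,
                                    s_min = s_min, b_window = b_window)
      fit <- do.call(fit_emg_mixture, c(list(hist), fit_args))
      idx <- pas_index(fit)
      comp <- fit$components
      row$pas_index <- as.numeric(idx)
      row[c("mu1", "mu2")] <- comp$mu
      row[c("sigma1", "sigma2")] <- comp$sigma
      row[c("tau1", "tau2")] <- comp$tau
      row[c("A1", "A2")] <- comp$area
      row$rss <- fit$rss
      row$converged <- fit$converged
      row$fallback_used <- isTRUE(attr(idx, "fallback_used"))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      row$error <- conditionMessage(attr(res, "condition"))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return a height x width x 3 array of intensities in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  img <- switch(tolower(tools::file_ext(path)),
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", path, call. = FALSE))
  if (length(dim(img)) == 2L) stop("expected an RGB image, got a single channel", call. = FALSE)
  if (dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  round(img * 255)
}

#' Write an 8-bit RGB image (PNG or TIFF)
#'
#' @param img a height x width x 3 array in `[0, 255]`.
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_rgb_image <- function(img, path) {
  check_rgb_image(img)
  scaled <- quantize8(img) / 255
  switch(tolower(tools::file_ext(path)),
         png = png::writePNG(scaled, path),
         tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8),
         stop("unsupported image format: ", path, call. = FALSE))
  invisible(path)
}

#' Read a 16-bit label mask (PNG or TIFF)
#'
#' @param path file path; values are rescaled from the file's unit range to
#'   integer labels (0 = background).
#' @return an integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- switch(tolower(tools::file_ext(path)),
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported mask format: ", path, call. = FALSE))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  out
}

#' Write a label mask as a 16-bit single-channel TIFF
#'
#' @param mask integer label matrix (0 = background, labels up to 65535).
#' @param path destination path ending in `.tif` or `.tiff`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535, min(mask) >= 0)
  if (!tolower(tools::file_ext(path)) %in% c("tif", "tiff"))
    stop("label masks are written as 16-bit TIFF; use a .tif/.tiff path", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}
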