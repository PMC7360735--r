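# Synthetic smear-image generator. Renders elliptical "cells" whose pixels
# mix two dye hue populations (hematoxylin near 250 deg, PAS near 270 deg)
# under an inhomogeneous illumination field with a dark offset and sensor
# noise, together with the matching calibration frames, label mask and
# per-cell ground truth. Every downstream stage of the pipeline is testable
# against these renders without any external data.

#' Per-channel polynomial illumination field
#'
#' Gain surface `g(u, v) = c0 + c1 u + c2 v + c3 u^2 + c4 u v + c5 v^2` on
#' normalized coordinates `u, v` in `[-1, 1]`, evaluated per color channel
#' and clamped to `[0.6, 1]`. The defaults give an asymmetric vignette that
#' is deliberately different per channel, so an uncorrected image acquires a
#' position-dependent color cast; this is what makes the flat-field
#' correction consequential for hue measurements.
#'
#' @param coef list of three numeric length-6 coefficient vectors (R, G, B
#'   channels). `NULL` uses the default vignette.
#' @param range gain clamp, default `c(0.6, 1)`.
#' @return an object of class `illumination_field`.
#' @export
illumination_field <- function(coef = NULL, range = c(0.6, 1)) {
  if (is.null(coef)) {
    coef <- list(
      r = c(1.00, 0.03, -0.02, -0.32, 0.05, -0.25),
      g = c(1.00, -0.02, 0.02, -0.22, -0.04, -0.18),
      b = c(1.00, 0.01, 0.03, -0.12, 0.03, -0.10)
    )
  }
  stopifnot(length(coef) == 3, all(vapply(coef, length, 1L) == 6))
  structure(list(coef = coef, range = range), class = "illumination_field")
}

#' A perfectly flat illumination field (gain 1 everywhere)
#' @return an `illumination_field` with unit gain.
#' @export
flat_field <- function() {
  illumination_field(coef = list(r = c(1, 0, 0, 0, 0, 0),
                                 g = c(1, 0, 0, 0, 0, 0),
                                 b = c(1, 0, 0, 0, 0, 0)),
                     range = c(0, 1))
}

# Evaluate an illumination field into a height x width x 3 gain array.
eval_gain <- function(field, height, width) {
  u <- matrix(seq(-1, 1, length.out = width), height, width, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = height), height, width)
  gain <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    cf <- field$coef[[ch]]
    g <- cf[1] + cf[2] * u + cf[3] * v + cf[4] * u^2 + cf[5] * u * v + cf[6] * v^2
    gain[, , ch] <- pmin(pmax(g, field$range[1]), field$range[2])
  }
  gain
}

#' Specify a synthetic stained-smear scene
#'
#' Defines the canvas, the cells (elliptical regions with a ground-truth PAS
#' dye fraction each), the dye hue model, the illumination field and the
#' sensor model. The scene is rendered by [render_scene()].
#'
#' Dye hues are drawn from exponentially modified Gaussian distributions
#' whose means sit at the nominal dye hues — the same peak family the
#' deconvolution stage fits, so that ground-truth recovery is limited by
#' sampling and sensor effects rather than by an arbitrary shape mismatch.
#' Saturation and brightness vary per pixel within `saturation` and
#' `brightness` ranges, emulating within-cell stain-density variation (and
#' preventing all cell pixels from falling onto a single quantized hue grid
#' after the 8-bit round trip).
#'
#' @param cells data frame with one row per cell: columns `x`, `y` (center,
#'   pixels, 1-based), `a`, `b` (ellipse semi-axes, pixels), `angle`
#'   (degrees) and `p_pas` (true PAS dye fraction in `[0, 1]`).
#' @param width,height canvas size in pixels.
#' @param hues nominal dye hue means in degrees `[0, 360)`, named
#'   `hematoxylin` and `pas`.
#' @param hue_sigma,hue_tau Gaussian width and exponential tail of the dye
#'   hue distributions (degrees).
#' @param saturation,brightness length-2 ranges for per-pixel saturation and
#'   brightness of cell pixels.
#' @param illumination an [illumination_field()].
#' @param noise_sd additive Gaussian sensor noise SD on 8-bit intensities.
#' @param dark_level sensor dark offset (intensity units).
#' @param seed integer; rendering is deterministic given the seed.
#' @param allow_overlap if `FALSE` (default), overlapping cells are an error.
#' @return an object of class `image_scene`.
#' @export
image_scene <- function(cells, width = 512, height = 512,
                        hues = c(hematoxylin = 250, pas = 270),
                        hue_sigma = 3, hue_tau = 2.5,
                        saturation = c(0.45, 0.65), brightness = c(0.5, 0.7),
                        illumination = illumination_field(),
                        noise_sd = 2, dark_level = 8, seed = 1L,
                        allow_overlap = FALSE) {
  stopifnot(is.data.frame(cells),
            all(c("x", "y", "a", "b", "angle", "p_pas") %in% names(cells)))
  if (any(cells$p_pas < 0 | cells$p_pas > 1))
    stop("all `p_pas` must lie in [0, 1]", call. = FALSE)
  if (any(hues < 0 | hues >= 360))
    stop("dye hue means must lie in [0, 360)", call. = FALSE)
  if (is.null(names(hues))) names(hues) <- c("hematoxylin", "pas")
  r <- pmax(cells$a, cells$b)
  if (any(cells$x - r < 1 | cells$x + r > width | cells$y - r < 1 | cells$y + r > height))
    stop("cell ellipses must lie within the canvas", call. = FALSE)
  structure(
    list(cells = cells, width = width, height = height, hues = hues,
         hue_sigma = hue_sigma, hue_tau = hue_tau,
         saturation = saturation, brightness = brightness,
         illumination = illumination, noise_sd = noise_sd,
         dark_level = dark_level, seed = as.integer(seed),
         allow_overlap = isTRUE(allow_overlap)),
    class = "image_scene"
  )
}

#' Render a synthetic scene to images, calibration frames and ground truth
#'
#' Produces the specimen image `dark + gain * ideal + noise` (quantized to
#' 8 bits by round-half-away-from-zero and clipping), the open-light-path
#' frame `dark + gain * 255 + noise`, the blocked-light-path frame
#' `dark + noise`, the 16-bit style label mask and the per-cell ground-truth
#' table. Within each cell, `round(p_pas * n)` of its `n` pixels (chosen by a
#' seeded permutation, so each pixel is PAS with probability `p_pas`) carry
#' the PAS dye hue distribution, the rest the hematoxylin one.
#'
#' @param scene an [image_scene()].
#' @return a list of class `rendered_scene`: `specimen`, `bright`, `dark`
#'   (8-bit arrays), `ideal` (the floating-point specimen before illumination
#'   and sensor effects), `mask` (integer label matrix), `truth` (data frame
#'   `cell`, `x`, `y`, `n_pixels`, `p_pas`) and the `scene`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "image_scene"))
  local_seed(scene$seed, {
    h <- scene$height; w <- scene$width
    mask <- matrix(0L, h, w)
    ideal <- array(255, c(h, w, 3))  # near-white background (S = 0)
    cells <- scene$cells
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    truth <- cells[0, ]
    n_px <- integer(nrow(cells))

    for (k in seq_len(nrow(cells))) {
      ck <- cells[k, ]
      th <- ck$angle * pi / 180
      dx <- xs - ck$x; dy <- ys - ck$y
      inside <- ((dx * cos(th) + dy * sin(th)) / ck$a)^2 +
        ((-dx * sin(th) + dy * cos(th)) / ck$b)^2 <= 1
      pix <- which(inside)
      clash <- pix[mask[pix] != 0L]
      if (length(clash) && !scene$allow_overlap)
        stop(sprintf("cells %d and %d overlap (set `allow_overlap = TRUE` to permit)",
                     mask[clash[1]], k), call. = FALSE)
      pix <- pix[mask[pix] == 0L]
      n <- length(pix)
      if (n == 0) next
      mask[pix] <- k
      n_px[k] <- n

      n_pas <- round(ck$p_pas * n)
      pas_sel <- logical(n)
      pas_sel[sample.int(n, n_pas)] <- TRUE
      hue <- numeric(n)
      if (n_pas < n)
        hue[!pas_sel] <- remg(n - n_pas, scene$hues[["hematoxylin"]] - scene$hue_tau,
                              scene$hue_sigma, scene$hue_tau)
      if (n_pas > 0)
        hue[pas_sel] <- remg(n_pas, scene$hues[["pas"]] - scene$hue_tau,
                             scene$hue_sigma, scene$hue_tau)
      s <- stats::runif(n, scene$saturation[1], scene$saturation[2])
      b <- stats::runif(n, scene$brightness[1], scene$brightness[2])
      rgb <- hsb_to_rgb(hue, s, b)
      npix_canvas <- h * w
      for (ch in 1:3) ideal[pix + (ch - 1L) * npix_canvas] <- rgb[, ch]
    }

    # Exposure is set so the open-path frame never saturates: the dark offset
    # plus full-scale signal at unit gain lands exactly at 255.
    gain <- eval_gain(scene$illumination, h, w) * (255 - scene$dark_level) / 255
    noise <- function() if (scene$noise_sd > 0)
      array(stats::rnorm(h * w * 3, 0, scene$noise_sd), c(h, w, 3)) else 0
    specimen <- quantize8(scene$dark_level + gain * ideal + noise())
    bright <- quantize8(scene$dark_level + gain * 255 + noise())
    dark <- quantize8(array(scene$dark_level, c(h, w, 3)) + noise())

    truth <- data.frame(cell = seq_len(nrow(cells)), x = cells$x, y = cells$y,
                        n_pixels = n_px, p_pas = cells$p_pas)
    structure(list(specimen = specimen, bright = bright, dark = dark,
                   ideal = ideal, mask = mask, truth = truth, scene = scene),
              class = "rendered_scene")
  })
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("Rendered smear scene: %d x %d px, %d cells, noise sd %g\n",
              x$scene$height, x$scene$width, nrow(x$truth), x$scene$noise_sd))
  invisible(x)
}

# Deterministic, non-overlapping cell layout on a jittered grid; used by the
# cohort simulator.
layout_cells <- function(n, width, height, axis_a, axis_b, jitter = 15) {
  slots <- expand.grid(
    x = seq(0.27, 0.73, length.out = 2) * width,
    y = seq(0.27, 0.73, length.out = 2) * height
  )
  if (n > nrow(slots))
    stop("too many cells for the fixed layout grid", call. = FALSE)
  data.frame(
    x = slots$x[seq_len(n)] + stats::runif(n, -jitter, jitter),
    y = slots$y[seq_len(n)] + stats::runif(n, -jitter, jitter),
    a = axis_a * stats::runif(n, 0.9, 1.1),
    b = axis_b * stats::runif(n, 0.9, 1.1),
    angle = stats::runif(n, 0, 180)
  )
}
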