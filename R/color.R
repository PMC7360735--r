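# Color-space handling: flat-field background correction and the RGB <-> HSB
# conversions the hue analysis rests on.

#' Flat-field background correction
#'
#' Removes inhomogeneous illumination and sensor response from a bright-field
#' specimen image using a calibration pair: an open-light-path frame `bright`
#' (no specimen) and a blocked-light-path frame `dark`. Per pixel and channel,
#'
#' \deqn{I_c = 255 (I_s - I_d) / (I_b - I_d)}
#'
#' computed in floating point and clipped to `[0, 255]`. Pixels whose
#' calibration difference `I_b - I_d` does not exceed `eps` are degenerate:
#' they are set to 0 and counted in attribute `n_degenerate`; a warning is
#' issued when more than 1 percent of pixels are degenerate.
#'
#' @param specimen raw specimen image, a height x width x 3 array in
#'   `[0, 255]`.
#' @param bright open-light-path calibration frame, same dimensions.
#' @param dark blocked-light-path calibration frame, same dimensions.
#' @param eps positive tolerance below which the calibration difference is
#'   treated as degenerate.
#' @return the corrected image as a floating-point array in `[0, 255]`, with
#'   attribute `n_degenerate` (number of pixels with any degenerate channel).
#' @examples
#' s <- array(120, c(2, 2, 3)); d <- array(20, c(2, 2, 3)); b <- array(220, c(2, 2, 3))
#' correct_background(s, b, d)[1, 1, 1]  # 255 * 100 / 200 = 127.5
#' @export
correct_background <- function(specimen, bright, dark, eps = 1e-6) {
  check_rgb_image(specimen)
  if (!identical(dim(specimen), dim(bright)) || !identical(dim(specimen), dim(dark)))
    stop("specimen and calibration frames must have identical dimensions", call. = FALSE)
  denom <- bright - dark
  degenerate <- denom <= eps
  denom[degenerate] <- 1  # placeholder; result overwritten below
  out <- 255 * (specimen - dark) / denom
  out[degenerate] <- 0
  d <- dim(out)
  out <- pmin.int(pmax.int(out, 0), 255)
  dim(out) <- d
  n_deg <- sum(rowSums(matrix(degenerate, ncol = 3L)) > 0)
  if (n_deg > 0.01 * prod(d[1:2]))
    warning(sprintf("%d of %d pixels have degenerate calibration (I_b - I_d <= eps)",
                    n_deg, prod(d[1:2])), call. = FALSE)
  attr(out, "n_degenerate") <- n_deg
  out
}

#' Convert an RGB image to hue-saturation-brightness
#'
#' Standard hexcone conversion (via [grDevices::rgb2hsv()]): hue in degrees
#' `[0, 360)`, saturation `(max - min) / max` in `[0, 1]` (0 when the maximum
#' channel is 0), brightness `max / 255`. Achromatic pixels (S = 0) get hue 0
#' by convention; they are later removed by the saturation filter.
#'
#' @param img a height x width x 3 array in `[0, 255]`.
#' @return an object of class `hsb_image`: a list of matrices `h` (degrees),
#'   `s` and `b` (unit scale), each height x width.
#' @examples
#' img <- array(c(64, 0, 128), c(1, 1, 3))
#' rgb_to_hsb(img)$h  # 270
#' @export
rgb_to_hsb <- function(img) {
  check_rgb_image(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(h = shape(hsv[1, ] * 360), s = shape(hsv[2, ]), b = shape(hsv[3, ])),
            class = "hsb_image")
}

#' Construct an HSB image from component matrices
#'
#' @param h hue matrix in degrees `[0, 360)`.
#' @param s saturation matrix in `[0, 1]`.
#' @param b brightness matrix in `[0, 1]`.
#' @return an `hsb_image`.
#' @export
hsb_image <- function(h, s, b) {
  stopifnot(identical(dim(h), dim(s)), identical(dim(h), dim(b)))
  if (min(s) < 0 || max(s) > 1 || min(b) < 0 || max(b) > 1)
    stop("saturation and brightness must lie in [0, 1]", call. = FALSE)
  structure(list(h = h %% 360, s = s, b = b), class = "hsb_image")
}

#' @export
print.hsb_image <- function(x, ...) {
  cat(sprintf("HSB image, %d x %d pixels; hue range [%.1f, %.1f] deg\n",
              nrow(x$h), ncol(x$h), min(x$h), max(x$h)))
  invisible(x)
}

#' Convert HSB values to RGB intensities
#'
#' Inverse hexcone transform, vectorized over pixels. Used by the scene
#' renderer; returned intensities are floating point in `[0, 255]` (not yet
#' quantized).
#'
#' @param h hue in degrees.
#' @param s saturation in `[0, 1]`.
#' @param b brightness in `[0, 1]`.
#' @return a length(h) x 3 matrix of intensities in `[0, 255]`.
#' @export
hsb_to_rgb <- function(h, s, b) {
  stopifnot(length(h) == length(s), length(h) == length(b))
  h6 <- (h %% 360) / 60
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- b * (1 - s)
  q <- b * (1 - s * f)
  t <- b * (1 - s * (1 - f))
  r <- g <- bl <- numeric(length(h))
  pick <- function(k, rr, gg, bb) {
    m <- i == k
    r[m] <<- rr[m]; g[m] <<- gg[m]; bl[m] <<- bb[m]
  }
  pick(0, b, t, p); pick(1, q, b, p); pick(2, p, b, t)
  pick(3, p, q, b); pick(4, t, p, b); pick(5, b, p, q)
  cbind(r = r, g = g, b = bl) * 255
}
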