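# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user RNG flow.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 8-bit quantization: round half away from zero, then clip to [0, 255].
# Dimensions are preserved (pmin/pmax with a scalar first would drop them).
quantize8 <- function(x) {
  d <- dim(x)
  y <- trunc(abs(x) + 0.5) * sign(x)
  y <- pmin.int(pmax.int(y, 0), 255)
  dim(y) <- d
  y
}

check_rgb_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be a height x width x 3 array", arg), call. = FALSE)
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must hold intensities in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x)) &&
    all(is.finite(x)) && min(x) >= 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
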