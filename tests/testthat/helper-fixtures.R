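# Shared fixtures, all generated in code.

# A small scene with well-separated cells on a 4-slot grid.
demo_cells <- function(p_pas = c(0.05, 0.2, 0.5, 0.8), size = 512,
                       a = 60, b = 52) {
  n <- length(p_pas)
  slots <- expand.grid(x = c(0.27, 0.73) * size, y = c(0.27, 0.73) * size)
  data.frame(x = slots$x[seq_len(n)], y = slots$y[seq_len(n)],
             a = a, b = b, angle = seq(0, 150, length.out = n), p_pas = p_pas)
}

# An HSB image holding given hue values at given saturation/brightness, as a
# single row; handy for exact histogram counting.
hsb_strip <- function(hues, s = 0.5, b = 0.5) {
  n <- length(hues)
  hsb_image(matrix(hues, 1, n), matrix(s, 1, n), matrix(b, 1, n))
}

# Construct a raw vector with exactly the requested sample mean and SD.
vector_with_moments <- function(mean, sd, n) {
  base <- seq_len(n)
  z <- (base - mean(base)) / stats::sd(base)
  mean + sd * z
}

# One-sided (greater) Fisher p by explicit enumeration over all tables with
# the observed margins, using only choose() arithmetic: independent of
# stats::fisher.test and of the d/phyper functions.
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  K <- a + b          # row-1 margin
  n1 <- a + c         # column-1 margin
  ks <- max(0, K + n1 - N):min(K, n1)
  probs <- choose(K, ks) * choose(N - K, n1 - ks) / choose(N, n1)
  sum(probs[ks >= a])
}
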