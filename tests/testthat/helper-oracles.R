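# Independent O(n^2) tau-b oracle: explicit pair enumeration, tied pairs
# counted per variable. Kept deliberately naive and separate from the
# package implementation.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx != 0 && dy != 0) {
      if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}
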