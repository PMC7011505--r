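# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# Independent Krawtchouk polynomial evaluation straight from the
# hypergeometric series (never via the package's coefficient expansion).
K_series <- function(n, x, p, N) {
  out <- numeric(length(x))
  for (ix in seq_along(x)) {
    tot <- 0
    for (s in 0:n) {
      poch_n <- if (s == 0) 1 else prod(-n + 0:(s - 1))
      poch_x <- if (s == 0) 1 else prod(-x[ix] + 0:(s - 1))
      poch_N <- if (s == 0) 1 else prod(-N + 0:(s - 1))
      tot <- tot + poch_n * poch_x / (poch_N * factorial(s)) * p^(-s)
    }
    out[ix] <- tot
  }
  out
}

# Naive double-loop geometric moments (oracle for the separable path).
moments_naive <- function(g, i, j) {
  tot <- 0
  for (x in 0:(nrow(g) - 1)) for (y in 0:(ncol(g) - 1))
    tot <- tot + x^i * y^j * g[x + 1, y + 1]
  tot
}

# A deterministic asymmetric test blob: sum of two unequal Gaussians,
# scaled to a 0..255-ish range. Centre (cx, cy) in 0-based coordinates.
test_blob <- function(S, cx, cy, width = S / 10) {
  xs <- 0:(S - 1)
  g1 <- outer(exp(-(xs - cx)^2 / (2 * width^2)),
              exp(-(xs - cy)^2 / (2 * width^2)))
  g2 <- outer(exp(-(xs - cx - width)^2 / (2 * (width / 2)^2)),
              exp(-(xs - cy + width)^2 / (2 * (width / 2)^2)))
  200 * g1 + 120 * g2
}

# Dark-on-white frame with an icon's pixels at its centre (query
# geometry used throughout the benchmark).
frame_icon <- function(px, S) {
  size <- nrow(px)
  pad <- (S - size) %/% 2
  fr <- matrix(255, S, S)
  fr[(pad + 1):(pad + size), (pad + 1):(pad + size)] <- px
  fr
}

# 90-degree counter-clockwise rotation of a matrix in the package's
# row/column convention: (x, y) -> (y, S-1-x); lossless.
rot90_ccw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

rel_err <- function(a, b, floor = 1e-12) abs(a - b) / pmax(abs(b), floor)
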