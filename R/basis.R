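# Krawtchouk polynomial machinery: binomial weights, squared norms,
# monomial-expansion coefficients and the 2D central weight envelope.
# All binomial quantities go through log-gamma so that grids of a few
# hundred pixels (C(149, 74) and friends) do not overflow.

#' Maximum polynomial order used by the descriptor
#'
#' The descriptor uses Krawtchouk moments of order up to 3 in each
#' dimension; kept as a single constant to ease extension.
#' @keywords internal
KD_MAX_ORDER <- 3L

#' Binomial weight function
#'
#' The weight \eqn{w(x; p, N) = \binom{N}{x} p^x (1-p)^{N-x}} with respect
#' to which the Krawtchouk polynomials are orthogonal on \eqn{\{0, \dots, N\}}.
#' Evaluated in log space.
#'
#' @param x Integer vector of evaluation points, each in `0..N`.
#' @param p Success probability in (0, 1).
#' @param N Upper end of the discrete support.
#' @return Numeric vector of weights; `sum(binomial_weight(0:N, p, N))` is 1.
#' @examples
#' binomial_weight(0:4, 0.5, 4)  # 1/16, 4/16, 6/16, 4/16, 1/16
#' @export
binomial_weight <- function(x, p, N) {
  stopifnot(length(p) == 1L, length(N) == 1L, p > 0, p < 1, N >= 0)
  if (any(x < 0 | x > N | x != round(x)))
    stop("x must be integers in 0..N", call. = FALSE)
  exp(lchoose(N, x) + x * log(p) + (N - x) * log1p(-p))
}

#' Squared norm of a Krawtchouk polynomial
#'
#' \eqn{\rho(n; p, N) = (-1)^n \left(\frac{1-p}{p}\right)^n \frac{n!}{(-N)_n}}
#' where \eqn{(-N)_n} is the rising product \eqn{(-N)(-N+1)\cdots(-N+n-1)}.
#' At \eqn{p = 0.5} this reduces to \eqn{n! (N-n)! / N!}.
#'
#' @param n Polynomial order (0..N).
#' @inheritParams binomial_weight
#' @return The squared norm, a positive scalar.
#' @export
krawtchouk_norm <- function(n, p, N) {
  stopifnot(length(n) == 1L, n == round(n), n >= 0)
  if (n > N) stop("order n must not exceed N", call. = FALSE)
  if (n == 0L) return(1)
  poch <- prod(-N + seq_len(n) - 1)          # (-N)(-N+1)...(-N+n-1)
  (-1)^n * ((1 - p) / p)^n * factorial(n) / poch
}

#' Monomial coefficients of a Krawtchouk polynomial
#'
#' Expands \eqn{K_n(x; p, N) = \sum_{s=0}^{n} \frac{(-n)_s (-x)_s}{(-N)_s s!}
#' p^{-s}} into powers of \eqn{x}, returning the coefficients
#' \eqn{a_{i,n,p,N}} with \eqn{K_n(x) = \sum_i a_i x^i}. The falling factors
#' \eqn{(-x)_s} are expanded by iterated polynomial multiplication.
#'
#' @param n Polynomial order (0..3 in this package).
#' @inheritParams binomial_weight
#' @return Numeric vector of length `n + 1`, constant term first.
#' @examples
#' krawtchouk_coeffs(1, 0.5, 10)   # c(1, -0.2): K_1(x) = 1 - 2x/N
#' @export
krawtchouk_coeffs <- function(n, p, N) {
  stopifnot(length(n) == 1L, n == round(n), n >= 0, n <= N)
  coef <- numeric(n + 1)
  fall <- 1                                   # coefficients of (-x)_s in x
  pref <- 1                                   # (-n)_s / ((-N)_s s!) * p^-s
  coef[1] <- 1
  if (n == 0L) return(coef)
  for (s in seq_len(n)) {
    # (-x)_{s} = (-x)_{s-1} * (-x + s - 1)
    fall <- c(fall, 0) * (s - 1) + c(0, -fall)
    pref <- pref * (-n + s - 1) / ((-N + s - 1) * s) / p
    coef[seq_len(s + 1)] <- coef[seq_len(s + 1)] + pref * fall
  }
  coef
}

#' Evaluate a Krawtchouk polynomial from its monomial coefficients
#' @param coef Coefficient vector, constant term first.
#' @param x Evaluation points (any reals).
#' @return `sum_i coef[i+1] * x^i`, vectorized over `x`.
#' @keywords internal
eval_poly <- function(coef, x) {
  out <- 0
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

#' Central 2D weight envelope
#'
#' The separable envelope \eqn{W_c(x, y) = \sqrt{w(x; 0.5, S-1)\,
#' w(y; 0.5, S-1)}} centred on an \eqn{S \times S} grid. The square-root
#' form makes the descriptor equal to a weighted Krawtchouk moment
#' \eqn{\sum \bar K_n(x) \bar K_m(y) f(x, y)} with
#' \eqn{\bar K_n = K_n \sqrt{w / \rho}}; the squared entries sum to 1.
#'
#' @param S Grid size in pixels (at least 8).
#' @return An `S x S` matrix, symmetric about the grid centre.
#' @export
central_weight <- function(S) {
  stopifnot(length(S) == 1L, S == round(S), S >= 2)
  sw <- sqrt(binomial_weight(0:(S - 1), 0.5, S - 1))
  outer(sw, sw)
}

#' Precompute basis constants for a window size
#'
#' Bundles, for a working window of `S` pixels, the squared norms
#' \eqn{\rho(n; 0.5, S-1)}, the monomial coefficients
#' \eqn{a_{i,n,0.5,S-1}} of \eqn{K_n} for n = 0..3, and the central 2D
#' weight envelope. A pure function of `S`; compute once and reuse for
#' every point-of-interest at that window size.
#'
#' @param S Window size in pixels; must be at least 8 so that order-3
#'   moments are meaningful.
#' @return An object of class `kd2d_basis` with fields `S`, `p`, `rho`
#'   (length 4), `coeffs` (list of 4 coefficient vectors), `A` (4x4
#'   lower-triangular coefficient matrix, `A[n+1, i+1] = a_{i,n}`) and
#'   `Wc` (the `S x S` envelope).
#' @examples
#' const <- prep_step(40)
#' const$rho[2]   # 1/39
#' @export
prep_step <- function(S) {
  stopifnot(length(S) == 1L, S == round(S))
  if (S < 8) stop("window size S must be at least 8", call. = FALSE)
  S <- as.integer(S)
  N <- S - 1L
  ord <- KD_MAX_ORDER
  rho <- vapply(0:ord, krawtchouk_norm, numeric(1), p = 0.5, N = N)
  coeffs <- lapply(0:ord, krawtchouk_coeffs, p = 0.5, N = N)
  A <- matrix(0, ord + 1L, ord + 1L)
  for (n in 0:ord) A[n + 1L, seq_len(n + 1L)] <- coeffs[[n + 1L]]
  structure(
    list(S = S, p = 0.5, rho = rho, coeffs = coeffs, A = A,
         Wc = central_weight(S)),
    class = "kd2d_basis")
}

#' @export
print.kd2d_basis <- function(x, ...) {
  cat(sprintf("Krawtchouk basis constants: S = %d, p = %.1f, orders 0..%d\n",
              x$S, x$p, length(x$rho) - 1L))
  cat("rho:", format(x$rho, digits = 6), "\n")
  invisible(x)
}
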