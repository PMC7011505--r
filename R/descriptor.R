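# Assembly of the six-component descriptor for a point-of-interest:
# shift the central weight envelope to the POI, weight the window,
# compute the invariant moments, and project them onto the Krawtchouk
# coefficient expansion.

#' Shift the central weight envelope to a point-of-interest
#'
#' Translates the central envelope so its peak sits on the window
#' coordinates `(x_s, y_s)`: \eqn{W_s(x, y) = W_c(x^*, y^*)} where
#' \eqn{x^* = x - x_s + (S-1)/2}, \eqn{y^* = y - y_s + (S-1)/2} map the
#' POI back to the envelope centre, rounded to the nearest grid point
#' (ties upward); positions falling outside the grid are 0, so an
#' envelope shifted toward a corner loses the three quadrants of its
#' support that fall off-grid.
#'
#' @param Wc `S x S` central weight matrix (see [central_weight()]).
#' @param x_s,y_s POI in 0-based window coordinates.
#' @return `S x S` shifted weight matrix.
#' @export
shift_weight <- function(Wc, x_s, y_s) {
  stopifnot(is.matrix(Wc), nrow(Wc) == ncol(Wc))
  S <- nrow(Wc)
  if (x_s < 0 || x_s > S - 1 || y_s < 0 || y_s > S - 1)
    stop("POI must lie inside the window", call. = FALSE)
  # integer translation of the envelope towards the POI; for even S the
  # ideal shift is a half-integer and ties round down, which keeps the
  # unshifted envelope for a central POI (x_s = S/2) instead of moving
  # its peak past the POI
  dx <- ceiling(x_s - (S - 1) / 2 - 0.5)
  dy <- ceiling(y_s - (S - 1) / 2 - 0.5)
  Ws <- matrix(0, S, S)
  xs <- 0:(S - 1); src_x <- xs - dx
  ys <- 0:(S - 1); src_y <- ys - dy
  okx <- src_x >= 0 & src_x <= S - 1
  oky <- src_y >= 0 & src_y <= S - 1
  Ws[okx, oky] <- Wc[src_x[okx] + 1L, src_y[oky] + 1L]
  Ws
}

#' Auxiliary (weighted) image
#'
#' Elementwise product \eqn{\tilde f(x, y) = f_s(x, y) \cdot W_s(x, y)}:
#' the envelope localizes the moment computation around the POI and
#' suppresses pixels far from it.
#'
#' @param f_s `S x S` density matrix or [density_image()].
#' @param W_s `S x S` shifted weight from [shift_weight()].
#' @return `S x S` matrix.
#' @export
auxiliary_image <- function(f_s, W_s) {
  if (inherits(f_s, "kd2d_image")) f_s <- f_s$pixels
  if (!identical(dim(f_s), dim(W_s)))
    stop("image window and weight grid have different shapes", call. = FALSE)
  f_s * W_s
}

#' Compute the six-component Krawtchouk descriptor of a window
#'
#' Runs the full descriptor pipeline on an `S x S` window around the POI
#' `(x_s, y_s)`: shift the weight envelope, form the auxiliary image,
#' compute its invariant moments \eqn{\lambda_{ij}}, and combine them
#' through the Krawtchouk coefficient expansion
#' \deqn{Q_{nm} = [\rho(n)\rho(m)]^{-1/2} \sum_{i=0}^{n}\sum_{j=0}^{m}
#'   a_{i,n}\, a_{j,m}\, \lambda_{ij}}
#' for n, m = 0..3. The four lowest-order components
#' \eqn{Q_{00}, Q_{01}, Q_{10}, Q_{11}} are constants irrespective of the
#' region (a consequence of the moment normalization) and are discarded;
#' the descriptor is the 6-vector
#' \eqn{V = [Q_{20}, Q_{02}, Q_{12}, Q_{21}, Q_{30}, Q_{03}]}.
#'
#' @param f_s `S x S` window ([density_image()] or matrix).
#' @param x_s,y_s POI in 0-based window coordinates (integers; fractional
#'   values are rounded on entry).
#' @param const Basis constants from [prep_step()] for the same `S`.
#' @param beta Reference mass threaded into [geometric_invariants()];
#'   must be identical for index and query. Default `S^2 / 12`.
#' @param image_id,x_p,y_p Provenance recorded in the descriptor; `x_p`,
#'   `y_p` default to the window coordinates.
#' @return A `kd2d_descriptor`: list with `V` (named length-6 vector in
#'   the order above), `Q` (the full 4x4 moment matrix, kept for
#'   diagnostics), `image_id`, `x_p`, `y_p`, `S`, `beta`.
#' @section Errors: a blank window raises a `kd2d_degenerate` error; POIs
#'   on empty background are reported unusable, never silently zeroed.
#' @export
comp_desc <- function(f_s, x_s, y_s, const, beta = const$S^2 / 12,
                      image_id = NULL, x_p = x_s, y_p = y_s) {
  stopifnot(inherits(const, "kd2d_basis"))
  if (inherits(f_s, "kd2d_image")) {
    if (is.null(image_id)) image_id <- f_s$image_id
    f_s <- f_s$pixels
  }
  if (is.null(image_id)) image_id <- "window"
  if (!identical(dim(f_s), dim(const$Wc)))
    stop("window size does not match the basis constants", call. = FALSE)
  x_s <- round(x_s); y_s <- round(y_s)
  Ws <- shift_weight(const$Wc, x_s, y_s)
  ft <- auxiliary_image(f_s, Ws)
  inv <- geometric_invariants(ft, beta = beta)
  R <- diag(1 / sqrt(const$rho))
  Q <- R %*% const$A %*% inv$lam %*% t(const$A) %*% R
  dimnames(Q) <- list(paste0("n", 0:KD_MAX_ORDER), paste0("m", 0:KD_MAX_ORDER))
  V <- c(Q20 = Q[3, 1], Q02 = Q[1, 3], Q12 = Q[2, 3],
         Q21 = Q[3, 2], Q30 = Q[4, 1], Q03 = Q[1, 4])
  structure(list(V = V, Q = Q, image_id = image_id,
                 x_p = x_p, y_p = y_p, S = const$S, beta = beta),
            class = "kd2d_descriptor")
}

#' @export
print.kd2d_descriptor <- function(x, ...) {
  cat(sprintf("2D Krawtchouk descriptor of '%s' at (%d, %d), S = %d:\n",
              x$image_id, x$x_p, x$y_p, x$S))
  cat(sprintf("  V = %s\n", paste(sprintf("%.8f", x$V), collapse = " ")))
  invisible(x)
}

#' Describe a point-of-interest in an image
#'
#' Convenience wrapper running read -> crop -> describe for one POI.
#'
#' @param image A [density_image()] or a path to an image file.
#' @param x_p,y_p POI in 0-based image coordinates.
#' @param S Window size; defaults to `min(N, M)` of the image.
#' @param beta Reference mass (see [comp_desc()]).
#' @return A `kd2d_descriptor`.
#' @examples
#' icons <- make_icons(2, 60, seed = 1)
#' describe_poi(icons[[1]], 30, 30, S = 60)
#' @export
describe_poi <- function(image, x_p, y_p, S = NULL, beta = NULL) {
  if (is.character(image)) image <- read_image(image)$image
  stopifnot(inherits(image, "kd2d_image"))
  if (is.null(S)) S <- min(image$N, image$M)
  if (is.null(beta)) beta <- S^2 / 12
  const <- prep_step(S)
  cr <- square_crop(image, x_p, y_p, S)
  comp_desc(cr$window, cr$x_s, cr$y_s, const, beta = beta,
            image_id = image$image_id, x_p = round(x_p), y_p = round(y_p))
}
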