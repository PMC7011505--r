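# Geometric moments, principal-axis angle and the translation / rotation /
# scale invariant moments lambda_ij of the weighted auxiliary image.
#
# The invariants are built by moment normalization: translate coordinates
# to the centre of mass, rotate by the principal angle, rescale so the
# region carries a fixed reference mass beta, and re-centre on the grid
# centre c = (S-1)/2. The first invariants are then constants by
# construction (lambda_00 = beta, lambda_10 = lambda_01 = beta*c,
# lambda_11 = beta*c^2), which is exactly why the four lowest-order
# descriptors carry no information and are discarded.

#' Geometric moments of a grid
#'
#' Raw monomial moments \eqn{M_{ij} = \sum_x \sum_y x^i y^j g(x, y)} over
#' the 0-based pixel grid, for all `i + j <= max_order`, computed by
#' separable accumulation.
#'
#' @param g Numeric matrix (densities; need not be nonnegative).
#' @param max_order Largest total order `i + j` to return.
#' @return Matrix `m` with `m[i+1, j+1]` = \eqn{M_{ij}}; entries with
#'   `i + j > max_order` are `NA`.
#' @export
geometric_moments <- function(g, max_order = 3L) {
  stopifnot(is.matrix(g), is.numeric(g), all(is.finite(g)))
  xs <- 0:(nrow(g) - 1L); ys <- 0:(ncol(g) - 1L)
  xp <- vapply(0:max_order, function(i) xs^i, numeric(nrow(g)))
  yp <- vapply(0:max_order, function(j) ys^j, numeric(ncol(g)))
  m <- t(xp) %*% g %*% yp
  m[outer(0:max_order, 0:max_order, "+") > max_order] <- NA_real_
  dimnames(m) <- list(paste0("i", 0:max_order), paste0("j", 0:max_order))
  m
}

#' Centre of mass and central moments
#'
#' Computes the raw moments up to order 1, the centre of mass, and the
#' central moments of order 2 and 3 used for the principal angle and its
#' disambiguation.
#'
#' @param g Numeric matrix of nonnegative densities.
#' @return A `kd2d_moments` object: `M00`, `M10`, `M01`, `xc`, `yc`,
#'   `mu20`, `mu02`, `mu11`, `mu30`, `mu21`, `mu12`, `mu03`, `S`.
#' @section Degenerate regions: a region whose total mass is below
#'   `1e-12 * S^2 * 255` (an essentially blank window) raises an error of
#'   class `kd2d_degenerate` rather than producing NaN descriptors.
#' @export
central_moments <- function(g) {
  stopifnot(is.matrix(g), is.numeric(g), all(is.finite(g)))
  S <- nrow(g)
  M00 <- sum(g)
  if (M00 <= 1e-12 * length(g) * 255)
    stop(structure(class = c("kd2d_degenerate", "error", "condition"),
                   list(message = "blank region of interest (total mass ~ 0)",
                        call = sys.call(-1))))
  xs <- 0:(nrow(g) - 1L); ys <- 0:(ncol(g) - 1L)
  rowmass <- rowSums(g); colmass <- colSums(g)
  M10 <- sum(xs * rowmass); M01 <- sum(ys * colmass)
  xc <- M10 / M00; yc <- M01 / M00
  dx <- xs - xc; dy <- ys - yc
  xp <- cbind(1, dx, dx^2, dx^3)
  yp <- cbind(1, dy, dy^2, dy^3)
  mu <- t(xp) %*% g %*% yp
  structure(list(M00 = M00, M10 = M10, M01 = M01, xc = xc, yc = yc,
                 mu20 = mu[3, 1], mu02 = mu[1, 3], mu11 = mu[2, 2],
                 mu30 = mu[4, 1], mu21 = mu[3, 2], mu12 = mu[2, 3],
                 mu03 = mu[1, 4], S = S),
            class = "kd2d_moments")
}

# Second/third central moments after rotating coordinates by -theta,
# i.e. in the frame u = c*dx + s*dy, v = -s*dx + c*dy.
rotated_moments <- function(ms, theta) {
  cc <- cos(theta); ss <- sin(theta)
  list(
    mu20 = cc^2 * ms$mu20 + 2 * cc * ss * ms$mu11 + ss^2 * ms$mu02,
    mu02 = ss^2 * ms$mu20 - 2 * cc * ss * ms$mu11 + cc^2 * ms$mu02,
    mu30 = cc^3 * ms$mu30 + 3 * cc^2 * ss * ms$mu21 +
           3 * cc * ss^2 * ms$mu12 + ss^3 * ms$mu03,
    mu03 = -ss^3 * ms$mu30 + 3 * ss^2 * cc * ms$mu21 -
           3 * ss * cc^2 * ms$mu12 + cc^3 * ms$mu03)
}

#' Principal-axis angle of a region
#'
#' The base angle is \eqn{\theta_0 = \tfrac{1}{2}\,\mathrm{atan2}(2\mu_{11},
#' \mu_{20} - \mu_{02})}, which is only defined modulo \eqn{\pi/2} for the
#' purpose of diagonalizing the second-moment tensor. The returned angle
#' is the unique representative among \eqn{\theta_0 + k\pi/2} (mapped to
#' \eqn{(-\pi, \pi]}) such that, in the rotated frame, (a) the spread
#' along the first axis dominates (\eqn{\mu'_{20} \ge \mu'_{02}}) and (b)
#' the dominant third-order skewness is nonnegative: the sign condition
#' is applied to whichever of \eqn{\mu'_{30}}, \eqn{\mu'_{03}} has the
#' larger magnitude, so a pattern whose skewness lies along the minor
#' axis (where \eqn{\mu'_{30}} vanishes by symmetry and carries only
#' resampling noise) is still oriented deterministically. If both third
#' moments vanish the smallest-magnitude candidate is returned.
#' Rotationally ambiguous regions (isotropic second moments) return 0
#' with `ambiguous = TRUE`.
#'
#' @param ms A `kd2d_moments` object (with third-order moments).
#' @return List with `theta` (radians, in \eqn{(-\pi, \pi]}) and
#'   `ambiguous`.
#' @export
principal_angle <- function(ms) {
  stopifnot(inherits(ms, "kd2d_moments"))
  tol2 <- 1e-9 * ms$M00 * ms$S^2
  tol3 <- 1e-9 * ms$M00 * ms$S^3
  if (abs(ms$mu11) <= tol2 && abs(ms$mu20 - ms$mu02) <= tol2) {
    # isotropic second moments: no principal axis; third moments could in
    # principle orient, but such regions are treated as symmetric.
    return(list(theta = 0, ambiguous = TRUE))
  }
  theta0 <- 0.5 * atan2(2 * ms$mu11, ms$mu20 - ms$mu02)
  cand <- theta0 + c(0, 0.5, 1, 1.5) * pi
  cand <- ((cand + pi) %% (2 * pi)) - pi        # to (-pi, pi]
  cand[cand == -pi] <- pi
  rot <- lapply(cand, rotated_moments, ms = ms)
  major <- vapply(rot, function(r) r$mu20 - r$mu02, numeric(1)) >= -tol2
  cand <- cand[major]; rot <- rot[major]
  mu30 <- vapply(rot, `[[`, numeric(1), "mu30")
  mu03 <- vapply(rot, `[[`, numeric(1), "mu03")
  # orient by the dominant skewness; both flip sign under theta + pi, so
  # any magnitude-priority rule selects a unique representative
  use30 <- max(abs(mu30)) >= max(abs(mu03))
  dec <- if (use30) mu30 else mu03
  pick <- if (any(abs(dec) > tol3)) which(dec >= 0) else integer(0)
  i <- if (length(pick)) pick[which.min(abs(cand[pick]))]
       else which.min(abs(cand))
  list(theta = cand[i], ambiguous = FALSE)
}

#' Translation/rotation/scale-invariant moments of a region
#'
#' Normalizes the region by moving the centre of mass to the grid centre
#' \eqn{c = (S-1)/2}, rotating by the principal angle, and scaling
#' coordinates by \eqn{\gamma = \sqrt{\beta / M_{00}}} so that the region
#' carries reference mass \eqn{\beta}:
#' \deqn{u = \gamma[(x - \bar x)\cos\theta + (y - \bar y)\sin\theta] + c}
#' \deqn{v = \gamma[-(x - \bar x)\sin\theta + (y - \bar y)\cos\theta] + c}
#' \deqn{\lambda_{ij} = \frac{\beta}{M_{00}} \sum_{x,y} g(x,y)\, u^i v^j.}
#'
#' By construction \eqn{\lambda_{00} = \beta},
#' \eqn{\lambda_{10} = \lambda_{01} = \beta c} and
#' \eqn{\lambda_{11} = \beta c^2} (the rotated product moment vanishes on
#' the principal axes).
#'
#' @param g Numeric matrix (the auxiliary image).
#' @param ms Moments of `g` from [central_moments()]; computed if `NULL`.
#' @param beta Reference mass; must be shared between index and query.
#'   Defaults to `S^2 / 12`.
#' @return A `kd2d_invariants` object: `lam` (4x4 matrix, `lam[i+1, j+1]`
#'   = \eqn{\lambda_{ij}}), `beta`, `gamma`, `theta`, `ambiguous`.
#' @export
geometric_invariants <- function(g, ms = NULL, beta = nrow(g)^2 / 12) {
  stopifnot(is.matrix(g), nrow(g) == ncol(g), beta > 0)
  S <- nrow(g)
  if (is.null(ms)) ms <- central_moments(g)
  ang <- principal_angle(ms)
  gamma <- sqrt(beta / ms$M00)
  cc <- cos(ang$theta); ss <- sin(ang$theta)
  ctr <- (S - 1) / 2
  dx <- (0:(S - 1)) - ms$xc
  dy <- (0:(S - 1)) - ms$yc
  U <- gamma * (outer(dx, dy, function(a, b) a * cc + b * ss))
  V <- gamma * (outer(dx, dy, function(a, b) -a * ss + b * cc))
  ord <- KD_MAX_ORDER
  # centred-rotated-scaled moments m_pq; m00 = beta, m10 = m01 = 0 and
  # m11 = 0 hold analytically (mass normalization, centre of mass,
  # principal-axis rotation) and are enforced exactly so the constant
  # low-order descriptors are constant in floating point too
  scale <- beta / ms$M00
  Upow <- list(matrix(1, S, S)); Vpow <- list(matrix(1, S, S))
  for (k in seq_len(ord)) {
    Upow[[k + 1L]] <- Upow[[k]] * U
    Vpow[[k + 1L]] <- Vpow[[k]] * V
  }
  m <- matrix(0, ord + 1L, ord + 1L)
  for (p in 0:ord) for (q in 0:ord)
    m[p + 1L, q + 1L] <- scale * sum(g * Upow[[p + 1L]] * Vpow[[q + 1L]])
  m[1, 1] <- beta
  m[2, 1] <- 0; m[1, 2] <- 0; m[2, 2] <- 0
  # shift to grid coordinates u = U + c, v = V + c by exact binomial
  # expansion: lambda_ij = sum_pq C(i,p) C(j,q) c^(i-p+j-q) m_pq
  lam <- matrix(0, ord + 1L, ord + 1L,
                dimnames = list(paste0("i", 0:ord), paste0("j", 0:ord)))
  for (i in 0:ord) for (j in 0:ord) {
    tot <- 0
    for (p in 0:i) for (q in 0:j)
      tot <- tot + choose(i, p) * choose(j, q) *
        ctr^(i - p + j - q) * m[p + 1L, q + 1L]
    lam[i + 1L, j + 1L] <- tot
  }
  structure(list(lam = lam, beta = beta, gamma = gamma,
                 theta = ang$theta, ambiguous = ang$ambiguous),
            class = "kd2d_invariants")
}
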