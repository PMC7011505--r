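# Synthetic benchmark generator: deterministic gray-scale icons, their
# rotated and scaled copies placed at random on large canvases, ground
# truth for scoring, and salt-and-pepper degradation. This replicates
# the logic of a clip-art retrieval experiment (9 icons x 12 rotations
# x 3 scales = 324 subimages on four 600x600 canvases) with generated,
# redistributable icons.
#
# Polarity: icons are dark ink on a bright (255) background, emulating
# gray-scale clip art on a white canvas. The ink mask is what gets
# rotated/scaled (with zero fill, so rotated tiles acquire no dark
# corners) and is then composited subtractively onto the canvas.
# Queries share the same polarity; the descriptor never inverts images.
#
# Resampling (bilinear rotation/scaling) lives only here, fixture-side;
# the descriptor path never resamples pixels.

#' Benchmark dataset specification
#'
#' Defaults replicate the reference protocol: 9 icons, rotations 0,30,
#' ...,330 degrees, scales 0.8/0.9/1.0, 81 slot centres (a 9x9 grid) on
#' each of four 600x600 canvases, icons of 60x60 pixels, queries centred
#' in a 150x150 frame.
#'
#' @param n_icons Number of icon classes.
#' @param angles Rotation angles in degrees.
#' @param scales Scale factors.
#' @param canvas Canvas side length in pixels.
#' @param slots Placement slots per canvas (must be a perfect square).
#' @param n_canvases Number of canvases.
#' @param icon_size Icon side length in pixels.
#' @param frame Query frame side length in pixels.
#' @param seed RNG seed controlling icon jitter and slot assignment.
#' @return A `kd2d_dataset_spec` list.
#' @export
dataset_spec <- function(n_icons = 9L, angles = seq(0, 330, by = 30),
                         scales = c(0.8, 0.9, 1.0), canvas = 600L,
                         slots = 81L, n_canvases = 4L, icon_size = 60L,
                         frame = 150L, seed = 1L) {
  spec <- list(n_icons = as.integer(n_icons), angles = angles,
               scales = scales, canvas = as.integer(canvas),
               slots = as.integer(slots), n_canvases = as.integer(n_canvases),
               icon_size = as.integer(icon_size), frame = as.integer(frame),
               seed = as.integer(seed))
  if (spec$slots < spec$n_icons)
    stop("need at least as many slots as icon classes", call. = FALSE)
  n_sub <- spec$n_icons * length(spec$angles) * length(spec$scales)
  if (n_sub != spec$slots * spec$n_canvases)
    stop(sprintf(paste("icons x angles x scales (%d) must equal slots x",
                       "canvases (%d)"), n_sub, spec$slots * spec$n_canvases),
         call. = FALSE)
  structure(spec, class = "kd2d_dataset_spec")
}

# Bilinear pull-back of `icon` under scale-then-rotate about its centre:
# one resampling pass; source positions outside the icon contribute 0.
transform_icon <- function(icon, angle_deg, scale) {
  px <- if (inherits(icon, "kd2d_image")) icon$pixels else icon
  n <- nrow(px)
  ctr <- (n - 1) / 2
  th <- angle_deg * pi / 180
  cc <- cos(th); ss <- sin(th)
  ix <- rep(0:(n - 1), times = n) - ctr     # output row offsets
  iy <- rep(0:(n - 1), each = n) - ctr      # output col offsets
  # inverse map: rotate by -angle, then unscale
  sx <- (cc * ix + ss * iy) / scale + ctr
  sy <- (-ss * ix + cc * iy) / scale + ctr
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xi, yi) {
    ok <- xi >= 0 & xi <= n - 1 & yi >= 0 & yi <= n - 1
    out <- numeric(length(xi))
    out[ok] <- px[cbind(xi[ok] + 1L, yi[ok] + 1L)]
    out
  }
  v <- (1 - fx) * (1 - fy) * val(x0, y0) +
       fx * (1 - fy)       * val(x0 + 1, y0) +
       (1 - fx) * fy       * val(x0, y0 + 1) +
       fx * fy             * val(x0 + 1, y0 + 1)
  matrix(v, n, n)
}

# One deterministic icon ink mask (0 = background) drawn analytically
# on a size x size grid; `kind` cycles through distinct families, `jit`
# perturbs radii / widths so different seeds give different (but still
# separated) icons. All patterns keep their ink inside radius
# ~0.43*size so that any rotation stays inside the icon square.
#
# Families are chosen to be robustly normalizable by the descriptor's
# principal-axis convention: rotation-symmetric (the angle is moot),
# 180-degree-symmetric (the theta vs theta+pi choice cannot matter), or
# clearly elongated with strong skewness along the major axis (the
# third-moment sign rule is decided far from its tolerance).
draw_icon <- function(kind, size, jit) {
  ctr <- (size - 1) / 2
  x <- outer(0:(size - 1), rep(1, size)) - ctr
  y <- t(x)
  r <- sqrt(x^2 + y^2)
  a <- atan2(y, x)
  rmax <- 0.43 * size
  soft <- function(m) 255 * pmin(pmax(m, 0), 1)
  g <- switch(as.integer(kind),
    # 1: annulus
    soft((r < rmax * (0.85 + 0.1 * jit[1])) & (r > rmax * 0.45)),
    # 2: filled disk
    soft(r < rmax * (0.6 + 0.05 * jit[1])),
    # 3: plus / cross
    soft((abs(x) < rmax * (0.18 + 0.05 * jit[1]) | abs(y) < rmax * 0.18) &
         r < rmax),
    # 4: pie wedge
    soft(r < rmax & abs(((a + pi * jit[1]) + pi) %% (2 * pi) - pi) <
           (0.6 + 0.2 * jit[2])),
    # 5: three parallel bars clipped to the inscribed circle
    soft(r < rmax & (abs(y + rmax * 0.55) < rmax * 0.14 |
         abs(y) < rmax * (0.12 + 0.04 * jit[1]) |
         abs(y - rmax * 0.55) < rmax * 0.14)),
    # 6: bar with a blob at one end (exclamation-like: elongated with
    # strong skewness along the major axis)
    soft((abs(y) < rmax * (0.14 + 0.04 * jit[1]) & x > -rmax & x < rmax * 0.3) |
         sqrt((x - rmax * 0.62)^2 + y^2) < rmax * 0.3),
    # 7: two thick parallel bars (180-degree symmetric, elongated; no
    # central bar, unlike 5), clipped to the inscribed circle
    soft(abs(abs(y) - rmax * 0.45) < rmax * (0.22 + 0.04 * jit[1]) &
         r < rmax),
    # 8: cluster of unequal disks
    soft(sqrt((x - rmax * 0.45)^2 + (y - rmax * 0.2)^2) <
           rmax * (0.28 + 0.05 * jit[1]) |
         sqrt((x + rmax * 0.35)^2 + (y - rmax * 0.4)^2) < rmax * 0.2 |
         sqrt((x + rmax * 0.1)^2 + (y + rmax * 0.45)^2) < rmax * 0.33),
    # 9: radial gradient disk with a sector cut
    {
      m <- pmax(1 - r / rmax, 0)
      m[abs(a - pi / 4) < 0.35 + 0.1 * jit[1]] <- 0
      255 * m
    })
  g
}

#' Generate deterministic, mutually distinguishable icons
#'
#' Produces `n` gray-scale icon images (dark ink on a bright 255
#' background, like gray-scale clip art) whose ink stays inside the
#' inscribed circle, so rotated copies remain inside the icon square.
#' Icons are checked for descriptor separation: the distance between any
#' two distinct icons must exceed 10 times the distance between an icon
#' and its own 30-degree-rotated copy. If a seed violates the criterion
#' a fresh jitter is drawn, up to 5 attempts.
#'
#' @param n Number of icons (at least 2).
#' @param size Icon side length in pixels.
#' @param seed RNG seed; the output is a pure function of `(n, size,
#'   seed)`.
#' @return List of `n` [density_image()] objects named `icon1..iconN`.
#' @export
make_icons <- function(n = 9L, size = 60L, seed = 1L) {
  stopifnot(n >= 2, size >= 16)
  for (attempt in seq_len(5L)) {
    rng <- local({ set.seed(seed + 7919L * (attempt - 1L));
                   matrix(stats::runif(2 * n, -1, 1), ncol = 2) })
    icons <- lapply(seq_len(n), function(i)
      density_image(ink_to_image(draw_icon((i - 1L) %% 9L + 1L, size,
                                           rng[i, ])),
                    paste0("icon", i)))
    if (icons_separated(icons)) return(icons)
  }
  stop("could not generate sufficiently separated icons in 5 attempts",
       call. = FALSE)
}

# ink mask (0 = background, bright = stroke) <-> dark-on-white image
ink_to_image <- function(ink) pmin(pmax(255 - ink, 0), 255)
image_to_ink <- function(px) pmin(pmax(255 - px, 0), 255)

# Descriptor-separation check used during generation: pairwise distance
# between distinct icons > 10x the self distance under a 30-deg rotation.
# Checked under retrieval geometry: each icon centred in a white frame
# 2.5x its size (the query frame proportion), described at the centre.
icons_separated <- function(icons) {
  size <- icons[[1]]$N
  S <- as.integer(round(2.5 * size))
  const <- prep_step(S)
  ctr <- S %/% 2
  pad <- (S - size) %/% 2
  desc <- function(px) {
    fr <- matrix(255, S, S)
    fr[(pad + 1):(pad + size), (pad + 1):(pad + size)] <- px
    comp_desc(fr, ctr, ctr, const)$V
  }
  V <- lapply(icons, function(ic) desc(ic$pixels))
  Vrot <- lapply(icons, function(ic)
    desc(ink_to_image(transform_icon(image_to_ink(ic$pixels), 30, 1))))
  self <- mapply(function(a, b) sum((a - b)^2), V, Vrot)
  n <- length(icons)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sum((V[[i]] - V[[j]])^2)
    if (dij <= 10 * max(self[i], self[j])) return(FALSE)
  }
  TRUE
}

# Slot centres of a sqrt(slots) x sqrt(slots) grid on the canvas,
# ((2i+1)*canvas/(2k), (2j+1)*canvas/(2k)) rounded to integers.
slot_centers <- function(canvas, slots) {
  k <- as.integer(round(sqrt(slots)))
  if (k * k != slots) stop("slots must be a perfect square", call. = FALSE)
  pos <- round((2 * (0:(k - 1)) + 1) * canvas / (2 * k))
  as.matrix(expand.grid(x = pos, y = pos))[, 1:2, drop = FALSE]
}

#' Build the benchmark dataset
#'
#' Generates the icons, forms every (icon, angle, scale) combination
#' exactly once, and composites the transformed copies (scaling before
#' rotation, bilinear resampling of the ink mask) onto the slot centres
#' of white 255 canvases under a seeded permutation. Queries are the
#' untransformed icons centred in a white `frame x frame` image.
#'
#' @param spec A [dataset_spec()].
#' @return List with `canvases` (list of [density_image()]), `queries`
#'   (list of [density_image()], one per icon class), `truth` (data
#'   frame: `canvas`, `x`, `y`, `icon`, `angle`, `scale`), and `spec`.
#' @export
build_dataset <- function(spec = dataset_spec()) {
  stopifnot(inherits(spec, "kd2d_dataset_spec"))
  icons <- make_icons(spec$n_icons, spec$icon_size, spec$seed)
  combos <- expand.grid(icon = seq_len(spec$n_icons),
                        angle = spec$angles, scale = spec$scales)
  centers <- slot_centers(spec$canvas, spec$slots)
  n_tot <- nrow(combos)
  set.seed(spec$seed)
  perm <- sample.int(n_tot)                 # combo -> (canvas, slot)
  canvases <- lapply(seq_len(spec$n_canvases),
                     function(i) matrix(255, spec$canvas, spec$canvas))
  truth <- vector("list", n_tot)
  half <- spec$icon_size %/% 2
  spacing <- spec$canvas / sqrt(spec$slots)
  if (spec$icon_size > spacing)             # icons may not span two slots
    stop("transformed icons exceed the slot spacing", call. = FALSE)
  for (idx in seq_len(n_tot)) {
    slot_id <- perm[idx]
    cv <- (slot_id - 1L) %/% spec$slots + 1L
    sl <- (slot_id - 1L) %% spec$slots + 1L
    cx <- centers[sl, 1]; cy <- centers[sl, 2]
    ink <- transform_icon(image_to_ink(icons[[combos$icon[idx]]]$pixels),
                          combos$angle[idx], combos$scale[idx])
    r0 <- cx - half; c0 <- cy - half
    rr <- (r0 + 1):(r0 + spec$icon_size)
    cc <- (c0 + 1):(c0 + spec$icon_size)
    canvases[[cv]][rr, cc] <- pmin(canvases[[cv]][rr, cc],
                                   ink_to_image(ink))
    truth[[idx]] <- data.frame(canvas = cv, x = cx, y = cy,
                               icon = combos$icon[idx],
                               angle = combos$angle[idx],
                               scale = combos$scale[idx])
  }
  qhalf <- spec$frame %/% 2
  queries <- lapply(seq_len(spec$n_icons), function(i) {
    q <- matrix(255, spec$frame, spec$frame)
    rr <- (qhalf - half + 1):(qhalf - half + spec$icon_size)
    q[rr, rr] <- icons[[i]]$pixels
    density_image(q, paste0("query", i))
  })
  list(canvases = lapply(seq_along(canvases), function(i)
         density_image(canvases[[i]], paste0("canvas", i))),
       queries = queries,
       truth = do.call(rbind, truth),
       spec = spec)
}

#' Degrade an image with salt-and-pepper noise
#'
#' A seeded fraction `density` of pixels, chosen uniformly without
#' replacement, is set to 0 or 255 with equal probability; all other
#' pixels are untouched.
#'
#' @param f A [density_image()].
#' @param density Fraction of pixels to corrupt, in `[0, 1]`.
#' @param seed RNG seed for the noise mask.
#' @return A new [density_image()], id suffixed with the noise level.
#' @export
add_salt_pepper <- function(f, density, seed = 1L) {
  stopifnot(inherits(f, "kd2d_image"), density >= 0, density <= 1)
  if (density == 0) return(f)
  px <- f$pixels
  n <- length(px)
  set.seed(seed)
  hit <- sample.int(n, size = round(density * n))
  px[hit] <- 255 * stats::rbinom(length(hit), 1L, 0.5)
  density_image(px, sprintf("%s+sp%.2f", f$image_id, density))
}

#' Score retrieval results against the ground truth
#'
#' Maps each retrieved POI to the nearest slot centre of its canvas (an
#' error if it is farther than half a slot spacing from every centre —
#' that indicates an index/truth mismatch) and calls it a hit when the
#' icon class there equals the query's class.
#'
#' @param results List (one per query, in icon-class order) of
#'   [db_search()] data frames.
#' @param truth Truth table from [build_dataset()].
#' @param spec The [dataset_spec()] used.
#' @param k Ranking depth for the top-k fraction.
#' @return List with `top1` (rank-1 accuracy over queries), `topk` (hit
#'   fraction among ranks `1..k` over `n_queries * k`), `top1_hits`,
#'   `topk_hits`, and the per-retrieval `detail` table.
#' @export
score_retrieval <- function(results, truth, spec, k = 5L) {
  spacing <- spec$canvas / sqrt(spec$slots)
  lookup <- function(canvas_id, x, y) {
    cand <- truth[truth$canvas == canvas_id, ]
    d <- sqrt((cand$x - x)^2 + (cand$y - y)^2)
    i <- which.min(d)
    if (d[i] > spacing / 2)
      stop("retrieved POI does not map to any slot centre", call. = FALSE)
    cand$icon[i]
  }
  detail <- do.call(rbind, lapply(seq_along(results), function(q) {
    r <- utils::head(results[[q]], k)
    cls <- vapply(seq_len(nrow(r)), function(i)
      lookup(as.integer(sub("^canvas(\\d+).*$", "\\1", r$image_id[i])),
             r$x_p[i], r$y_p[i]), numeric(1))
    data.frame(query = q, rank = seq_len(nrow(r)), icon = cls,
               hit = cls == q)
  }))
  nq <- length(results)
  top1_hits <- sum(detail$hit[detail$rank == 1])
  topk_hits <- sum(detail$hit)
  list(top1 = top1_hits / nq, topk = topk_hits / (nq * k),
       top1_hits = top1_hits, topk_hits = topk_hits, detail = detail)
}
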