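# Offline descriptor indexing of all subimages in a database and ranked
# retrieval for a query descriptor. The index is a plain data frame
# (one row per described POI) carried with its creation parameters; it
# round-trips through a TSV file with a small '#'-prefixed metadata
# header, so an index is a one-shot offline artifact.

descriptor_cols <- c("Q20", "Q02", "Q12", "Q21", "Q30", "Q03")

#' Variance pre-filter for candidate subimage centres
#'
#' Keeps exactly those centres whose window (clamped at borders like
#' [square_crop()]) has pixel variance at least the whole-image pixel
#' variance; low-contrast centres (flat background, regions between
#' particles) are dropped before indexing. Population variance (divide
#' by the pixel count) is used on both sides, so a constant image keeps
#' every centre.
#'
#' @param f A [density_image()].
#' @param centers Two-column matrix or data frame of 0-based `(x, y)`
#'   centres.
#' @param window Filter window size in pixels (e.g. 40).
#' @return The kept rows of `centers`, original order preserved.
#' @export
local_variance_filter <- function(f, centers, window) {
  stopifnot(inherits(f, "kd2d_image"), window <= min(f$N, f$M))
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2)
  pvar <- function(v) mean((v - mean(v))^2)
  gvar <- pvar(f$pixels)
  keep <- vapply(seq_len(nrow(centers)), function(i) {
    r0 <- min(max(centers[i, 1] - window %/% 2, 0), f$N - window)
    c0 <- min(max(centers[i, 2] - window %/% 2, 0), f$M - window)
    w <- f$pixels[(r0 + 1):(r0 + window), (c0 + 1):(c0 + window)]
    pvar(w) >= gvar
  }, logical(1))
  centers[keep, , drop = FALSE]
}

# Regular grid of window centres with stride k, keeping windows of size S
# fully inside after clamping (centres range over the whole image).
grid_centers <- function(N, M, S, stride) {
  half <- S %/% 2
  xs <- seq(half, N - 1 - (S - 1 - half), by = stride)
  ys <- seq(half, M - 1 - (S - 1 - half), by = stride)
  as.matrix(expand.grid(x = xs, y = ys))[, 1:2, drop = FALSE]
}

#' Build a descriptor index over an image database
#'
#' Computes the descriptor of every candidate subimage of every image
#' and collects the rows `<image id, x_p, y_p, V>`. Candidate POIs come
#' either from an explicit per-image list or from a regular grid with a
#' given stride; the optional local-variance pre-filter drops flat
#' regions first. Blank (degenerate) POIs are skipped with a warning.
#' Row order is deterministic: images in input order, POIs in the given
#' (or row-major grid) order.
#'
#' @param images List of [density_image()] objects (a single image is
#'   accepted).
#' @param pois Either a list (one two-column matrix/data frame of
#'   0-based POIs per image) or `NULL` to scan a regular grid.
#' @param S Window size shared by all rows.
#' @param beta Reference mass shared by all rows; default `S^2 / 12`.
#' @param stride Grid stride in pixels when `pois` is `NULL` (default 8).
#' @param variance_filter Apply [local_variance_filter()] first?
#' @param filter_window Window size of the variance filter (default 40).
#' @return A `kd2d_index`: data frame with columns `image_id`, `x_p`,
#'   `y_p`, `Q20`..`Q03`, and attribute `meta` (S, beta, mode, stride,
#'   filter settings).
#' @export
db_index <- function(images, pois = NULL, S, beta = S^2 / 12, stride = 8L,
                     variance_filter = FALSE, filter_window = 40L) {
  if (inherits(images, "kd2d_image")) images <- list(images)
  if (length(images) == 0) stop("empty image database", call. = FALSE)
  stopifnot(all(vapply(images, inherits, logical(1), "kd2d_image")))
  if (S > min(vapply(images, function(f) min(f$N, f$M), numeric(1))))
    stop("S exceeds the smallest image dimension", call. = FALSE)
  const <- prep_step(S)
  rows <- vector("list", length(images))
  for (k in seq_along(images)) {
    f <- images[[k]]
    centers <- if (is.null(pois)) grid_centers(f$N, f$M, S, stride)
               else as.matrix(pois[[k]])
    if (variance_filter)
      centers <- local_variance_filter(f, centers, filter_window)
    if (nrow(centers) == 0) { rows[[k]] <- NULL; next }
    recs <- vector("list", nrow(centers))
    for (i in seq_len(nrow(centers))) {
      cr <- square_crop(f, centers[i, 1], centers[i, 2], S)
      d <- tryCatch(
        comp_desc(cr$window, cr$x_s, cr$y_s, const, beta = beta),
        kd2d_degenerate = function(e) NULL)
      if (is.null(d)) {
        warning(sprintf("skipping blank POI (%d, %d) in '%s'",
                        centers[i, 1], centers[i, 2], f$image_id),
                call. = FALSE)
        next
      }
      recs[[i]] <- data.frame(image_id = f$image_id,
                              x_p = as.integer(round(centers[i, 1])),
                              y_p = as.integer(round(centers[i, 2])),
                              as.list(d$V))
    }
    rows[[k]] <- do.call(rbind, recs)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    stop("no indexable subimages (all POIs degenerate?)", call. = FALSE)
  if (anyDuplicated(tab[c("image_id", "x_p", "y_p")]))
    stop("duplicate (image, POI) entries in the index", call. = FALSE)
  rownames(tab) <- NULL
  structure(tab, class = c("kd2d_index", "data.frame"),
            meta = list(S = as.integer(S), beta = beta,
                        mode = if (is.null(pois)) "grid" else "poi-list",
                        stride = as.integer(stride),
                        variance_filter = variance_filter,
                        filter_window = as.integer(filter_window)))
}

#' Squared Euclidean distance between two descriptors
#'
#' \eqn{d(V^Q, V^{DB}) = \sum_{i=1}^{6} (V^Q_i - V^{DB}_i)^2}. Raw
#' components are compared directly, with no per-component weighting.
#' Descriptors computed with different `S` or `beta` are not comparable
#' and raise an error.
#'
#' @param VQ,VDB `kd2d_descriptor` objects (or bare length-6 vectors, in
#'   which case no provenance check is possible).
#' @return Nonnegative scalar.
#' @export
descriptor_distance <- function(VQ, VDB) {
  if (inherits(VQ, "kd2d_descriptor") && inherits(VDB, "kd2d_descriptor")) {
    if (VQ$S != VDB$S || !isTRUE(all.equal(VQ$beta, VDB$beta)))
      stop("descriptors computed with different S/beta are not comparable",
           call. = FALSE)
  }
  vq <- if (inherits(VQ, "kd2d_descriptor")) VQ$V else VQ
  vd <- if (inherits(VDB, "kd2d_descriptor")) VDB$V else VDB
  stopifnot(length(vq) == 6, length(vd) == 6)
  sum((vq - vd)^2)
}

#' Ranked retrieval of the most similar indexed subimages
#'
#' Sorts the index rows by squared Euclidean distance to the query
#' descriptor and returns the best `k`, distances ascending. Ties are
#' broken deterministically by `(image_id, x_p, y_p)`, so the result
#' does not depend on index row order.
#'
#' @param query A `kd2d_descriptor` (from [comp_desc()] /
#'   [describe_poi()]).
#' @param index A `kd2d_index`.
#' @param k Number of hits to return; if larger than the index, all rows
#'   are returned and the result is flagged (`truncated` attribute).
#' @return Data frame `image_id`, `x_p`, `y_p`, `distance`, ranked.
#' @export
db_search <- function(query, index, k = 5L) {
  stopifnot(inherits(index, "kd2d_index"), nrow(index) > 0, k >= 1)
  meta <- attr(index, "meta")
  if (inherits(query, "kd2d_descriptor")) {
    if (query$S != meta$S || !isTRUE(all.equal(query$beta, meta$beta)))
      stop("query descriptor S/beta do not match the index", call. = FALSE)
    vq <- query$V
  } else vq <- query
  D <- as.matrix(index[descriptor_cols])
  d <- colSums((t(D) - vq)^2)
  ord <- order(d, index$image_id, index$x_p, index$y_p)
  truncated <- k > nrow(index)
  top <- ord[seq_len(min(k, nrow(index)))]
  out <- data.frame(index[top, c("image_id", "x_p", "y_p")],
                    distance = d[top], row.names = NULL)
  attr(out, "truncated") <- truncated
  out
}

#' Write an index to a TSV file
#'
#' Header lines prefixed `#` carry the creation parameters (S, beta,
#' mode, stride, filter settings); descriptor values are written with 8
#' significant digits, which is lossless for ranking purposes.
#'
#' @param index A `kd2d_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "kd2d_index"))
  m <- attr(index, "meta")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# S=%d", m$S),
    sprintf("# beta=%.10g", m$beta),
    sprintf("# mode=%s", m$mode),
    sprintf("# stride=%d", m$stride),
    sprintf("# variance_filter=%s", m$variance_filter),
    sprintf("# filter_window=%d", m$filter_window),
    paste(c("image_id", "x_p", "y_p", descriptor_cols), collapse = "\t")),
    con)
  body <- index
  for (cl in descriptor_cols) body[[cl]] <- sprintf("%.8g", body[[cl]])
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an index written by [write_index()]
#' @param path TSV file path.
#' @return A `kd2d_index`.
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE))
  meta <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  structure(tab, class = c("kd2d_index", "data.frame"),
            meta = list(S = as.integer(meta$S), beta = as.numeric(meta$beta),
                        mode = meta$mode, stride = as.integer(meta$stride),
                        variance_filter = as.logical(meta$variance_filter),
                        filter_window = as.integer(meta$filter_window)))
}
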