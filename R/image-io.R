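# Reading gray-scale rasters into density matrices and cropping square
# working windows around a point-of-interest.
#
# Coordinate convention used throughout the package: x indexes rows, y
# indexes columns, both 0-based, origin at the top-left pixel. Densities
# live on the 0..255 scale (the descriptor normalizes mass downstream, so
# the global scale cancels, but index and query must share one convention).
# Images are never inverted: queries and databases must share polarity
# (bright features on dark background, or the reverse, but the same).

#' Construct a density image
#'
#' Wraps an `N x M` matrix of nonnegative pixel densities with an image
#' id. Rows are the x coordinate, columns the y coordinate, 0-based.
#'
#' @param pixels Numeric matrix, all entries finite and `>= 0`.
#' @param image_id Opaque label attached to descriptors of this image.
#' @return A `kd2d_image` object: list with `pixels`, `N`, `M`, `image_id`.
#' @export
density_image <- function(pixels, image_id = "image") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixel densities must be finite numerics", call. = FALSE)
  if (any(pixels < 0))
    stop("pixel densities must be nonnegative", call. = FALSE)
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop("images smaller than 8x8 are not supported", call. = FALSE)
  structure(list(pixels = pixels, N = nrow(pixels), M = ncol(pixels),
                 image_id = as.character(image_id)),
            class = "kd2d_image")
}

#' @export
print.kd2d_image <- function(x, ...) {
  cat(sprintf("kd2d_image '%s': %d x %d, density range [%g, %g]\n",
              x$image_id, x$N, x$M, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a gray-scale image file
#'
#' Decodes PNG, JPEG or TIFF via EBImage. Color inputs are converted to
#' luminance; densities are returned on the 0..255 scale (16-bit inputs
#' are rescaled). Also returns the default window size `S = min(N, M)`,
#' which callers typically override with the query region size.
#'
#' @param path Path to a raster image file.
#' @param image_id Label for the image; defaults to the file name.
#' @return A list with `image` (a [density_image()]) and `S`.
#' @export
read_image <- function(path, image_id = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("cannot decode '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (EBImage::colorMode(img) == EBImage::Color)
    img <- EBImage::channel(img, "luminance")
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2) dat <- dat[, , 1]   # collapse stray frames
  # EBImage stores width x height; transpose to rows x columns.
  pixels <- t(dat) * 255
  pixels[pixels < 0] <- 0
  list(image = density_image(pixels, image_id), S = min(dim(pixels)))
}

#' Crop a square window containing a point-of-interest
#'
#' Extracts an `S x S` window from the image, centred on the POI when
#' possible. Near a border the window is clamped to lie fully inside the
#' image (contents are never padded), so the POI is always contained but
#' not necessarily central. Pixels are copied verbatim.
#'
#' @param f A [density_image()].
#' @param x_p,y_p POI row/column, 0-based integers.
#' @param S Window size; must not exceed either image dimension.
#' @return List with `window` (an `S x S` [density_image()]), and `x_s`,
#'   `y_s`, the POI in 0-based window coordinates.
#' @examples
#' img <- density_image(matrix(runif(64, 0, 255), 8, 8))
#' square_crop(img, 4, 4, 8)$x_s   # identity crop keeps the POI
#' @export
square_crop <- function(f, x_p, y_p, S) {
  stopifnot(inherits(f, "kd2d_image"))
  x_p <- round(x_p); y_p <- round(y_p)
  if (S > min(f$N, f$M))
    stop("window size S exceeds the image dimensions", call. = FALSE)
  if (x_p < 0 || x_p >= f$N || y_p < 0 || y_p >= f$M)
    stop("point-of-interest lies outside the image", call. = FALSE)
  r0 <- min(max(x_p - S %/% 2, 0), f$N - S)
  c0 <- min(max(y_p - S %/% 2, 0), f$M - S)
  win <- f$pixels[(r0 + 1):(r0 + S), (c0 + 1):(c0 + S), drop = FALSE]
  list(window = density_image(win, f$image_id),
       x_s = x_p - r0, y_s = y_p - c0)
}
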