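#' 8-bit greyscale en-face angiogram
#'
#' Lightweight container for an 8-bit greyscale en-face OCTA image: an
#' integer pixel matrix in \[0, 255\] together with the physical scale and the
#' retinal layer it was projected from.
#'
#' @param pixels Integer matrix with values in \[0, 255\] (rows = y, cols = x).
#' @param layer Retinal layer label, `"superficial"` or `"deep"`.
#' @param mm_per_pixel Physical scale of one pixel in millimetres.
#' @return An object of class `grey_image`: a list with elements `pixels`,
#'   `width`, `height`, `mm_per_pixel` and `layer`.
#' @export
grey_image <- function(pixels, layer = c("superficial", "deep"),
                       mm_per_pixel = 3 / 1024) {
  layer <- match.arg(layer)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a non-empty matrix")
  if (is.double(pixels)) {
    if (any(pixels != floor(pixels), na.rm = TRUE))
      stop("pixel values must be integers")
    storage.mode(pixels) <- "integer"
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
         mm_per_pixel = mm_per_pixel, layer = layer),
    class = "grey_image"
  )
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %dx%d px, %.4f mm/px, layer: %s\n",
              x$width, x$height, x$mm_per_pixel, x$layer))
  invisible(x)
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "grey_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a `grey_image` or a pixel matrix")
}

#' Read / write an 8-bit greyscale PNG
#'
#' Images are stored as single-channel 8-bit greyscale PNG files. On reading,
#' RGB(A) files are rejected so that accidental colour exports are caught
#' early rather than silently averaged.
#'
#' @param path File path.
#' @param layer,mm_per_pixel Metadata attached to the returned [grey_image()].
#' @return `read_grey_png()` returns a [grey_image()]; `write_grey_png()`
#'   returns `path` invisibly.
#' @export
read_grey_png <- function(path, layer = c("superficial", "deep"),
                          mm_per_pixel = 3 / 1024) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L &&
        !(all(arr[, , 1] == arr[, , 2]) && all(arr[, , 2] == arr[, , 3])))
      stop("not an 8-bit greyscale image: ", path)
    arr <- arr[, , 1]
  }
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  grey_image(px, layer = match.arg(layer), mm_per_pixel = mm_per_pixel)
}

#' @rdname read_grey_png
#' @param image A [grey_image()] or integer pixel matrix.
#' @export
write_grey_png <- function(image, path) {
  px <- as_pixel_matrix(image)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' FAZ polygon utilities
#'
#' The foveal avascular zone (FAZ) is delineated as a simple polygon in pixel
#' coordinates (columns `x`, `y`, in pixel units, origin at the top-left
#' pixel centre). `faz_polygon_is_simple()` checks that no two
#' non-adjacent edges intersect; `rasterize_polygon()` converts the polygon
#' to a logical mask over an `height x width` pixel grid (a pixel belongs to
#' the mask when its centre falls inside the polygon); polygons can be
#' round-tripped through JSON vertex lists.
#'
#' @param poly Two-column numeric matrix of vertices (x, y), in order.
#' @return `faz_polygon_is_simple()` a logical; `rasterize_polygon()` a
#'   logical matrix; `read_faz_json()` a vertex matrix.
#' @export
faz_polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
  intersects <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (intersects(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

#' @rdname faz_polygon_is_simple
#' @param width,height Dimensions of the target pixel grid.
#' @export
rasterize_polygon <- function(poly, width, height) {
  stopifnot(nrow(poly) >= 3L)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  # restrict the point-in-polygon test to the polygon's bounding box
  xr <- max(1L, floor(min(poly[, 1]))):min(width,  ceiling(max(poly[, 1])))
  yr <- max(1L, floor(min(poly[, 2]))):min(height, ceiling(max(poly[, 2])))
  if (length(xr) == 0L || length(yr) == 0L) return(mask)
  pts <- cbind(rep(xr, each = length(yr)), rep(yr, times = length(xr)))
  bnd <- rbind(poly, poly[1L, , drop = FALSE])
  inside <- mgcv::in.out(bnd, pts)
  mask[cbind(pts[inside, 2L], pts[inside, 1L])] <- TRUE
  mask
}

#' @rdname faz_polygon_is_simple
#' @param path JSON file path holding `{"x": [...], "y": [...]}`.
#' @export
read_faz_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  cbind(x = as.numeric(v$x), y = as.numeric(v$y))
}

#' @rdname faz_polygon_is_simple
#' @export
write_faz_json <- function(poly, path) {
  jsonlite::write_json(list(x = poly[, 1], y = poly[, 2]), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
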