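# Polygon rasterization and geometry. Fill rule: even-odd, a pixel is set
# iff its center (x + 0.5, y + 0.5) lies inside the polygon. With integer
# vertex coordinates (as produced by mask_to_polygon) pixel centers never
# coincide with vertices, so the rule has no ties.

#' Rasterize a polygon to a binary mask
#'
#' Scanline even-odd fill: for each pixel row the crossings of the polygon
#' edges with the line through the pixel centers are computed, sorted, and
#' pixels between odd/even crossing pairs are set. A pixel is set iff its
#' center lies inside the polygon under the even-odd rule, which makes the
#' result exactly countable (an axis-aligned `n x n` square with corners on
#' the lattice covers exactly `n^2` pixels).
#'
#' @param xs,ys Polygon vertex coordinates (0-based pixel coordinates), or
#'   `xs` may be a two-column matrix / `PolygonAnnotation` with `ys` missing.
#' @param width,height Output raster size in pixels.
#' @return Logical `height x width` matrix. A degenerate (zero-area) polygon
#'   yields an empty mask with a warning.
#' @export
polygon_to_mask <- function(xs, ys = NULL, width, height) {
  if (inherits(xs, "PolygonAnnotation")) { ys <- xs$ys; xs <- xs$xs }
  if (is.matrix(xs) && is.null(ys)) { ys <- xs[, 2]; xs <- xs[, 1] }
  ot_assert(length(xs) == length(ys) && length(xs) >= 3,
            "polygon needs at least 3 vertices")
  mask <- matrix(FALSE, height, width)
  # degenerate = all vertices collinear (a bow-tie has zero SIGNED area
  # but a non-empty even-odd interior, so the signed area is no test)
  dx <- xs - xs[1]; dy <- ys - ys[1]
  ref <- which.max(dx^2 + dy^2)
  if (all(abs(dx * dy[ref] - dy * dx[ref]) < 1e-12)) {
    warning("degenerate (zero-area) polygon; returning empty mask")
    return(mask)
  }
  n <- length(xs)
  x1 <- xs; y1 <- ys
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  centers <- seq_len(width) - 0.5
  row_lo <- max(1L, ceiling(min(ylo) + 0.5))
  row_hi <- min(height, ceiling(max(yhi) + 0.5) - 1L)
  if (row_lo > row_hi) return(mask)
  for (row in row_lo:row_hi) {
    yc <- row - 0.5
    sel <- ylo <= yc & yc < yhi
    if (!any(sel)) next
    cx <- x1[sel] + (yc - y1[sel]) * (x2[sel] - x1[sel]) / (y2[sel] - y1[sel])
    cx <- sort(cx)
    inside <- logical(width)
    for (k in seq(1, length(cx) - 1, by = 2)) {
      inside <- inside | (centers >= cx[k] & centers < cx[k + 1])
    }
    mask[row, ] <- inside
  }
  mask
}

#' Signed area of a polygon (shoelace formula)
#'
#' Positive when the vertex order is clockwise in screen coordinates
#' (y pointing down).
#'
#' @param xs,ys Vertex coordinates.
#' @return Signed area.
#' @export
polygon_area <- function(xs, ys = NULL) {
  if (is.matrix(xs) && is.null(ys)) { ys <- xs[, 2]; xs <- xs[, 1] }
  n <- length(xs)
  j <- c(2:n, 1)
  sum(xs * ys[j] - xs[j] * ys) / 2
}
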