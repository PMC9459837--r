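# Contour shape comparison via Hu invariant moments.
#
# Moments are computed ANALYTICALLY from the polygon contour using the
# classical Green's-theorem closed forms (the same semantics as treating the
# contour as a filled continuous region), so the seven Hu invariants are
# exactly translation-, scale- and rotation-invariant up to floating point,
# independent of any rasterization.

#' Raw geometric moments of a filled simple polygon
#'
#' Computes m_pq = integral of x^p y^q over the polygon interior for all
#' p + q <= 3, via line-integral closed forms over the edges. Vertex order
#' is normalized so the returned m00 (the area) is positive.
#'
#' @param xs,ys Vertex coordinates, or a two-column matrix as `xs`.
#' @return Named numeric vector m00, m10, m01, m20, m11, m02, m30, m21,
#'   m12, m03.
#' @export
polygon_raw_moments <- function(xs, ys = NULL) {
  if (is.matrix(xs) && is.null(ys)) { ys <- xs[, 2]; xs <- xs[, 1] }
  ot_assert(length(xs) == length(ys) && length(xs) >= 3,
            "polygon needs at least 3 vertices")
  n <- length(xs)
  j <- c(2:n, 1)
  xa <- xs; ya <- ys; xb <- xs[j]; yb <- ys[j]
  cr <- xa * yb - xb * ya
  m <- c(
    m00 = sum(cr) / 2,
    m10 = sum(cr * (xa + xb)) / 6,
    m01 = sum(cr * (ya + yb)) / 6,
    m20 = sum(cr * (xa^2 + xa * xb + xb^2)) / 12,
    m11 = sum(cr * (2 * xa * ya + xa * yb + xb * ya + 2 * xb * yb)) / 24,
    m02 = sum(cr * (ya^2 + ya * yb + yb^2)) / 12,
    m30 = sum(cr * (xa^3 + xa^2 * xb + xa * xb^2 + xb^3)) / 20,
    m21 = sum(cr * (3 * xa^2 * ya + xa^2 * yb + 2 * xa * xb * ya +
                      2 * xa * xb * yb + xb^2 * ya + 3 * xb^2 * yb)) / 60,
    m12 = sum(cr * (3 * ya^2 * xa + ya^2 * xb + 2 * ya * yb * xa +
                      2 * ya * yb * xb + yb^2 * xa + 3 * yb^2 * xb)) / 60,
    m03 = sum(cr * (ya^3 + ya^2 * yb + ya * yb^2 + yb^3)) / 20
  )
  if (m["m00"] < 0) m <- -m
  ot_assert(m[["m00"]] > 0, "degenerate contour: zero area")
  m
}

# Central then scale-normalized moments from raw moments.
normalized_moments <- function(m) {
  xb <- m[["m10"]] / m[["m00"]]
  yb <- m[["m01"]] / m[["m00"]]
  mu <- c(
    mu00 = m[["m00"]],
    mu20 = m[["m20"]] - xb * m[["m10"]],
    mu11 = m[["m11"]] - xb * m[["m01"]],
    mu02 = m[["m02"]] - yb * m[["m01"]],
    mu30 = m[["m30"]] - 3 * xb * m[["m20"]] + 2 * xb^2 * m[["m10"]],
    mu21 = m[["m21"]] - 2 * xb * m[["m11"]] - yb * m[["m20"]] + 2 * xb^2 * m[["m01"]],
    mu12 = m[["m12"]] - 2 * yb * m[["m11"]] - xb * m[["m02"]] + 2 * yb^2 * m[["m10"]],
    mu03 = m[["m03"]] - 3 * yb * m[["m02"]] + 2 * yb^2 * m[["m01"]]
  )
  s2 <- mu[["mu00"]]^2
  s25 <- mu[["mu00"]]^2.5
  c(eta20 = mu[["mu20"]] / s2, eta11 = mu[["mu11"]] / s2, eta02 = mu[["mu02"]] / s2,
    eta30 = mu[["mu30"]] / s25, eta21 = mu[["mu21"]] / s25,
    eta12 = mu[["mu12"]] / s25, eta03 = mu[["mu03"]] / s25)
}

#' Seven Hu invariant moments of a polygon contour
#'
#' @param xs,ys Vertex coordinates, or a two-column matrix as `xs`.
#' @return Numeric vector h1..h7.
#' @export
hu_moments <- function(xs, ys = NULL) {
  eta <- normalized_moments(polygon_raw_moments(xs, ys))
  e20 <- eta[["eta20"]]; e11 <- eta[["eta11"]]; e02 <- eta[["eta02"]]
  e30 <- eta[["eta30"]]; e21 <- eta[["eta21"]]; e12 <- eta[["eta12"]]; e03 <- eta[["eta03"]]
  p <- e30 + e12; q <- e21 + e03
  r <- e30 - 3 * e12; s <- 3 * e21 - e03
  c(h1 = e20 + e02,
    h2 = (e20 - e02)^2 + 4 * e11^2,
    h3 = r^2 + s^2,
    h4 = p^2 + q^2,
    h5 = r * p * (p^2 - 3 * q^2) + s * q * (3 * p^2 - q^2),
    h6 = (e20 - e02) * (p^2 - q^2) + 4 * e11 * p * q,
    h7 = s * p * (p^2 - 3 * q^2) - r * q * (3 * p^2 - q^2))
}

#' Contour shape dissimilarity (Hu-moment distance)
#'
#' The OpenCV `matchShapes` I1 distance: with
#' `m_i = sign(h_i) * log10(|h_i|)` over the seven Hu invariants of each
#' filled contour, returns `sum_i |1/m_i^A - 1/m_i^B|`. Smaller values mean
#' more similar shapes; identical shapes (up to translation, rotation and
#' scaling) score 0. Invariant pairs where either `|h_i|` falls below the
#' floor `eps` are skipped.
#'
#' @param contour_a,contour_b Two-column (x, y) vertex matrices with at
#'   least 3 vertices and non-zero area.
#' @param eps Magnitude floor below which an invariant pair is skipped
#'   (default 1e-5, the OpenCV value).
#' @return Non-negative dissimilarity.
#' @export
shape_dissimilarity <- function(contour_a, contour_b, eps = 1e-5) {
  ha <- hu_moments(contour_a)
  hb <- hu_moments(contour_b)
  keep <- abs(ha) > eps & abs(hb) > eps
  if (!any(keep)) return(0)
  ma <- sign(ha[keep]) * log10(abs(ha[keep]))
  mb <- sign(hb[keep]) * log10(abs(hb[keep]))
  sum(abs(1 / ma - 1 / mb))
}
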