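#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout the package: 0-based pixel indices,
# origin at the top-left, x rightward (columns), y downward (rows).
# Pixel (x, y) covers the unit square [x, x+1) x [y, y+1); its center is at
# (x + 0.5, y + 0.5). Boxes are half-open [x_min, x_max) x [y_min, y_max).
# Images are numeric arrays h x w x 3 with values in [0, 1]; masks are
# logical h x w matrices.

ot_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-sample seed from a master seed
#'
#' Mixes a sample index into a master seed with a fixed affine rule modulo
#' 2^31 - 1, so datasets are order-independent and resumable: sample `i`
#' always receives the same seed regardless of which samples were generated
#' before it.
#'
#' @param master Integer master seed.
#' @param index Integer sample index (1-based).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
split_seed <- function(master, index) {
  ot_assert(is.numeric(master) && length(master) == 1, "master seed must be a single number")
  ot_assert(is.numeric(index) && length(index) == 1 && index >= 0, "index must be a single non-negative number")
  m <- 2147483647
  s <- (abs(as.double(master)) %% m)
  # two rounds of a multiplicative mix keep per-index streams well separated
  s <- (s * 48271 + as.double(index) * 2246822519 + 374761393) %% m
  s <- (s * 69621 + 1013904223) %% m
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Tight bounding box of a binary mask
#'
#' @param mask Logical matrix.
#' @return `c(x_min, y_min, x_max, y_max)` with half-open extents in the
#'   package's 0-based pixel coordinates, or `NULL` for an empty mask.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
    x_max = max(idx[, 2]), y_max = max(idx[, 1]))
}

#' Centroid of a binary mask
#'
#' Mean of the centers of the set pixels.
#'
#' @param mask Logical matrix.
#' @return `c(x, y)` in 0-based pixel coordinates.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ot_assert(nrow(idx) > 0, "mask is empty")
  c(x = mean(idx[, 2]) - 0.5, y = mean(idx[, 1]) - 0.5)
}

#' Label 4-connected components of a binary mask
#'
#' Layer-synchronous flood fill; component ids are assigned in scan order
#' (top-to-bottom, left-to-right of each component's first pixel).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  remaining <- which(t(mask))  # scan order: row-major over (row, col)
  # translate row-major scan order back to column-major linear indices
  if (length(remaining)) {
    rm_row <- ((remaining - 1L) %/% w) + 1L
    rm_col <- ((remaining - 1L) %% w) + 1L
    remaining <- (rm_col - 1L) * h + rm_row
  }
  visited <- matrix(FALSE, h, w)
  next_id <- 0L
  for (start in remaining) {
    if (visited[start]) next
    next_id <- next_id + 1L
    frontier <- start
    visited[frontier] <- TRUE
    while (length(frontier)) {
      labels[frontier] <- next_id
      r <- ((frontier - 1L) %% h) + 1L
      cc <- ((frontier - 1L) %/% h) + 1L
      cand <- c(frontier[r > 1L] - 1L, frontier[r < h] + 1L,
                frontier[cc > 1L] - h, frontier[cc < w] + h)
      cand <- unique(cand)
      cand <- cand[mask[cand] & !visited[cand]]
      visited[cand] <- TRUE
      frontier <- cand
    }
  }
  labels
}

# Largest 4-connected component of a mask (ties broken by scan order).
largest_component <- function(mask) {
  labs <- label_components(mask)
  if (max(labs) == 0L) return(mask & FALSE)
  sizes <- tabulate(labs[labs > 0L])
  labs == which.max(sizes)
}

#' Trace the outer boundary of a mask's largest component
#'
#' Crack-following boundary trace along pixel edges: the returned polygon
#' runs along the lattice lines between set and unset pixels, with vertices
#' at pixel corners (integer coordinates) and collinear runs merged.
#' Rasterizing the polygon with [polygon_to_mask()] reproduces the component
#' with any interior holes filled, which makes
#' polygon -> mask -> polygon -> mask idempotent.
#'
#' @param mask Logical matrix with at least one set pixel.
#' @return A two-column matrix of (x, y) vertices, 0-based corner coordinates.
#' @export
mask_to_polygon <- function(mask) {
  ot_assert(any(mask), "mask is empty")
  comp <- largest_component(mask)
  h <- nrow(comp); w <- ncol(comp)
  filled <- function(px, py) {
    px >= 0 && px < w && py >= 0 && py < h && comp[py + 1L, px + 1L]
  }
  idx <- which(comp, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  p0 <- idx[ord[1], ]  # topmost, then leftmost pixel
  sx <- p0[2] - 1L; sy <- p0[1] - 1L  # start corner = its top-left corner
  dirs <- matrix(c(1L, 0L, 0L, 1L, -1L, 0L, 0L, -1L), ncol = 2, byrow = TRUE)  # E,S,W,N
  # front-left / front-right pixel offsets relative to the current corner,
  # indexed by direction (walking with the filled region on the right)
  fl <- matrix(c(0L, -1L, 0L, 0L, -1L, 0L, -1L, -1L), ncol = 2, byrow = TRUE)
  fr <- matrix(c(0L, 0L, -1L, 0L, -1L, -1L, 0L, -1L), ncol = 2, byrow = TRUE)
  x <- sx; y <- sy; d <- 1L  # start heading east along the top edge
  verts_x <- integer(0); verts_y <- integer(0)
  prev_d <- 0L
  max_steps <- 4L * (sum(comp) + h + w) + 16L
  for (step in seq_len(max_steps)) {
    if (d != prev_d) {
      verts_x <- c(verts_x, x); verts_y <- c(verts_y, y)
      prev_d <- d
    }
    x <- x + dirs[d, 1]; y <- y + dirs[d, 2]
    if (x == sx && y == sy) break
    if (filled(x + fl[d, 1], y + fl[d, 2])) {
      d <- if (d == 1L) 4L else d - 1L  # turn left
    } else if (filled(x + fr[d, 1], y + fr[d, 2])) {
      # straight on
    } else {
      d <- if (d == 4L) 1L else d + 1L  # turn right
    }
  }
  cbind(x = verts_x, y = verts_y)
}
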