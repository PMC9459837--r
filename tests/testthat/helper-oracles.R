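# Independent oracles used to freeze expected values. These deliberately
# use different algorithms from the package code paths they check.

# --- even-odd point-in-polygon (classic crossing count, per pixel) -------

oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_polygon_mask <- function(xs, ys, width, height) {
  m <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      m[row, col] <- oracle_point_in_polygon(col - 0.5, row - 0.5, xs, ys)
    }
  }
  m
}

# --- exact polygon moments via signed triangle-fan decomposition ---------

# integral of x^p y^q over the triangle (0, A, B), via the barycentric
# expansion: x = xA*u + xB*v, y = yA*u + yB*v over u,v >= 0, u+v <= 1 and
# Int u^a v^b du dv = a! b! / (a+b+2)!
oracle_triangle_moment <- function(xa, ya, xb, yb, p, q) {
  J <- xa * yb - xb * ya
  total <- 0
  for (i in 0:p) {
    for (j in 0:q) {
      total <- total + choose(p, i) * choose(q, j) *
        xa^i * xb^(p - i) * ya^j * yb^(q - j) *
        factorial(i + j) * factorial(p + q - i - j) / factorial(p + q + 2)
    }
  }
  J * total
}

oracle_polygon_moment <- function(xs, ys, p, q) {
  n <- length(xs)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    total <- total + oracle_triangle_moment(xs[i], ys[i], xs[j], ys[j], p, q)
  }
  total
}

# Hu moments by an independent route: translate the polygon so its
# centroid is at the origin (central moments become raw moments of the
# shifted polygon), normalize, then apply the invariant formulas.
oracle_hu_moments <- function(xs, ys) {
  a <- oracle_polygon_moment(xs, ys, 0, 0)
  if (a < 0) { xs <- rev(xs); ys <- rev(ys); a <- -a }
  cx <- oracle_polygon_moment(xs, ys, 1, 0) / a
  cy <- oracle_polygon_moment(xs, ys, 0, 1) / a
  xs <- xs - cx; ys <- ys - cy
  mu <- function(p, q) oracle_polygon_moment(xs, ys, p, q)
  eta <- function(p, q) mu(p, q) / a^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e11 <- eta(1, 1); e02 <- eta(0, 2)
  e30 <- eta(3, 0); e21 <- eta(2, 1); e12 <- eta(1, 2); e03 <- eta(0, 3)
  pp <- e30 + e12; qq <- e21 + e03
  rr <- e30 - 3 * e12; ss <- 3 * e21 - e03
  c(e20 + e02,
    (e20 - e02)^2 + 4 * e11^2,
    rr^2 + ss^2,
    pp^2 + qq^2,
    rr * pp * (pp^2 - 3 * qq^2) + ss * qq * (3 * pp^2 - qq^2),
    (e20 - e02) * (pp^2 - qq^2) + 4 * e11 * pp * qq,
    ss * pp * (pp^2 - 3 * qq^2) - rr * qq * (3 * pp^2 - qq^2))
}

oracle_match_shapes <- function(ca, cb, eps = 1e-5) {
  ha <- oracle_hu_moments(ca[, 1], ca[, 2])
  hb <- oracle_hu_moments(cb[, 1], cb[, 2])
  total <- 0
  for (i in 1:7) {
    if (abs(ha[i]) > eps && abs(hb[i]) > eps) {
      ma <- sign(ha[i]) * log10(abs(ha[i]))
      mb <- sign(hb[i]) * log10(abs(hb[i]))
      total <- total + abs(1 / ma - 1 / mb)
    }
  }
  total
}

# --- exact binomial 99% central interval on a count ----------------------

binom_ci99 <- function(n, p) {
  c(lo = qbinom(0.005, n, p), hi = qbinom(0.995, n, p))
}

# --- brute-force one-to-one assignment enumeration -----------------------

# All MAXIMAL (non-extendable) one-to-one assignments permitted by a
# logical feasibility matrix (rows = tracks, cols = detections). Any
# greedy pass over the feasible pairs produces one of these; when the
# instance admits exactly one, the greedy result is forced. Returns a list
# of two-column matrices (row, col).
enumerate_assignments <- function(feasible) {
  nr <- nrow(feasible); nc <- ncol(feasible)
  all_matchings <- list()
  recurse <- function(row, used_cols, pairs) {
    if (row > nr) {
      all_matchings[[length(all_matchings) + 1]] <<- pairs
      return(invisible(NULL))
    }
    recurse(row + 1, used_cols, pairs)  # leave this row unassigned
    for (col in seq_len(nc)) {
      if (feasible[row, col] && !(col %in% used_cols)) {
        recurse(row + 1, c(used_cols, col), rbind(pairs, c(row, col)))
      }
    }
  }
  recurse(1L, integer(0), matrix(integer(0), 0, 2))
  is_maximal <- vapply(all_matchings, function(m) {
    used_r <- m[, 1]; used_c <- m[, 2]
    for (i in setdiff(seq_len(nr), used_r)) {
      for (j in setdiff(seq_len(nc), used_c)) {
        if (feasible[i, j]) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  unique(lapply(all_matchings[is_maximal],
                function(m) m[order(m[, 1]), , drop = FALSE]))
}

# --- shape/detection fixtures --------------------------------------------

# star-shaped (hence simple) random polygon around a center
random_simple_polygon <- function(n_vertices = 8, center = c(10, 10),
                                  radius_range = c(3, 8)) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, radius_range[1], radius_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

disc_mask <- function(cx, cy, r, height, width) {
  g <- expand.grid(row = seq_len(height), col = seq_len(width))
  matrix((g$col - 0.5 - cx)^2 + (g$row - 0.5 - cy)^2 <= r^2, height, width)
}

disc_contour <- function(cx, cy, r, n = 40) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# a synthetic Detection without any rendering
make_disc_detection <- function(cx, cy, r, date, n_vertices = 40) {
  detection(contour = disc_contour(cx, cy, r, n_vertices),
            bbox = c(x_min = cx - r, y_min = cy - r, x_max = cx + r, y_max = cy + r),
            center = c(x = cx, y = cy), radius = r, capture_date = date)
}

# a fake CompositeSample carrying hand-built instances (for oracle_detect)
fake_sample <- function(instances, seed_used = 1L, canvas = c(64, 64)) {
  structure(list(image = array(0, c(canvas, 3)),
                 instances = instances, seed_used = as.integer(seed_used)),
            class = "CompositeSample")
}

fake_instance <- function(id, mask, visible = mask) {
  structure(list(instance_id = id, amodal_mask = mask, visible_mask = visible,
                 bbox = mask_bbox(mask), center = mask_centroid(mask),
                 is_red = TRUE),
            class = "FruitInstance")
}

# small fast GenerationParams for compositor tests
small_params <- function(...) {
  defaults <- list(canvas_size = c(192, 192), fruit_size_range = c(30, 44),
                   leaf_size_range = c(14, 20), n_fruits_range = c(2, 4),
                   n_foreground_leaves = 8, n_background_leaves = 6)
  do.call(generation_params, utils::modifyList(defaults, list(...)))
}

small_assets <- function(seed = 1) {
  generate_fixture_assets(seed, n_fruit = 4, n_leaf = 4, fruit_px = 48,
                          leaf_px = 22, background_size = c(224, 224))
}
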