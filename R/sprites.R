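# Sprites: the unit of compositing. A sprite is an RGB pixel raster plus a
# binary footprint (TRUE = opaque) of the same size, tagged with a kind.

#' Construct a sprite
#'
#' @param pixels Numeric h x w x 3 array in \[0, 1\].
#' @param footprint Logical h x w matrix, TRUE where the sprite is opaque.
#' @param kind One of `"fruit_red"`, `"fruit_green"`, `"leaf"`,
#'   `"background"`, `"shadow"`.
#' @return A `Sprite` object.
#' @export
sprite <- function(pixels, footprint, kind) {
  kind <- match.arg(kind, c("fruit_red", "fruit_green", "leaf", "background", "shadow"))
  ot_assert(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
            "pixels must be an h x w x 3 array")
  ot_assert(is.matrix(footprint) && all(dim(footprint) == dim(pixels)[1:2]),
            "footprint must match pixel dimensions")
  if (kind %in% c("fruit_red", "fruit_green", "leaf"))
    ot_assert(any(footprint), "fruit and leaf sprites need a non-empty footprint")
  if (kind == "background")
    ot_assert(all(footprint), "background sprites must have a full footprint")
  structure(list(pixels = pixels, footprint = footprint, kind = kind),
            class = "Sprite")
}

#' @export
print.Sprite <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<Sprite %s %dx%d, footprint %d px>\n", x$kind, d[1], d[2], sum(x$footprint)))
  invisible(x)
}

is_fruit_kind <- function(kind) kind %in% c("fruit_red", "fruit_green")

# Pixel-center coordinate grids for an h x w raster (0-based convention).
center_grids <- function(h, w) {
  list(x = matrix(rep(seq_len(w) - 0.5, each = h), h, w),
       y = matrix(rep(seq_len(h) - 0.5, w), h, w))
}

# Draw one shaded fruit blob: a near-elliptical star-convex region whose
# boundary radius is modulated by low-order harmonics, with radial shading
# and a specular highlight.
draw_fruit_sprite <- function(size, red) {
  h <- w <- size
  g <- center_grids(h, w)
  cx <- w / 2; cy <- h / 2
  dx <- g$x - cx; dy <- g$y - cy
  th <- atan2(dy, dx)
  a1 <- runif(1, 0.02, 0.07); a2 <- runif(1, 0.01, 0.05)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  squash <- runif(1, 0.88, 1.0)  # mild vertical squash
  bound <- 1 + a1 * sin(2 * th + p1) + a2 * sin(3 * th + p2)
  rr <- sqrt(dx^2 + (dy / squash)^2) / (size / 2 * 0.94)
  inside <- rr <= bound
  base <- if (red) c(runif(1, 0.65, 0.85), runif(1, 0.08, 0.2), runif(1, 0.08, 0.18))
          else c(runif(1, 0.45, 0.6), runif(1, 0.6, 0.75), runif(1, 0.15, 0.3))
  depth <- sqrt(pmax(0, 1 - pmin(rr / pmax(bound, 1e-9), 1)^2))
  shade <- 0.45 + 0.55 * depth
  hx <- cx - size * 0.15; hy <- cy - size * 0.18
  hl <- exp(-(((g$x - hx)^2 + (g$y - hy)^2) / (2 * (size * 0.12)^2)))
  px <- array(0, c(h, w, 3))
  for (k in 1:3) {
    ch <- base[k] * shade + 0.5 * hl * depth
    ch[!inside] <- 0
    px[, , k] <- clamp(ch, 0, 1)
  }
  sprite(px, inside, if (red) "fruit_red" else "fruit_green")
}

# Draw one leaf: an elongated harmonic-modulated ellipse with a darker
# midrib along the major axis and a lengthwise shading gradient.
draw_leaf_sprite <- function(size) {
  h <- w <- size
  g <- center_grids(h, w)
  cx <- w / 2; cy <- h / 2
  elong <- runif(1, 0.35, 0.55)
  dx <- (g$x - cx) / (size / 2 * 0.95)
  dy <- (g$y - cy) / (size / 2 * 0.95 * elong)
  th <- atan2(dy, dx)
  a1 <- runif(1, 0.05, 0.18); p1 <- runif(1, 0, 2 * pi)
  # taper toward the tip so the outline is leaf- rather than lens-shaped
  taper <- 1 - 0.25 * pmax(0, cos(th))^2
  inside <- sqrt(dx^2 + dy^2) <= (1 + a1 * sin(3 * th + p1)) * taper
  base <- c(runif(1, 0.1, 0.25), runif(1, 0.4, 0.62), runif(1, 0.1, 0.22))
  grad <- 0.7 + 0.3 * (g$x / w)
  midrib <- abs(g$y - cy) < size * 0.02
  px <- array(0, c(h, w, 3))
  for (k in 1:3) {
    ch <- base[k] * grad
    ch[midrib] <- ch[midrib] * 0.6
    ch[!inside] <- 0
    px[, , k] <- clamp(ch, 0, 1)
  }
  sprite(px, inside, "leaf")
}

# Textured background plate: a low-frequency mixture of green/brown tones
# from random-phase sinusoids plus fine uniform noise.
draw_background_sprite <- function(height, width) {
  g <- center_grids(height, width)
  field <- matrix(0, height, width)
  for (k in 1:4) {
    fx <- runif(1, 0.5, 3) * 2 * pi / width
    fy <- runif(1, 0.5, 3) * 2 * pi / height
    field <- field + runif(1, 0.5, 1) * sin(fx * g$x + runif(1, 0, 2 * pi)) *
      sin(fy * g$y + runif(1, 0, 2 * pi))
  }
  field <- (field - min(field)) / max(1e-9, diff(range(field)))
  noise <- matrix(runif(height * width, -0.04, 0.04), height, width)
  dark <- c(0.13, 0.18, 0.08); light <- c(0.35, 0.42, 0.2)
  px <- array(0, c(height, width, 3))
  for (k in 1:3) px[, , k] <- clamp(dark[k] + (light[k] - dark[k]) * field + noise, 0, 1)
  sprite(px, matrix(TRUE, height, width), "background")
}

#' Generate procedural fixture assets
#'
#' Stands in for manually cropped orchard photographs: draws shaded
#' near-elliptical fruit blobs (alternating red/green base colors),
#' irregular green leaf polygons, and one textured background plate.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_fruit Number of fruit sprites (>= 1; alternates red/green so
#'   both colors are present whenever `n_fruit >= 2`).
#' @param n_leaf Number of leaf sprites (>= 1).
#' @param fruit_px,leaf_px Native sprite sizes in px.
#' @param background_size `c(height, width)` of the background plate; must
#'   be at least the compositing canvas size.
#' @return A list of `Sprite` objects (fruits, then leaves, then background).
#' @export
generate_fixture_assets <- function(seed, n_fruit = 4, n_leaf = 6,
                                    fruit_px = 180, leaf_px = 80,
                                    background_size = c(1152, 1152)) {
  ot_assert(n_fruit >= 1 && n_leaf >= 1, "counts must be >= 1")
  with_seed(seed, {
    fruits <- lapply(seq_len(n_fruit), function(i) draw_fruit_sprite(fruit_px, red = i %% 2 == 1))
    leaves <- lapply(seq_len(n_leaf), function(i) draw_leaf_sprite(leaf_px))
    bg <- draw_background_sprite(background_size[1], background_size[2])
    c(fruits, leaves, list(bg))
  })
}
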