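# Cut-and-paste scene composition. Layers are painted in the order
# background -> background leaves -> fruits -> (shadow, foreground leaf)
# pairs. Each fruit's amodal mask is its full transformed footprint BEFORE
# any foreground occlusion; its visible mask keeps only pixels not covered
# by a later-painted opaque layer (a later fruit or a foreground leaf).
# Shadows darken multiplicatively and are not opaque, so they never remove
# visibility.

transformed_dims <- function(target_h, target_w, angle) {
  rad <- angle * pi / 180
  c(h = max(1L, ceiling(target_h * abs(cos(rad)) + target_w * abs(sin(rad)))),
    w = max(1L, ceiling(target_w * abs(cos(rad)) + target_h * abs(sin(rad)))))
}

#' Sample random placements for one scene
#'
#' Draws the number of fruits uniformly from `n_fruits_range`, colors each
#' fruit red with probability `p_red_apple`, samples target height and
#' width independently and uniformly from the kind's size range (realizing
#' aspect-ratio variation), brightness and angle uniformly from their
#' ranges, and sprite centers uniformly over the canvas. The returned rows
#' are ordered background leaves, then fruits, then (shadow, foreground
#' leaf) pairs; each shadow immediately precedes its leaf and is offset
#' from it by a random displacement.
#'
#' Consumes the caller's RNG stream (seed it, or pass `seed`).
#'
#' @param params A `GenerationParams` object.
#' @param seed Optional seed; if given, sampling is wrapped in a local RNG.
#' @return A data frame with one row per placement: `layer`, `kind`,
#'   `target_h`, `target_w`, `brightness`, `angle`, `center_x`, `center_y`,
#'   `pos_x`, `pos_y` (top-left of the transformed sprite's bounding box),
#'   `is_red`, `pair` (shadow/leaf pairing index).
#' @export
sample_placements <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) return(with_seed(seed, sample_placements(params)))
  H <- params$canvas_size[1]; W <- params$canvas_size[2]
  n_bg <- if (is.null(params$n_background_leaves)) {
    params$background_leaf_choices[sample.int(length(params$background_leaf_choices), 1)]
  } else params$n_background_leaves
  n_fruit <- sample(seq(params$n_fruits_range[1], params$n_fruits_range[2]), 1)
  n_fg <- params$n_foreground_leaves

  draw_rows <- function(n, layer, kind, size_range, is_red = NA) {
    if (n == 0) return(NULL)
    th <- runif(n, size_range[1], size_range[2])
    tw <- runif(n, size_range[1], size_range[2])
    ang <- runif(n, params$angle_range[1], params$angle_range[2])
    br <- runif(n, params$brightness_range[1], params$brightness_range[2])
    cx <- runif(n, 0, W); cy <- runif(n, 0, H)
    data.frame(layer = layer, kind = kind, target_h = th, target_w = tw,
               brightness = br, angle = ang, center_x = cx, center_y = cy,
               is_red = is_red, pair = NA_integer_)
  }

  bg <- draw_rows(n_bg, "background_leaf", "leaf", params$leaf_size_range)
  red <- stats::runif(n_fruit) < params$p_red_apple
  fruit <- draw_rows(n_fruit, "fruit", ifelse(red, "fruit_red", "fruit_green"),
                     params$fruit_size_range, is_red = red)
  fg <- NULL
  if (n_fg > 0) {
    leaf <- draw_rows(n_fg, "foreground_leaf", "leaf", params$leaf_size_range)
    leaf$pair <- seq_len(n_fg)
    sh_th <- runif(n_fg, params$leaf_size_range[1], params$leaf_size_range[2])
    sh_tw <- runif(n_fg, params$leaf_size_range[1], params$leaf_size_range[2])
    sh_ang <- runif(n_fg, params$angle_range[1], params$angle_range[2])
    off_r <- runif(n_fg, params$shadow_offset_range[1], params$shadow_offset_range[2])
    off_t <- runif(n_fg, 0, 2 * pi)
    shadow <- data.frame(layer = "shadow", kind = "shadow", target_h = sh_th,
                         target_w = sh_tw, brightness = NA_real_, angle = sh_ang,
                         center_x = leaf$center_x + off_r * cos(off_t),
                         center_y = leaf$center_y + off_r * sin(off_t),
                         is_red = NA, pair = seq_len(n_fg))
    ord <- as.vector(rbind(seq_len(n_fg), n_fg + seq_len(n_fg)))
    fg <- rbind(shadow, leaf)[ord, ]
  }
  out <- rbind(bg, fruit, fg)
  dims <- t(mapply(transformed_dims, out$target_h, out$target_w, out$angle))
  out$pos_x <- round(out$center_x - dims[, 2] / 2)
  out$pos_y <- round(out$center_y - dims[, 1] / 2)
  rownames(out) <- NULL
  out
}

#' Geometrically and photometrically transform a sprite
#'
#' Resamples the sprite to `target_h x target_w` (anisotropic scaling),
#' rotates it by `angle` degrees about its center (footprint transformed
#' identically, nearest-neighbor sampling), and multiplies pixel
#' intensities by `brightness / 100`, clamped to \[0, 1\]. The identity
#' placement (native size, angle 0, brightness 100) returns the sprite
#' unchanged.
#'
#' @param spr A `Sprite`.
#' @param placement A list or one-row data frame with `target_h`,
#'   `target_w`, `angle` and optionally `brightness` (percent).
#' @return A transformed `Sprite` sized to the rotated bounding box.
#' @export
transform_sprite <- function(spr, placement) {
  th <- as.numeric(placement$target_h); tw <- as.numeric(placement$target_w)
  ang <- as.numeric(placement$angle)
  br <- placement$brightness
  br <- if (is.null(br) || is.na(br)) 100 else as.numeric(br)
  h0 <- dim(spr$pixels)[1]; w0 <- dim(spr$pixels)[2]
  if (th == h0 && tw == w0 && ang == 0) {
    px <- if (br == 100) spr$pixels else clamp(spr$pixels * br / 100, 0, 1)
    out <- spr; out$pixels <- px
    return(out)
  }
  d <- transformed_dims(th, tw, ang)
  Hp <- d[["h"]]; Wp <- d[["w"]]
  rad <- ang * pi / 180
  g <- center_grids(Hp, Wp)
  du <- g$x - Wp / 2; dv <- g$y - Hp / 2
  # rotate output coords back by -angle, then unscale into source pixels
  xs <- cos(rad) * du + sin(rad) * dv
  ys <- -sin(rad) * du + cos(rad) * dv
  ix <- floor(xs * (w0 / tw) + w0 / 2)
  iy <- floor(ys * (h0 / th) + h0 / 2)
  valid <- ix >= 0 & ix < w0 & iy >= 0 & iy < h0
  lin <- (ix * h0 + iy + 1)[valid]  # column-major index into h0 x w0
  fp <- matrix(FALSE, Hp, Wp)
  fp[valid] <- spr$footprint[lin]
  if (!any(fp)) stop("degenerate transform: empty footprint", call. = FALSE)
  px <- array(0, c(Hp, Wp, 3))
  scale_f <- br / 100
  for (k in 1:3) {
    ch <- matrix(0, Hp, Wp)
    ch[valid] <- spr$pixels[, , k][lin]
    ch[!fp] <- 0
    px[, , k] <- clamp(ch * scale_f, 0, 1)
  }
  out <- list(pixels = px, footprint = fp, kind = spr$kind)
  class(out) <- "Sprite"
  out
}

#' Derive a shadow sprite from a leaf
#'
#' The shadow's footprint is the leaf footprint under an independently
#' drawn aspect/scale/angle transform (sizes from `leaf_size_range`, angle
#' from `angle_range`); its compositing semantics are multiplicative
#' darkening of underlying pixels by `shadow_luminance_factor`.
#' Consumes the caller's RNG stream.
#'
#' @param leaf_sprite A leaf `Sprite`.
#' @param params A `GenerationParams` object.
#' @return A `Sprite` of kind `"shadow"` with a `factor` attribute.
#' @export
make_shadow <- function(leaf_sprite, params) {
  ot_assert(inherits(leaf_sprite, "Sprite") && leaf_sprite$kind == "leaf",
            "make_shadow needs a leaf sprite")
  pl <- list(target_h = runif(1, params$leaf_size_range[1], params$leaf_size_range[2]),
             target_w = runif(1, params$leaf_size_range[1], params$leaf_size_range[2]),
             angle = runif(1, params$angle_range[1], params$angle_range[2]),
             brightness = 100)
  tr <- transform_sprite(leaf_sprite, pl)
  out <- list(pixels = tr$pixels * 0, footprint = tr$footprint, kind = "shadow")
  class(out) <- "Sprite"
  attr(out, "factor") <- params$shadow_luminance_factor
  out
}

# Overlap of a sprite pasted at (pos_x, pos_y) with the canvas; NULL if none.
paste_region <- function(pos_x, pos_y, sh, sw, H, W) {
  if (pos_y + sh < 1 || pos_y + 1 > H || pos_x + sw < 1 || pos_x + 1 > W) return(NULL)
  dst_r <- max(1L, pos_y + 1L):min(H, pos_y + sh)
  dst_c <- max(1L, pos_x + 1L):min(W, pos_x + sw)
  list(dst_r = dst_r, dst_c = dst_c,
       src_r = dst_r - pos_y, src_c = dst_c - pos_x)
}


# Canvas-sized logical mask of a sprite footprint pasted at (pos_x, pos_y).
footprint_on_canvas <- function(footprint, pos_x, pos_y, H, W) {
  m <- matrix(FALSE, H, W)
  reg <- paste_region(pos_x, pos_y, nrow(footprint), ncol(footprint), H, W)
  if (!is.null(reg)) m[reg$dst_r, reg$dst_c] <- footprint[reg$src_r, reg$src_c, drop = FALSE]
  m
}

split_assets <- function(assets) {
  kinds <- vapply(assets, function(a) a$kind, character(1))
  list(red = assets[kinds == "fruit_red"], green = assets[kinds == "fruit_green"],
       leaf = assets[kinds == "leaf"], background = assets[kinds == "background"])
}

#' Compose one canopy scene with amodal per-fruit masks
#'
#' Paints layers in order background, background leaves, fruits, then
#' (shadow, foreground leaf) pairs. Records each fruit's amodal mask as its
#' full transformed footprint before any foreground occlusion, and its
#' visible mask as the footprint pixels not covered by any later-painted
#' opaque layer. Deterministic for fixed (assets, params, seed). Fruits
#' whose on-canvas footprint is clipped below `min_onframe_fraction` of the
#' unclipped footprint are redrawn at a new position.
#'
#' @param assets List of `Sprite`s: at least one fruit of each color, at
#'   least one leaf, and one background at least canvas-sized.
#' @param params A `GenerationParams` object.
#' @param seed Integer seed for this scene.
#' @param placements Optional pre-built placement data frame (as from
#'   [sample_placements()]); when supplied the random placement step is
#'   skipped (used to construct deterministic scenes in tests).
#' @return A `CompositeSample`: list with `image` (h x w x 3 array),
#'   `instances` (list of `FruitInstance`: `instance_id`, `amodal_mask`,
#'   `visible_mask`, `bbox`, `center`, `is_red`), `params_used`,
#'   `seed_used`, `placements`.
#' @export
compose_scene <- function(assets, params, seed, placements = NULL) {
  validate_params(params)
  ak <- split_assets(assets)
  ot_assert(length(ak$red) >= 1 && length(ak$green) >= 1,
            "assets must contain at least one fruit of each color")
  ot_assert(length(ak$leaf) >= 1, "assets must contain at least one leaf")
  ot_assert(length(ak$background) >= 1, "assets must contain one background")
  bg <- ak$background[[1]]
  H <- params$canvas_size[1]; W <- params$canvas_size[2]
  ot_assert(dim(bg$pixels)[1] >= H && dim(bg$pixels)[2] >= W,
            "background smaller than canvas")
  with_seed(seed, {
    pl <- if (is.null(placements)) sample_placements(params) else placements
    # per-channel canvases: painting by region subassignment in this
    # environment avoids copying the whole canvas on every paste
    ch <- list(bg$pixels[seq_len(H), seq_len(W), 1],
               bg$pixels[seq_len(H), seq_len(W), 2],
               bg$pixels[seq_len(H), seq_len(W), 3])
    paint_opaque <- function(tr, pos_x, pos_y) {
      reg <- paste_region(pos_x, pos_y, nrow(tr$footprint), ncol(tr$footprint), H, W)
      if (is.null(reg)) return(invisible(NULL))
      fp <- tr$footprint[reg$src_r, reg$src_c, drop = FALSE]
      if (!any(fp)) return(invisible(NULL))
      for (k in 1:3) {
        sub <- ch[[k]][reg$dst_r, reg$dst_c, drop = FALSE]
        src <- tr$pixels[reg$src_r, reg$src_c, k]
        sub[fp] <- src[fp]
        ch[[k]][reg$dst_r, reg$dst_c] <<- sub
      }
      invisible(NULL)
    }
    paint_multiply <- function(fp_full, pos_x, pos_y, factor) {
      reg <- paste_region(pos_x, pos_y, nrow(fp_full), ncol(fp_full), H, W)
      if (is.null(reg)) return(invisible(NULL))
      fp <- fp_full[reg$src_r, reg$src_c, drop = FALSE]
      if (!any(fp)) return(invisible(NULL))
      for (k in 1:3) {
        sub <- ch[[k]][reg$dst_r, reg$dst_c, drop = FALSE]
        sub[fp] <- sub[fp] * factor
        ch[[k]][reg$dst_r, reg$dst_c] <<- sub
      }
      invisible(NULL)
    }
    instances <- list()
    amodals <- list()
    visibles <- list()
    # clear the pixels of `fp` (pasted at pos) from every visible mask,
    # touching only the overlap region
    occlude_visibles <- function(fp, pos_x, pos_y, upto = length(visibles)) {
      reg <- paste_region(pos_x, pos_y, nrow(fp), ncol(fp), H, W)
      if (is.null(reg) || upto < 1) return(invisible(NULL))
      fpc <- fp[reg$src_r, reg$src_c, drop = FALSE]
      if (!any(fpc)) return(invisible(NULL))
      for (j in seq_len(upto)) {
        sub <- visibles[[j]][reg$dst_r, reg$dst_c, drop = FALSE]
        if (!any(sub & fpc)) next
        sub[fpc] <- FALSE
        visibles[[j]][reg$dst_r, reg$dst_c] <<- sub
      }
      invisible(NULL)
    }
    leaf_asset_for_pair <- list()
    for (i in seq_len(nrow(pl))) {
      row <- pl[i, ]
      fixed_asset <- if (!is.null(row$asset) && !is.na(row$asset)) assets[[row$asset]] else NULL
      if (row$layer == "background_leaf") {
        spr <- if (!is.null(fixed_asset)) fixed_asset else ak$leaf[[sample.int(length(ak$leaf), 1)]]
        tr <- transform_sprite(spr, row)
        paint_opaque(tr, row$pos_x, row$pos_y)
      } else if (row$layer == "fruit") {
        pool <- if (isTRUE(row$is_red)) ak$red else ak$green
        spr <- if (!is.null(fixed_asset)) fixed_asset else pool[[sample.int(length(pool), 1)]]
        tr <- transform_sprite(spr, row)
        total <- sum(tr$footprint)
        pos_x <- row$pos_x; pos_y <- row$pos_y
        d <- dim(tr$footprint)
        for (try in seq_len(100)) {
          amodal <- footprint_on_canvas(tr$footprint, pos_x, pos_y, H, W)
          if (sum(amodal) >= params$min_onframe_fraction * total) break
          cx <- runif(1, 0, W); cy <- runif(1, 0, H)
          pos_x <- round(cx - d[2] / 2); pos_y <- round(cy - d[1] / 2)
        }
        # later fruits occlude earlier ones
        occlude_visibles(tr$footprint, pos_x, pos_y)
        paint_opaque(tr, pos_x, pos_y)
        k <- length(instances) + 1L
        instances[[k]] <- list(instance_id = k, is_red = isTRUE(row$is_red))
        amodals[[k]] <- amodal
        visibles[[k]] <- amodal
      } else if (row$layer == "shadow") {
        spr <- if (!is.null(fixed_asset)) fixed_asset else ak$leaf[[sample.int(length(ak$leaf), 1)]]
        leaf_asset_for_pair[[as.character(row$pair)]] <- spr
        tr <- transform_sprite(spr, row)
        if (params$shadow_luminance_factor < 1) {
          paint_multiply(tr$footprint, row$pos_x, row$pos_y,
                         params$shadow_luminance_factor)
        }
      } else if (row$layer == "foreground_leaf") {
        spr <- if (!is.null(fixed_asset)) fixed_asset else leaf_asset_for_pair[[as.character(row$pair)]]
        if (is.null(spr)) spr <- ak$leaf[[sample.int(length(ak$leaf), 1)]]
        tr <- transform_sprite(spr, row)
        paint_opaque(tr, row$pos_x, row$pos_y)
        occlude_visibles(tr$footprint, row$pos_x, row$pos_y)
      }
    }
    instances <- lapply(seq_along(instances), function(k) {
      inst <- instances[[k]]
      inst$amodal_mask <- amodals[[k]]
      inst$visible_mask <- visibles[[k]]
      inst$bbox <- mask_bbox(inst$amodal_mask)
      inst$center <- mask_centroid(inst$amodal_mask)
      class(inst) <- "FruitInstance"
      inst
    })
    canvas <- array(c(ch[[1]], ch[[2]], ch[[3]]), c(H, W, 3))
    structure(list(image = canvas, instances = instances,
                   params_used = params, seed_used = as.integer(seed),
                   placements = pl),
              class = "CompositeSample")
  })
}

#' @export
print.CompositeSample <- function(x, ...) {
  cat(sprintf("<CompositeSample %dx%d, %d fruit instances, seed %d>\n",
              dim(x$image)[1], dim(x$image)[2], length(x$instances), x$seed_used))
  invisible(x)
}

#' Generate a training dataset of composite scenes
#'
#' Writes `n_samples` composite PNG images with per-instance amodal binary
#' mask PNGs, a VIA polygon annotation project, a COCO-style instances
#' JSON, and a manifest. Per-sample seeds are derived from `params$seed`
#' with [split_seed()], so the dataset is order-independent, reproducible,
#' and resumable: samples whose files already exist are loaded rather than
#' regenerated.
#'
#' @param params A `GenerationParams` object (`params$seed` is the master
#'   seed).
#' @param n_samples Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param assets Optional sprite list; procedural fixture assets are
#'   generated when omitted.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(params, n_samples, out_dir, assets = NULL) {
  validate_params(params)
  ot_assert(n_samples >= 1, "n_samples must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ot_assert(dir.exists(out_dir), "cannot create output directory")
  if (is.null(assets)) {
    assets <- generate_fixture_assets(split_seed(params$seed, 0),
                                      background_size = params$canvas_size + 64L)
  }
  entries <- list()
  via_anns <- list()
  coco_images <- list(); coco_anns <- list(); ann_id <- 0L
  H <- params$canvas_size[1]; W <- params$canvas_size[2]
  for (i in seq_len(n_samples)) {
    seed_i <- split_seed(params$seed, i)
    img_name <- sprintf("sample_%04d.png", i)
    img_path <- file.path(out_dir, img_name)
    mask_glob <- sprintf("sample_%04d_mask_", i)
    existing <- sort(list.files(out_dir, pattern = paste0("^", mask_glob)))
    if (file.exists(img_path) && length(existing) > 0) {
      masks <- lapply(file.path(out_dir, existing), read_mask_png)
      mask_files <- existing
    } else {
      sample_i <- compose_scene(assets, params, seed_i)
      write_image_png(sample_i$image, img_path)
      masks <- lapply(sample_i$instances, function(inst) inst$amodal_mask)
      mask_files <- sprintf("%s%02d.png", mask_glob, seq_along(masks))
      for (k in seq_along(masks)) write_mask_png(masks[[k]], file.path(out_dir, mask_files[k]))
    }
    coco_images[[i]] <- list(id = i, file_name = img_name, width = W, height = H)
    for (k in seq_along(masks)) {
      poly <- mask_to_polygon(masks[[k]])
      via_anns[[length(via_anns) + 1]] <- polygon_annotation(img_name, poly[, 1], poly[, 2])
      bb <- mask_bbox(masks[[k]])
      ann_id <- ann_id + 1L
      coco_anns[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = 1,
        segmentation = list(as.vector(t(poly))),
        area = sum(masks[[k]]),
        bbox = c(bb[["x_min"]], bb[["y_min"]],
                 bb[["x_max"]] - bb[["x_min"]], bb[["y_max"]] - bb[["y_min"]]),
        iscrowd = 0)
    }
    entries[[i]] <- list(image = img_name, masks = as.list(mask_files),
                         n_instances = length(masks), seed = seed_i)
  }
  write_via(via_anns, file.path(out_dir, "annotations_via.json"))
  coco <- list(images = coco_images, annotations = coco_anns,
               categories = list(list(id = 1, name = "apple")))
  jsonlite::write_json(coco, file.path(out_dir, "annotations_coco.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(n_samples = n_samples, master_seed = params$seed,
                   params = unclass(params), entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
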