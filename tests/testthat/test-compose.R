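test_that("sample_placements honors ranges and layer ordering", {
  p <- small_params()
  for (seed in 1:25) {
    pl <- sample_placements(p, seed = seed)
    n_fruit <- sum(pl$layer == "fruit")
    expect_true(n_fruit >= p$n_fruits_range[1] && n_fruit <= p$n_fruits_range[2])
    expect_equal(sum(pl$layer == "background_leaf"), p$n_background_leaves)
    expect_equal(sum(pl$layer == "foreground_leaf"), p$n_foreground_leaves)
    expect_equal(sum(pl$layer == "shadow"), p$n_foreground_leaves)
    # order: background leaves, fruits, then alternating shadow/leaf pairs
    expect_equal(unique(pl$layer),
                 c("background_leaf", "fruit", "shadow", "foreground_leaf"))
    fg <- pl[pl$layer %in% c("shadow", "foreground_leaf"), ]
    expect_equal(fg$layer, rep(c("shadow", "foreground_leaf"), p$n_foreground_leaves))
    expect_equal(fg$pair, rep(seq_len(p$n_foreground_leaves), each = 2))
    fr <- pl[pl$layer == "fruit", ]
    expect_true(all(fr$target_h >= p$fruit_size_range[1] &
                      fr$target_h <= p$fruit_size_range[2]))
    expect_true(all(fr$target_w >= p$fruit_size_range[1] &
                      fr$target_w <= p$fruit_size_range[2]))
    expect_true(all(pl$angle >= p$angle_range[1] & pl$angle <= p$angle_range[2]))
    expect_true(all(fr$center_x >= 0 & fr$center_x <= p$canvas_size[2] &
                      fr$center_y >= 0 & fr$center_y <= p$canvas_size[1]))
  }
})

test_that("degenerate red-apple probabilities behave", {
  p1 <- small_params(p_red_apple = 1)
  pl <- sample_placements(p1, seed = 4)
  expect_true(all(pl$is_red[pl$layer == "fruit"]))
  p0 <- small_params(p_red_apple = 0)
  pl0 <- sample_placements(p0, seed = 4)
  expect_true(!any(pl0$is_red[pl0$layer == "fruit"]))
})

test_that("red fraction and fruit counts match configured distributions", {
  # statistics over the generator's own sampling path; >= 1000 fruits
  p <- generation_params(seed = 1)
  set.seed(101)
  reds <- logical(0); counts <- integer(0)
  while (length(reds) < 1000) {
    pl <- sample_placements(p)
    fr <- pl$layer == "fruit"
    counts <- c(counts, sum(fr))
    reds <- c(reds, pl$is_red[fr])
  }
  ci <- binom_ci99(length(reds), 0.553)
  expect_gte(sum(reds), ci[["lo"]])
  expect_lte(sum(reds), ci[["hi"]])
  expect_true(all(counts >= 3 & counts <= 8))
  # counts roughly uniform over 3..8: each bin within multinomial 99% bounds
  n <- length(counts)
  bin_ci <- binom_ci99(n, 1 / 6)
  tab <- tabulate(counts - 2, nbins = 6)
  expect_true(all(tab >= bin_ci[["lo"]] & tab <= bin_ci[["hi"]]))
})

test_that("transform_sprite: identity, brightness, rotation area", {
  assets <- small_assets()
  spr <- assets[[1]]
  h0 <- nrow(spr$footprint); w0 <- ncol(spr$footprint)
  idt <- transform_sprite(spr, list(target_h = h0, target_w = w0,
                                    angle = 0, brightness = 100))
  expect_identical(idt$pixels, spr$pixels)
  expect_identical(idt$footprint, spr$footprint)

  # brightness 60 on a uniform sprite scales intensities by 0.6
  uni <- sprite(array(0.5, c(10, 10, 3)), matrix(TRUE, 10, 10), "leaf")
  dim6 <- transform_sprite(uni, list(target_h = 10, target_w = 10,
                                     angle = 0, brightness = 60))
  expect_equal(dim6$pixels, array(0.3, c(10, 10, 3)))
  # clamping at 120% of bright pixels
  bright <- sprite(array(0.9, c(5, 5, 3)), matrix(TRUE, 5, 5), "leaf")
  clip <- transform_sprite(bright, list(target_h = 5, target_w = 5,
                                        angle = 0, brightness = 120))
  expect_equal(clip$pixels, array(1, c(5, 5, 3)))

  # rotation preserves footprint area within 2% (asymmetric footprint)
  for (ang in c(90, 45, -30, 137)) {
    rot <- transform_sprite(spr, list(target_h = h0, target_w = w0,
                                      angle = ang, brightness = 100))
    expect_lt(abs(sum(rot$footprint) - sum(spr$footprint)) / sum(spr$footprint), 0.02)
  }
  # anisotropic scaling reaches the target size
  sc <- transform_sprite(spr, list(target_h = 30, target_w = 60, angle = 0,
                                   brightness = 100))
  expect_equal(dim(sc$footprint), c(30, 60))
})

test_that("make_shadow varies geometry and darkens multiplicatively", {
  p <- small_params()
  leaf <- small_assets()[[6]]
  set.seed(5)
  sh <- make_shadow(leaf, p)
  expect_equal(sh$kind, "shadow")
  expect_equal(attr(sh, "factor"), p$shadow_luminance_factor)
  # with an unequal aspect draw the footprint area differs from the source
  areas <- replicate(10, sum(make_shadow(leaf, p)$footprint))
  expect_gt(length(unique(areas)), 1)
  expect_true(any(areas != sum(leaf$footprint)))
})

test_that("shadow compositing: factor 1 is identity, factor 0.5 halves", {
  assets <- small_assets()
  # identical placements, shadows enabled vs factor 1.0
  p_half <- small_params(shadow_luminance_factor = 0.5, n_background_leaves = 0)
  p_one <- small_params(shadow_luminance_factor = 1.0, n_background_leaves = 0)
  pl <- sample_placements(p_half, seed = 9)
  s_half <- compose_scene(assets, p_half, seed = 9, placements = pl)
  s_one <- compose_scene(assets, p_one, seed = 9, placements = pl)
  ratio <- s_half$image / s_one$image
  # pixels are either untouched (ratio 1) or darkened to exactly half
  expect_true(all(abs(ratio - 1) < 1e-12 | abs(ratio - 0.5) < 1e-12, na.rm = TRUE))
  expect_true(any(abs(ratio - 0.5) < 1e-12, na.rm = TRUE))
})

test_that("compose_scene: no occluders means visible equals amodal", {
  assets <- small_assets()
  p <- small_params(n_foreground_leaves = 0, n_background_leaves = 0,
                    shadow_luminance_factor = 1.0)
  # fixed placements: two fruits far apart, no mutual overlap
  pl <- data.frame(layer = "fruit", kind = c("fruit_red", "fruit_green"),
                   target_h = c(40, 40), target_w = c(40, 40),
                   brightness = 100, angle = 0,
                   center_x = c(50, 140), center_y = c(50, 140),
                   is_red = c(TRUE, FALSE), pair = NA_integer_,
                   pos_x = c(30, 120), pos_y = c(30, 120))
  s <- compose_scene(assets, p, seed = 1, placements = pl)
  expect_length(s$instances, 2)
  for (inst in s$instances) {
    expect_identical(inst$visible_mask, inst$amodal_mask)
  }
})

test_that("overlapping fruits: later fruit occludes earlier, amodal keeps overlap", {
  assets <- small_assets()
  p <- small_params(n_foreground_leaves = 0, n_background_leaves = 0,
                    shadow_luminance_factor = 1.0, min_onframe_fraction = 0)
  pl <- data.frame(layer = "fruit", kind = c("fruit_red", "fruit_green"),
                   target_h = 40, target_w = 40, brightness = 100, angle = 0,
                   center_x = c(90, 110), center_y = c(96, 96),
                   is_red = c(TRUE, FALSE), pair = NA_integer_,
                   pos_x = c(70, 90), pos_y = c(76, 76))
  s <- compose_scene(assets, p, seed = 1, placements = pl)
  first <- s$instances[[1]]; second <- s$instances[[2]]
  overlap <- first$amodal_mask & second$amodal_mask
  expect_gt(sum(overlap), 0)
  expect_true(!any(first$visible_mask & overlap))   # earlier loses overlap
  expect_true(all(first$amodal_mask[overlap]))      # amodal keeps it
  expect_identical(second$visible_mask, second$amodal_mask)
})

test_that("visible is a subset of amodal with tight bboxes (default-style scene)", {
  assets <- small_assets()
  p <- small_params()
  for (seed in c(3, 14)) {
    s <- compose_scene(assets, p, seed = seed)
    for (inst in s$instances) {
      expect_true(!any(inst$visible_mask & !inst$amodal_mask))
      expect_gt(sum(inst$amodal_mask), 0)
      expect_equal(inst$bbox, mask_bbox(inst$amodal_mask))
    }
  }
})

test_that("layering: removing foreground leaves and shadows re-exposes fruit pixels", {
  assets <- small_assets()
  p <- small_params(shadow_luminance_factor = 1.0)
  pl <- sample_placements(p, seed = 21)
  full <- compose_scene(assets, p, seed = 21, placements = pl)
  bare_pl <- pl[!pl$layer %in% c("shadow", "foreground_leaf"), ]
  bare <- compose_scene(assets, p, seed = 21, placements = bare_pl)
  # on originally-visible fruit pixels the two renders agree exactly
  for (k in seq_along(full$instances)) {
    vis <- full$instances[[k]]$visible_mask
    for (chan in 1:3) {
      expect_identical(full$image[, , chan][vis], bare$image[, , chan][vis])
    }
    # without occluders the visible mask can only grow
    expect_true(all(bare$instances[[k]]$visible_mask[vis]))
  }
})

test_that("compose_scene is deterministic per (assets, params, seed)", {
  assets <- small_assets()
  p <- small_params()
  s1 <- compose_scene(assets, p, seed = 8)
  s2 <- compose_scene(assets, p, seed = 8)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$instances, s2$instances)
  s3 <- compose_scene(assets, p, seed = 9)
  expect_false(identical(s1$image, s3$image))
})

test_that("generate_dataset writes a reproducible, resumable dataset", {
  p <- small_params(seed = 77)
  assets <- small_assets()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(p, 4, d1, assets = assets)
  m2 <- generate_dataset(p, 4, d2, assets = assets)
  expect_length(m1$entries, 4)
  for (e in m1$entries) expect_gte(e$n_instances, p$n_fruits_range[1])
  # byte-identical masks across independent runs
  for (e in m1$entries) {
    for (mf in e$masks) {
      expect_identical(readBin(file.path(d1, mf), "raw", 1e6),
                       readBin(file.path(d2, mf), "raw", 1e6))
    }
  }
  expect_true(file.exists(file.path(d1, "annotations_via.json")))
  expect_true(file.exists(file.path(d1, "annotations_coco.json")))
  # resuming does not rewrite existing images
  before <- file.mtime(file.path(d1, m1$entries[[1]]$image))
  m1b <- generate_dataset(p, 4, d1, assets = assets)
  expect_identical(file.mtime(file.path(d1, m1$entries[[1]]$image)), before)
  expect_length(m1b$entries, 4)
  # the COCO export describes every instance
  coco <- jsonlite::fromJSON(file.path(d1, "annotations_coco.json"),
                             simplifyVector = FALSE)
  expect_length(coco$images, 4)
  expect_equal(length(coco$annotations),
               sum(vapply(m1$entries, function(e) e$n_instances, integer(1))))
  expect_equal(coco$categories[[1]]$name, "apple")
})

test_that("paper-scale configuration passes validation", {
  p <- generation_params()  # 1088 x 1088, Table-style defaults
  expect_silent(validate_params(p))
  expect_equal(p$canvas_size, c(1088L, 1088L))
  # invalid configurations are rejected
  expect_error(generation_params(fruit_size_range = c(190, 140)), "interval")
  expect_error(generation_params(p_red_apple = 1.2), "configuration error")
  expect_error(generation_params(canvas_size = c(0, 10)), "positive")
})

test_that("compose_scene fails when the background is smaller than the canvas", {
  assets <- small_assets()  # 224 x 224 background
  p <- generation_params(canvas_size = c(512, 512), fruit_size_range = c(30, 44),
                         leaf_size_range = c(14, 20), n_fruits_range = c(2, 3),
                         n_foreground_leaves = 2, n_background_leaves = 0)
  expect_error(compose_scene(assets, p, seed = 1), "background smaller")
})
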