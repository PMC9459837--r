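#' Scene generation parameters
#'
#' Parameter set controlling the cut-and-paste canopy compositor. Defaults
#' are the published generation settings for apple canopies: 1088 x 1088 px
#' canvases containing 3-8 fruits of 140-190 px, 80 foreground leaves of
#' 60-90 px, a background leaf count drawn from {0, 100, 200, 400},
#' brightness jitter 60-120%, rotation -90..90 degrees, and a 55.3%
#' probability that a fruit is a red apple. Height and width are sampled
#' independently within the size range, which realizes the aspect-ratio
#' variation without a separate parameter.
#'
#' @param canvas_size `c(height, width)` of the composite canvas in px.
#' @param fruit_size_range Fruit target height/width interval in px.
#' @param leaf_size_range Leaf target height/width interval in px.
#' @param brightness_range Brightness multiplier interval in percent.
#' @param angle_range Rotation interval in degrees.
#' @param n_fruits_range Inclusive integer interval for fruits per image.
#' @param n_foreground_leaves Number of leaves painted over the fruit layer.
#' @param n_background_leaves Number of leaves painted under the fruit
#'   layer, or `NULL` to draw uniformly from `background_leaf_choices` per
#'   scene.
#' @param background_leaf_choices Candidate background leaf counts.
#' @param p_red_apple Probability that a fruit placement is a red apple.
#' @param shadow_luminance_factor Multiplicative darkening applied under a
#'   leaf's shadow footprint, in (0, 1]; 1 disables shadows.
#' @param shadow_offset_range Pixel interval for the random displacement of
#'   a shadow from its leaf.
#' @param min_onframe_fraction Fruits whose on-canvas (amodal) footprint
#'   falls below this fraction of the unclipped footprint are redrawn.
#' @param seed Master seed for dataset generation.
#' @return A validated `GenerationParams` list.
#' @export
generation_params <- function(canvas_size = c(1088, 1088),
                              fruit_size_range = c(140, 190),
                              leaf_size_range = c(60, 90),
                              brightness_range = c(60, 120),
                              angle_range = c(-90, 90),
                              n_fruits_range = c(3, 8),
                              n_foreground_leaves = 80,
                              n_background_leaves = NULL,
                              background_leaf_choices = c(0, 100, 200, 400),
                              p_red_apple = 0.553,
                              shadow_luminance_factor = 0.55,
                              shadow_offset_range = c(10, 30),
                              min_onframe_fraction = 0.25,
                              seed = 42) {
  p <- list(canvas_size = as.integer(canvas_size),
            fruit_size_range = fruit_size_range,
            leaf_size_range = leaf_size_range,
            brightness_range = brightness_range,
            angle_range = angle_range,
            n_fruits_range = as.integer(n_fruits_range),
            n_foreground_leaves = as.integer(n_foreground_leaves),
            n_background_leaves = if (is.null(n_background_leaves)) NULL else as.integer(n_background_leaves),
            background_leaf_choices = as.integer(background_leaf_choices),
            p_red_apple = p_red_apple,
            shadow_luminance_factor = shadow_luminance_factor,
            shadow_offset_range = shadow_offset_range,
            min_onframe_fraction = min_onframe_fraction,
            seed = as.integer(seed))
  class(p) <- "GenerationParams"
  validate_params(p)
  p
}

#' Validate generation parameters
#' @param p A `GenerationParams` object.
#' @return `p`, invisibly; stops with a configuration error otherwise.
#' @export
validate_params <- function(p) {
  chk_interval <- function(r, name, strict = TRUE) {
    ot_assert(length(r) == 2 && all(is.finite(r)) &&
                (if (strict) r[1] < r[2] else r[1] <= r[2]),
              sprintf("configuration error: %s must be an ordered interval", name))
  }
  ot_assert(length(p$canvas_size) == 2 && all(p$canvas_size > 0),
            "configuration error: canvas dimensions must be positive")
  chk_interval(p$fruit_size_range, "fruit_size_range")
  chk_interval(p$leaf_size_range, "leaf_size_range")
  chk_interval(p$brightness_range, "brightness_range")
  chk_interval(p$angle_range, "angle_range")
  chk_interval(p$n_fruits_range, "n_fruits_range", strict = FALSE)
  ot_assert(p$n_fruits_range[1] >= 1, "configuration error: n_fruits_range must be >= 1")
  ot_assert(p$n_foreground_leaves >= 0, "configuration error: n_foreground_leaves must be >= 0")
  ot_assert(is.null(p$n_background_leaves) || p$n_background_leaves >= 0,
            "configuration error: n_background_leaves must be >= 0")
  ot_assert(p$p_red_apple >= 0 && p$p_red_apple <= 1,
            "configuration error: p_red_apple must be in [0, 1]")
  ot_assert(p$shadow_luminance_factor > 0 && p$shadow_luminance_factor <= 1,
            "configuration error: shadow_luminance_factor must be in (0, 1]")
  ot_assert(p$min_onframe_fraction >= 0 && p$min_onframe_fraction <= 1,
            "configuration error: min_onframe_fraction must be in [0, 1]")
  invisible(p)
}

#' Read/write generation parameters as YAML
#' @param path YAML file path.
#' @return A `GenerationParams` object.
#' @export
read_params_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(generation_params))
  vals <- vals[intersect(names(vals), known)]
  do.call(generation_params, vals)
}

#' @rdname read_params_yaml
#' @param p A `GenerationParams` object.
#' @export
write_params_yaml <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}
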