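# Per-frame fruit detections. A Detection is one observed fruit in one
# frame: contour polygon, bounding box, center, radius and capture date.
# The oracle derives detections from synthetic ground truth (amodal or
# visible masks) with controllable corruption, standing in for a trained
# instance-segmentation model. Any callable mapping (image, date) to a
# list of Detections satisfies the tracker's detector-adapter contract.

#' Construct a detection
#'
#' @param contour Two-column (x, y) vertex matrix.
#' @param bbox `c(x_min, y_min, x_max, y_max)`, half-open.
#' @param center `c(x, y)` pixel coordinates.
#' @param radius Radius estimate in px (> 0).
#' @param capture_date A `Date`.
#' @param score Confidence in \[0, 1\].
#' @return A `Detection` object.
#' @export
detection <- function(contour, bbox, center, radius, capture_date, score = 1) {
  ot_assert(radius > 0, "radius must be positive")
  ot_assert(score >= 0 && score <= 1, "score must be in [0, 1]")
  structure(list(contour = contour, bbox = bbox, center = center,
                 radius = radius, capture_date = as.Date(capture_date),
                 score = score),
            class = "Detection")
}

#' @export
print.Detection <- function(x, ...) {
  cat(sprintf("<Detection %s r=%.1f center=(%.1f, %.1f) score=%.2f>\n",
              format(x$capture_date), x$radius, x$center[1], x$center[2], x$score))
  invisible(x)
}

#' Derive a detection from a binary mask
#'
#' Uses the largest 4-connected component: contour is its outer boundary
#' trace, bbox the tight box, center the mask centroid, and radius the
#' equivalent-circle radius `sqrt(area / pi)` (rotation-invariant and
#' stable under partial contour jitter). `radius_method = "bbox"` instead
#' uses half the mean of the bounding-box height and width.
#'
#' @param mask Non-empty logical matrix.
#' @param capture_date Capture date of the frame.
#' @param radius_method `"area"` (default) or `"bbox"`.
#' @return A `Detection` with score 1.
#' @export
detection_from_mask <- function(mask, capture_date,
                                radius_method = c("area", "bbox")) {
  ot_assert(any(mask), "empty mask")
  radius_method <- match.arg(radius_method)
  comp <- largest_component(mask)
  contour <- mask_to_polygon(comp)
  bbox <- mask_bbox(comp)
  center <- mask_centroid(comp)
  radius <- if (radius_method == "area") sqrt(sum(comp) / pi)
            else mean(c(bbox[["x_max"]] - bbox[["x_min"]],
                        bbox[["y_max"]] - bbox[["y_min"]])) / 2
  detection(contour, bbox, center, radius, capture_date)
}

#' Corruption settings for the detection oracle
#'
#' @param drop_prob Probability that a true fruit yields no detection.
#' @param spurious_rate Expected false detections per frame (Poisson).
#' @param contour_jitter Std dev (px) of Gaussian noise added to contour
#'   vertices.
#' @param radius_bias Std dev of the multiplicative radius error (the
#'   contour is rescaled about its centroid by `1 + N(0, radius_bias)`).
#' @param seed Integer seed; corruption is deterministic per (seed, frame).
#' @return A `CorruptionSpec` object.
#' @export
corruption_spec <- function(drop_prob = 0, spurious_rate = 0,
                            contour_jitter = 0, radius_bias = 0, seed = 1) {
  ot_assert(drop_prob >= 0 && drop_prob <= 1, "drop_prob must be in [0, 1]")
  ot_assert(spurious_rate >= 0 && contour_jitter >= 0 && radius_bias >= 0,
            "rates must be non-negative")
  structure(list(drop_prob = drop_prob, spurious_rate = spurious_rate,
                 contour_jitter = contour_jitter, radius_bias = radius_bias,
                 seed = as.integer(seed)),
            class = "CorruptionSpec")
}

# Rebuild a detection from a (possibly corrupted) contour polygon: bbox,
# center and radius are recomputed from the polygon itself.
detection_from_contour <- function(contour, capture_date, score = 1) {
  m <- polygon_raw_moments(contour)
  area <- m[["m00"]]
  center <- c(x = m[["m10"]] / area, y = m[["m01"]] / area)
  bbox <- c(x_min = min(contour[, 1]), y_min = min(contour[, 2]),
            x_max = max(contour[, 1]), y_max = max(contour[, 2]))
  detection(contour, bbox, center, sqrt(area / pi), capture_date, score)
}

#' Oracle detections from a composite sample
#'
#' Emulates a perfect hidden-region detector by converting each fruit
#' instance's amodal mask (or visible mask in `"modal"` mode) into a
#' detection, then applies the corruption spec: instance drops, contour
#' vertex jitter, multiplicative radius bias, and spurious elliptical
#' detections. Deterministic for a fixed `(spec$seed, sample$seed_used)`.
#'
#' @param sample A `CompositeSample`.
#' @param spec A `CorruptionSpec`.
#' @param capture_date Capture date assigned to the detections.
#' @param mode `"amodal"` (default) or `"modal"`.
#' @return List of `Detection` (with a `truth_id` attribute on each
#'   non-spurious detection naming the source instance).
#' @export
oracle_detect <- function(sample, spec = corruption_spec(),
                          capture_date = as.Date("2016-07-01"),
                          mode = c("amodal", "modal")) {
  mode <- match.arg(mode)
  frame_seed <- split_seed(spec$seed, sample$seed_used %% 65536)
  with_seed(frame_seed, {
    dets <- list()
    for (inst in sample$instances) {
      if (stats::runif(1) < spec$drop_prob) next
      mask <- if (mode == "amodal") inst$amodal_mask else inst$visible_mask
      if (!any(mask)) next
      det <- detection_from_mask(mask, capture_date)
      contour <- det$contour
      if (spec$contour_jitter > 0) {
        contour <- contour + matrix(stats::rnorm(length(contour), 0, spec$contour_jitter),
                                    ncol = 2)
      }
      if (spec$radius_bias > 0) {
        s <- 1 + stats::rnorm(1, 0, spec$radius_bias)
        s <- max(s, 0.05)
        ctr <- matrix(det$center, nrow(contour), 2, byrow = TRUE)
        contour <- ctr + (contour - ctr) * s
      }
      det <- if (spec$contour_jitter > 0 || spec$radius_bias > 0) {
        detection_from_contour(contour, capture_date)
      } else det
      attr(det, "truth_id") <- inst$instance_id
      dets[[length(dets) + 1]] <- det
    }
    n_spur <- if (spec$spurious_rate > 0) stats::rpois(1, spec$spurious_rate) else 0L
    H <- dim(sample$image)[1]; W <- dim(sample$image)[2]
    for (s in seq_len(n_spur)) {
      cx <- stats::runif(1, 0.1 * W, 0.9 * W); cy <- stats::runif(1, 0.1 * H, 0.9 * H)
      rx <- stats::runif(1, 10, 40); ry <- stats::runif(1, 10, 40)
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      contour <- cbind(cx + rx * cos(th), cy + ry * sin(th))
      dets[[length(dets) + 1]] <- detection_from_contour(contour, capture_date,
                                                         score = stats::runif(1, 0.3, 0.9))
    }
    dets
  })
}

#' Write/read detections as JSON Lines
#'
#' One JSON object per line with fields `contour` (list of \[x, y\]),
#' `bbox`, `center`, `radius`, `date` (ISO-8601) and `score`. This format
#' is both the oracle output and the tracker input.
#'
#' @param detections List of `Detection`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_detections_jsonl <- function(detections, path) {
  lines <- vapply(detections, function(d) {
    jsonlite::toJSON(list(contour = unname(apply(d$contour, 1, c, simplify = FALSE)),
                          bbox = unname(as.list(d$bbox)),
                          center = unname(as.list(d$center)),
                          radius = d$radius,
                          date = format(d$capture_date, "%Y-%m-%d"),
                          score = d$score),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    contour <- if (is.matrix(o$contour)) o$contour else do.call(rbind, o$contour)
    colnames(contour) <- c("x", "y")
    detection(contour = contour,
              bbox = stats::setNames(o$bbox, c("x_min", "y_min", "x_max", "y_max")),
              center = stats::setNames(o$center, c("x", "y")),
              radius = o$radius, capture_date = as.Date(o$date), score = o$score)
  })
}
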