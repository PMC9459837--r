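# Instance-segmentation and growth-accuracy metrics:
#   precision = TP / (TP + FP)        recall = TP / (TP + FN)
#   IoU       = |CA intersect PA| / |CA union PA|
# where CA is the correct (annotated) area and PA the predicted area, plus
# MAPE (as a fraction), Pearson correlation and linear-regression R^2, and
# the per-day filtered vs. averaged IoU of tracked fruits.

#' Intersection over union of two masks
#'
#' Pixel-count IoU. Undefined (error) when both masks are empty.
#'
#' @param ca,pa Logical matrices of identical size (correct and predicted
#'   areas), or a list with elements `CA`/`PA` as `ca`.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(ca, pa = NULL) {
  if (is.list(ca) && is.null(pa)) { pa <- ca$PA; ca <- ca$CA }
  ot_assert(all(dim(ca) == dim(pa)), "masks must share raster dimensions")
  u <- sum(ca | pa)
  ot_assert(u > 0, "IoU undefined: both masks empty")
  sum(ca & pa) / u
}

#' Match predicted to annotated masks
#'
#' One-to-one greedy matching by descending IoU: pairs with
#' IoU >= `iou_threshold` become true positives, unmatched predictions
#' false positives, unmatched annotations false negatives. The matching
#' criterion (greedy, threshold 0.5) is a package convention — exposed
#' here because no canonical rule is universal.
#'
#' @param predicted,annotated Lists of logical masks on a common raster.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @return List with `counts` (`MatchCounts`: TP, FP, FN), `matches` (data
#'   frame of prediction index, annotation index, IoU), `ious` (IoU of
#'   each matched pair).
#' @export
match_predictions <- function(predicted, annotated, iou_threshold = 0.5) {
  np <- length(predicted); na <- length(annotated)
  pairs <- NULL
  for (i in seq_len(np)) {
    for (j in seq_len(na)) {
      if (!any(predicted[[i]] & annotated[[j]])) next
      v <- iou(annotated[[j]], predicted[[i]])
      if (v >= iou_threshold) pairs <- rbind(pairs, data.frame(pred = i, ann = j, iou = v))
    }
  }
  matches <- data.frame(pred = integer(0), ann = integer(0), iou = numeric(0))
  if (!is.null(pairs) && nrow(pairs)) {
    ord <- order(-pairs$iou, pairs$pred, pairs$ann)
    used_p <- logical(np); used_a <- logical(na)
    for (k in ord) {
      i <- pairs$pred[k]; j <- pairs$ann[k]
      if (used_p[i] || used_a[j]) next
      used_p[i] <- TRUE; used_a[j] <- TRUE
      matches <- rbind(matches, pairs[k, ])
    }
  }
  tp <- nrow(matches)
  counts <- structure(list(TP = tp, FP = np - tp, FN = na - tp),
                      class = "MatchCounts")
  list(counts = counts, matches = matches, ious = matches$iou)
}

#' Precision and recall from match counts
#'
#' @param counts A `MatchCounts` (or list with TP, FP, FN).
#' @return `TP / (TP + FP)` resp. `TP / (TP + FN)`; `NA` with a warning
#'   when the denominator is zero (undefined metric).
#' @export
precision <- function(counts) {
  if (counts$TP + counts$FP == 0) { warning("precision undefined: no predictions"); return(NA_real_) }
  counts$TP / (counts$TP + counts$FP)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  if (counts$TP + counts$FN == 0) { warning("recall undefined: no annotations"); return(NA_real_) }
  counts$TP / (counts$TP + counts$FN)
}

#' Mean absolute percentage error
#'
#' Reported as a fraction (0.079 means 7.9%).
#'
#' @param truth,estimate Equal-length numeric series; truth values must be
#'   non-zero.
#' @return `mean(|estimate - truth| / |truth|)`.
#' @export
mape <- function(truth, estimate) {
  ot_assert(length(truth) == length(estimate) && length(truth) >= 1,
            "series must have equal positive length")
  ot_assert(all(truth != 0), "MAPE undefined: zero truth value")
  mean(abs(estimate - truth) / abs(truth))
}

#' Pearson correlation and linear-regression R-squared
#'
#' Pearson product-moment correlation of the two series and the R^2 of the
#' ordinary least-squares regression `estimate ~ truth` (for simple linear
#' regression R^2 = r^2).
#'
#' @param truth,estimate Numeric series of length >= 3, non-constant.
#' @return `list(r, r_squared)`; both `NA` with a warning for constant
#'   series.
#' @export
correlation_and_r2 <- function(truth, estimate) {
  ot_assert(length(truth) == length(estimate) && length(truth) >= 3,
            "need at least 3 paired values")
  if (stats::sd(truth) == 0 || stats::sd(estimate) == 0) {
    warning("correlation undefined for constant series")
    return(list(r = NA_real_, r_squared = NA_real_))
  }
  r <- stats::cor(truth, estimate)
  fit <- stats::lm(estimate ~ truth)
  list(r = r, r_squared = summary(fit)$r.squared)
}

#' Filtered vs. averaged IoU of tracked fruits
#'
#' For each tracked fruit and day: the filtered IoU is the IoU between the
#' detection the tracker assigned to that fruit and the fruit's
#' ground-truth mask; the averaged IoU is the mean IoU over ALL detections
#' whose mask overlaps that ground-truth mask that day. A day with no
#' overlapping detection yields missing values.
#'
#' @param assigned_masks Named-by-date list: for each day, the mask the
#'   tracker assigned to the fruit (or NULL if unassigned that day).
#' @param all_detection_masks Named-by-date list of lists of all detection
#'   masks in each day's frame.
#' @param truth_masks Named-by-date list of the fruit's ground-truth mask.
#' @return Data frame with columns `date`, `filtered_iou`, `averaged_iou`.
#' @export
filtered_vs_averaged_iou <- function(assigned_masks, all_detection_masks,
                                     truth_masks) {
  days <- names(truth_masks)
  res <- lapply(days, function(d) {
    gt <- truth_masks[[d]]
    assigned <- assigned_masks[[d]]
    filtered <- if (!is.null(assigned) && any(assigned & gt)) iou(gt, assigned) else NA_real_
    overlapping <- Filter(function(m) any(m & gt), all_detection_masks[[d]])
    averaged <- if (length(overlapping)) {
      mean(vapply(overlapping, function(m) iou(gt, m), numeric(1)))
    } else {
      message("no overlapping detection for day ", d)
      NA_real_
    }
    data.frame(date = d, filtered_iou = filtered, averaged_iou = averaged)
  })
  do.call(rbind, res)
}
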