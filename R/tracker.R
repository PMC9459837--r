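# Same-fruit identification across days. A candidate (track, detection)
# pair must pass three gates simultaneously:
#   distance:  ||center_det - center_last||_2 < 40 + 2 * T        (strict)
#   size:      100 * |r_det - r_last| / r_last <= 10 + 0.1 * T    (inclusive)
#   contour:   Hu-moment dissimilarity <= 0.05                    (inclusive)
# T is the per-track count of consecutive non-detect days: it grows by the
# elapsed calendar days whenever the track goes unmatched (relaxing the
# distance and size gates linearly) and resets to 0 on a match. All gates
# compare against the track's most recent observation.

#' Tracker configuration
#'
#' @param distance_base Distance gate intercept in px (default 40).
#' @param distance_slope Distance gate relaxation in px per non-detect day
#'   (default 2).
#' @param size_base Size gate intercept in percent (default 10).
#' @param size_slope Size gate relaxation in percent per non-detect day
#'   (default 0.1).
#' @param contour_max Maximum contour dissimilarity (default 0.05).
#' @param max_gap_days Terminate tracks whose T exceeds this; `Inf`
#'   (default) never terminates, matching unbounded T growth.
#' @param spawn_tracks Start a new track from every unmatched detection
#'   (default TRUE). Disable to restrict tracking to pre-selected target
#'   fruits.
#' @return A `TrackerConfig` object.
#' @export
tracker_config <- function(distance_base = 40, distance_slope = 2,
                           size_base = 10, size_slope = 0.1,
                           contour_max = 0.05, max_gap_days = Inf,
                           spawn_tracks = TRUE) {
  ot_assert(distance_base >= 0 && distance_slope >= 0 && size_base >= 0 &&
              size_slope >= 0, "gate parameters must be non-negative")
  ot_assert(contour_max > 0, "contour_max must be positive")
  structure(list(distance_base = distance_base, distance_slope = distance_slope,
                 size_base = size_base, size_slope = size_slope,
                 contour_max = contour_max, max_gap_days = max_gap_days,
                 spawn_tracks = spawn_tracks),
            class = "TrackerConfig")
}

#' Start a track from a detection
#'
#' @param track_id Integer id.
#' @param det The founding `Detection`.
#' @return A `Track` with T = 0 and state `"active"`.
#' @export
new_track <- function(track_id, det) {
  structure(list(track_id = as.integer(track_id),
                 observations = list(det),
                 T = 0, last_eval_date = det$capture_date,
                 state = "active"),
            class = "Track")
}

#' @export
print.Track <- function(x, ...) {
  cat(sprintf("<Track %d: %d observations, T=%g, %s>\n",
              x$track_id, length(x$observations), x$T, x$state))
  invisible(x)
}

last_observation <- function(track) {
  ot_assert(length(track$observations) >= 1, "track has no observations")
  track$observations[[length(track$observations)]]
}

#' Tracker gates
#'
#' `distance_gate` passes iff the Euclidean distance between the detection
#' center and the track's last observed center is strictly less than
#' `distance_base + distance_slope * T`. `size_gate` passes iff the radius
#' variability `100 * |r_det - r_last| / r_last` is within (inclusive)
#' `size_base + size_slope * T` percent. `contour_gate` passes iff the
#' Hu-moment [shape_dissimilarity()] between the last observed contour and
#' the detection contour is at most (inclusive) `contour_max`.
#'
#' @param track A `Track` with at least one observation.
#' @param det A `Detection`.
#' @param cfg A `TrackerConfig`.
#' @return Logical.
#' @export
distance_gate <- function(track, det, cfg) {
  prev <- last_observation(track)
  d <- sqrt(sum((det$center - prev$center)^2))
  d < cfg$distance_base + cfg$distance_slope * track$T
}

#' @rdname distance_gate
#' @export
size_gate <- function(track, det, cfg) {
  prev <- last_observation(track)
  ot_assert(prev$radius > 0, "non-positive reference radius")
  variability <- 100 * abs(det$radius - prev$radius) / prev$radius
  variability <= cfg$size_base + cfg$size_slope * track$T
}

#' @rdname distance_gate
#' @export
contour_gate <- function(track, det, cfg) {
  prev <- last_observation(track)
  shape_dissimilarity(prev$contour, det$contour) <= cfg$contour_max
}

#' Match one frame of detections against the active tracks
#'
#' Candidate pairs are the (track, detection) pairs passing all three
#' gates. A one-to-one assignment is chosen greedily by ascending center
#' distance, with ties broken by lower shape dissimilarity and then lower
#' track id. Assigned tracks append the detection and reset T to 0;
#' unassigned tracks increment T by the calendar days elapsed since their
#' last evaluation; unassigned detections spawn new tracks when
#' `cfg$spawn_tracks` is TRUE; tracks whose T exceeds `cfg$max_gap_days`
#' are terminated.
#'
#' @param tracks List of `Track`.
#' @param detections List of `Detection` sharing a capture date later than
#'   every track's last observation.
#' @param date Frame capture date.
#' @param cfg A `TrackerConfig`.
#' @param next_id First id for newly spawned tracks (default: one past the
#'   current maximum).
#' @return List with `tracks` (updated) and `assignment` (data frame of
#'   matched `track_id`, `detection_index`, `distance`, `dissimilarity`).
#' @export
match_frame <- function(tracks, detections, date, cfg, next_id = NULL) {
  date <- as.Date(date)
  active <- which(vapply(tracks, function(t) t$state == "active", logical(1)))
  for (i in active) {
    ot_assert(date > last_observation(tracks[[i]])$capture_date,
              "out-of-order dates: frame not later than an existing observation")
  }
  if (is.null(next_id)) {
    next_id <- if (length(tracks)) max(vapply(tracks, function(t) t$track_id, integer(1))) + 1L else 1L
  }
  cand <- NULL
  for (i in active) {
    for (j in seq_along(detections)) {
      det <- detections[[j]]
      if (distance_gate(tracks[[i]], det, cfg) &&
          size_gate(tracks[[i]], det, cfg) &&
          contour_gate(tracks[[i]], det, cfg)) {
        prev <- last_observation(tracks[[i]])
        cand <- rbind(cand, data.frame(
          track = i, det = j,
          distance = sqrt(sum((det$center - prev$center)^2)),
          dissim = shape_dissimilarity(prev$contour, det$contour)))
      }
    }
  }
  assigned_track <- integer(0); assigned_det <- integer(0)
  assignment <- data.frame(track_id = integer(0), detection_index = integer(0),
                           distance = numeric(0), dissimilarity = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    ids <- vapply(cand$track, function(i) tracks[[i]]$track_id, integer(1))
    ord <- order(cand$distance, cand$dissim, ids)
    for (k in ord) {
      i <- cand$track[k]; j <- cand$det[k]
      if (i %in% assigned_track || j %in% assigned_det) next
      assigned_track <- c(assigned_track, i)
      assigned_det <- c(assigned_det, j)
      assignment <- rbind(assignment, data.frame(
        track_id = tracks[[i]]$track_id, detection_index = j,
        distance = cand$distance[k], dissimilarity = cand$dissim[k]))
    }
  }
  for (i in active) {
    if (i %in% assigned_track) {
      j <- assigned_det[match(i, assigned_track)]
      tracks[[i]]$observations <- c(tracks[[i]]$observations, list(detections[[j]]))
      tracks[[i]]$T <- 0
      tracks[[i]]$last_eval_date <- date
    } else {
      gap <- as.numeric(date - tracks[[i]]$last_eval_date)
      tracks[[i]]$T <- tracks[[i]]$T + gap
      tracks[[i]]$last_eval_date <- date
      if (tracks[[i]]$T > cfg$max_gap_days) tracks[[i]]$state <- "terminated"
    }
  }
  if (cfg$spawn_tracks) {
    for (j in setdiff(seq_along(detections), assigned_det)) {
      tracks[[length(tracks) + 1]] <- new_track(next_id, detections[[j]])
      next_id <- next_id + 1L
    }
  }
  list(tracks = tracks, assignment = assignment)
}

#' Track fruits through an ordered sequence of frames
#'
#' Folds [match_frame()] over per-date detection collections.
#'
#' @param frames List of `list(date, detections)` in strictly increasing
#'   date order (duplicate dates are an error).
#' @param cfg A `TrackerConfig`.
#' @param initial_detections Optional list of detections founding the
#'   initial tracks (the "targets" mode restricting tracking to selected
#'   fruits, typically with `spawn_tracks = FALSE` in `cfg`).
#' @return List of `Track` with full observation histories and an
#'   `assignments` attribute (per-frame assignment tables).
#' @export
track_sequence <- function(frames, cfg = tracker_config(),
                           initial_detections = NULL) {
  dates <- as.Date(vapply(frames, function(f) as.character(as.Date(f$date)), character(1)))
  ot_assert(!anyDuplicated(dates), "duplicate frame dates")
  ot_assert(all(diff(dates) > 0), "frames must be in strictly increasing date order")
  tracks <- list()
  if (!is.null(initial_detections)) {
    tracks <- lapply(seq_along(initial_detections),
                     function(i) new_track(i, initial_detections[[i]]))
  }
  assignments <- list()
  for (f in seq_along(frames)) {
    dets <- frames[[f]]$detections
    if (length(tracks) == 0 && cfg$spawn_tracks) {
      tracks <- lapply(seq_along(dets), function(j) new_track(j, dets[[j]]))
      n <- length(dets)
      assignments[[f]] <- data.frame(track_id = seq_len(n),
                                     detection_index = seq_len(n),
                                     distance = rep(0, n),
                                     dissimilarity = rep(0, n))
      next
    }
    res <- match_frame(tracks, dets, dates[f], cfg)
    tracks <- res$tracks
    assignments[[f]] <- res$assignment
  }
  attr(tracks, "assignments") <- assignments
  tracks
}

#' Per-fruit radius time series from a track
#'
#' @param track A `Track`.
#' @param reference_year Year whose April 1 anchors the elapsed-day axis
#'   (default: year of the first observation).
#' @return Data frame with columns `date`, `elapsed_day`, `radius_px`.
#' @export
track_radius_series <- function(track, reference_year = NULL) {
  dates <- as.Date(vapply(track$observations,
                          function(o) as.character(o$capture_date), character(1)))
  if (is.null(reference_year)) {
    reference_year <- as.integer(format(dates[1], "%Y"))
  }
  data.frame(date = dates,
             elapsed_day = vapply(dates, elapsed_days, numeric(1),
                                  reference_year = reference_year),
             radius_px = vapply(track$observations, function(o) o$radius, numeric(1)))
}

#' Serialize tracks to JSON / radius series to CSV
#'
#' @param tracks List of `Track`.
#' @param path Output JSON file.
#' @return The path, invisibly.
#' @export
write_tracks_json <- function(tracks, path) {
  out <- lapply(tracks, function(t) {
    list(track_id = t$track_id, T = t$T, state = t$state,
         observations = lapply(t$observations, function(o) {
           list(date = format(o$capture_date, "%Y-%m-%d"),
                center = unname(as.list(o$center)), radius = o$radius,
                score = o$score)
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracks_json
#' @param track A single `Track`.
#' @param reference_year Passed to [track_radius_series()].
#' @export
write_radius_series_csv <- function(track, path, reference_year = NULL) {
  utils::write.csv(track_radius_series(track, reference_year), path,
                   row.names = FALSE)
  invisible(path)
}
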