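cfg0 <- tracker_config()

track_at <- function(cx, cy, r, date = as.Date("2016-07-01"), T = 0, id = 1L) {
  t <- new_track(id, make_disc_detection(cx, cy, r, date))
  t$T <- T
  t
}

test_that("distance gate flips exactly at 40 + 2T (strict)", {
  tr <- track_at(100, 100, 20)
  day2 <- as.Date("2016-07-02")
  expect_true(distance_gate(tr, make_disc_detection(139.9, 100, 20, day2), cfg0))
  expect_false(distance_gate(tr, make_disc_detection(140, 100, 20, day2), cfg0))
  # T = 5: threshold 50
  tr5 <- track_at(100, 100, 20, T = 5)
  expect_true(distance_gate(tr5, make_disc_detection(149, 100, 20, day2), cfg0))
  expect_false(distance_gate(tr5, make_disc_detection(150, 100, 20, day2), cfg0))
  # identical centers pass for any T
  expect_true(distance_gate(tr, make_disc_detection(100, 100, 20, day2), cfg0))
})

test_that("size gate flips exactly at 10 + 0.1T percent (inclusive)", {
  tr <- track_at(100, 100, 50)
  day2 <- as.Date("2016-07-02")
  expect_true(size_gate(tr, make_disc_detection(100, 100, 55, day2), cfg0))    # 10.0%
  expect_false(size_gate(tr, make_disc_detection(100, 100, 55.1, day2), cfg0)) # 10.2%
  expect_true(size_gate(tr, make_disc_detection(100, 100, 50, day2), cfg0))
  # shrinkage is judged by the same symmetric variability
  expect_true(size_gate(tr, make_disc_detection(100, 100, 45, day2), cfg0))
  expect_false(size_gate(tr, make_disc_detection(100, 100, 44.9, day2), cfg0))
  # T = 10: threshold 11%
  tr10 <- track_at(100, 100, 50, T = 10)
  expect_true(size_gate(tr10, make_disc_detection(100, 100, 55.5, day2), cfg0))
  expect_false(size_gate(tr10, make_disc_detection(100, 100, 55.6, day2), cfg0))
})

test_that("contour gate is inclusive at the threshold", {
  day2 <- as.Date("2016-07-02")
  tr <- new_track(1L, detection(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                                c(0, 0, 10, 10), c(5, 5), 5,
                                as.Date("2016-07-01")))
  same <- detection(cbind(c(20, 30, 30, 20), c(0, 0, 10, 10)),
                    c(20, 0, 30, 10), c(25, 5), 5, day2)
  expect_true(contour_gate(tr, same, cfg0))  # D = 0
  thin <- detection(cbind(c(0, 40, 40, 0), c(0, 0, 4, 4)),
                    c(0, 0, 40, 4), c(20, 2), 7, day2)
  D <- shape_dissimilarity(tr$observations[[1]]$contour, thin$contour)
  expect_gt(D, 0.05)
  expect_false(contour_gate(tr, thin, cfg0))
  # inclusivity: a config whose threshold equals D passes; slightly
  # smaller fails
  cfg_eq <- tracker_config(contour_max = D)
  expect_true(contour_gate(tr, thin, cfg_eq))
  cfg_lt <- tracker_config(contour_max = D * (1 - 1e-9))
  expect_false(contour_gate(tr, thin, cfg_lt))
})

test_that("gate relaxation is monotone in T", {
  withr::local_seed(31)
  day2 <- as.Date("2016-07-02")
  for (rep in 1:20) {
    r0 <- runif(1, 20, 60)
    tr <- track_at(100, 100, r0)
    det <- make_disc_detection(100 + runif(1, 0, 80), 100, r0 * runif(1, 0.85, 1.15), day2)
    for (T1 in c(0, 3, 11)) {
      for (T2 in c(15, 40)) {
        tr$T <- T1; d1 <- distance_gate(tr, det, cfg0); s1 <- size_gate(tr, det, cfg0)
        tr$T <- T2; d2 <- distance_gate(tr, det, cfg0); s2 <- size_gate(tr, det, cfg0)
        if (d1) expect_true(d2)
        if (s1) expect_true(s2)
      }
    }
  }
})

test_that("match_frame assigns a unique passing candidate and resets T", {
  tr <- list(track_at(100, 100, 30))
  det <- make_disc_detection(105, 100, 30.5, as.Date("2016-07-02"))
  res <- match_frame(tr, list(det), as.Date("2016-07-02"), cfg0)
  expect_equal(nrow(res$assignment), 1)
  expect_equal(res$tracks[[1]]$T, 0)
  expect_length(res$tracks[[1]]$observations, 2)
})

test_that("T relaxation recovers a fruit just outside the base distance gate", {
  # day 1: detection 41 px away fails (threshold 40); T grows to 1;
  # day 2: same offset passes (threshold 42)
  tr <- list(track_at(100, 100, 30, date = as.Date("2016-07-01")))
  d1 <- make_disc_detection(141, 100, 30, as.Date("2016-07-02"))
  res1 <- match_frame(tr, list(d1), as.Date("2016-07-02"), cfg0,
                      next_id = 99L)
  expect_equal(nrow(res1$assignment), 0)
  expect_equal(res1$tracks[[1]]$T, 1)
  d2 <- make_disc_detection(141, 100, 30, as.Date("2016-07-03"))
  res2 <- match_frame(res1$tracks[1], list(d2), as.Date("2016-07-03"), cfg0)
  expect_equal(nrow(res2$assignment), 1)
  expect_equal(res2$tracks[[1]]$T, 0)
})

test_that("unmatched tracks accumulate T by elapsed calendar days", {
  tr <- list(track_at(100, 100, 30, date = as.Date("2016-07-01")))
  # next frame 4 days later with nothing nearby
  far <- make_disc_detection(500, 500, 30, as.Date("2016-07-05"))
  res <- match_frame(tr, list(far), as.Date("2016-07-05"),
                     tracker_config(spawn_tracks = FALSE))
  expect_equal(res$tracks[[1]]$T, 4)
  # termination beyond max_gap_days
  res2 <- match_frame(res$tracks, list(), as.Date("2016-07-20"),
                      tracker_config(spawn_tracks = FALSE, max_gap_days = 10))
  expect_equal(res2$tracks[[1]]$state, "terminated")
})

test_that("assignment is one-to-one and greedy matches exhaustive search", {
  withr::local_seed(23)
  day2 <- as.Date("2016-07-02")
  checked <- 0
  for (rep in 1:40) {
    nt <- sample(2:4, 1); nd <- sample(2:4, 1)
    tracks <- lapply(seq_len(nt), function(i)
      track_at(runif(1, 50, 250), runif(1, 50, 250), runif(1, 20, 40), id = i))
    dets <- lapply(seq_len(nd), function(j) {
      i <- ((j - 1) %% nt) + 1
      prev <- tracks[[i]]$observations[[1]]
      make_disc_detection(prev$center[["x"]] + runif(1, -30, 30),
                          prev$center[["y"]] + runif(1, -30, 30),
                          prev$radius * runif(1, 0.92, 1.08), day2)
    })
    feasible <- matrix(FALSE, nt, nd)
    for (i in seq_len(nt)) for (j in seq_len(nd)) {
      feasible[i, j] <- distance_gate(tracks[[i]], dets[[j]], cfg0) &&
        size_gate(tracks[[i]], dets[[j]], cfg0) &&
        contour_gate(tracks[[i]], dets[[j]], cfg0)
    }
    res <- match_frame(tracks, dets, day2, cfg0)
    a <- res$assignment
    # one-to-one always
    expect_false(anyDuplicated(a$track_id) > 0)
    expect_false(anyDuplicated(a$detection_index) > 0)
    # T bookkeeping: T == 0 exactly for assigned tracks
    for (i in seq_len(nt)) {
      expect_equal(res$tracks[[i]]$T == 0, i %in% a$track_id)
    }
    best <- enumerate_assignments(feasible)
    if (length(best) == 1) {  # unique gate-feasible maximal assignment
      checked <- checked + 1
      got <- cbind(a$track_id, a$detection_index)
      got <- got[order(got[, 1]), , drop = FALSE]
      expect_equal(unname(got), unname(best[[1]]))
    }
  }
  expect_gt(checked, 5)
})

test_that("track_sequence recovers growing fruits without identity switches", {
  dates <- as.Date("2016-07-01") + 0:9
  centers <- list(c(100, 100), c(300, 120), c(180, 320))
  radii0 <- c(30, 36, 42)
  frames <- lapply(seq_along(dates), function(f) {
    dets <- lapply(seq_along(centers), function(i) {
      make_disc_detection(centers[[i]][1], centers[[i]][2],
                          radii0[i] * 1.01^(f - 1), dates[f])
    })
    list(date = dates[f], detections = dets)
  })
  tracks <- track_sequence(frames, cfg0)
  expect_length(tracks, 3)
  for (t in tracks) {
    expect_length(t$observations, 10)
    expect_equal(t$T, 0)
    # strictly increasing dates and monotone radii
    obs_dates <- as.Date(vapply(t$observations,
                                function(o) as.character(o$capture_date),
                                character(1)))
    expect_true(all(diff(obs_dates) > 0))
    # each track stays at one fruit (no switches): constant center
    cx <- vapply(t$observations, function(o) o$center[["x"]], numeric(1))
    expect_equal(length(unique(cx)), 1)
  }
  # a radius series ready for growth fitting
  series <- track_radius_series(tracks[[1]])
  expect_equal(nrow(series), 10)
  expect_true(all(diff(series$elapsed_day) == 1))
})

test_that("a dropped frame is re-acquired through the T mechanism", {
  dates <- as.Date("2016-07-01") + 0:9
  frames <- lapply(seq_along(dates), function(f) {
    dets <- if (f == 5) list() else {
      list(make_disc_detection(100, 100, 30 * 1.01^(f - 1), dates[f]))
    }
    list(date = dates[f], detections = dets)
  })
  tracks <- track_sequence(frames, cfg0)
  expect_length(tracks, 1)
  expect_length(tracks[[1]]$observations, 9)
  expect_equal(tracks[[1]]$T, 0)  # re-acquired after the gap
})

test_that("degenerate tracker inputs", {
  expect_length(track_sequence(list(), cfg0), 0)
  frames <- list(list(date = as.Date("2016-07-01"), detections = list()),
                 list(date = as.Date("2016-07-02"), detections = list()))
  expect_length(track_sequence(frames, cfg0), 0)
  dup <- list(list(date = as.Date("2016-07-01"), detections = list()),
              list(date = as.Date("2016-07-01"), detections = list()))
  expect_error(track_sequence(dup, cfg0), "duplicate")
  tr <- list(track_at(1, 1, 5, date = as.Date("2016-07-02")))
  expect_error(match_frame(tr, list(), as.Date("2016-07-01"), cfg0),
               "out-of-order")
})

test_that("targets mode restricts tracking to the selected fruits", {
  dates <- as.Date("2016-07-01") + 0:4
  frames <- lapply(seq_along(dates), function(f) {
    list(date = dates[f],
         detections = list(make_disc_detection(100, 100, 30, dates[f]),
                           make_disc_detection(300, 300, 40, dates[f])))
  })
  init <- list(make_disc_detection(100, 100, 30, as.Date("2016-06-30")))
  tracks <- track_sequence(frames, tracker_config(spawn_tracks = FALSE),
                           initial_detections = init)
  expect_length(tracks, 1)
  expect_length(tracks[[1]]$observations, 6)  # founder + 5 frames
})
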