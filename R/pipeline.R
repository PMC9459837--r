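# End-to-end pipeline: generate -> detect (oracle) -> track -> fit ->
# evaluate, plus a demo scenario exercising every stage from one seed.
# The demo synthesizes a multi-day scene sequence in which each fruit's
# sprite scale follows a logistic schedule with fixed positions and a
# small downward drift (emulating the hanging of heavier fruit), runs
# oracle detection, tracking, per-track growth fits and real-time
# predictions, and writes a structured, byte-reproducible report.

#' Pipeline configuration
#'
#' @param generation A `GenerationParams`.
#' @param corruption A `CorruptionSpec`.
#' @param tracker A `TrackerConfig`.
#' @param fit_min_points Minimum observations before a growth fit.
#' @param fit_min_span_days Minimum observation span (days) before a
#'   real-time prediction is emitted.
#' @param iou_threshold True-positive IoU threshold for evaluation.
#' @param run_seed Master seed for the run.
#' @param output_root Output directory.
#' @param demo Demo-scenario settings: `n_days`, `n_fruits`, `n_leaves`,
#'   `rate_per_day` (logistic c, per day), `asymptote_range` (sprite
#'   target-size asymptote, px), `drift_px_per_day` (downward position
#'   drift), `start_date`, `min_separation_px`.
#' @return A `PipelineConfig` object.
#' @export
pipeline_config <- function(generation = generation_params(canvas_size = c(768, 768)),
                            corruption = corruption_spec(),
                            tracker = tracker_config(),
                            fit_min_points = 5, fit_min_span_days = 14,
                            iou_threshold = 0.5,
                            run_seed = 7, output_root = tempfile("orchardtrack_run_"),
                            demo = list()) {
  demo_defaults <- list(n_days = 30, n_fruits = 4, n_leaves = 6,
                        rate_per_day = -0.08, asymptote_range = c(150, 190),
                        drift_px_per_day = 0.5, start_date = "2016-07-01",
                        min_separation_px = 250)
  demo <- utils::modifyList(demo_defaults, demo)
  validate_params(generation)
  structure(list(generation = generation, corruption = corruption,
                 tracker = tracker, fit_min_points = fit_min_points,
                 fit_min_span_days = fit_min_span_days,
                 iou_threshold = iou_threshold, run_seed = as.integer(run_seed),
                 output_root = output_root, demo = demo),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; the `generation`,
#' `corruption`, `tracker` and `demo` sections mirror their constructors.
#'
#' @param path YAML file.
#' @param overrides Named list applied over the file's values (CLI flags).
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, overrides)
  args <- list()
  if (!is.null(vals$generation)) {
    gen <- vals$generation
    gen <- gen[intersect(names(gen), names(formals(generation_params)))]
    args$generation <- do.call(generation_params, gen)
  }
  if (!is.null(vals$corruption)) {
    args$corruption <- do.call(corruption_spec,
      vals$corruption[intersect(names(vals$corruption), names(formals(corruption_spec)))])
  }
  if (!is.null(vals$tracker)) {
    args$tracker <- do.call(tracker_config,
      vals$tracker[intersect(names(vals$tracker), names(formals(tracker_config)))])
  }
  for (k in c("fit_min_points", "fit_min_span_days", "iou_threshold",
              "run_seed", "output_root", "demo")) {
    if (!is.null(vals[[k]])) args[[k]] <- vals[[k]]
  }
  do.call(pipeline_config, args)
}

# Place n points on the canvas with pairwise separation >= min_sep.
spaced_positions <- function(n, H, W, min_sep, margin) {
  pts <- matrix(NA_real_, 0, 2)
  for (tries in seq_len(5000)) {
    p <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
    if (nrow(pts) == 0 || all(sqrt(colSums((t(pts) - p)^2)) >= min_sep)) {
      pts <- rbind(pts, p)
      if (nrow(pts) == n) return(pts)
    }
  }
  stop("could not place ", n, " fruits with separation ", min_sep,
       " on a ", W, "x", H, " canvas", call. = FALSE)
}

# Build the placement table of one demo frame: the scheduled fruits at
# their (drifted) fixed positions plus per-frame random foreground leaves.
demo_frame_placements <- function(fruits, day_index, cfg, leaf_assets_idx) {
  gp <- cfg$generation
  H <- gp$canvas_size[1]; W <- gp$canvas_size[2]
  rows <- lapply(seq_len(nrow(fruits)), function(i) {
    s <- fruits$size[i]
    cy <- fruits$cy[i] + cfg$demo$drift_px_per_day * (day_index - 1)
    data.frame(layer = "fruit", kind = fruits$kind[i], target_h = s, target_w = s,
               brightness = 100, angle = 0, center_x = fruits$cx[i], center_y = cy,
               is_red = fruits$is_red[i], pair = NA_integer_,
               pos_x = round(fruits$cx[i] - s / 2), pos_y = round(cy - s / 2),
               asset = fruits$asset[i])
  })
  fruit_rows <- do.call(rbind, rows)
  n_leaf <- cfg$demo$n_leaves
  if (n_leaf > 0) {
    th <- runif(n_leaf, gp$leaf_size_range[1], gp$leaf_size_range[2])
    tw <- runif(n_leaf, gp$leaf_size_range[1], gp$leaf_size_range[2])
    ang <- runif(n_leaf, gp$angle_range[1], gp$angle_range[2])
    br <- runif(n_leaf, gp$brightness_range[1], gp$brightness_range[2])
    cx <- runif(n_leaf, 0, W); cy <- runif(n_leaf, 0, H)
    dims <- t(mapply(transformed_dims, th, tw, ang))
    leaf_rows <- data.frame(layer = "foreground_leaf", kind = "leaf",
                            target_h = th, target_w = tw, brightness = br,
                            angle = ang, center_x = cx, center_y = cy,
                            is_red = NA, pair = seq_len(n_leaf),
                            pos_x = round(cx - dims[, 2] / 2),
                            pos_y = round(cy - dims[, 1] / 2),
                            asset = sample(leaf_assets_idx, n_leaf, replace = TRUE))
    rbind(fruit_rows, leaf_rows)
  } else fruit_rows
}

#' Run the end-to-end demo pipeline
#'
#' Synthesizes `demo$n_days` daily frames in which each of `demo$n_fruits`
#' fruits grows along a logistic size schedule anchored at its inflection
#' point on day 1, runs oracle detection (with the configured corruption),
#' the three-gate tracker, per-track growth fits and real-time
#' predictions, and evaluates identity accuracy, asymptote recovery and
#' MAPE between the scheduled and tracked radii. Fully reproducible per
#' `run_seed`: the report JSON is byte-identical across runs.
#'
#' @param config A `PipelineConfig`.
#' @param write_plots Also write diagnostic PDF plots (default TRUE).
#' @return The run report (list), invisibly; written to
#'   `output_root/report.json` along with per-stage artifacts.
#' @export
run_demo <- function(config = pipeline_config(), write_plots = TRUE) {
  cfg <- config
  out <- cfg$output_root
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  gp <- cfg$generation
  H <- gp$canvas_size[1]; W <- gp$canvas_size[2]
  stage <- "setup"
  report <- tryCatch({
    assets <- generate_fixture_assets(split_seed(cfg$run_seed, 0),
                                      n_fruit = max(4, cfg$demo$n_fruits),
                                      background_size = gp$canvas_size + 64L)
    kinds <- vapply(assets, function(a) a$kind, character(1))
    leaf_idx <- which(kinds == "leaf")
    fruit_idx <- which(kinds %in% c("fruit_red", "fruit_green"))

    # Scheduled world: fixed positions, logistic size schedules. kappa maps
    # a sprite's target size to its equivalent-circle radius, so scheduled
    # radii are known without rendering.
    fruits <- with_seed(split_seed(cfg$run_seed, 1), {
      pos <- spaced_positions(cfg$demo$n_fruits, H, W,
                              cfg$demo$min_separation_px,
                              margin = max(gp$fruit_size_range) / 2 + 10)
      idx <- fruit_idx[((seq_len(cfg$demo$n_fruits) - 1) %% length(fruit_idx)) + 1]
      data.frame(
        fruit_id = seq_len(cfg$demo$n_fruits),
        asset = idx, kind = kinds[idx],
        is_red = kinds[idx] == "fruit_red",
        cx = pos[, 1], cy = pos[, 2],
        asymptote = runif(cfg$demo$n_fruits, cfg$demo$asymptote_range[1],
                          cfg$demo$asymptote_range[2]))
    })
    fruits$kappa <- vapply(fruits$asset, function(a) {
      spr <- assets[[a]]
      sqrt(sum(spr$footprint) / pi) / nrow(spr$footprint)
    }, numeric(1))

    dates <- as.Date(cfg$demo$start_date) + seq_len(cfg$demo$n_days) - 1
    ref_year <- as.integer(format(dates[1], "%Y"))
    Xs <- vapply(dates, elapsed_days, numeric(1), reference_year = ref_year)
    cc <- cfg$demo$rate_per_day
    # inflection on day 1: size(X) = asymptote / (1 + exp(cc * (X - X[1])))
    schedule <- function(i, X) fruits$asymptote[i] / (1 + exp(cc * (X - Xs[1])))

    stage <- "generate+detect"
    frames <- vector("list", length(dates))
    for (f in seq_along(dates)) {
      fr <- fruits
      fr$size <- vapply(seq_len(nrow(fr)), function(i) schedule(i, Xs[f]), numeric(1))
      frame_seed <- split_seed(cfg$run_seed, 100 + f)
      sample_f <- with_seed(frame_seed, {
        pl <- demo_frame_placements(fr, f, cfg, leaf_idx)
        compose_scene(assets, gp, frame_seed, placements = pl)
      })
      dets <- oracle_detect(sample_f, cfg$corruption, capture_date = dates[f])
      write_detections_jsonl(dets, file.path(out, sprintf("detections_%s.jsonl", dates[f])))
      frames[[f]] <- list(date = dates[f], detections = dets)
    }

    stage <- "track"
    tracks <- track_sequence(frames, cfg$tracker)
    write_tracks_json(tracks, file.path(out, "tracks.json"))

    # identity accuracy: fraction of tracked observations whose true
    # instance id matches their track's majority id
    truth_of <- function(o) {
      ti <- attr(o, "truth_id")
      if (is.null(ti)) NA_integer_ else ti
    }
    obs_truth <- lapply(tracks, function(t) vapply(t$observations, truth_of, integer(1)))
    maj <- vapply(obs_truth, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_integer_)
      as.integer(names(sort(table(v), decreasing = TRUE))[1])
    }, integer(1))
    all_truth <- unlist(obs_truth)
    all_maj <- rep(maj, vapply(obs_truth, length, integer(1)))
    scored <- !is.na(all_truth)
    identity_accuracy <- if (any(scored)) mean(all_truth[scored] == all_maj[scored]) else NA_real_
    gap_episodes <- sum(vapply(tracks, function(t) t$T > 0, logical(1)))

    stage <- "fit"
    per_fruit <- list()
    mape_vals <- numeric(0)
    for (t in tracks) {
      ids <- vapply(t$observations, truth_of, integer(1))
      fid <- maj[[match(t$track_id, vapply(tracks, function(x) x$track_id, integer(1)))]]
      if (is.na(fid) || length(t$observations) < cfg$fit_min_points) next
      series <- track_radius_series(t, reference_year = ref_year)
      fit <- fit_growth_curve(series)
      write_fit_json(fit, file.path(out, sprintf("fit_track%02d.json", t$track_id)))
      i <- match(fid, fruits$fruit_id)
      sched_asym <- fruits$kappa[i] * fruits$asymptote[i]
      sched_radii <- fruits$kappa[i] *
        vapply(series$elapsed_day, function(x) schedule(i, x), numeric(1))
      m <- mape(sched_radii, series$radius_px)
      mape_vals <- c(mape_vals, m)
      rt <- realtime_predictions(series, cfg$fit_min_points, cfg$fit_min_span_days)
      utils::write.csv(rt, file.path(out, sprintf("realtime_track%02d.csv", t$track_id)),
                       row.names = FALSE)
      per_fruit[[length(per_fruit) + 1]] <- list(
        track_id = t$track_id, fruit_id = fid,
        n_observations = length(t$observations),
        recovered_a = fit$a, scheduled_asymptote = sched_asym,
        rel_error_a = abs(fit$a - sched_asym) / sched_asym,
        converged = fit$converged, mape_vs_schedule = m)
      if (write_plots) {
        grDevices::pdf(file.path(out, sprintf("growth_track%02d.pdf", t$track_id)),
                       width = 6, height = 4)
        graphics::plot(series$elapsed_day, series$radius_px, pch = 19,
                       xlab = "elapsed days from April 1",
                       ylab = "radius [px]",
                       main = sprintf("Track %d growth fit", t$track_id))
        xx <- seq(min(series$elapsed_day), max(series$elapsed_day) + 60, by = 1)
        graphics::lines(xx, growth_curve(xx, fit), col = "red3")
        graphics::abline(h = fit$a, lty = 2, col = "red3")
        grDevices::dev.off()
      }
    }

    stage <- "report"
    report <- list(
      run_seed = cfg$run_seed,
      n_days = cfg$demo$n_days, n_fruits = cfg$demo$n_fruits,
      corruption = unclass(cfg$corruption),
      tracker = unclass(cfg$tracker)[c("distance_base", "distance_slope",
                                       "size_base", "size_slope", "contour_max")],
      n_tracks = length(tracks),
      identity_accuracy = identity_accuracy,
      tracks_with_gaps = gap_episodes,
      mape_vs_schedule_mean = if (length(mape_vals)) mean(mape_vals) else NA_real_,
      max_rel_error_a = if (length(per_fruit)) max(vapply(per_fruit, function(p) p$rel_error_a, numeric(1))) else NA_real_,
      per_fruit = per_fruit)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, error = function(e) {
    stop(sprintf("demo pipeline failed at stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), out), call. = FALSE)
  })
  invisible(report)
}
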