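# Logistic fruit-radius growth model
#
#   Y(X) = a / (1 + b * exp(c * X)),   a > 0, b > 0, c < 0
#
# where X counts calendar days elapsed from April 1 of the detection year
# and Y is the fruit radius (px). With c < 0 the curve rises from
# a / (1 + b) toward the asymptote a, which serves as the harvest-radius
# prediction (the curve's convergence value).

#' Evaluate the logistic growth curve
#'
#' @param X Elapsed days (vector).
#' @param fit A `GrowthFit`, or a numeric `a` with `b`, `c` supplied.
#' @param b,c Coefficients when `fit` is the scalar `a`.
#' @return Radius values `a / (1 + b * exp(c * X))`.
#' @export
growth_curve <- function(X, fit, b = NULL, c = NULL) {
  if (is.numeric(fit) && !is.null(b)) fit <- list(a = fit, b = b, c = c)
  fit$a / (1 + fit$b * exp(fit$c * X))
}

#' Days elapsed from April 1 of the reference year
#'
#' April 1 maps to 0. Reports elsewhere apply a display offset of +1 where
#' a 1-based "elapsed days 1..227" axis is wanted (day 227 lands on
#' November 14 of a non-leap year).
#'
#' @param date A `Date` (or coercible).
#' @param reference_year Year whose April 1 is the origin (default: the
#'   year of `date`).
#' @return Integer day count (>= 0); dates before April 1 are an error.
#' @export
elapsed_days <- function(date, reference_year = NULL) {
  date <- as.Date(date)
  if (is.null(reference_year)) reference_year <- as.integer(format(date, "%Y"))
  origin <- as.Date(sprintf("%d-04-01", reference_year))
  d <- as.numeric(date - origin)
  ot_assert(all(d >= 0), "date before April 1 of the reference year")
  d
}

#' Construct a growth fit
#'
#' @param a Asymptotic radius (> 0).
#' @param b Shape offset (> 0).
#' @param c Rate per day (< 0 for a growing fruit).
#' @param rss Residual sum of squares.
#' @param n_points Number of fitted points.
#' @param converged Did the optimizer converge.
#' @param flags Character vector of diagnostic flags.
#' @return A `GrowthFit` object.
#' @export
growth_fit <- function(a, b, c, rss = NA_real_, n_points = NA_integer_,
                       converged = TRUE, flags = character(0)) {
  structure(list(a = a, b = b, c = c, rss = rss, n_points = n_points,
                 converged = converged, flags = flags),
            class = "GrowthFit")
}

#' @export
print.GrowthFit <- function(x, ...) {
  cat(sprintf("<GrowthFit a=%.4g b=%.4g c=%.4g rss=%.4g n=%d%s>\n",
              x$a, x$b, x$c, x$rss, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Fit the logistic growth curve by least squares
#'
#' Minimizes `sum((Y - a / (1 + b * exp(c * X)))^2)` over a > 0, b > 0,
#' c < 0, with bounds a in (max(Y), 50 max(Y)), b in (1e-6, 1e6),
#' c in (-1, -1e-6). Initialization: `a0 = 1.05 * max(Y)`; `log(b0)` and
#' `c0` from the linear regression of `log(a0 / Y - 1)` on X. Bounded
#' Gauss-Newton (`nls` "port") with an `optim` L-BFGS-B fallback;
#' non-convergence yields a flagged fit, not an exception.
#'
#' @param X Elapsed days, or a data frame with columns `elapsed_day` and
#'   `radius_px` (a tracker radius series) with `Y` missing.
#' @param Y Radii (> 0).
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative RSS convergence tolerance (default 1e-10).
#' @return A `GrowthFit`.
#' @export
fit_growth_curve <- function(X, Y = NULL, max_iter = 500, tol = 1e-10) {
  if (is.data.frame(X) && is.null(Y)) { Y <- X$radius_px; X <- X$elapsed_day }
  ot_assert(length(X) == length(Y), "X and Y lengths differ")
  ot_assert(length(X) >= 3, "insufficient points: need at least 3")
  ot_assert(length(unique(X)) >= 2, "insufficient points: need at least 2 distinct X")
  ot_assert(all(Y > 0), "radii must be positive")
  flags <- character(0)
  a0 <- 1.05 * max(Y)
  lo <- c(a = max(Y) * (1 + 1e-9), b = 1e-6, c = -1)
  hi <- c(a = 50 * max(Y), b = 1e6, c = -1e-6)
  z <- log(pmax(a0 / Y - 1, 1e-12))
  lmfit <- stats::lm(z ~ X)
  b0 <- clamp(exp(stats::coef(lmfit)[[1]]), lo[["b"]], hi[["b"]])
  c0 <- clamp(stats::coef(lmfit)[[2]], lo[["c"]], hi[["c"]])
  rss_of <- function(p) sum((Y - p[1] / (1 + p[2] * exp(p[3] * X)))^2)
  fit <- tryCatch({
    df <- data.frame(X = X, Y = Y)
    nl <- stats::nls(Y ~ a / (1 + b * exp(c * X)), data = df,
                     start = list(a = a0, b = b0, c = c0),
                     algorithm = "port", lower = lo, upper = hi,
                     control = stats::nls.control(maxiter = max_iter, tol = tol,
                                                  warnOnly = FALSE))
    p <- stats::coef(nl)
    list(p = p, converged = nl$convInfo$isConv)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    op <- stats::optim(c(a0, b0, c0), rss_of, method = "L-BFGS-B",
                       lower = lo, upper = hi,
                       control = list(maxit = max_iter, factr = 1e3))
    fit <- list(p = stats::setNames(op$par, c("a", "b", "c")),
                converged = op$convergence == 0)
    flags <- c(flags, "nls_failed")
  }
  p <- fit$p
  if (!fit$converged) flags <- c(flags, "non_convergent")
  if (stats::sd(Y) < 1e-8 * mean(Y)) flags <- c(flags, "degenerate_flat_series")
  if (p[["c"]] > hi[["c"]] * 1.0000001 || abs(p[["c"]] - hi[["c"]]) < 1e-12)
    flags <- c(flags, "rate_at_bound")
  growth_fit(p[["a"]], p[["b"]], p[["c"]], rss = rss_of(p),
             n_points = length(X), converged = fit$converged, flags = flags)
}

#' Predict the harvest radius from a growth fit
#'
#' The harvest-radius prediction is the curve's convergence value: for
#' c < 0, `Y(X) -> a` as X grows. A non-negative rate has no convergence
#' value and is an error.
#'
#' @param fit A `GrowthFit` with c < 0.
#' @return The asymptote `a`.
#' @export
predict_harvest_radius <- function(fit) {
  ot_assert(fit$c < 0, "undefined convergence: rate c must be negative")
  fit$a
}

#' Real-time per-day harvest-radius predictions
#'
#' For each observed day `d`, fits the growth curve on the observations
#' with X <= d and records the predicted harvest radius. Days with fewer
#' than `min_points` observations, spanning less than `min_span_days`, or
#' whose fit does not converge (or hits the rate bound) are recorded as
#' missing — suppressing the instability of very early prefixes.
#'
#' @param series Data frame with `elapsed_day` and `radius_px` (a tracker
#'   radius series), or `X`/`Y` via `...`.
#' @param min_points Minimum prefix size before predicting (default 5).
#' @param min_span_days Minimum X span before predicting (default 14).
#' @return Data frame with columns `day`, `predicted_harvest_radius`
#'   (NA where unavailable), `n_points`, `converged`.
#' @export
realtime_predictions <- function(series, min_points = 5, min_span_days = 14) {
  if (!is.data.frame(series)) series <- as.data.frame(series)
  if (nrow(series) == 0) {
    return(data.frame(day = numeric(0), predicted_harvest_radius = numeric(0),
                      n_points = integer(0), converged = logical(0)))
  }
  ord <- order(series$elapsed_day)
  X <- series$elapsed_day[ord]; Y <- series$radius_px[ord]
  days <- unique(X)
  res <- lapply(days, function(d) {
    sel <- X <= d
    n <- sum(sel)
    if (n < min_points || diff(range(X[sel])) < min_span_days) {
      return(data.frame(day = d, predicted_harvest_radius = NA_real_,
                        n_points = n, converged = NA))
    }
    f <- tryCatch(fit_growth_curve(X[sel], Y[sel]), error = function(e) NULL)
    ok <- !is.null(f) && f$converged && f$c < 0 && !("rate_at_bound" %in% f$flags)
    data.frame(day = d,
               predicted_harvest_radius = if (ok) predict_harvest_radius(f) else NA_real_,
               n_points = n, converged = isTRUE(ok))
  })
  do.call(rbind, res)
}

#' Calibrate relative predictions to physical units
#'
#' The pipeline's radii are relative (px). Multiplies all predictions by
#' `measured_radius / prediction(at_day)`, anchoring the curve to one
#' physical measurement so the whole prediction series is expressed in the
#' measurement's units.
#'
#' @param predictions Output of [realtime_predictions()].
#' @param measured_radius Physically measured radius at `at_day`.
#' @param at_day The day the measurement was taken; a prediction must
#'   exist there.
#' @return `predictions` with `predicted_harvest_radius` rescaled.
#' @export
calibrate_to_physical <- function(predictions, measured_radius, at_day) {
  i <- match(at_day, predictions$day)
  ot_assert(!is.na(i) && !is.na(predictions$predicted_harvest_radius[i]),
            "no prediction available at at_day")
  scale_f <- measured_radius / predictions$predicted_harvest_radius[i]
  predictions$predicted_harvest_radius <- predictions$predicted_harvest_radius * scale_f
  predictions
}

#' Write a growth fit as JSON
#' @param fit A `GrowthFit`.
#' @param path Output file.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(a = fit$a, b = fit$b, c = fit$c, rss = fit$rss,
                            n = fit$n_points, converged = fit$converged,
                            flags = fit$flags),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
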