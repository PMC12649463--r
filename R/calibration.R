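# Personalized mEAR threshold calibration: bisection of the threshold
# interval against a manual blink count on a calibration window.

#' Calibrate the blink-detection threshold by bisection
#'
#' Searches for the mEAR threshold at which the automatic blink count on a
#' calibration window (conventionally the first two minutes of a recording)
#' matches a manual count. Because the set of below-threshold frames grows
#' with the threshold, the interval is updated so that it brackets the
#' matching count: at the midpoint `mid = (lo + hi) / 2`, if the automatic
#' count is below the manual count the lower limit is raised (`lo <- mid`),
#' if above, the upper limit is lowered (`hi <- mid`). Iteration stops when
#' the counts match, the interval is narrower than `min_interval`, or
#' `max_iter` is reached. The blink count is not strictly monotone in the
#' threshold (adjacent runs can merge), so if no visited midpoint matches
#' exactly the result is the visited threshold minimizing the absolute count
#' difference (ties broken towards the lower threshold) with
#' `converged = FALSE`.
#'
#' @param series [ear_series()] restricted to the calibration window; must be
#'   at least 60 s long.
#' @param manual_count manually counted blinks in the window (non-negative).
#' @param lo,hi initial threshold interval; the default `[0.05, 0.45]` spans
#'   physiologic mEAR. `interval = "auto"` replaces it with the observed
#'   signal range.
#' @param max_iter maximum bisection iterations (default 50).
#' @param min_interval stop when `hi - lo` falls below this (default 1e-4).
#' @param interval `"fixed"` to use `lo`/`hi` as given, `"auto"` to use
#'   `range(series)`.
#' @param min_frames,max_duration_ms passed to [detect_blinks()].
#'
#' @return A `calibration_result`: `threshold`, `iterations`,
#'   `achieved_count` (valid blinks at the returned threshold),
#'   `manual_count`, `converged` (`TRUE` iff achieved equals manual), and a
#'   `trace` data frame with one row per iteration
#'   (`lo, hi, mid, auto_count`).
#' @export
calibrate_threshold <- function(series, manual_count, lo = 0.05, hi = 0.45,
                                max_iter = 50L, min_interval = 1e-4,
                                interval = c("fixed", "auto"),
                                min_frames = 2L, max_duration_ms = 500) {
  stopifnot(inherits(series, "ear_series"))
  interval <- match.arg(interval)
  if (interval == "auto") {
    rng <- range(unclass(series), na.rm = TRUE)
    lo <- rng[1]
    hi <- rng[2]
  }
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || lo >= hi) {
    stop("require 0 <= lo < hi for the calibration interval", call. = FALSE)
  }
  if (manual_count < 0) stop("`manual_count` must be non-negative", call. = FALSE)
  if (length(series) / series_fps(series) < 60) {
    stop("calibration window must be at least 60 s long", call. = FALSE)
  }

  count_at <- function(thr) {
    ev <- detect_blinks(series, thr,
      min_frames = min_frames,
      max_duration_ms = max_duration_ms
    )
    sum(ev$valid)
  }

  trace <- data.frame(
    lo = numeric(0), hi = numeric(0),
    mid = numeric(0), auto_count = integer(0)
  )
  converged <- FALSE
  iterations <- 0L
  threshold <- (lo + hi) / 2

  while (iterations < max_iter && (hi - lo) >= min_interval) {
    mid <- (lo + hi) / 2
    auto <- count_at(mid)
    iterations <- iterations + 1L
    trace[iterations, ] <- list(lo, hi, mid, auto)
    if (auto == manual_count) {
      threshold <- mid
      converged <- TRUE
      break
    } else if (auto < manual_count) {
      lo <- mid
    } else {
      hi <- mid
    }
  }

  if (!converged) {
    if (nrow(trace) == 0L) {
      # degenerate interval narrower than min_interval from the start
      mid <- (lo + hi) / 2
      trace[1L, ] <- list(lo, hi, mid, count_at(mid))
    }
    diffs <- abs(trace$auto_count - manual_count)
    best <- which(diffs == min(diffs))
    threshold <- min(trace$mid[best]) # ties -> lower threshold
  }
  achieved <- count_at(threshold)

  structure(
    list(
      threshold = threshold,
      iterations = iterations,
      achieved_count = achieved,
      manual_count = as.integer(manual_count),
      converged = achieved == manual_count,
      trace = trace
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> threshold = %.5f after %d iteration(s)%s\n",
    x$threshold, x$iterations, if (x$converged) "" else " (no exact match)"
  ))
  cat(sprintf(
    "  automatic count %d vs manual count %d\n",
    x$achieved_count, x$manual_count
  ))
  invisible(x)
}

#' Write a calibration report to JSON
#'
#' Includes the full bisection trace for audit.
#'
#' @param result a `calibration_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  out <- list(
    threshold = result$threshold,
    iterations = result$iterations,
    achieved_count = result$achieved_count,
    manual_count = result$manual_count,
    converged = result$converged,
    trace = result$trace
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
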