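# Eye-aspect-ratio (EAR) computation from 6-point eye landmarks.
#
# Landmark order follows the 68-point facial-landmark convention for one eye:
# p1 temporal corner, p4 nasal corner, p2/p3 upper lid, p6/p5 lower lid.
# EAR = (A + B) / (2 C) with A = |p2 - p6|, B = |p3 - p5|, C = |p1 - p4|.

#' Compute the eye aspect ratio of one eye
#'
#' The eye aspect ratio (EAR) is the ratio of the summed vertical lid openings
#' to twice the horizontal aperture, \eqn{EAR = (A + B) / (2C)}, where
#' \eqn{A = \|p_2 - p_6\|}, \eqn{B = \|p_3 - p_5\|} and \eqn{C = \|p_1 - p_4\|}.
#' It is dimensionless, non-negative, and invariant to translation, rotation
#' and uniform scaling of the landmark set. EAR drops towards zero during lid
#' closure, which makes it the standard per-frame signal for blink detection.
#'
#' @param points numeric 6 x 2 matrix of landmark coordinates (pixels), rows
#'   ordered p1..p6 per the 68-point eye convention (p1 temporal corner, p4
#'   nasal corner, p2/p3 upper lid, p6/p5 lower lid).
#' @param eps horizontal apertures below `eps` (in pixels) are treated as
#'   degenerate; the frame is flagged missing (`NA`) rather than erroring so a
#'   failed detection does not abort a run.
#'
#' @return A single non-negative number, or `NA_real_` for a degenerate frame
#'   (non-finite coordinates or \eqn{C < eps}).
#' @examples
#' eye <- rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
#' compute_ear(eye) # 0.5
#' @export
compute_ear <- function(points, eps = 1e-6) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 6L || ncol(points) != 2L) {
    stop("`points` must be a numeric 6 x 2 matrix (rows p1..p6)", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    return(NA_real_)
  }
  a <- sqrt(sum((points[2L, ] - points[6L, ])^2))
  b <- sqrt(sum((points[3L, ] - points[5L, ])^2))
  cc <- sqrt(sum((points[1L, ] - points[4L, ])^2))
  if (cc < eps) {
    return(NA_real_)
  }
  (a + b) / (2 * cc)
}

#' Mean EAR of the two eyes
#'
#' Arithmetic mean of the left- and right-eye EAR for one frame (the mEAR
#' detection signal). If exactly one eye is missing the other is returned and
#' the frame can be flagged by the caller; if both are missing the frame is
#' masked (`NA`).
#'
#' @param left,right per-eye EAR values; `NA` marks a missing eye.
#' @return The per-frame mean EAR; `NA_real_` when both eyes are missing.
#' @examples
#' mean_ear(0.20, 0.40) # 0.30
#' mean_ear(0.25, NA)   # 0.25
#' @export
mean_ear <- function(left, right) {
  stopifnot(length(left) == 1L, length(right) == 1L)
  if (is.na(left) && is.na(right)) {
    return(NA_real_)
  }
  for (v in c(left, right)) {
    if (!is.na(v) && v < 0) stop("EAR values must be non-negative", call. = FALSE)
  }
  mean(c(left, right), na.rm = TRUE)
}

#' Construct a mean-EAR time series
#'
#' @param values numeric vector of per-frame mean-EAR values; `NA` entries are
#'   masked frames (failed landmark detection or degenerate geometry).
#' @param fps frames per second of the recording (default 30).
#' @param single_eye optional logical vector flagging frames where only one eye
#'   contributed.
#'
#' @return An `ear_series` object: the values with attributes `fps` and
#'   `single_eye` and a mask implied by `NA` entries.
#' @export
ear_series <- function(values, fps = 30, single_eye = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("an EAR series must contain at least one frame", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (any(values[!is.na(values)] < 0)) {
    stop("unmasked EAR values must be non-negative", call. = FALSE)
  }
  if (is.null(single_eye)) single_eye <- rep(FALSE, length(values))
  stopifnot(length(single_eye) == length(values))
  structure(values,
    fps = fps, single_eye = as.logical(single_eye),
    class = "ear_series"
  )
}

#' @export
print.ear_series <- function(x, ...) {
  n <- length(x)
  fps <- attr(x, "fps")
  cat(sprintf(
    "<ear_series> %d frames @ %g fps (%.1f s), %d masked\n",
    n, fps, n / fps, sum(is.na(x))
  ))
  rng <- range(unclass(x), na.rm = TRUE)
  if (all(is.finite(rng))) cat(sprintf("  mEAR range: [%.3f, %.3f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Frames-per-second of an EAR series
#' @param x an `ear_series`.
#' @return the frame rate in frames per second.
#' @export
series_fps <- function(x) {
  stopifnot(inherits(x, "ear_series"))
  attr(x, "fps")
}

#' Masked-frame indicator of an EAR series
#' @param x an `ear_series`.
#' @return logical vector, `TRUE` where the frame is masked.
#' @export
series_mask <- function(x) {
  stopifnot(inherits(x, "ear_series"))
  is.na(unclass(x))
}

#' Build a mean-EAR series from per-frame eye landmarks
#'
#' Applies [compute_ear()] to each eye of each frame and [mean_ear()] across
#' eyes. Frames where both eyes are degenerate are masked, not dropped, so
#' indices stay aligned with the video timeline.
#'
#' @param left,right lists of 6 x 2 landmark matrices, one per frame, in the
#'   p1..p6 order of [compute_ear()].
#' @param fps frames per second (default 30).
#' @param eps degenerate-aperture threshold passed to [compute_ear()].
#' @return An [ear_series()] of the same length as the input, with
#'   `single_eye` flags where only one eye was valid.
#' @export
series_from_landmarks <- function(left, right, fps = 30, eps = 1e-6) {
  if (length(left) == 0L) stop("empty recording", call. = FALSE)
  if (length(left) != length(right)) {
    stop("`left` and `right` must have one landmark set per frame", call. = FALSE)
  }
  l <- vapply(left, compute_ear, numeric(1), eps = eps)
  r <- vapply(right, compute_ear, numeric(1), eps = eps)
  values <- mapply(mean_ear, l, r)
  ear_series(values, fps = fps, single_eye = xor(is.na(l), is.na(r)))
}
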