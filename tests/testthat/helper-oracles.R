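# Independent oracles, deliberately written with plain cursor loops and
# direct formulas so they share no code path with the implementation.

# Run scanner: walk the signal frame by frame, opening an event when the
# value drops below threshold and closing it when it rises (or is masked).
oracle_detect <- function(values, threshold, min_frames = 2L,
                          max_duration_ms = 500, fps = 30) {
  onset <- offset <- integer(0)
  run_start <- NA_integer_
  for (i in seq_along(values)) {
    below <- !is.na(values[i]) && values[i] < threshold
    if (below && is.na(run_start)) run_start <- i
    if (!below && !is.na(run_start)) {
      if (i - run_start >= min_frames) {
        onset <- c(onset, run_start - 1L)
        offset <- c(offset, i - 2L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) && length(values) - run_start + 1L >= min_frames) {
    onset <- c(onset, run_start - 1L)
    offset <- c(offset, length(values) - 1L)
  }
  dur <- (offset - onset + 1L) / fps * 1000
  data.frame(
    onset_frame = onset, offset_frame = offset,
    duration_ms = dur, valid = dur <= max_duration_ms
  )
}

# Cronbach's alpha from first principles: variances by explicit sums.
oracle_alpha <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  var_hand <- function(x) sum((x - sum(x) / n)^2) / (n - 1)
  total <- numeric(n)
  for (i in seq_len(n)) total[i] <- sum(mat[i, ])
  item_vars <- numeric(k)
  for (j in seq_len(k)) item_vars[j] <- var_hand(mat[, j])
  k / (k - 1) * (1 - sum(item_vars) / var_hand(total))
}

# Two-predictor standardized regression by explicit 2x2 normal-equation
# inversion: coefficients of y ~ x + m with all variables standardized.
oracle_std_regression <- function(r_xm, r_xy, r_my) {
  xtx <- matrix(c(1, r_xm, r_xm, 1), 2, 2)
  xty <- c(r_xy, r_my)
  det <- xtx[1, 1] * xtx[2, 2] - xtx[1, 2] * xtx[2, 1]
  inv <- matrix(c(xtx[2, 2], -xtx[2, 1], -xtx[1, 2], xtx[1, 1]), 2, 2) / det
  beta <- inv %*% xty
  list(c_prime = beta[1], b = beta[2])
}

# Random 6-point eye with a guaranteed non-degenerate horizontal aperture.
random_eye <- function() {
  repeat {
    pts <- matrix(stats::runif(12, -5, 5), ncol = 2)
    if (sqrt(sum((pts[1, ] - pts[4, ])^2)) > 0.5) {
      return(pts)
    }
  }
}

# Canonical symmetric "rectangle" eye with EAR = 0.5.
rect_eye <- function(scale = 1) {
  scale * rbind(c(0, 0), c(1, 1), c(3, 1), c(4, 0), c(3, -1), c(1, -1))
}

# Random valid 3x3 correlation triple (PSD by construction from a random
# full-rank loading matrix).
random_corr_triple <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- A %*% t(A)
  d <- sqrt(diag(S))
  R <- S / outer(d, d)
  list(r_xm = R[1, 2], r_xy = R[1, 3], r_my = R[2, 3])
}
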