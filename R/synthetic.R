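# Synthetic-data generators: EAR signals with frame-exact blink ground
# truth, multivariate-normal trait/stress/blink samples with a target
# correlation structure, and keyed Likert item matrices.

#' Specification of a synthetic mean-EAR signal
#'
#' Describes a noisy open-eye baseline interrupted by V-shaped blink dips.
#' Defaults reflect typical screen-task recordings: an open-eye mEAR around
#' 0.30, closures reaching about 0.08, a resting blink rate in the 10--25
#' per-minute range, and spontaneous blink durations of roughly 220--380 ms.
#'
#' @param duration_s recording length in seconds.
#' @param fps frames per second (default 30).
#' @param rate_bpm target blink rate, blinks per minute (default 15, the
#'   middle of the typical resting range).
#' @param open_ear_mean baseline open-eye mEAR (default 0.30).
#' @param closed_ear_mean mEAR at full closure (default 0.08); must be below
#'   `open_ear_mean`.
#' @param noise_sd SD of the Gaussian frame noise (default 0.02).
#' @param blink_duration_ms_mean,blink_duration_ms_sd mean and SD of the
#'   truncated-normal blink-duration law (defaults 300 and 50 ms, truncated
#'   to `[200, 500]` ms, the conventional spontaneous-blink duration range).
#' @param refractory_ms minimum eyes-open gap between consecutive blinks
#'   (default 200 ms); blinks cannot overlap.
#' @param seed integer seed; all randomness flows through one generator
#'   seeded per call, no global state is relied upon.
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(duration_s, fps = 30, rate_bpm = 15,
                        open_ear_mean = 0.30, closed_ear_mean = 0.08,
                        noise_sd = 0.02, blink_duration_ms_mean = 300,
                        blink_duration_ms_sd = 50, refractory_ms = 200,
                        seed = 1L) {
  stopifnot(
    duration_s > 0, fps > 0, rate_bpm > 0, open_ear_mean > 0,
    closed_ear_mean > 0, closed_ear_mean < open_ear_mean,
    noise_sd >= 0, blink_duration_ms_mean > 0, blink_duration_ms_sd >= 0,
    refractory_ms >= 0
  )
  mean_cycle_s <- blink_duration_ms_mean / 1000 + refractory_ms / 1000
  if (60 / rate_bpm <= mean_cycle_s) {
    stop("infeasible rate/refractory combination: blinks would overlap",
      call. = FALSE
    )
  }
  structure(
    list(
      duration_s = duration_s, fps = fps, rate_bpm = rate_bpm,
      open_ear_mean = open_ear_mean, closed_ear_mean = closed_ear_mean,
      noise_sd = noise_sd, blink_duration_ms_mean = blink_duration_ms_mean,
      blink_duration_ms_sd = blink_duration_ms_sd,
      refractory_ms = refractory_ms, seed = as.integer(seed)
    ),
    class = "signal_spec"
  )
}

# normal truncated to [lo, hi] by inverse-CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    return(rep(min(max(mean, lo), hi), n))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic mean-EAR signal with known blink ground truth
#'
#' The baseline is Gaussian noise around the open-eye mean. Blink onsets
#' follow a renewal process: eyes-open gaps between consecutive blinks are
#' the refractory period plus a gamma-distributed interval whose mean is set
#' so the long-run rate matches `rate_bpm` (a renewal rather than Poisson
#' process, honouring the refractory period so events can never overlap).
#' Each blink is a symmetric V-shaped dip from the open baseline to the
#' closed mean and back, with its duration drawn from a truncated-normal
#' law; the V shape (rather than a square pulse) makes threshold-crossing
#' onset/offset detection non-trivial.
#'
#' @param spec a [signal_spec()].
#' @return A list with `series` (an [ear_series()]) and `events`, a data
#'   frame of frame-exact ground truth (`onset_frame`, `offset_frame`,
#'   0-based, and `duration_ms`) covering every generated dip.
#' @export
generate_ear_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  set.seed(spec$seed)
  fps <- spec$fps
  n_frames <- round(spec$duration_s * fps)
  dur_lo <- max(200, 2000 / fps) # spontaneous-blink floor; >= 2 frames
  dur_hi <- 500

  mean_dur_s <- spec$blink_duration_ms_mean / 1000
  refr_s <- spec$refractory_ms / 1000
  mean_gap_s <- 60 / spec$rate_bpm - mean_dur_s - refr_s
  if (mean_gap_s <= 0) {
    stop("infeasible rate/refractory combination: blinks would overlap",
      call. = FALSE
    )
  }

  # draw blink cycles until the recording is covered
  onset_s <- numeric(0)
  dur_ms <- numeric(0)
  gap_shape <- 2 # mild regularity beyond the hard refractory gap
  t <- stats::rgamma(1L, shape = gap_shape, scale = mean_gap_s / gap_shape)
  while (t < spec$duration_s) {
    d <- .rtruncnorm(1L, spec$blink_duration_ms_mean,
      spec$blink_duration_ms_sd,
      lo = dur_lo, hi = dur_hi
    )
    if (t + d / 1000 > spec$duration_s) break # dip must fit the recording
    onset_s <- c(onset_s, t)
    dur_ms <- c(dur_ms, d)
    gap <- refr_s + stats::rgamma(1L, shape = gap_shape, scale = mean_gap_s / gap_shape)
    t <- t + d / 1000 + gap
  }

  values <- stats::rnorm(n_frames, spec$open_ear_mean, spec$noise_sd)
  onset_f <- integer(0)
  offset_f <- integer(0)
  for (k in seq_along(onset_s)) {
    i0 <- floor(onset_s[k] * fps) # 0-based first dip frame
    len <- max(2L, round(dur_ms[k] / 1000 * fps))
    i1 <- min(i0 + len - 1L, n_frames - 1L)
    idx <- i0:i1
    # symmetric V sampled at frame midpoints: every ground-truth frame
    # carries nonzero closure, full closure at the dip midpoint
    pos <- (seq_along(idx) - 0.5) / length(idx)
    depth <- 1 - abs(2 * pos - 1)
    values[idx + 1L] <- values[idx + 1L] -
      depth * (spec$open_ear_mean - spec$closed_ear_mean)
    onset_f <- c(onset_f, i0)
    offset_f <- c(offset_f, i1)
  }
  values <- pmax(values, 0)

  list(
    series = ear_series(values, fps = fps),
    events = data.frame(
      onset_frame = onset_f, offset_frame = offset_f,
      duration_ms = (offset_f - onset_f + 1L) / fps * 1000
    )
  )
}

#' Reference correlation structure for trait/stress/blink samples
#'
#' A 7 x 7 correlation matrix over the five personality domains, perceived
#' stress and objective blink rate, used as the default target of
#' [generate_trait_sample()]. The trait--stress and trait--blink entries and
#' the stress--blink correlation are set to values representative of
#' personality--stress--blink studies (e.g. Neuroticism--stress 0.35,
#' Conscientiousness--stress -0.26, stress--blink 0.27); trait
#' intercorrelations are left at zero.
#'
#' @return A symmetric positive semi-definite matrix with unit diagonal and
#'   dimnames over `Extraversion, Agreeableness, Conscientiousness,
#'   NegativeEmotionality, OpenMindedness, stress, blink_rate`.
#' @export
default_trait_correlations <- function() {
  vars <- c(
    "Extraversion", "Agreeableness", "Conscientiousness",
    "NegativeEmotionality", "OpenMindedness", "stress", "blink_rate"
  )
  R <- diag(7)
  dimnames(R) <- list(vars, vars)
  stress_r <- c(-0.033, -0.16, -0.26, 0.35, -0.10)
  blink_r <- c(0.05, -0.07, 0.001, -0.17, -0.21)
  R[1:5, "stress"] <- R["stress", 1:5] <- stress_r
  R[1:5, "blink_rate"] <- R["blink_rate", 1:5] <- blink_r
  R["stress", "blink_rate"] <- R["blink_rate", "stress"] <- 0.27
  R
}

#' Draw standardized multivariate-normal trait/stress/blink samples
#'
#' Samples n observations from a multivariate normal distribution with zero
#' mean, unit variances and the target correlation matrix (via a matrix
#' square root of the target). Sample correlations converge to the target as
#' n grows.
#'
#' @param n number of participants (>= 3).
#' @param R target correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite); default [default_trait_correlations()].
#' @param seed integer seed.
#' @return An n x ncol(R) numeric matrix with R's dimnames.
#' @export
generate_trait_sample <- function(n, R = default_trait_correlations(),
                                  seed = 1L) {
  if (n < 3L) stop("need n >= 3 to estimate correlations", call. = FALSE)
  R <- as.matrix(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
    any(abs(diag(R) - 1) > 1e-8)) {
    stop("`R` must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("`R` is not positive semi-definite", call. = FALSE)
  }
  set.seed(seed)
  out <- MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R)
  colnames(out) <- colnames(R)
  out
}

#' Generate keyed Likert item responses from latent domain scores
#'
#' Each item is a clipped, rounded copy of the respondent's latent domain
#' score shrunk towards the scale midpoint by `1 - loading`, plus Gaussian
#' noise. Reverse-keyed items are emitted pre-reversed (i.e. reflected on
#' the response range) so that [score_scale()] with the same definition
#' recovers the latent mean up to rounding noise.
#'
#' @param domain_scores numeric vector of latent scores, one per respondent,
#'   within the scale's response range.
#' @param def a [scale_definition()].
#' @param loading weight of the latent score in each item, in `[0, 1]`
#'   (0 = pure noise items, 1 = items centred on the latent score).
#' @param noise_sd SD of the per-item Gaussian noise (default 0.5).
#' @param seed integer seed.
#' @return An integer matrix, respondents x items.
#' @export
generate_likert_responses <- function(domain_scores, def, loading = 0.8,
                                      noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(def, "scale_definition"))
  if (!is.numeric(loading) || length(loading) != 1L || loading < 0 || loading > 1) {
    stop("`loading` must lie in [0, 1]", call. = FALSE)
  }
  lo <- def$response_min
  hi <- def$response_max
  if (any(domain_scores < lo | domain_scores > hi)) {
    stop("domain scores must lie within the response range", call. = FALSE)
  }
  set.seed(seed)
  n <- length(domain_scores)
  k <- def$item_count
  midpoint <- (lo + hi) / 2
  latent <- loading * domain_scores + (1 - loading) * midpoint
  items <- matrix(
    round(pmin(pmax(
      rep(latent, times = k) + stats::rnorm(n * k, 0, noise_sd), lo
    ), hi)),
    nrow = n, ncol = k
  )
  # emit reverse-keyed items pre-reversed so scoring undoes the reflection
  ridx <- def$reverse_items
  if (length(ridx)) {
    items[, ridx] <- lo + hi - items[, ridx]
  }
  storage.mode(items) <- "integer"
  items
}

#' Write a synthetic EAR signal and its ground truth to CSV
#'
#' The signal goes to a `frame, mear` CSV readable by [read_ear_csv()]; the
#' ground-truth events to an `onset_frame, offset_frame, duration_ms` CSV.
#'
#' @param signal a list from [generate_ear_signal()].
#' @param signal_path,truth_path output file paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_signal_csv <- function(signal, signal_path = NULL, truth_path = NULL) {
  stopifnot(is.list(signal), inherits(signal$series, "ear_series"))
  if (!is.null(signal_path)) {
    utils::write.csv(
      data.frame(
        frame = seq_along(signal$series) - 1L,
        mear = as.numeric(signal$series)
      ),
      signal_path,
      row.names = FALSE
    )
  }
  if (!is.null(truth_path)) {
    utils::write.csv(signal$events, truth_path, row.names = FALSE)
  }
  invisible(c(signal_path, truth_path))
}
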