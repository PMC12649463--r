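test_that("signal generation is deterministic under a seed", {
  sp <- signal_spec(duration_s = 60, seed = 123)
  a <- generate_ear_signal(sp)
  b <- generate_ear_signal(sp)
  expect_identical(as.numeric(a$series), as.numeric(b$series))
  expect_identical(a$events, b$events)
  c <- generate_ear_signal(signal_spec(duration_s = 60, seed = 124))
  expect_false(identical(as.numeric(a$series), as.numeric(c$series)))
})

test_that("a noiseless signal is recovered event-for-event at the midpoint", {
  sp <- signal_spec(duration_s = 60, rate_bpm = 6, noise_sd = 0, seed = 5)
  sig <- generate_ear_signal(sp)
  thr <- (sp$open_ear_mean + sp$closed_ear_mean) / 2
  ev <- detect_blinks(sig$series, thr)
  expect_equal(nrow(ev), nrow(sig$events))
  # every detected run sits inside its ground-truth dip
  for (i in seq_len(nrow(ev))) {
    expect_gte(ev$onset_frame[i], sig$events$onset_frame[i])
    expect_lte(ev$offset_frame[i], sig$events$offset_frame[i])
  }
})

test_that("event counts track the target rate and detection is near-perfect", {
  sp <- signal_spec(duration_s = 300, rate_bpm = 12, seed = 99)
  sig <- generate_ear_signal(sp)
  n_true <- nrow(sig$events)
  # 12 per minute over 5 minutes: expect about 60, Poisson-scale tolerance
  expect_lt(abs(n_true - 60), 3 * sqrt(60))
  thr <- (sp$open_ear_mean + sp$closed_ear_mean) / 2
  ev <- detect_blinks(sig$series, thr)
  hits <- vapply(seq_len(n_true), function(i) {
    any(ev$onset_frame <= sig$events$offset_frame[i] &
      ev$offset_frame >= sig$events$onset_frame[i])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # zero false positives: every detection overlaps some ground-truth dip
  fp <- vapply(seq_len(nrow(ev)), function(j) {
    !any(sig$events$onset_frame <= ev$offset_frame[j] &
      sig$events$offset_frame >= ev$onset_frame[j])
  }, logical(1))
  expect_equal(sum(fp), 0L)
})

test_that("ground-truth dips respect duration law, refractory gap and flags", {
  sp <- signal_spec(duration_s = 300, rate_bpm = 20, seed = 17)
  sig <- generate_ear_signal(sp)
  dur <- sig$events$duration_ms
  expect_true(all(dur >= 200 - 1000 / sp$fps & dur <= 500 + 1000 / sp$fps))
  gaps <- sig$events$onset_frame[-1] - sig$events$offset_frame[-nrow(sig$events)]
  # frame discretization can shave up to two frames off the nominal gap
  expect_true(all(gaps / sp$fps * 1000 >= sp$refractory_ms - 2000 / sp$fps))
  expect_true(all(as.numeric(sig$series) >= 0))
})

test_that("infeasible blink rates are rejected before generation", {
  expect_error(
    signal_spec(duration_s = 60, rate_bpm = 150, blink_duration_ms_mean = 300),
    "infeasible"
  )
  expect_error(signal_spec(duration_s = 60, closed_ear_mean = 0.4), "closed_ear_mean")
})

test_that("trait samples reproduce the target correlation structure", {
  # independence target
  d0 <- generate_trait_sample(10000, diag(3), seed = 1)
  r0 <- stats::cor(d0)
  expect_true(all(abs(r0[upper.tri(r0)]) < 0.05))

  # study-scale triple converges at large n
  R <- matrix(c(1, 0.35, -0.17, 0.35, 1, 0.27, -0.17, 0.27, 1), 3, 3)
  d1 <- generate_trait_sample(100000, R, seed = 2)
  r1 <- stats::cor(d1)
  expect_true(all(abs(r1 - R) < 0.01))

  expect_error(generate_trait_sample(2, diag(3)), "n >= 3")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(generate_trait_sample(100, bad), "positive semi-definite")
  notsym <- diag(3)
  notsym[1, 2] <- 0.5
  expect_error(generate_trait_sample(100, notsym), "symmetric")

  # the shipped default structure is a valid correlation matrix
  Rd <- default_trait_correlations()
  expect_equal(Rd, t(Rd))
  expect_equal(unname(diag(Rd)), rep(1, 7))
  expect_gte(min(eigen(Rd, symmetric = TRUE, only.values = TRUE)$values), 0)
  d2 <- generate_trait_sample(50000, Rd, seed = 3)
  expect_lt(abs(stats::cor(d2[, "NegativeEmotionality"], d2[, "stress"]) - 0.35), 0.02)
})

test_that("Likert generation is keyed so scoring recovers the latent scores", {
  def <- scale_definition("dom", 12, 1, 5,
    reverse_items = c(2, 5, 9), aggregation = "mean"
  )
  latent <- c(1, 2, 3, 4, 5)
  items <- generate_likert_responses(latent, def,
    loading = 1, noise_sd = 0, seed = 1
  )
  scores <- apply(items, 1, score_scale, def = def)
  expect_equal(scores, latent)
  # reverse-keyed columns really are reflected in the emitted matrix
  expect_equal(unname(items[1, 2]), 5)
  expect_equal(unname(items[5, 2]), 1)

  # internally consistent items at high loading
  set.seed(8)
  latent2 <- pmin(pmax(stats::rnorm(500, 3, 0.8), 1), 5)
  it2 <- generate_likert_responses(latent2, def, loading = 1, noise_sd = 0.5, seed = 2)
  sc2 <- it2
  sc2[, def$reverse_items] <- 6 - sc2[, def$reverse_items]
  expect_gt(cronbach_alpha(sc2), 0.8)

  # zero loading: pure noise items, negligible consistency (large n so the
  # sampling spread of alpha is well below the tolerance)
  latent3 <- pmin(pmax(stats::rnorm(2000, 3, 0.8), 1), 5)
  it3 <- generate_likert_responses(latent3, def, loading = 0, noise_sd = 1, seed = 3)
  sc3 <- it3
  sc3[, def$reverse_items] <- 6 - sc3[, def$reverse_items]
  expect_lt(abs(cronbach_alpha(sc3)), 0.1)

  expect_error(generate_likert_responses(latent, def, loading = 1.5), "loading")
  expect_error(generate_likert_responses(c(0, 3), def), "response range")
})

test_that("same-seed Likert and trait draws are reproducible", {
  def <- pss14_definition()
  a <- generate_likert_responses(c(1, 2, 3), def, seed = 4)
  b <- generate_likert_responses(c(1, 2, 3), def, seed = 4)
  expect_identical(a, b)
  expect_identical(
    generate_trait_sample(50, diag(2), seed = 6),
    generate_trait_sample(50, diag(2), seed = 6)
  )
})
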