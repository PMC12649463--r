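test_that("reverse keying reflects the response range and is an involution", {
  expect_equal(reverse_item(5, 1, 5), 1)
  expect_equal(reverse_item(3, 1, 5), 3) # midpoint is a fixed point
  expect_equal(reverse_item(0, 0, 4), 4)
  for (x in 1:5) expect_equal(reverse_item(reverse_item(x, 1, 5), 1, 5), x)
  for (x in 0:4) expect_equal(reverse_item(reverse_item(x, 0, 4), 0, 4), x)
  expect_error(reverse_item(6, 1, 5, item = 12, participant = "p1"), "item 12")
})

test_that("scale scoring reverses keyed items then aggregates per definition", {
  dom <- scale_definition("dom", 12, 1, 5,
    reverse_items = c(2, 5, 9), aggregation = "mean"
  )
  # midpoint responses are invariant to any keying
  expect_equal(score_scale(rep(3, 12), dom), 3.0)
  pss <- pss14_definition()
  expect_equal(score_scale(rep(2, 14), pss), 28)
  # all-zero responses: each of the k reverse-keyed items scores 4
  k <- length(pss$reverse_items)
  expect_equal(score_scale(rep(0, 14), pss), 4 * k)

  expect_error(score_scale(rep(3, 10), dom), "expected 12")
  expect_error(
    score_scale(c(rep(3, 11), 9), dom, participant = "p7"),
    "p7"
  )
  # missing responses: error by default, person-mean imputation on request
  resp <- c(NA, rep(4, 11))
  expect_error(score_scale(resp, dom), "missing")
  imputed <- score_scale(resp, dom, missing = "impute")
  reversed <- c(NA, 2, 4, 4, 2, 4, 4, 4, 2, 4, 4, 4)
  expect_equal(imputed, mean(replace(reversed, 1, mean(reversed, na.rm = TRUE))))
  expect_error(score_scale(rep(NA_real_, 12), dom, missing = "impute"), "missing")
})

test_that("scoring is invariant to item order given a matching keying map", {
  set.seed(3)
  resp <- sample(1:5, 12, replace = TRUE)
  def <- scale_definition("d", 12, 1, 5, reverse_items = c(1, 4, 7, 10))
  perm <- sample(12)
  def_perm <- scale_definition("d", 12, 1, 5,
    reverse_items = match(def$reverse_items, perm)
  )
  expect_equal(score_scale(resp[perm], def_perm), score_scale(resp, def))
})

test_that("the shipped instrument keys score full questionnaires", {
  defs <- bfi2_definitions()
  expect_named(defs, c(
    "Extraversion", "Agreeableness", "Conscientiousness",
    "NegativeEmotionality", "OpenMindedness"
  ))
  expect_true(all(vapply(defs, function(d) d$item_count == 12L, logical(1))))
  # the five domains partition the 60 items; 30 items are reverse-keyed
  all_items <- sort(unname(unlist(lapply(defs, attr, "items"))))
  expect_equal(all_items, 1:60)
  expect_equal(sum(vapply(defs, function(d) length(d$reverse_items), integer(1))), 30L)

  items <- data.frame(participant_id = c("a", "b"))
  items[paste0("bfi_", 1:60)] <- 3
  items[paste0("pss_", 1:14)] <- 2
  items$subjective_blink <- c(4, 7)
  scores <- score_questionnaires(items)
  for (d in names(defs)) expect_equal(scores[[d]], c(3, 3))
  expect_equal(scores$pss14_total, c(28, 28))
  expect_equal(scores$subjective_blink, c(4, 7))

  # JSON keying round-trip matches the built-in defaults
  path <- system.file("extdata", "default_keys.json", package = "blinkpath")
  keys <- read_keying_json(path)
  for (d in names(defs)) {
    expect_equal(keys[[d]]$reverse_items, defs[[d]]$reverse_items)
    expect_equal(attr(keys[[d]], "items"), attr(defs[[d]], "items"))
  }
  expect_equal(keys$PSS14$reverse_items, pss14_definition()$reverse_items)
})

test_that("Cronbach's alpha matches hand computation and its limit cases", {
  # worked 3-item matrix against the by-hand variance oracle
  m <- matrix(c(
    1, 2, 3,
    2, 3, 4,
    3, 3, 5,
    4, 5, 5,
    2, 1, 2
  ), ncol = 3, byrow = TRUE)
  expect_equal(cronbach_alpha(m), oracle_alpha(m), tolerance = 1e-12)

  # perfectly parallel items
  x <- stats::rnorm(20)
  expect_equal(cronbach_alpha(cbind(x, x, x, x)), 1)

  # independent items: alpha near zero
  set.seed(41)
  ind <- matrix(stats::rnorm(10000 * 12), ncol = 12)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)

  expect_warning(a0 <- cronbach_alpha(matrix(3, 5, 4)), "zero variance")
  expect_true(is.na(a0))
  expect_error(cronbach_alpha(matrix(1:4, 2, 2)), "at least 2 items")
})

test_that("alpha is invariant to reflecting items with flipped keys", {
  set.seed(42)
  items <- matrix(sample(1:5, 50 * 6, replace = TRUE), ncol = 6)
  reflected <- 1 + 5 - items
  expect_equal(cronbach_alpha(items), cronbach_alpha(reflected))
})

test_that("descriptives reproduce SPSS-style adjusted estimators", {
  d <- descriptives(c(5, 5, 5, 5))
  expect_equal(d$sd, 0)
  expect_true(is.na(d$skewness) && is.na(d$kurtosis))

  expect_equal(descriptives(c(1, 2, 3))$skewness, 0)

  skip_if_not_installed("e1071")
  for (x in list(
    c(1, 2, 3, 4, 100),
    stats::rnorm(50),
    stats::rexp(31)
  )) {
    d <- descriptives(x)
    expect_equal(d$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
    expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2), tolerance = 1e-12)
    expect_equal(d$sd, stats::sd(x))
  }
})

test_that("correlation matrix reproduces cor.test and is well-formed", {
  set.seed(13)
  df <- data.frame(
    a = stats::rnorm(40), b = stats::rnorm(40),
    c = stats::rnorm(40)
  )
  df$b <- df$b + 0.8 * df$a
  pm <- pearson_matrix(df)
  expect_equal(pm$r, t(pm$r))
  expect_equal(diag(pm$r), c(a = 1, b = 1, c = 1))
  expect_true(all(abs(pm$r) <= 1))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ct <- stats::cor.test(df[[pair[1]]], df[[pair[2]]])
    expect_equal(pm$r[pair[1], pair[2]], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pm$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-12)
  }

  # independent columns at large n: negligible correlation
  set.seed(14)
  big <- data.frame(x = stats::rnorm(10000), y = stats::rnorm(10000))
  expect_lt(abs(pearson_matrix(big)$r["x", "y"]), 0.05)

  # zero-variance column flagged, not an error
  dz <- data.frame(x = stats::rnorm(10), z = rep(1, 10))
  pz <- pearson_matrix(dz)
  expect_true(is.na(pz$r["x", "z"]))
})

test_that("the descriptives table carries M, SD, shape and correlations", {
  set.seed(15)
  df <- data.frame(stress = stats::rnorm(30, 22, 7), blink = stats::rnorm(30, 16, 10))
  tab <- descriptives_table(df, targets = "blink")
  expect_equal(tab$variable, c("stress", "blink"))
  expect_equal(tab$M, c(mean(df$stress), mean(df$blink)))
  expect_equal(tab$r_blink[2], 1)
})
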