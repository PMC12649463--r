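# Likert-scale scoring (BFI-2 domains, PSS-14 total), internal consistency,
# SPSS-compatible descriptives, and Pearson correlation matrices.

#' Define a Likert scale
#'
#' @param name scale name.
#' @param item_count number of items.
#' @param response_min,response_max response range (e.g. 1--5 for the BFI-2,
#'   0--4 for the PSS-14).
#' @param reverse_items integer indices (within the scale) of reverse-keyed
#'   items.
#' @param aggregation `"mean"` (trait domains) or `"sum"` (stress total).
#' @return A `scale_definition` list.
#' @export
scale_definition <- function(name, item_count, response_min, response_max,
                             reverse_items = integer(0),
                             aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  stopifnot(item_count >= 1L, response_min < response_max)
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) &&
    (min(reverse_items) < 1L || max(reverse_items) > item_count)) {
    stop("`reverse_items` indices must lie within 1..item_count", call. = FALSE)
  }
  structure(
    list(
      name = name, item_count = as.integer(item_count),
      response_min = response_min, response_max = response_max,
      reverse_items = reverse_items, aggregation = aggregation
    ),
    class = "scale_definition"
  )
}

# Published 60-item BFI-2 key: items cycle through the five domains in the
# order Extraversion, Agreeableness, Conscientiousness, Negative
# Emotionality, Open-Mindedness (item 1 = E, 2 = A, ..., 6 = E, ...).
.bfi2_domain_items <- list(
  Extraversion = seq(1L, 56L, by = 5L),
  Agreeableness = seq(2L, 57L, by = 5L),
  Conscientiousness = seq(3L, 58L, by = 5L),
  NegativeEmotionality = seq(4L, 59L, by = 5L),
  OpenMindedness = seq(5L, 60L, by = 5L)
)
.bfi2_reverse <- c(
  3L, 4L, 5L, 8L, 9L, 11L, 12L, 16L, 17L, 22L, 23L, 24L, 25L, 26L, 28L, 29L,
  30L, 31L, 36L, 37L, 42L, 44L, 45L, 47L, 48L, 49L, 50L, 51L, 55L, 58L
)
.pss14_reverse <- c(4L, 5L, 6L, 7L, 9L, 10L, 13L)

#' Default BFI-2 domain definitions
#'
#' Published instrument keys for the 60-item Big Five Inventory-2: five
#' domains of 12 items each on a 1--5 response range, scored as item means
#' after reversal. These are instrument defaults; site-specific keying can be
#' supplied via [read_keying_json()].
#'
#' @return Named list of five [scale_definition()]s with an `items` attribute
#'   giving each domain's item positions in the 60-item questionnaire.
#' @export
bfi2_definitions <- function() {
  out <- lapply(names(.bfi2_domain_items), function(domain) {
    items <- .bfi2_domain_items[[domain]]
    def <- scale_definition(
      name = domain, item_count = 12L,
      response_min = 1, response_max = 5,
      reverse_items = match(intersect(.bfi2_reverse, items), items),
      aggregation = "mean"
    )
    attr(def, "items") <- items
    def
  })
  names(out) <- names(.bfi2_domain_items)
  out
}

#' Default PSS-14 definition
#'
#' Published instrument key for the 14-item Perceived Stress Scale: 0--4
#' response range, seven positively worded items reverse-keyed, summed to a
#' 0--56 total with higher scores indicating higher perceived stress.
#'
#' @return A [scale_definition()].
#' @export
pss14_definition <- function() {
  scale_definition(
    name = "PSS14", item_count = 14L,
    response_min = 0, response_max = 4,
    reverse_items = .pss14_reverse, aggregation = "sum"
  )
}

#' Reverse-key a Likert response
#'
#' Standard reflection `response_min + response_max - x`; applying it twice
#' returns the original response.
#'
#' @param x response value(s).
#' @param response_min,response_max the response range.
#' @param item,participant optional labels used in the out-of-range error
#'   message.
#' @return The reversed response(s).
#' @examples
#' reverse_item(5, 1, 5) # 1
#' reverse_item(0, 0, 4) # 4
#' @export
reverse_item <- function(x, response_min, response_max,
                         item = NULL, participant = NULL) {
  bad <- !is.na(x) & (x < response_min | x > response_max)
  if (any(bad)) {
    stop(sprintf(
      "response %s out of range [%s, %s]%s%s",
      paste(x[bad], collapse = ", "), response_min, response_max,
      if (is.null(item)) "" else paste0(" for item ", item),
      if (is.null(participant)) "" else paste0(" (participant ", participant, ")")
    ), call. = FALSE)
  }
  response_min + response_max - x
}

#' Score a Likert scale for one respondent
#'
#' Reverse-keyed items are reversed, then aggregated by mean (trait domains)
#' or sum (stress total) per the scale definition.
#'
#' @param responses numeric vector of raw item responses, length
#'   `def$item_count`, in the scale's item order.
#' @param def a [scale_definition()].
#' @param missing `"error"` (default) rejects any missing response;
#'   `"impute"` replaces up to `max_impute` missing items with the
#'   person mean of the remaining (already-reversed) items.
#' @param max_impute maximum number of imputable items (default 2).
#' @param participant optional label for error messages.
#' @return The scale score (a domain mean or a scale total).
#' @export
score_scale <- function(responses, def, missing = c("error", "impute"),
                        max_impute = 2L, participant = NULL) {
  stopifnot(inherits(def, "scale_definition"))
  missing <- match.arg(missing)
  if (length(responses) != def$item_count) {
    stop(sprintf(
      "expected %d responses for scale %s, got %d",
      def$item_count, def$name, length(responses)
    ), call. = FALSE)
  }
  n_missing <- sum(is.na(responses))
  if (n_missing > 0L && (missing == "error" || n_missing > max_impute)) {
    stop(sprintf(
      "missing responses on scale %s%s (items %s)",
      def$name,
      if (is.null(participant)) "" else paste0(", participant ", participant),
      paste(which(is.na(responses)), collapse = ", ")
    ), call. = FALSE)
  }
  x <- responses
  idx <- def$reverse_items
  x[idx] <- reverse_item(x[idx], def$response_min, def$response_max,
    participant = participant
  )
  bad <- !is.na(x) & (x < def$response_min | x > def$response_max)
  if (any(bad)) {
    stop(sprintf(
      "out-of-range response on scale %s, item(s) %s%s",
      def$name, paste(which(bad), collapse = ", "),
      if (is.null(participant)) "" else paste0(", participant ", participant)
    ), call. = FALSE)
  }
  if (n_missing > 0L) x[is.na(x)] <- mean(x, na.rm = TRUE)
  switch(def$aggregation,
    mean = mean(x),
    sum = sum(x)
  )
}

#' Score BFI-2 domains, PSS-14 total and the subjective blink rating
#'
#' Expects one row per participant with columns `participant_id`,
#' `bfi_1..bfi_60`, `pss_1..pss_14` and `subjective_blink` (1--7), as read by
#' [read_items_csv()].
#'
#' @param items data frame of raw item responses.
#' @param bfi2 list of domain definitions, default [bfi2_definitions()].
#' @param pss14 stress-scale definition, default [pss14_definition()].
#' @param missing,max_impute passed to [score_scale()].
#' @return Data frame with `participant_id`, the five domain means (1--5),
#'   `pss14_total` (0--56) and `subjective_blink`.
#' @export
score_questionnaires <- function(items, bfi2 = bfi2_definitions(),
                                 pss14 = pss14_definition(),
                                 missing = "error", max_impute = 2L) {
  stopifnot(is.data.frame(items), "participant_id" %in% names(items))
  bfi_cols <- paste0("bfi_", 1:60)
  pss_cols <- paste0("pss_", 1:14)
  need <- c(bfi_cols, pss_cols)
  if (!all(need %in% names(items))) {
    stop(
      "items data must contain columns bfi_1..bfi_60 and pss_1..pss_14",
      call. = FALSE
    )
  }
  n <- nrow(items)
  out <- data.frame(participant_id = items$participant_id)
  for (domain in names(bfi2)) {
    def <- bfi2[[domain]]
    cols <- bfi_cols[attr(def, "items")]
    out[[domain]] <- vapply(seq_len(n), function(i) {
      score_scale(as.numeric(items[i, cols]), def,
        missing = missing,
        max_impute = max_impute, participant = items$participant_id[i]
      )
    }, numeric(1))
  }
  out$pss14_total <- vapply(seq_len(n), function(i) {
    score_scale(as.numeric(items[i, pss_cols]), pss14,
      missing = missing,
      max_impute = max_impute, participant = items$participant_id[i]
    )
  }, numeric(1))
  if ("subjective_blink" %in% names(items)) {
    sb <- items$subjective_blink
    if (any(!is.na(sb) & (sb < 1 | sb > 7))) {
      stop("subjective_blink ratings must lie in 1..7", call. = FALSE)
    }
    out$subjective_blink <- sb
  }
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' sample item variances and \eqn{s_T^2} the sample variance of the total
#' score. Reverse-keyed items must already be reversed.
#'
#' @param items numeric participants x items matrix (at least 3 participants,
#'   2 items).
#' @return Alpha, or `NA_real_` (with a warning) when the total score has
#'   zero variance.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L || nrow(items) < 3L) {
    stop("alpha needs at least 2 items and 3 participants", call. = FALSE)
  }
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0) {
    warning("total score has zero variance; alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  item_var <- apply(items, 2L, stats::var)
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' SPSS-compatible descriptive statistics
#'
#' Mean, sample SD (n-1), adjusted Fisher--Pearson skewness
#' \eqn{G_1 = \frac{n}{(n-1)(n-2)} \sum z_i^3} and excess kurtosis with the
#' small-sample correction
#' \eqn{G_2 = \frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum z_i^4 -
#' \frac{3(n-1)^2}{(n-2)(n-3)}}, where \eqn{z_i} standardizes by the sample
#' SD. These match the estimators printed by mainstream statistical GUIs.
#'
#' @param x numeric vector; `NA`s dropped. Skewness needs n >= 3, kurtosis
#'   n >= 4; a constant vector has SD 0 and undefined shape statistics
#'   (returned as `NA`).
#' @return List with `n`, `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
descriptives <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  skew <- kurt <- NA_real_
  if (!is.na(s) && s > 0) {
    z <- (x - m) / s
    if (n >= 3L) skew <- n / ((n - 1) * (n - 2)) * sum(z^3)
    if (n >= 4L) {
      kurt <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
        3 * (n - 1)^2 / ((n - 2) * (n - 3))
    }
  }
  list(n = n, mean = m, sd = s, skewness = skew, kurtosis = kurt)
}

#' Pearson correlation matrix with two-tailed significance
#'
#' Pairwise-complete Pearson correlations; each p-value comes from
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} against the t distribution with
#' \eqn{n-2} degrees of freedom, two-tailed. Zero-variance columns yield
#' flagged (`NA`) pairs.
#'
#' @param data data frame or matrix of numeric columns.
#' @return A `pearson_matrix` list with matrices `r`, `p` and `n`
#'   (pairwise-complete sample sizes).
#' @export
pearson_matrix <- function(data) {
  data <- as.data.frame(data)
  stopifnot(ncol(data) >= 2L)
  vars <- names(data)
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- data[[i]]
      y <- data[[j]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 3L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      rij <- stats::cor(x[ok], y[ok])
      r[i, j] <- rij
      tt <- rij * sqrt(n - 2) / sqrt(1 - rij^2)
      p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  structure(list(r = r, p = p, n = nmat), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  cat("<pearson_matrix>\n$r\n")
  print(round(x$r, digits))
  cat("$p (two-tailed)\n")
  print(signif(x$p, 2))
  invisible(x)
}

#' Descriptives-and-correlations summary table
#'
#' One row per variable with M, SD, skewness, kurtosis and the zero-order
#' correlations against the selected target columns — the conventional layout
#' for reporting trait/stress/blink studies.
#'
#' @param data data frame of numeric study variables.
#' @param targets character vector of column names to correlate every
#'   variable against (default: all columns).
#' @return A data frame with one row per variable.
#' @export
descriptives_table <- function(data, targets = names(data)) {
  data <- as.data.frame(data)
  pm <- pearson_matrix(data)
  rows <- lapply(names(data), function(v) {
    d <- descriptives(data[[v]])
    base <- data.frame(
      variable = v, M = d$mean, SD = d$sd,
      Skewness = d$skewness, Kurtosis = d$kurtosis
    )
    for (tg in targets) base[[paste0("r_", tg)]] <- pm$r[v, tg]
    base
  })
  do.call(rbind, rows)
}
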