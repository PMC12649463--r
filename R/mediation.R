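# Saturated standardized mediation path model X -> M -> Y with a direct
# path X -> Y, fitted from a 3x3 correlation matrix or raw data, plus
# suppression classification and a bootstrap CI for the indirect effect.
#
# For standardized variables the maximum-likelihood estimates of a saturated
# path model coincide with OLS normal-equation solutions:
#   a  = r_xm
#   b  = (r_my - r_xm r_xy) / (1 - r_xm^2)
#   c' = (r_xy - r_xm r_my) / (1 - r_xm^2)
# and the total effect decomposes exactly: c = r_xy = c' + a b.

#' Correlation-matrix input for the mediation model
#'
#' Bundles the three pairwise correlations among predictor X, mediator M and
#' outcome Y with the sample size, validating that the implied 3x3 matrix is
#' positive semi-definite (eigenvalues >= -1e-10).
#'
#' @param r_xm,r_xy,r_my pairwise Pearson correlations in `[-1, 1]`.
#' @param n sample size (>= 4).
#' @return A `correlation_input` list.
#' @examples
#' correlation_input(r_xm = 0.35, r_xy = -0.17, r_my = 0.27, n = 86)
#' @export
correlation_input <- function(r_xm, r_xy, r_my, n) {
  vals <- c(r_xm = r_xm, r_xy = r_xy, r_my = r_my)
  if (any(!is.finite(vals)) || any(abs(vals) > 1)) {
    stop("correlations must be finite and within [-1, 1]", call. = FALSE)
  }
  if (!is.finite(n) || n < 4) stop("`n` must be at least 4", call. = FALSE)
  R <- matrix(c(
    1, r_xm, r_xy,
    r_xm, 1, r_my,
    r_xy, r_my, 1
  ), 3, 3, dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("the implied 3x3 correlation matrix is not positive semi-definite",
      call. = FALSE
    )
  }
  structure(
    list(r_xm = r_xm, r_xy = r_xy, r_my = r_my, n = as.integer(n), matrix = R),
    class = "correlation_input"
  )
}

#' Pairwise correlations of raw X, M, Y data
#'
#' @param x,m,y numeric vectors of equal length (n >= 4) for the predictor,
#'   mediator and outcome.
#' @return A [correlation_input()]; degenerate all-unit correlations are
#'   flagged with a warning.
#' @export
corr_from_data <- function(x, m, y) {
  n <- length(x)
  if (length(m) != n || length(y) != n) {
    stop("`x`, `m`, `y` must have equal length", call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 complete observations", call. = FALSE)
  if (anyNA(x) || anyNA(m) || anyNA(y)) {
    ok <- stats::complete.cases(x, m, y)
    x <- x[ok]
    m <- m[ok]
    y <- y[ok]
    n <- length(x)
    if (n < 4L) stop("need at least 4 complete observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  ci <- correlation_input(
    r_xm = stats::cor(x, m), r_xy = stats::cor(x, y),
    r_my = stats::cor(m, y), n = n
  )
  if (all(abs(c(ci$r_xm, ci$r_xy, ci$r_my)) >= 1 - 1e-12)) {
    warning("degenerate input: all three correlations are unity", call. = FALSE)
  }
  ci
}

#' Fit the saturated standardized mediation model
#'
#' Computes standardized path coefficients for the model in which predictor X
#' affects outcome Y directly (c') and indirectly through mediator M
#' (a then b), from the three pairwise correlations. For a saturated model of
#' standardized variables the maximum-likelihood point estimates equal the
#' OLS normal-equation solutions, and the total effect decomposes exactly as
#' \eqn{c = c' + ab}. t statistics use finite-sample OLS forms:
#' \eqn{t_a = a\sqrt{n-2}/\sqrt{1-a^2}} on \eqn{n-2} df for the simple
#' regression of M on X, and
#' \eqn{t = \beta \big/ \sqrt{(1-R^2_Y)/\{(n-3)(1-r_{xm}^2)\}}} on \eqn{n-3}
#' df for the two-predictor outcome equation. Explained variances are
#' \eqn{R^2_M = a^2} and \eqn{R^2_Y = c'\,r_{xy} + b\,r_{my}}.
#'
#' @param input a [correlation_input()] (use [corr_from_data()] for raw
#'   vectors).
#' @param alpha two-tailed significance level used to classify the effect
#'   pattern (default 0.05).
#' @return A `mediation_fit` list: paths `a`, `b`, `c_prime`, `c_total`,
#'   `indirect`; `r2_m`, `r2_y`; `t` and `p` per path; `n`; and
#'   `classification` (see [classify_effect()]).
#' @examples
#' fit_mediation(correlation_input(0.35, -0.17, 0.27, n = 86))
#' @export
fit_mediation <- function(input, alpha = 0.05) {
  stopifnot(inherits(input, "correlation_input"))
  r_xm <- input$r_xm
  r_xy <- input$r_xy
  r_my <- input$r_my
  n <- input$n
  if (abs(r_xm) == 1) {
    stop("predictor and mediator are collinear (|r_xm| = 1)", call. = FALSE)
  }
  denom <- 1 - r_xm^2
  a <- r_xm
  b <- (r_my - r_xm * r_xy) / denom
  c_prime <- (r_xy - r_xm * r_my) / denom
  indirect <- a * b
  c_total <- r_xy
  r2_m <- a^2
  r2_y <- c_prime * r_xy + b * r_my

  t_a <- a * sqrt(n - 2) / sqrt(1 - a^2)
  p_a <- 2 * stats::pt(-abs(t_a), df = n - 2)
  se_out <- sqrt((1 - r2_y) / ((n - 3) * denom))
  t_b <- b / se_out
  t_cprime <- c_prime / se_out
  p_b <- 2 * stats::pt(-abs(t_b), df = n - 3)
  p_cprime <- 2 * stats::pt(-abs(t_cprime), df = n - 3)

  fit <- structure(
    list(
      a = a, b = b, c_prime = c_prime, c_total = c_total, indirect = indirect,
      r2_m = r2_m, r2_y = r2_y,
      t = c(a = t_a, b = t_b, c_prime = t_cprime),
      p = c(a = p_a, b = p_b, c_prime = p_cprime),
      n = n, alpha = alpha, classification = NA_character_
    ),
    class = "mediation_fit"
  )
  fit$classification <- classify_effect(fit, alpha = alpha)
  fit
}

#' Classify the mediation pattern
#'
#' Distinguishes four patterns from the fitted standardized paths at a
#' two-tailed significance level:
#' * `"suppression"` — the indirect effect and the direct effect carry
#'   opposite signs and the direct effect is significant: including the
#'   mediator strengthens (and here reverses) the predictor's association
#'   with the outcome;
#' * `"indirect-only"` — both constituent indirect paths (a and b) are
#'   significant while the direct path is not (inconsistent mediation with a
#'   null direct effect);
#' * `"consistent-mediation"` — direct and indirect effects share a sign and
#'   both indirect paths are significant;
#' * `"no-effect"` — anything else.
#'
#' @param fit a `mediation_fit`.
#' @param alpha two-tailed significance level (default 0.05).
#' @return A classification string.
#' @export
classify_effect <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mediation_fit"))
  sig <- fit$p < alpha
  indirect_sig <- sig[["a"]] && sig[["b"]]
  opposite <- sign(fit$indirect) != sign(fit$c_prime) &&
    fit$indirect != 0 && fit$c_prime != 0
  if (opposite && sig[["c_prime"]]) {
    "suppression"
  } else if (indirect_sig && !sig[["c_prime"]]) {
    "indirect-only"
  } else if (!opposite && indirect_sig && sig[["c_prime"]]) {
    "consistent-mediation"
  } else {
    "no-effect"
  }
}

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  cat("<mediation_fit> saturated standardized path model X -> M -> Y\n")
  cat(sprintf("  n = %d, classification: %s\n", x$n, x$classification))
  paths <- data.frame(
    path = c("a (X->M)", "b (M->Y | X)", "c' (X->Y | M)"),
    beta = round(c(x$a, x$b, x$c_prime), digits),
    t = round(unname(x$t), 2),
    p = signif(unname(x$p), 2)
  )
  print(paths, row.names = FALSE)
  cat(sprintf(
    "  indirect a*b = %.3f, total c = %.3f (= c' + a*b)\n",
    x$indirect, x$c_total
  ))
  cat(sprintf(
    "  R^2: mediator %.0f%%, outcome %.0f%%\n",
    100 * x$r2_m, 100 * x$r2_y
  ))
  invisible(x)
}

#' Bootstrap percentile CI for the indirect effect
#'
#' Nonparametric case-resampling bootstrap of the standardized indirect
#' effect a*b, with a seeded generator for reproducibility. Supplements the
#' path t statistics with a distribution-free interval.
#'
#' @param x,m,y raw data vectors (equal length).
#' @param replicates number of bootstrap resamples (>= 1000).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param conf confidence level (default 0.95).
#' @return List with `estimate` (point estimate of a*b), `lower`, `upper`,
#'   `replicates`, `conf`.
#' @export
bootstrap_indirect <- function(x, m, y, replicates = 2000L, seed = 1L,
                               conf = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n) {
    stop("`x`, `m`, `y` must have equal length", call. = FALSE)
  }
  if (n < 10L) stop("too few observations for a bootstrap", call. = FALSE)
  if (replicates < 1000L) stop("use at least 1000 replicates", call. = FALSE)

  point <- fit_mediation(corr_from_data(x, m, y))$indirect
  rng <- local({
    set.seed(seed)
    function(n_draw) sample.int(n, n_draw, replace = TRUE)
  })
  ab <- vapply(seq_len(replicates), function(i) {
    idx <- rng(n)
    xi <- x[idx]
    mi <- m[idx]
    yi <- y[idx]
    sx <- stats::sd(xi)
    sm <- stats::sd(mi)
    sy <- stats::sd(yi)
    if (sx == 0 || sm == 0 || sy == 0) {
      return(NA_real_)
    }
    r_xm <- stats::cor(xi, mi)
    r_xy <- stats::cor(xi, yi)
    r_my <- stats::cor(mi, yi)
    a <- r_xm
    b <- (r_my - r_xm * r_xy) / (1 - r_xm^2)
    a * b
  }, numeric(1))
  ab <- ab[!is.na(ab)]
  qs <- stats::quantile(ab, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
    names = FALSE, type = 7
  )
  list(
    estimate = point, lower = qs[1], upper = qs[2],
    replicates = replicates, conf = conf
  )
}

#' Write a fitted mediation model to JSON
#'
#' Emits the paths, t and p values, explained variances and classification.
#'
#' @param fit a `mediation_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mediation_json <- function(fit, path) {
  stopifnot(inherits(fit, "mediation_fit"))
  out <- list(
    n = fit$n,
    paths = list(
      a = fit$a, b = fit$b, c_prime = fit$c_prime,
      c_total = fit$c_total, indirect = fit$indirect
    ),
    t = as.list(fit$t), p = as.list(fit$p),
    r2 = list(mediator = fit$r2_m, outcome = fit$r2_y),
    classification = fit$classification
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
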