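#' Method-agreement regression and precipitation-response model selection
#'
#' Agreement between survey methods is summarised by a degree-1 least-squares
#' fit (R-squared, model F-test p) plus deviations from the 1:1 line. The
#' response of each diversity index to precipitation is modelled as either a
#' simple linear or a quadratic polynomial; the two nested fits are compared
#' with a Gaussian-likelihood ratio test, LRT = n * ln(RSS1 / RSS2) against
#' chi-squared with 1 df, and the quadratic is chosen when its p-value falls
#' below the alpha level (0.05 by default). An F-test variant is available
#' and must agree in selection on well-behaved data.
#'
#' @name gradient-stats
NULL

#' Polynomial least-squares fit with R-squared and model F-test
#'
#' @param x covariate vector.
#' @param y response vector; pairs with a missing value are dropped.
#' @param degree polynomial degree, 1 (linear) or 2 (quadratic).
#' @return list of class `ols_fit`: `degree`, `coefficients` (intercept
#'   first), `r_squared`, `p_value` (F-test against the intercept-only
#'   model), `n`, `rss`, `fitted`, `x`, `y`.
#' @export
ols_fit <- function(x, y, degree = 1) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (!degree %in% c(1, 2)) abort("degree must be 1 or 2")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < degree + 2) {
    abort(sprintf("need at least %d complete observations for degree %d",
                  degree + 2, degree))
  }
  if (length(unique(x)) <= degree) {
    abort("degenerate design: too few distinct covariate values")
  }
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  s <- summary(fit)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  # a zero-variance response is a perfect intercept-only fit: R2 = 0, no F
  r_squared <- if (tss == 0) 0 else 1 - rss / tss
  p_value <- if (is.null(s$fstatistic)) {
    NA_real_
  } else {
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE))
  }
  structure(list(
    degree = degree,
    coefficients = unname(coef(fit)),
    r_squared = r_squared,
    p_value = p_value,
    n = n,
    rss = rss,
    fitted = unname(fit$fitted.values),
    x = x, y = y
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("degree-%d fit (n = %d): R2 = %.4f, p = %.4g\n  coefficients: %s\n",
              x$degree, x$n, x$r_squared, x$p_value,
              paste(signif(x$coefficients, 6), collapse = ", ")))
  invisible(x)
}

#' Agreement between two methods' measurements of the same index
#'
#' Linear fit of method-2 values on method-1 values plus diagnostics against
#' the 1:1 line (the line the two methods would trace if they agreed
#' exactly).
#'
#' @param x index values per site under the reference method.
#' @param y the same index, same sites, under the compared method.
#' @return list of class `method_agreement`: the degree-1 `fit`, plus
#'   `mean_deviation` (mean of y - x) and `max_abs_deviation`.
#' @export
method_agreement <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("method agreement needs at least 3 complete pairs")
  fit <- ols_fit(x[ok], y[ok], degree = 1)
  structure(list(
    fit = fit,
    mean_deviation = mean(y[ok] - x[ok]),
    max_abs_deviation = max(abs(y[ok] - x[ok]))
  ), class = "method_agreement")
}

#' Likelihood-ratio choice between linear and quadratic response models
#'
#' Fits nested degree-1 and degree-2 polynomials by least squares and
#' compares them with the Gaussian likelihood-ratio statistic
#' n * ln(RSS1 / RSS2) referred to chi-squared(1) (`test = "lrt"`), or with
#' the extra-sum-of-squares F-test (`test = "ftest"`). The quadratic is
#' chosen iff p < alpha.
#'
#' @param x covariate (precipitation, mm).
#' @param y response (a diversity index).
#' @param alpha selection level (default 0.05).
#' @param test `"lrt"` (default) or `"ftest"`.
#' @return list of class `model_choice`: `chosen_degree`, `statistic`,
#'   `p_value`, `alpha`, `test`, `flag` (NA or a note on degenerate fits),
#'   `fit` (the selected model's [ols_fit]), `fit_linear`, `fit_quadratic`.
#' @export
lrt_select <- function(x, y, alpha = 0.05, test = c("lrt", "ftest")) {
  test <- match.arg(test)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 5) abort("model selection needs at least 5 complete pairs")
  f1 <- ols_fit(x[ok], y[ok], degree = 1)
  f2 <- ols_fit(x[ok], y[ok], degree = 2)
  n <- f1$n
  flag <- NA_character_
  eps <- .Machine$double.eps * max(1, sum(y[ok]^2))
  if (f2$rss <= eps && f1$rss <= eps) {
    # both models interpolate: keep the simpler one
    choice <- list(degree = 1, stat = 0, p = 1)
    flag <- "both fits saturated; linear kept by parsimony"
  } else if (f2$rss <= eps) {
    choice <- list(degree = 2, stat = Inf, p = 0)
    flag <- "saturated quadratic fit"
  } else {
    stat <- if (test == "lrt") {
      n * log(f1$rss / f2$rss)
    } else {
      (f1$rss - f2$rss) / (f2$rss / (n - 3))
    }
    p <- if (test == "lrt") {
      pchisq(stat, df = 1, lower.tail = FALSE)
    } else {
      pf(stat, 1, n - 3, lower.tail = FALSE)
    }
    choice <- list(degree = if (p < alpha) 2 else 1, stat = stat, p = p)
  }
  structure(list(
    chosen_degree = choice$degree,
    statistic = choice$stat,
    p_value = choice$p,
    alpha = alpha,
    test = test,
    flag = flag,
    fit = if (choice$degree == 2) f2 else f1,
    fit_linear = f1,
    fit_quadratic = f2
  ), class = "model_choice")
}

#' Shapiro-Wilk normality check
#'
#' Reported in the pipeline log for each index; it does not gate any
#' analysis.
#'
#' @param y numeric sample, 3 <= n <= 5000 after dropping NA.
#' @return list with `statistic` (W) and `p_value`.
#' @export
shapiro_normality <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 3 || length(y) > 5000) {
    abort("Shapiro-Wilk requires between 3 and 5000 observations")
  }
  s <- shapiro.test(y)
  list(statistic = unname(s$statistic), p_value = s$p.value)
}

#' Precipitation response of a set of diversity indices
#'
#' Joins index values to precipitation and runs [lrt_select] per index,
#' returning the selected model for each. Undefined index values (e.g.
#' Pielou at single-species sites) are dropped pairwise; an index with no
#' usable values raises an error naming it.
#'
#' @param values tibble with an identifier column plus one numeric column
#'   per index (e.g. the output of [alpha_profile], or an adjacent-bin beta
#'   series with `midpoint_mm`).
#' @param x name of the covariate column in `values` (e.g. `"precip_mm"`),
#'   which must already be joined in.
#' @param indices character vector of index column names to model.
#' @param alpha selection level.
#' @param test passed to [lrt_select].
#' @return tibble with one row per index: `index`, `n`, `chosen_degree`,
#'   `lrt_stat`, `lrt_p`, `coef0`, `coef1`, `coef2` (NA for a linear
#'   choice), `r2`, `p_value`.
#' @export
gradient_response <- function(values, x, indices, alpha = 0.05,
                              test = c("lrt", "ftest")) {
  test <- match.arg(test)
  if (!x %in% names(values)) abort(sprintf("covariate column '%s' not found", x))
  rows <- lapply(indices, function(idx) {
    if (!idx %in% names(values)) abort(sprintf("index column '%s' not found", idx))
    yv <- values[[idx]]
    xv <- values[[x]]
    if (all(is.na(yv))) {
      abort(sprintf("index '%s' has no defined values", idx))
    }
    mc <- lrt_select(xv, yv, alpha = alpha, test = test)
    cf <- mc$fit$coefficients
    tibble::tibble(
      index = idx, n = mc$fit$n, chosen_degree = mc$chosen_degree,
      lrt_stat = mc$statistic, lrt_p = mc$p_value,
      coef0 = cf[1], coef1 = cf[2],
      coef2 = if (length(cf) > 2) cf[3] else NA_real_,
      r2 = mc$fit$r_squared, p_value = mc$fit$p_value
    )
  })
  dplyr::bind_rows(rows)
}
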