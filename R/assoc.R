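#' Polynomial OLS fit of a function or EMF on a predictor
#'
#' Fits `y ~ x` (degree 1) or `y ~ x + x^2` (degree 2) by least squares.
#' Raw and standardized coefficients (the same polynomial refit on z-scored
#' x and y) are both reported, together with R^2, AIC and the two-sided
#' p-value of the highest-order term. Diversity-multifunctionality
#' relationships are often hump-shaped, hence the quadratic option.
#'
#' @param x Numeric predictor (nonconstant).
#' @param y Numeric response.
#' @param degree 1 (linear) or 2 (quadratic).
#' @param predictor_name,response_name Labels for printing.
#' @return An `emf_ols`: list with `coefficients` (raw), `std_coefficients`,
#'   `r_squared`, `p_value` (highest-order term), `aic`, `degree`, `n`, and
#'   the underlying `lm` fit.
#' @export
ols_fit <- function(x, y, degree = 1,
                    predictor_name = deparse(substitute(x)),
                    response_name = deparse(substitute(y))) {
  if (!degree %in% c(1, 2)) stop("ols_fit: degree must be 1 or 2")
  if (length(x) != length(y)) stop("ols_fit: x and y lengths differ")
  n <- length(x)
  if (n < degree + 2) stop("ols_fit: need at least degree + 2 observations")
  if (stats::var(x) == 0) stop("ols_fit: predictor is constant")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", "x", if (degree == 2) "x^2")
  zfit <- stats::lm(scale(y)[, 1] ~ stats::poly(scale(x)[, 1], degree, raw = TRUE))
  zcf <- stats::coef(zfit)
  names(zcf) <- names(cf)
  sm <- summary(fit)$coefficients
  structure(list(coefficients = cf, std_coefficients = zcf,
                 r_squared = summary(fit)$r.squared,
                 p_value = sm[nrow(sm), "Pr(>|t|)"],
                 aic = stats::AIC(fit), degree = degree, n = n,
                 predictor_name = predictor_name,
                 response_name = response_name, fit = fit),
            class = "emf_ols")
}

#' @export
print.emf_ols <- function(x, ...) {
  cat(sprintf("OLS fit (degree %d): %s ~ %s, n = %d\n", x$degree,
              x$response_name, x$predictor_name, x$n))
  cat(sprintf("  R^2 = %.4f, p(highest-order term) = %.4g, AIC = %.2f\n",
              x$r_squared, x$p_value, x$aic))
  cat("  raw coefficients: ",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.emf_ols <- function(object, standardized = FALSE, ...) {
  if (standardized) object$std_coefficients else object$coefficients
}

#' Linear and quadratic fits with AIC comparison
#'
#' Produces both polynomial fits and flags the one with the lower AIC — the
#' linear/hump-shape question is left to the data rather than decided per
#' predictor.
#'
#' @inheritParams ols_fit
#' @return List with `linear`, `quadratic` (both `emf_ols`) and `preferred`
#'   (`"linear"` or `"quadratic"`).
#' @export
ols_both <- function(x, y, predictor_name = deparse(substitute(x)),
                     response_name = deparse(substitute(y))) {
  l1 <- ols_fit(x, y, 1, predictor_name, response_name)
  l2 <- ols_fit(x, y, 2, predictor_name, response_name)
  list(linear = l1, quadratic = l2,
       preferred = if (l2$aic < l1$aic) "quadratic" else "linear")
}

#' Predictor x function correlation matrix with FDR adjustment
#'
#' Pairwise correlations between every predictor column and every function
#' column (Spearman by default, Pearson optional), with Benjamini-Hochberg
#' adjustment over all cells of the matrix. Rows must be aligned on the same
#' plots (matching rownames when both sides carry them).
#'
#' @param predictors data.frame/matrix of predictor columns (plots in rows).
#' @param functions data.frame/matrix of response columns, same plots.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `cor_heatmap`: long-format data.frame with columns `predictor`,
#'   `response`, `rho`, `p`, `q`.
#' @export
correlation_heatmap <- function(predictors, functions,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pm <- as.matrix(predictors); fm <- as.matrix(functions)
  if (nrow(pm) != nrow(fm))
    stop("correlation_heatmap: predictor and function tables differ in rows")
  if (nrow(pm) < 4) stop("correlation_heatmap: need >= 4 plots")
  if (!is.null(rownames(pm)) && !is.null(rownames(fm)) &&
      !identical(rownames(pm), rownames(fm)))
    stop("correlation_heatmap: plot ids are misaligned")
  grid <- expand.grid(predictor = colnames(pm), response = colnames(fm),
                      stringsAsFactors = FALSE)
  n <- nrow(pm)
  res <- t(apply(grid, 1, function(g) {
    x <- pm[, g[["predictor"]]]; y <- fm[, g[["response"]]]
    r <- suppressWarnings(stats::cor(x, y, method = method))
    p <- if (!is.finite(r)) NA_real_
    else if (method == "spearman") .spearman_p(r, n)
    else if (abs(r) >= 1) 0
    else 2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2,
                       lower.tail = FALSE)
    c(rho = r, p = p)
  }))
  out <- cbind(grid, as.data.frame(res))
  out$q <- bh_adjust(out$p, allow_na = TRUE)
  class(out) <- c("cor_heatmap", "data.frame")
  out
}

#' Random-forest permutation importance for EMF drivers
#'
#' Fits a regression forest and reports, per feature, the percent increase in
#' out-of-bag mean squared error when that feature is permuted: 100 x (raw
#' OOB permutation increase) / (OOB MSE of the forest). Deterministic given
#' the seed.
#'
#' @param features data.frame/matrix of numeric feature columns (n >= 20
#'   rows, >= 2 features).
#' @param response Numeric response (e.g. the EMF index).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return An `importance_table`: data.frame with `feature`,
#'   `importance_pct`, `rank`, sorted by decreasing importance.
#' @export
rf_importance <- function(features, response, n_trees = 500, seed = 1) {
  x <- as.data.frame(features)
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("rf_importance: all features must be numeric")
  if (nrow(x) < 20) stop("rf_importance: need n >= 20")
  if (ncol(x) < 2) stop("rf_importance: need >= 2 features")
  if (length(response) != nrow(x))
    stop("rf_importance: response length must match features")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = x, y = response, ntree = n_trees,
    mtry = max(1L, floor(ncol(x) / 3)), importance = TRUE)
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  pct <- 100 * raw / rf$mse[n_trees]
  ord <- order(pct, decreasing = TRUE)
  out <- data.frame(feature = names(pct)[ord],
                    importance_pct = unname(pct[ord]),
                    rank = seq_along(pct),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}
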