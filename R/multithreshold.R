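#' Rescale functions to [0, 1]
#'
#' Maps each function column to `(x - min) / (max - min)` so that a threshold
#' `t` can be read as a fraction of each function's observed maximum. With
#' `max_method = "top_mean"` the upper anchor is the mean of the top
#' `top_frac` of values instead of the single observed maximum (values above
#' the anchor are capped at 1), a common guard against a single outlier plot
#' defining the maximum.
#'
#' @param fm Numeric matrix / `function_matrix` of raw function values.
#' @param max_method `"observed"` (default) or `"top_mean"`.
#' @param top_frac Fraction of top values averaged when `max_method =
#'   "top_mean"` (default 0.05).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
rescale_functions <- function(fm, max_method = c("observed", "top_mean"),
                              top_frac = 0.05) {
  max_method <- match.arg(max_method)
  m <- as.matrix(fm)
  rng <- apply(m, 2, range)
  if (any(rng[2, ] - rng[1, ] == 0)) {
    bad <- colnames(m)[rng[2, ] - rng[1, ] == 0]
    if (is.null(bad)) bad <- which(rng[2, ] - rng[1, ] == 0)
    stop("rescale_functions: zero-range column(s): ", paste(bad, collapse = ", "))
  }
  hi <- if (max_method == "observed") rng[2, ] else
    apply(m, 2, function(x) {
      k <- max(1L, ceiling(top_frac * length(x)))
      mean(sort(x, decreasing = TRUE)[seq_len(k)])
    })
  out <- sweep(sweep(m, 2, rng[1, ], "-"), 2, hi - rng[1, ], "/")
  pmin(out, 1)
}

#' Number of functions at or above a threshold
#'
#' @param scaled Matrix of functions rescaled to `[0, 1]`.
#' @param t Threshold fraction in `(0, 1]`; comparison is `>=`.
#' @return Integer vector, one count per plot.
#' @export
func_maxed <- function(scaled, t) {
  m <- as.matrix(scaled)
  if (length(t) != 1 || !is.finite(t) || t <= 0 || t > 1)
    stop("func_maxed: threshold must be a single value in (0, 1]")
  if (min(m) < 0 || max(m) > 1)
    stop("func_maxed: matrix must be rescaled to [0, 1]")
  as.integer(rowSums(m >= t))
}

# closed-form simple OLS of y on x: slope, 95% CI, two-sided p.
# Constant y => slope 0, p 1 (no diversity effect detectable, not an error).
.ols_slope <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("predictor has zero variance")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  if (stats::var(y) == 0)
    return(c(slope = 0, ci_low = 0, ci_high = 0, p_value = 1))
  res <- y - mean(y) - b * (x - mean(x))
  df <- n - 2
  se <- sqrt(sum(res^2) / df / sxx)
  tq <- stats::qt(0.975, df)
  p <- if (se == 0) 0 else 2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
  c(slope = b, ci_low = b - tq * se, ci_high = b + tq * se, p_value = p)
}

#' Per-threshold diversity slopes (multithreshold analysis)
#'
#' At every threshold `t` on the grid, regresses the per-plot number of
#' functions at or above `t` (the threshold-based multifunctionality index
#' MFt) on a diversity predictor, by ordinary least squares. The slope is in
#' functions per unit of the predictor (e.g. functions per species). A
#' quasi-Poisson GLM family is exposed for the count response but linear OLS
#' is the default.
#'
#' @param scaled Function matrix rescaled to `[0, 1]` (see
#'   [rescale_functions()]).
#' @param predictor Numeric diversity values, one per plot, nonconstant.
#' @param grid Thresholds in `(0, 1)`; default 1 to 99 percent in 1 percent steps.
#' @param family `"gaussian"` (OLS, default) or `"quasipoisson"`.
#' @param predictor_name Label stored with the curve.
#' @return A `threshold_curve`: list with `table` (threshold, slope, ci_low,
#'   ci_high, p_value), `counts` (plots x thresholds MFt surface), `n`,
#'   `predictor_name`.
#' @export
threshold_slopes <- function(scaled, predictor, grid = seq(0.01, 0.99, by = 0.01),
                             family = c("gaussian", "quasipoisson"),
                             predictor_name = deparse(substitute(predictor))) {
  family <- match.arg(family)
  m <- as.matrix(scaled)
  if (nrow(m) < 3) stop("threshold_slopes: need at least 3 plots")
  if (length(predictor) != nrow(m))
    stop("threshold_slopes: predictor length must equal number of plots")
  if (stats::var(predictor) == 0)
    stop("threshold_slopes: predictor has zero variance")
  if (any(grid <= 0 | grid >= 1)) stop("threshold_slopes: grid must lie in (0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) stop("threshold_slopes: grid must be strictly increasing")
  counts <- vapply(grid, function(t) func_maxed(m, t), integer(nrow(m)))
  colnames(counts) <- sprintf("t%.2f", grid)
  rownames(counts) <- rownames(m)
  fit_one <- function(y) {
    if (family == "gaussian") return(.ols_slope(predictor, y))
    if (stats::var(y) == 0)
      return(c(slope = 0, ci_low = 0, ci_high = 0, p_value = 1))
    g <- stats::glm(y ~ predictor, family = stats::quasipoisson())
    cf <- summary(g)$coefficients
    b <- cf["predictor", "Estimate"]; se <- cf["predictor", "Std. Error"]
    tq <- stats::qt(0.975, g$df.residual)
    c(slope = b, ci_low = b - tq * se, ci_high = b + tq * se,
      p_value = cf["predictor", "Pr(>|t|)"])
  }
  fits <- t(apply(counts, 2, fit_one))
  structure(list(table = data.frame(threshold = grid,
                                    slope = fits[, "slope"],
                                    ci_low = fits[, "ci_low"],
                                    ci_high = fits[, "ci_high"],
                                    p_value = fits[, "p_value"],
                                    row.names = NULL),
                 counts = counts, n = nrow(m),
                 predictor_name = predictor_name, family = family),
            class = "threshold_curve")
}

#' Summarise a threshold curve (Tmin, Tmax, Tmde, Rmde)
#'
#' Scans the significant part of the slope curve: `t_min` / `t_max` are the
#' smallest / largest grid thresholds with `p < alpha`; `t_mde` is the
#' significant threshold with the largest absolute slope (smallest such
#' threshold on exact ties) and `r_mde` the signed slope there. When no
#' threshold is significant all four are `NA` — diversity has no detectable
#' effect at any threshold.
#'
#' @param curve A `threshold_curve`.
#' @param alpha Significance level (default 0.05).
#' @return A `threshold_summary`: list `t_min`, `t_max`, `t_mde`, `r_mde`,
#'   `alpha`, `predictor_name`.
#' @export
summarize_thresholds <- function(curve, alpha = 0.05) {
  if (!inherits(curve, "threshold_curve"))
    stop("summarize_thresholds: input must be a threshold_curve")
  tab <- curve$table
  sig <- which(tab$p_value < alpha)
  if (!length(sig)) {
    out <- list(t_min = NA_real_, t_max = NA_real_, t_mde = NA_real_,
                r_mde = NA_real_)
  } else {
    imde <- sig[which.max(abs(tab$slope[sig]))]  # which.max takes first on ties
    out <- list(t_min = tab$threshold[min(sig)],
                t_max = tab$threshold[max(sig)],
                t_mde = tab$threshold[imde],
                r_mde = tab$slope[imde])
  }
  structure(c(out, list(alpha = alpha, predictor_name = curve$predictor_name)),
            class = "threshold_summary")
}

#' One-call multithreshold analysis
#'
#' Convenience wrapper: rescale raw functions, fit the per-threshold slope
#' curve, summarise it.
#'
#' @inheritParams threshold_slopes
#' @inheritParams summarize_thresholds
#' @param fm Raw `function_matrix`.
#' @param ... Passed to [rescale_functions()].
#' @return List with `curve` and `summary`.
#' @export
multithreshold_analysis <- function(fm, predictor, grid = seq(0.01, 0.99, by = 0.01),
                                    alpha = 0.05,
                                    predictor_name = deparse(substitute(predictor)),
                                    ...) {
  scaled <- rescale_functions(fm, ...)
  curve <- threshold_slopes(scaled, predictor, grid = grid,
                            predictor_name = predictor_name)
  list(curve = curve, summary = summarize_thresholds(curve, alpha = alpha))
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("Multithreshold curve: %s, %d plots, grid %.2f-%.2f (%d thresholds)\n",
              x$predictor_name, x$n, min(x$table$threshold),
              max(x$table$threshold), nrow(x$table)))
  sig <- sum(x$table$p_value < 0.05)
  cat(sprintf("  significant thresholds at alpha=0.05: %d\n", sig))
  invisible(x)
}

#' @export
print.threshold_summary <- function(x, ...) {
  cat(sprintf("Multithreshold summary for %s (alpha = %g):\n",
              x$predictor_name, x$alpha))
  if (is.na(x$t_min)) {
    cat("  no significant thresholds\n")
  } else {
    cat(sprintf("  Tmin = %.2f  Tmax = %.2f  Tmde = %.2f  Rmde = %+.4f\n",
                x$t_min, x$t_max, x$t_mde, x$r_mde))
  }
  invisible(x)
}
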