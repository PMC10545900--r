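#' Specify a recursive path model
#'
#' A directed acyclic diagram over observed variables. Edges can be given as
#' a data.frame with columns `from`, `to`, or as character lines of the form
#' `"SOURCE -> TARGET"` (the format of a plain-text spec file). Cycles are
#' rejected with a message naming one cycle. Exogenous variables (never a
#' target) are identified automatically; their variances and pairwise
#' covariances are free parameters of the fitted model.
#'
#' @param edges data.frame (`from`, `to`) or character vector of
#'   `"A -> B"` lines.
#' @return A `path_spec`: list with `edges`, `variables` (topologically
#'   sorted), `exogenous`, `endogenous`.
#' @export
path_spec <- function(edges) {
  if (is.character(edges)) {
    lines <- trimws(edges[nzchar(trimws(edges))])
    lines <- lines[!startsWith(lines, "#")]
    parts <- strsplit(lines, "->", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("path_spec: each line must read 'SOURCE -> TARGET'")
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1)),
                        to = trimws(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges)))
    stop("path_spec: edges need 'from' and 'to' columns")
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("path_spec: self-loops are not allowed")
  if (anyDuplicated(edges[, c("from", "to")]))
    stop("path_spec: duplicate edges")
  vars <- unique(c(edges$from, edges$to))
  order <- .topo_sort(vars, edges)   # errors on cycles, naming one
  exo <- setdiff(vars, edges$to)
  structure(list(edges = edges[, c("from", "to")],
                 variables = order,
                 exogenous = order[order %in% exo],
                 endogenous = order[!order %in% exo]),
            class = "path_spec")
}

# Kahn topological sort; on failure, walks the leftover subgraph to name a cycle
.topo_sort <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  active <- edges
  queue <- vars[indeg == 0]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    hit <- active$from == v
    for (w in active$to[hit]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    active <- active[!hit, , drop = FALSE]
  }
  if (length(out) < length(vars)) {
    rem <- setdiff(vars, out)
    # walk successors within the remainder until a vertex repeats
    nxt <- function(v) intersect(edges$to[edges$from == v], rem)
    path <- rem[1]
    repeat {
      succ <- nxt(path[length(path)])[1]
      if (succ %in% path) {
        cyc <- c(path[which(path == succ):length(path)], succ)
        stop("path_spec: the diagram contains a cycle: ",
             paste(cyc, collapse = " -> "))
      }
      path <- c(path, succ)
    }
  }
  out
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("Path model spec: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edges)))
    cat("  ", x$edges$from[i], "->", x$edges$to[i], "\n")
  invisible(x)
}

# coefficient matrix B with B[target, source] = coefficient
.b_matrix <- function(spec, coefficients) {
  v <- spec$variables
  B <- matrix(0, length(v), length(v), dimnames = list(v, v))
  B[cbind(match(coefficients$to, v), match(coefficients$from, v))] <-
    coefficients$coef
  B
}

#' Model-implied covariance of a recursive system
#'
#' `Sigma = (I - B)^-1 Psi (I - B)^-T`, where `B` holds the path
#' coefficients and `Psi` the exogenous (co)variances and endogenous
#' residual variances.
#'
#' @param spec A `path_spec`.
#' @param coefficients data.frame `from`, `to`, `coef`.
#' @param residual_variances Named vector of residual variances for the
#'   endogenous variables (>= 0).
#' @param exo_cov Optional covariance matrix of the exogenous variables
#'   (default: identity, i.e. standardized independent exogenous inputs).
#' @return Symmetric positive-semidefinite covariance matrix over
#'   `spec$variables`.
#' @export
implied_covariance <- function(spec, coefficients, residual_variances,
                               exo_cov = NULL) {
  stopifnot(inherits(spec, "path_spec"))
  if (any(residual_variances < 0))
    stop("implied_covariance: residual variances must be >= 0")
  v <- spec$variables
  B <- .b_matrix(spec, coefficients)
  Psi <- matrix(0, length(v), length(v), dimnames = list(v, v))
  if (is.null(exo_cov)) {
    diag(Psi)[match(spec$exogenous, v)] <- 1
  } else {
    Psi[spec$exogenous, spec$exogenous] <-
      as.matrix(exo_cov)[spec$exogenous, spec$exogenous]
  }
  diag(Psi)[match(names(residual_variances), v)] <- residual_variances
  IB <- solve(diag(length(v)) - B)
  S <- IB %*% Psi %*% t(IB)
  (S + t(S)) / 2
}

#' Fit a recursive path model
#'
#' Observed-variable path analysis: variables are z-scored, each endogenous
#' variable is regressed on its parents (equation-by-equation least squares,
#' the maximum-likelihood estimator for a recursive system with independent
#' errors), so the coefficients are standardized path coefficients. The
#' model-implied covariance is assembled from the coefficient matrix, the
#' residual variances and the free exogenous covariances, and global fit is
#' summarised by the ML discrepancy chi-square
#' `(n-1) * [ln|Sigma| + tr(S Sigma^-1) - ln|S| - p]`, the goodness-of-fit
#' index `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]` and
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n-1)))` (0 when df = 0).
#'
#' @param data data.frame/matrix of observed variables (plots in rows); must
#'   contain every variable of the spec, each nonconstant, with
#'   `n > p + 2` rows.
#' @param spec A `path_spec`.
#' @return A `path_fit`: list with `edges` (from, to, coef, se, p_value),
#'   `residual_variances`, `chi_square`, `df`, `p_value`, `gfi`, `rmsea`,
#'   `n`, `observed` and `implied` correlation matrices, and `spec`.
#' @export
fit_path_model <- function(data, spec) {
  stopifnot(inherits(spec, "path_spec"))
  d <- as.data.frame(data)
  miss <- setdiff(spec$variables, names(d))
  if (length(miss))
    stop("fit_path_model: data lacks variable(s): ", paste(miss, collapse = ", "))
  d <- d[, spec$variables, drop = FALSE]
  n <- nrow(d); p <- ncol(d)
  if (n <= p + 2) stop("fit_path_model: need n > number of variables + 2")
  z <- zscore_columns(d)   # errors on constant columns, naming them
  S <- stats::cov(z)       # correlation matrix of the observed variables
  if (abs(det(S)) < 1e-12)
    stop("fit_path_model: observed covariance matrix is singular")
  edges <- spec$edges
  edges$coef <- NA_real_; edges$se <- NA_real_; edges$p_value <- NA_real_
  resid_var <- stats::setNames(numeric(length(spec$endogenous)), spec$endogenous)
  for (y in spec$endogenous) {
    pa <- edges$from[edges$to == y]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, y])
    rv <- S[y, y] - drop(crossprod(b, S[pa, y]))
    resid_var[y] <- max(rv, 0)
    k <- length(pa)
    se <- sqrt(pmax(resid_var[y], 1e-300) / (n - k - 1) *
                 diag(solve(S[pa, pa, drop = FALSE])))
    tstat <- b / se
    idx <- match(paste(pa, y), paste(edges$from, edges$to))
    edges$coef[idx] <- b
    edges$se[idx] <- se
    edges$p_value[idx] <- 2 * stats::pt(abs(tstat), n - k - 1, lower.tail = FALSE)
  }
  Sigma <- implied_covariance(spec, edges, resid_var,
                              exo_cov = S[spec$exogenous, spec$exogenous,
                                          drop = FALSE])
  SigInv <- solve(Sigma)
  f_ml <- as.numeric(determinant(Sigma)$modulus + sum(diag(S %*% SigInv)) -
                       determinant(S)$modulus - p)
  chi2 <- max((n - 1) * f_ml, 0)
  nexo <- length(spec$exogenous)
  free <- nrow(edges) + length(resid_var) + nexo + choose(nexo, 2)
  df <- p * (p + 1) / 2 - free
  if (df < 0) stop("fit_path_model: model has negative degrees of freedom")
  M <- SigInv %*% S
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) / sum(diag(M %*% M))
  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  pval <- if (df == 0) NA_real_ else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(edges = edges, residual_variances = resid_var,
                 chi_square = chi2, df = df, p_value = pval,
                 gfi = gfi, rmsea = rmsea, n = n,
                 observed = S, implied = Sigma, spec = spec),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model fit (n = %d):\n", x$n))
  cat(sprintf("  chi-square = %.4f on %d df (p = %s), GFI = %.4f, RMSEA = %.4f\n",
              x$chi_square, x$df,
              if (is.na(x$p_value)) "NA, saturated" else sprintf("%.4f", x$p_value),
              x$gfi, x$rmsea))
  e <- x$edges
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s -> %s: %+.3f (se %.3f, p %.4g)\n",
                e$from[i], e$to[i], e$coef[i], e$se[i], e$p_value[i]))
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) {
  stats::setNames(object$edges$coef,
                  paste(object$edges$from, object$edges$to, sep = "->"))
}

#' @export
summary.path_fit <- function(object, ...) {
  eff <- effect_decomposition(object$spec, object$edges)
  structure(list(fit = object, effects = eff), class = "summary.path_fit")
}

#' @export
print.summary.path_fit <- function(x, ...) {
  print(x$fit)
  cat("Effect decomposition (nonzero totals):\n")
  e <- x$effects[x$effects$total != 0, , drop = FALSE]
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s => %s: direct %+.3f, indirect %+.3f, total %+.3f\n",
                e$source[i], e$target[i], e$direct[i], e$indirect[i], e$total[i]))
  invisible(x)
}

#' Direct, indirect and total effects
#'
#' For an acyclic system the total-effect matrix is the geometric series
#' `B + B^2 + ... = (I - B)^-1 - I` (finite because `B` is nilpotent);
#' direct effects are the edge coefficients and indirect effects the sum of
#' coefficient products over all directed paths of length >= 2.
#'
#' @param spec A `path_spec`.
#' @param coefficients data.frame `from`, `to`, `coef` (e.g. `fit$edges`).
#' @return data.frame with columns `source`, `target`, `direct`, `indirect`,
#'   `total` for every ordered variable pair.
#' @export
effect_decomposition <- function(spec, coefficients) {
  stopifnot(inherits(spec, "path_spec"))
  v <- spec$variables
  B <- .b_matrix(spec, coefficients)
  Tot <- solve(diag(length(v)) - B) - diag(length(v))
  grid <- expand.grid(source = v, target = v, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid$direct <- B[cbind(grid$target, grid$source)]
  grid$total <- Tot[cbind(grid$target, grid$source)]
  grid$indirect <- grid$total - grid$direct
  rownames(grid) <- NULL
  grid[, c("source", "target", "direct", "indirect", "total")]
}

#' Default path diagram for the EMF analysis
#'
#' The indicator-level recursive diagram wiring plant species richness (TSR,
#' LSR, SSR), environment (SWC, SBD), microbial diversity (BSR, FSR) and
#' network complexity (BNC, FNC) to EMF: diversity drives complexity,
#' environment drives liana richness and fungal complexity, and TSR, LSR,
#' BNC and FNC carry direct paths to EMF. An editable default, not a fixed
#' truth; pass any edge list to [path_spec()] to change it.
#'
#' @return A `path_spec`.
#' @export
default_emf_path_spec <- function() {
  path_spec(c("TSR -> EMF", "LSR -> EMF", "BNC -> EMF", "FNC -> EMF",
              "BSR -> BNC", "FSR -> FNC", "SWC -> LSR", "SBD -> FNC"))
}
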