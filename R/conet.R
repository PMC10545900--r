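#' Construct an OTU table
#'
#' Container for a samples x OTUs count matrix with an optional OTU -> phylum
#' taxonomy map. Counts must be non-negative integers; duplicate sample or
#' OTU ids are rejected.
#'
#' @param counts Numeric matrix, samples in rows, OTUs in columns, with
#'   dimnames.
#' @param taxonomy Optional named character vector (names = OTU ids, values =
#'   phylum labels).
#' @return Object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("otu_table: counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("otu_table: duplicate sample or OTU ids")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("otu_table: counts must be non-negative integers")
  storage.mode(m) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("otu_table: taxonomy must be named by OTU id")
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(m))]
  }
  structure(list(counts = m, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, total count %.0f%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (is.null(x$taxonomy)) "" else ", taxonomy attached"))
  invisible(x)
}

#' Filter OTUs by overall relative abundance
#'
#' Keeps OTUs whose share of the grand total strictly exceeds
#' `min_rel_abund` (default 10^-4, i.e. relative abundance > 0.01 percent). The
#' sample set is unchanged. Fewer than 2 surviving OTUs is an error, with
#' before/after counts reported.
#'
#' @param table An `otu_table`.
#' @param min_rel_abund Abundance threshold as a fraction (default `1e-4`).
#' @return Filtered `otu_table`.
#' @export
filter_otus <- function(table, min_rel_abund = 1e-4) {
  stopifnot(inherits(table, "otu_table"))
  if (min_rel_abund < 0) stop("filter_otus: min_rel_abund must be >= 0")
  tot <- colSums(table$counts)
  keep <- tot / sum(tot) > min_rel_abund
  if (sum(keep) < 2)
    stop(sprintf(paste0("filter_otus: only %d of %d OTUs exceed relative ",
                        "abundance %g; need at least 2"),
                 sum(keep), ncol(table$counts), min_rel_abund))
  otu_table(table$counts[, keep, drop = FALSE], table$taxonomy)
}

# two-sided p for a Spearman rho via the t approximation (mid-ranks)
.spearman_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- is.finite(r)
  r1 <- abs(r[ok]) >= 1
  p[ok][r1] <- 0
  idx <- which(ok)[!r1]
  tt <- abs(r[idx]) * sqrt((n - 2) / (1 - r[idx]^2))
  p[idx] <- 2 * stats::pt(tt, n - 2, lower.tail = FALSE)
  p
}

#' Pairwise Spearman correlation with BH-adjusted significance
#'
#' Computes mid-rank Spearman correlations between all OTU pairs on per-sample
#' relative abundances (Spearman is invariant to any monotone per-sample
#' scaling, so proportions and counts agree when depths are equal; proportions
#' are the safer default for unequal depths). Two-sided p-values use the t
#' approximation; q-values are Benjamini-Hochberg over the upper triangle.
#' Constant OTU columns have undefined correlations: they are flagged in
#' `$excluded` and their rows/columns carry `NA`, which removes them from
#' edge candidacy.
#'
#' @param table An `otu_table` with >= 4 samples.
#' @param use_relative Convert counts to per-sample proportions first
#'   (default `TRUE`).
#' @return A `cor_result`: list with matrices `rho`, `p`, `q`, sample size
#'   `n` and character vector `excluded`.
#' @export
spearman_matrix <- function(table, use_relative = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  if (nrow(m) < 4) stop("spearman_matrix: need at least 4 samples")
  if (use_relative) {
    depth <- rowSums(m)
    if (any(depth == 0)) stop("spearman_matrix: sample(s) with zero total count")
    m <- m / depth
  }
  sds <- apply(m, 2, stats::sd)
  excluded <- colnames(m)[sds == 0]
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(rho) <- 1
  rho[excluded, ] <- NA; rho[, excluded] <- NA
  n <- nrow(m)
  p <- matrix(.spearman_p(rho, n), ncol(m), ncol(m),
              dimnames = dimnames(rho))
  diag(p) <- 0
  ut <- upper.tri(rho)
  q <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(rho))
  q[ut] <- bh_adjust(p[ut], allow_na = TRUE)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  structure(list(rho = rho, p = p, q = q, n = n, excluded = excluded),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Spearman correlation result: %d OTUs, n = %d samples",
              nrow(x$rho), x$n))
  if (length(x$excluded)) cat(sprintf(", %d constant OTU(s) excluded", length(x$excluded)))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate q-values: on the sorted scale,
#' `q(i) = min over j >= i of m * p(j) / j`, capped at 1. Delegates to
#' [stats::p.adjust()] after validation; the adjustment is order-preserving.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param allow_na Tolerate `NA` entries (returned as `NA`, excluded from m).
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values, allow_na = FALSE) {
  if (!allow_na && any(is.na(p_values)))
    stop("bh_adjust: NA p-values not allowed")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

# ---- random-matrix-theory threshold selection ----------------------------

# Unfold a spectrum by Gaussian broadening of the cumulative spectral
# function and return nearest-neighbour spacings normalised to mean 1.
.unfold_spacings <- function(evals, bw_factor = 2.5) {
  ev <- sort(evals)
  n <- length(ev)
  rng <- ev[n] - ev[1]
  if (rng < 1e-10) stop("degenerate spectrum: all eigenvalues equal")
  h <- bw_factor * rng / (n - 1)
  # smoothed cumulative distribution evaluated at each eigenvalue
  e <- n * vapply(ev, function(x) mean(stats::pnorm(x, mean = ev, sd = h)),
                  numeric(1))
  s <- diff(e)
  s / mean(s)
}

# chi-square goodness of fit of spacings against the Poisson law e^(-s)
.nnsd_poisson_test <- function(spacings, n_bins = 40) {
  n <- length(spacings)
  edges <- seq(0, max(spacings), length.out = n_bins + 1)
  edges[n_bins + 1] <- Inf  # tail bin absorbs everything beyond
  obs <- as.vector(table(cut(spacings, edges, include.lowest = TRUE)))
  expd <- n * (exp(-edges[-(n_bins + 1)]) - exp(-edges[-1]))
  stat <- sum((obs - expd)^2 / expd)
  df <- n_bins - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' RMT-based correlation threshold selection
#'
#' Scans candidate thresholds: at each `t`, correlations with `|rho| < t` are
#' zeroed (diagonal kept), the eigenvalue spectrum of the thresholded matrix
#' is unfolded by Gaussian broadening, and the nearest-neighbour spacing
#' distribution (NNSD) is tested against the Poisson law `e^(-s)` by
#' chi-square goodness of fit. Below the transition the spectrum shows
#' Wigner-type level repulsion (correlated noise); the selected threshold is
#' the smallest `t` whose NNSD is Poisson-compatible (`p > alpha`), i.e. the
#' point where surviving edges behave as independent signal.
#'
#' @param rho Symmetric correlation matrix with unit diagonal, >= 20 rows
#'   (below that the spacing distribution is meaningless).
#' @param scan Candidate thresholds (default `seq(0.30, 0.99, 0.01)`).
#' @param alpha Poisson-compatibility level (default 0.05).
#' @param bw_factor Gaussian-broadening bandwidth as a multiple of the mean
#'   level spacing (default 2.5).
#' @param n_bins Number of spacing histogram bins (default 40).
#' @return An `rmt_scan`: list with `threshold` (selected, or `NA`), `status`
#'   (`"selected"` / `"no-selection"`), `p_value` at selection and `trace`
#'   (data.frame threshold, chi_square, p_value, n_edges).
#' @export
rmt_threshold <- function(rho, scan = seq(0.30, 0.99, by = 0.01), alpha = 0.05,
                          bw_factor = 2.5, n_bins = 40) {
  m <- as.matrix(rho)
  if (nrow(m) != ncol(m)) stop("rmt_threshold: matrix must be square")
  if (nrow(m) < 20) stop("rmt_threshold: need >= 20 OTUs for a meaningful NNSD")
  m[is.na(m)] <- 0
  if (max(abs(m - t(m))) > 1e-8) stop("rmt_threshold: matrix must be symmetric")
  diag(m) <- 1
  if (any(scan <= 0 | scan > 1)) stop("rmt_threshold: scan thresholds must lie in (0, 1]")
  scan <- sort(scan)
  trace <- data.frame(threshold = scan, chi_square = NA_real_,
                      p_value = NA_real_, n_edges = NA_integer_)
  selected <- NA_real_; sel_p <- NA_real_
  for (i in seq_along(scan)) {
    a <- m
    a[abs(a) < scan[i]] <- 0
    diag(a) <- 1
    trace$n_edges[i] <- sum(a[upper.tri(a)] != 0)
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    res <- tryCatch(.nnsd_poisson_test(.unfold_spacings(ev, bw_factor), n_bins),
                    error = function(e) e)
    if (inherits(res, "error")) {
      # a spectrum can only degenerate once thresholding has emptied the
      # matrix; if even the first candidate is degenerate the input is
      if (i == 1) stop("rmt_threshold: ", conditionMessage(res))
      break
    }
    trace$chi_square[i] <- res$statistic
    trace$p_value[i] <- res$p_value
    if (is.na(selected) && res$p_value > alpha) {
      selected <- scan[i]; sel_p <- res$p_value
    }
  }
  structure(list(threshold = selected,
                 status = if (is.na(selected)) "no-selection" else "selected",
                 p_value = sel_p, alpha = alpha, trace = trace),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  if (x$status == "selected") {
    cat(sprintf("RMT threshold scan: selected t = %.3f (NNSD Poisson p = %.3f)\n",
                x$threshold, x$p_value))
  } else {
    cat("RMT threshold scan: no candidate threshold was Poisson-compatible\n")
  }
  cat(sprintf("  scanned %d thresholds in [%.3f, %.3f]\n",
              nrow(x$trace), min(x$trace$threshold), max(x$trace$threshold)))
  invisible(x)
}

#' Build the co-occurrence network
#'
#' An edge joins two OTUs when `|rho| >= threshold` and the BH-adjusted
#' q-value is below `alpha`; the signed rho is kept as the edge weight.
#' Nodes are the OTUs incident to at least one edge; the OTU universe of the
#' correlation result is retained for subnetwork extraction. An empty result
#' is a warning status, not an error.
#'
#' @param corr A `cor_result`.
#' @param threshold Similarity cutoff on `|rho|`, in `(0, 1]` (e.g. an
#'   [rmt_threshold()] selection, or the fixed values 0.850 / 0.540).
#' @param alpha FDR level for edges (default 0.05).
#' @return A `cooccurrence_network`: list with `graph` (igraph), `edges`
#'   (data.frame source, target, rho, q), `nodes`, `universe`, `threshold`,
#'   `alpha`, `status`.
#' @export
build_network <- function(corr, threshold, alpha = 0.05) {
  stopifnot(inherits(corr, "cor_result"))
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("build_network: threshold must be a single value in (0, 1]")
  ids <- rownames(corr$rho)
  ut <- which(upper.tri(corr$rho), arr.ind = TRUE)
  keep <- !is.na(corr$rho[ut]) & abs(corr$rho[ut]) >= threshold &
    !is.na(corr$q[ut]) & corr$q[ut] < alpha
  edges <- data.frame(source = ids[ut[keep, 1]],
                      target = ids[ut[keep, 2]],
                      rho = corr$rho[ut][keep],
                      q = corr$q[ut][keep],
                      stringsAsFactors = FALSE)
  status <- "ok"
  if (!nrow(edges)) {
    warning("build_network: no edges satisfy |rho| >= ", threshold,
            " with q < ", alpha)
    status <- "empty"
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = if (length(nodes)) nodes else NULL)
  if (nrow(edges)) igraph::E(g)$weight <- edges$rho
  structure(list(graph = g, edges = edges, nodes = nodes, universe = ids,
                 threshold = threshold, alpha = alpha, status = status),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(paste0("Co-occurrence network: %d nodes, %d edges ",
                     "(|rho| >= %.3f, BH q < %g)\n"),
              length(x$nodes), nrow(x$edges), x$threshold, x$alpha))
  if (x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' Per-sample induced subnetwork
#'
#' The subgraph of the global network induced on the OTUs present (count > 0)
#' in one sample; edges are inherited. A sample containing every networked
#' OTU reproduces the global network exactly.
#'
#' @param network A `cooccurrence_network`.
#' @param abundances Named count/abundance vector over the OTU universe (or a
#'   superset).
#' @return A `cooccurrence_network` for the subgraph (status `"empty"` when
#'   no networked OTU is present).
#' @export
sample_subnetwork <- function(network, abundances) {
  stopifnot(inherits(network, "cooccurrence_network"))
  if (is.null(names(abundances)))
    stop("sample_subnetwork: abundances must be named by OTU id")
  present <- names(abundances)[abundances > 0]
  keep <- intersect(network$nodes, present)
  g <- igraph::induced_subgraph(network$graph, keep)
  edges <- network$edges[network$edges$source %in% keep &
                           network$edges$target %in% keep, , drop = FALSE]
  structure(list(graph = g, edges = edges, nodes = keep,
                 universe = network$universe, threshold = network$threshold,
                 alpha = network$alpha,
                 status = if (length(keep)) "ok" else "empty"),
            class = "cooccurrence_network")
}

#' Topological metrics of a network
#'
#' Node and edge counts, average degree (2E/N), mean local clustering
#' (nodes of degree < 2 contribute 0), average shortest-path length and
#' diameter (computed on the largest connected component; 0 when that
#' component has fewer than 2 nodes), graph density, and modularity of a
#' deterministic greedy agglomerative partition (fast-greedy, unweighted).
#'
#' @param network A `cooccurrence_network` or igraph graph with >= 1 node.
#' @return A `topology_metrics`: named list `n_nodes`, `n_edges`,
#'   `avg_degree`, `clustering`, `avg_path_length`, `diameter`, `density`,
#'   `modularity`.
#' @export
topology <- function(network) {
  g <- if (inherits(network, "cooccurrence_network")) network$graph else network
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")  # metrics are unweighted
  n <- igraph::vcount(g)
  if (n < 1) stop("topology: network has no nodes")
  e <- igraph::ecount(g)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  comps <- igraph::components(g)
  lcc <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  if (igraph::vcount(lcc) >= 2) {
    apl <- igraph::mean_distance(lcc)
    diam <- igraph::diameter(lcc, weights = NA)
  } else {
    apl <- 0; diam <- 0
  }
  modul <- if (e > 0) {
    igraph::modularity(igraph::cluster_fast_greedy(g, weights = NULL))
  } else 0
  structure(list(n_nodes = as.integer(n), n_edges = as.integer(e),
                 avg_degree = 2 * e / n,
                 clustering = mean(loc),
                 avg_path_length = apl,
                 diameter = as.numeric(diam),
                 density = if (n > 1) e / (n * (n - 1) / 2) else 0,
                 modularity = modul),
            class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf(paste0("Topology: %d nodes, %d edges | avg degree %.3f, ",
                     "clustering %.3f,\n  avg path length %.3f, diameter %g, ",
                     "density %.3f, modularity %.3f\n"),
              x$n_nodes, x$n_edges, x$avg_degree, x$clustering,
              x$avg_path_length, x$diameter, x$density, x$modularity))
  invisible(x)
}

#' Per-sample network-complexity composite
#'
#' Condenses per-sample subnetwork topology into one complexity score (BNC
#' for bacteria, FNC for fungi). Pipeline per metric: average path length and
#' diameter are replaced by their reciprocal `1/x` (so larger = more complex;
#' `x <= 0`, which only arises for degenerate edgeless subnetworks, maps to
#' 0), then `log10(x + 1)` for normality, then a column z-score; samples are
#' embedded by classical (Torgerson) metric MDS on Euclidean distances and
#' the first axis, sign-oriented to correlate positively with average degree,
#' is the composite.
#'
#' @param metrics A list of `topology_metrics` (one per sample, named), or a
#'   data.frame/matrix of the eight metric columns with sample rownames.
#' @return A `complexity_table`: data.frame with sample id, the raw metrics
#'   and the `composite` column.
#' @export
complexity_scores <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics) &&
      all(vapply(metrics, inherits, logical(1), "topology_metrics"))) {
    m <- do.call(rbind, lapply(metrics, function(x) unlist(unclass(x))))
    rownames(m) <- names(metrics)
  } else {
    m <- as.matrix(metrics)
  }
  if (nrow(m) < 3) stop("complexity_scores: need >= 3 samples")
  raw <- m
  for (col in intersect(c("avg_path_length", "diameter"), colnames(m)))
    m[, col] <- ifelse(m[, col] > 0, 1 / m[, col], 0)
  m <- log10(m + 1)
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0))
    stop("complexity_scores: all metric columns are constant across samples")
  if (any(sds == 0)) {
    warning("complexity_scores: dropping constant metric column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- zscore_columns(m)
  comp <- stats::cmdscale(stats::dist(z), k = 1)[, 1]
  if ("avg_degree" %in% colnames(raw) && stats::sd(raw[, "avg_degree"]) > 0) {
    r <- stats::cor(comp, raw[, "avg_degree"])
    if (is.finite(r) && r < 0) comp <- -comp
  }
  out <- data.frame(sample_id = rownames(raw), raw, composite = comp,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("complexity_table", "data.frame")
  out
}

#' Dominant phyla by relative abundance
#'
#' Shares of the total count per phylum, in decreasing order; OTUs with no
#' taxonomy entry are pooled as `"unclassified"`.
#'
#' @param table An `otu_table` with taxonomy.
#' @return data.frame with columns `phylum`, `share` (summing to 1).
#' @export
dominant_phyla <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$taxonomy))
    stop("dominant_phyla: the OTU table carries no taxonomy")
  phy <- table$taxonomy[colnames(table$counts)]
  phy[is.na(phy)] <- "unclassified"
  tot <- tapply(colSums(table$counts), phy, sum)
  share <- sort(tot / sum(tot), decreasing = TRUE)
  data.frame(phylum = names(share), share = as.numeric(share),
             row.names = NULL, stringsAsFactors = FALSE)
}
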