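# Shared fixtures and independent oracles, all built in code.

# small OTU table with a known monotone pair and an unrelated column
toy_otu_table <- function() {
  counts <- rbind(P1 = c(10, 1, 5, 0),
                  P2 = c(20, 4, 2, 1),
                  P3 = c(30, 9, 8, 0),
                  P4 = c(40, 16, 1, 3))
  colnames(counts) <- paste0("OTU", 1:4)
  otu_table(counts, taxonomy = c(OTU1 = "PhyA", OTU2 = "PhyA",
                                 OTU3 = "PhyB", OTU4 = "PhyB"))
}

# hand-buildable correlation result for build_network tests
toy_cor_result <- function(rho, q) {
  diag(rho) <- 1; diag(q) <- 0
  p <- q / 2
  structure(list(rho = rho, p = p, q = q, n = 10, excluded = character(0)),
            class = "cor_result")
}

# brute-force count of functions >= t, plot by plot, function by function
oracle_func_maxed <- function(scaled, t) {
  out <- integer(nrow(scaled))
  for (i in seq_len(nrow(scaled))) {
    k <- 0L
    for (j in seq_len(ncol(scaled))) if (scaled[i, j] >= t) k <- k + 1L
    out[i] <- k
  }
  out
}

# brute-force scan of a slope table for Tmin/Tmax/Tmde/Rmde
oracle_summarize <- function(tab, alpha = 0.05) {
  sig <- tab[tab$p_value < alpha, , drop = FALSE]
  if (!nrow(sig)) return(list(t_min = NA_real_, t_max = NA_real_,
                              t_mde = NA_real_, r_mde = NA_real_))
  best <- sig[abs(sig$slope) == max(abs(sig$slope)), , drop = FALSE][1, ]
  list(t_min = min(sig$threshold), t_max = max(sig$threshold),
       t_mde = best$threshold, r_mde = best$slope)
}

# exhaustive Floyd-Warshall / triangle-count oracle for small graphs;
# adj is a symmetric 0/1 matrix without self-loops
oracle_topology <- function(adj) {
  n <- nrow(adj)
  e <- sum(adj[upper.tri(adj)])
  deg <- rowSums(adj)
  # local clustering: triangles among neighbours / possible pairs
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    sum(sub[upper.tri(sub)]) / choose(length(nb), 2)
  }, numeric(1))
  # Floyd-Warshall distances
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # largest connected component by reachability
  sizes <- colSums(is.finite(d))
  lcc <- which(is.finite(d[which.max(sizes), ]))
  if (length(lcc) >= 2) {
    dl <- d[lcc, lcc]
    apl <- mean(dl[upper.tri(dl)])
    diam <- max(dl[upper.tri(dl)])
  } else {
    apl <- 0; diam <- 0
  }
  list(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
       clustering = mean(loc), avg_path_length = apl, diameter = diam,
       density = if (n > 1) e / choose(n, 2) else 0)
}

# igraph from a 0/1 adjacency matrix
graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# random simple graph on n nodes with edge probability p
random_adj <- function(n, p) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(stats::runif(choose(n, 2)) < p)
  adj + t(adj)
}

# all directed paths source -> target, product of coefficients summed
oracle_total_effect <- function(edges, source, target) {
  total <- 0
  walk <- function(v, prod) {
    if (v == target) { total <<- total + prod; return(invisible()) }
    nxt <- which(edges$from == v)
    for (i in nxt) walk(edges$to[i], prod * edges$coef[i])
  }
  walk(source, 1)
  total
}
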