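test_that("filter_otus keeps OTUs strictly above the abundance fraction", {
  tab <- toy_otu_table()
  zero <- otu_table(cbind(tab$counts, OTU5 = rep(0, 4)))
  filt <- filter_otus(zero, 0)          # boundary: only all-zero OTUs removed
  expect_identical(colnames(filt$counts), paste0("OTU", 1:4))
  # totals (9998, 1, 1): at the 0.01% rule only one OTU survives -> error
  skew <- otu_table(matrix(c(4999, 4999, 1, 0, 0, 1), 2, 3,
                           dimnames = list(c("S1", "S2"), paste0("OTU", 1:3))))
  expect_error(filter_otus(skew, 1e-4), "1 of 3")
  # sample set unchanged by filtering
  expect_identical(rownames(filt$counts), rownames(zero$counts))
})

test_that("spearman_matrix is rank-exact, symmetric, with q >= p", {
  # monotone pair -> rho 1; hand-ranked pair with sum(d^2) = 2 -> rho 0.8
  counts <- rbind(P1 = c(1, 1, 1), P2 = c(2, 4, 3),
                  P3 = c(3, 9, 2), P4 = c(4, 16, 4))
  colnames(counts) <- c("x", "mono", "perm")
  res <- spearman_matrix(otu_table(counts), use_relative = FALSE)
  expect_equal(res$rho["x", "mono"], 1)
  expect_equal(res$rho["x", "perm"], 0.8)   # 1 - 6*2/(4*15)
  set.seed(9)
  big <- otu_table(matrix(rpois(20 * 8, 30), 20, 8,
                          dimnames = list(paste0("S", 1:20), paste0("O", 1:8))))
  r <- spearman_matrix(big)
  expect_equal(r$rho, t(r$rho)); expect_equal(r$p, t(r$p)); expect_equal(r$q, t(r$q))
  expect_equal(unname(diag(r$rho)), rep(1, 8))
  ut <- upper.tri(r$p)
  expect_true(all(r$q[ut] >= r$p[ut] - 1e-15))
  # constant OTU flagged and excluded from candidacy
  cst <- big$counts; cst[, 1] <- 5
  rc <- spearman_matrix(otu_table(cst), use_relative = FALSE)
  expect_identical(rc$excluded, "O1")
  expect_true(all(is.na(rc$rho["O1", -1])))
  expect_error(spearman_matrix(otu_table(big$counts[1:3, ])), "4 samples")
})

test_that("bh_adjust reproduces the step-up q-values and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # exchangeable case
  expect_equal(bh_adjust(0.33), 0.33)                # m = 1
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH keeps roughly the nominal fraction of true nulls", {
  set.seed(31)
  p <- runif(500)                       # all null
  q <- bh_adjust(p)
  expect_lte(sum(q < 0.05), sum(p < 0.05))
  expect_lt(mean(q < 0.05), 0.05)       # BH is conservative under the full null
})

test_that("build_network applies both the |rho| and the FDR filter", {
  rho <- matrix(c(1, 0.9, 0.2, -0.8,
                  0.9, 1, 0.85, 0.1,
                  0.2, 0.85, 1, 0.05,
                  -0.8, 0.1, 0.05, 1), 4, 4,
                dimnames = list(paste0("O", 1:4), paste0("O", 1:4)))
  q <- matrix(0.001, 4, 4, dimnames = dimnames(rho))
  q["O2", "O3"] <- q["O3", "O2"] <- 0.2      # strong rho but not significant
  corr <- toy_cor_result(rho, q)
  net <- build_network(corr, threshold = 0.8, alpha = 0.05)
  # hand enumeration over the 6 pairs: O1-O2 (0.9) and O1-O4 (-0.8) survive
  got <- sort(paste(net$edges$source, net$edges$target))
  expect_identical(got, c("O1 O2", "O1 O4"))
  expect_equal(sort(net$edges$rho), c(-0.8, 0.9))
  # lowering alpha never adds edges; raising threshold never adds edges
  expect_lte(suppressWarnings(nrow(build_network(corr, 0.8, 0.0005)$edges)),
             nrow(net$edges))
  expect_lte(suppressWarnings(nrow(build_network(corr, 0.95, 0.05)$edges)),
             nrow(net$edges))
  n1 <- suppressWarnings(build_network(corr, 1.0, 0.05))  # only |rho| = 1 pairs
  expect_equal(nrow(n1$edges), 0)
  expect_warning(build_network(corr, 0.99, 0.05), "no edges")
})

test_that("sample_subnetwork induces the present-OTU subgraph", {
  rho <- diag(5); rho[upper.tri(rho)] <- 0.9; rho <- pmax(rho, t(rho))
  dimnames(rho) <- list(paste0("O", 1:5), paste0("O", 1:5))
  q <- matrix(0.001, 5, 5, dimnames = dimnames(rho))
  net <- build_network(toy_cor_result(rho, q), 0.5)   # complete K5
  full <- setNames(rep(1, 5), paste0("O", 1:5))
  expect_equal(nrow(sample_subnetwork(net, full)$edges), 10)
  one <- setNames(c(1, 0, 0, 0, 0), paste0("O", 1:5))
  sub1 <- sample_subnetwork(net, one)
  expect_equal(length(sub1$nodes), 1); expect_equal(nrow(sub1$edges), 0)
  # missing two nodes: hand-filtered edge list on the remaining triangle
  some <- setNames(c(1, 1, 1, 0, 0), paste0("O", 1:5))
  sub <- sample_subnetwork(net, some)
  expect_identical(sort(paste(sub$edges$source, sub$edges$target)),
                   c("O1 O2", "O1 O3", "O2 O3"))
  none <- setNames(rep(0, 5), paste0("O", 1:5))
  expect_identical(sample_subnetwork(net, none)$status, "empty")
})

test_that("topology matches closed forms on K4 and P4", {
  k4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  t4 <- topology(k4)
  expect_equal(t4[c("avg_degree", "clustering", "avg_path_length",
                    "diameter", "density")],
               list(avg_degree = 3, clustering = 1, avg_path_length = 1,
                    diameter = 1, density = 1))
  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  tp <- topology(graph_from_adj(p4))
  expect_equal(tp$avg_degree, 1.5)
  expect_equal(tp$density, 0.5)
  expect_equal(tp$diameter, 3)
  expect_equal(tp$avg_path_length, 10 / 6)
  expect_equal(tp$clustering, 0)
  expect_error(topology(igraph::make_empty_graph(0, directed = FALSE)), "node")
})

test_that("complexity composite behaves under degenerate and 1-D variation", {
  # identical samples -> identical composites (plus one contrast sample)
  m <- rbind(a = c(10, 20, 4, 0.5, 2, 4, 0.4, 0.3),
             b = c(10, 20, 4, 0.5, 2, 4, 0.4, 0.3),
             c = c(30, 90, 6, 0.7, 1.5, 3, 0.6, 0.2))
  colnames(m) <- c("n_nodes", "n_edges", "avg_degree", "clustering",
                   "avg_path_length", "diameter", "density", "modularity")
  ct <- suppressWarnings(complexity_scores(m))
  expect_equal(ct$composite[1], ct$composite[2], tolerance = 1e-10)
  # variation along avg_degree only -> composite ranks follow avg_degree
  m2 <- matrix(rep(c(10, 20, 0.5, 2, 4, 0.4, 0.3), each = 5), 5, 7)
  colnames(m2) <- c("n_nodes", "n_edges", "clustering", "avg_path_length",
                    "diameter", "density", "modularity")
  m2 <- cbind(m2, avg_degree = c(2, 7, 4, 9, 1))
  rownames(m2) <- paste0("s", 1:5)
  ct2 <- suppressWarnings(complexity_scores(m2))
  expect_equal(order(ct2$composite), order(m2[, "avg_degree"]))
  expect_error(complexity_scores(matrix(1, 4, 3)), "constant")
})

test_that("dominant_phyla returns descending shares summing to one", {
  tab <- toy_otu_table()
  ph <- dominant_phyla(tab)
  expect_equal(sum(ph$share), 1, tolerance = 1e-12)
  expect_true(all(diff(ph$share) <= 0))
  # hand proportions on two phyla
  counts <- rbind(S1 = c(10, 30), S2 = c(20, 40))
  colnames(counts) <- c("O1", "O2")
  p2 <- dominant_phyla(otu_table(counts, c(O1 = "A", O2 = "B")))
  expect_equal(p2$share[p2$phylum == "A"], 0.30)
  expect_equal(p2$share[p2$phylum == "B"], 0.70)
  # missing taxonomy pooled as unclassified; single phylum -> 100%
  pu <- dominant_phyla(otu_table(counts, c(O1 = "A")))
  expect_equal(pu$share[pu$phylum == "unclassified"], 0.7)
  p1 <- dominant_phyla(otu_table(counts, c(O1 = "A", O2 = "A")))
  expect_equal(p1$share, 1)
})
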