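test_that("agb_stem evaluates the allometric power law exactly", {
  # independent log-scale evaluation of the same printed formula
  expect_equal(agb_stem(0.6, 10, 15), 1.28616226066815, tolerance = 1e-12)
  set.seed(42)
  wd <- runif(50, 0.2, 1); dbh <- runif(50, 1, 80); h <- runif(50, 2, 45)
  oracle <- 0.0673 * exp(0.976 * (log(wd) + 2 * log(dbh) + log(h))) * 25 / 1000
  expect_equal(agb_stem(wd, dbh, h), oracle, tolerance = 1e-12)
})

test_that("agb_stem scales with the exponent and is strictly monotone", {
  base <- agb_stem(0.5, 12, 18)
  expect_equal(agb_stem(0.5, 24, 18) / base, 4^0.976, tolerance = 1e-12)
  # zero limit in wood density
  expect_lt(agb_stem(1e-12, 10, 15), 1e-10)
  grid <- expand.grid(wd = c(0.3, 0.6), dbh = c(5, 20), h = c(5, 25))
  for (v in c("wd", "dbh", "h")) {
    lo <- grid; hi <- grid; hi[[v]] <- hi[[v]] * 1.1
    expect_true(all(agb_stem(hi$wd, hi$dbh, hi$h) >
                      agb_stem(lo$wd, lo$dbh, lo$h)))
  }
  expect_error(agb_stem(0, 10, 10), "wood_density")
  expect_error(agb_stem(0.5, -1, 10), "dbh")
})

test_that("plot_agb sums per-stem contributions, empty plot gives zero", {
  stems <- data.frame(plot_id = c("A", "A", "A", "B", "B"),
                      growth_form = c("tree", "liana", "shrub", "tree", "tree"),
                      species_id = paste0("sp", 1:5),
                      dbh = c(12, 3, 2, 30, 1.5),
                      height = c(15, 8, 3, 28, 2.5),
                      wood_density = c(0.6, 0.45, 0.5, 0.7, 0.55))
  per_stem <- agb_stem(stems$wood_density, stems$dbh, stems$height)
  expect_equal(plot_agb(stems, "A"), sum(per_stem[1:3]))
  expect_equal(plot_agb(stems, "C"), 0)
  two <- stems[c(1, 1), ]
  expect_equal(plot_agb(two, "A"), 2 * per_stem[1])
  all_plots <- plot_agb(stems)
  expect_equal(unname(all_plots["B"]), sum(per_stem[4:5]))
  # inventory rule: DBH >= 1 cm
  bad <- stems; bad$dbh[1] <- 0.5
  expect_error(plot_agb(bad), "DBH")
})

test_that("socs is the linear stock formula with gravel annihilation", {
  expect_equal(socs(20, 1.2, 20, 0), 48)
  expect_equal(socs(20, 1.2, 20, 1), 0)
  expect_equal(socs(40, 1.2, 20, 0), 2 * socs(20, 1.2, 20, 0))
  expect_equal(socs(13.7, 1.31, 20, 0.12), 0.1 * 13.7 * 1.31 * 20 * 0.88)
  expect_error(socs(20, 1.2, 20, 1.2), "gravel")
  expect_error(socs(-1, 1.2, 20, 0), "carbon")
})

test_that("zscore_columns standardises with sample sd and rejects constants", {
  expect_equal(unname(zscore_columns(cbind(a = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  m <- cbind(x = rnorm(20, 5, 3), y = runif(20, 0, 100))
  z <- zscore_columns(m)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(zscore_columns(z), z, tolerance = 1e-12)  # idempotent
  expect_error(zscore_columns(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("nutrient cycling composite is the mean of six z-scores", {
  set.seed(7)
  nut <- as.data.frame(matrix(rnorm(24, 10, 2), 4, 6))
  names(nut) <- c("tn", "tp", "tk", "hn", "ap", "ak")
  # spreadsheet-style oracle: z-score each column independently, average rows
  oracle <- rowMeans(sapply(nut, function(x) (x - mean(x)) / sd(x)))
  expect_equal(nutrient_cycling_index(nut), oracle, tolerance = 1e-12)
  expect_equal(mean(nutrient_cycling_index(nut)), 0, tolerance = 1e-12)
  same <- nut; for (k in names(same)) same[[k]] <- nut$tn
  expect_equal(nutrient_cycling_index(same),
               (nut$tn - mean(nut$tn)) / sd(nut$tn), tolerance = 1e-12)
})

test_that("emf_average means the four z-scores and rejects raw input", {
  z <- zscore_columns(matrix(rnorm(32), 8, 4,
                             dimnames = list(paste0("P", 1:8),
                                             c("AGB", "SOCS", "NutrientCycling", "SWHC"))))
  fm <- function_matrix(z, standardized = TRUE)
  expect_equal(unname(emf_average(fm)), unname(rowMeans(z)))
  expect_equal(mean(emf_average(fm)), 0, tolerance = 1e-12)
  expect_equal(unname(emf_average(fm)[1]), mean(z[1, ]))
  raw <- function_matrix(matrix(rnorm(32, 10, 4), 8, 4), standardized = FALSE)
  expect_error(emf_average(raw), "standardized")
  expect_error(function_matrix(matrix(rnorm(32, 10, 4), 8, 4), standardized = TRUE))
})

test_that("EMF is invariant to positive affine rescaling of raw functions", {
  set.seed(11)
  raw <- matrix(rnorm(40, 50, 10), 10, 4,
                dimnames = list(paste0("P", 1:10), c("F1", "F2", "F3", "F4")))
  emf1 <- emf_average(standardize_functions(function_matrix(raw)))
  scaled <- sweep(sweep(raw, 2, c(2, 0.5, 10, 3), "*"), 2, c(-5, 7, 0, 100), "+")
  emf2 <- emf_average(standardize_functions(function_matrix(scaled)))
  expect_equal(emf1, emf2, tolerance = 1e-12)
})

test_that("compute_functions assembles AGB, SOCS, nutrients and SWHC per plot", {
  ds <- generate_dataset(list(n_plots = 12,
                              bacteria = list(n_otus = 24, n_modules = 2),
                              fungi = list(n_otus = 24, n_modules = 2)),
                         seed = 3)
  fm <- compute_functions(ds$stems, ds$plots)
  expect_s3_class(fm, "function_matrix")
  expect_identical(colnames(fm), c("AGB", "SOCS", "NutrientCycling", "SWHC"))
  expect_identical(rownames(fm), ds$plots$plot_id)
  expect_equal(unname(fm[, "AGB"]), unname(plot_agb(ds$stems)[ds$plots$plot_id]))
  expect_equal(unname(fm[, "SOCS"]),
               socs(ds$plots$soc_content, ds$plots$bulk_density,
                    ds$plots$layer_thickness, ds$plots$gravel_fraction))
  # nine-function alternative keeps the six nutrients separate
  fm9 <- compute_functions(ds$stems, ds$plots, composite = FALSE)
  expect_equal(ncol(fm9), 9)
  expect_equal(unname(fm9[, "TN"]), ds$plots$tn)
})
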