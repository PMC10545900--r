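# deterministic sub-seed derivation: one user-facing seed, many independent
# streams, all below 2^31
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% .Machine$integer.max)
}

#' Simulate from a recursive linear model
#'
#' Draws standardized data from a declared acyclic path diagram: exogenous
#' variables are unit-variance Gaussians, each endogenous variable is the
#' coefficient-weighted sum of its parents plus Gaussian noise scaled so the
#' variable has unit population variance (making the generative coefficients
#' directly comparable to standardized path estimates). `noise_scale`
#' multiplies every residual standard deviation (1 preserves unit variances).
#'
#' @param coefficients data.frame `from`, `to`, `coef`, all coefficients in
#'   `[-1, 1]`; the implied diagram must be acyclic.
#' @param n Number of rows to draw.
#' @param seed Integer seed.
#' @param noise_scale Positive multiplier on residual standard deviations.
#' @param extra_exogenous Optional names of additional independent N(0,1)
#'   columns not appearing in any edge.
#' @return data.frame of simulated variables; attributes `residual_variances`
#'   and `spec`.
#' @export
simulate_recursive <- function(coefficients, n, seed = 1, noise_scale = 1,
                               extra_exogenous = character(0)) {
  if (any(abs(coefficients$coef) > 1))
    stop("simulate_recursive: coefficients must lie in [-1, 1]")
  if (!is.numeric(noise_scale) || length(noise_scale) != 1 || noise_scale <= 0)
    stop("simulate_recursive: noise scale must be a single positive number")
  spec <- path_spec(coefficients[, c("from", "to")])
  v <- spec$variables
  # implied covariance assembled sequentially in topological order
  Sigma <- diag(length(v)); dimnames(Sigma) <- list(v, v)
  resid <- stats::setNames(numeric(0), character(0))
  for (y in spec$endogenous) {
    pa <- coefficients$from[coefficients$to == y]
    b <- stats::setNames(coefficients$coef[coefficients$to == y], pa)
    var_exp <- drop(crossprod(b, Sigma[pa, pa, drop = FALSE] %*% b))
    if (var_exp >= 1)
      stop("simulate_recursive: coefficients into '", y,
           "' imply explained variance >= 1; no unit-variance scaling exists")
    resid[y] <- 1 - var_exp
    cv <- drop(Sigma[, pa, drop = FALSE] %*% b)
    Sigma[, y] <- cv; Sigma[y, ] <- cv; Sigma[y, y] <- 1
  }
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, n, length(v), dimnames = list(NULL, v))
  for (x in v) {
    if (x %in% spec$exogenous) {
      out[, x] <- stats::rnorm(n)
    } else {
      pa <- coefficients$from[coefficients$to == x]
      b <- coefficients$coef[coefficients$to == x]
      out[, x] <- drop(out[, pa, drop = FALSE] %*% b) +
        stats::rnorm(n, sd = sqrt(resid[x]) * noise_scale)
    }
  }
  extra <- setdiff(extra_exogenous, v)
  for (x in extra) out <- cbind(out, stats::setNames(list(stats::rnorm(n)), x)[[1]])
  colnames(out) <- c(v, extra)
  d <- as.data.frame(out)
  attr(d, "residual_variances") <- resid
  attr(d, "spec") <- spec
  d
}

#' Generate a modular OTU count table
#'
#' Latent Gaussian abundances with block-exchangeable correlation
#' (`within_module_rho` inside each module, 0 between modules) are mapped to
#' counts by a rank-preserving quantile transform onto negative-binomial
#' marginals (per-OTU lognormal means, configurable dispersion). Because the
#' transform is monotone, the Spearman structure consumed by the network
#' stage is exactly that of the latent copula.
#'
#' @param n_samples,n_otus Table dimensions; `n_otus` must divide evenly
#'   into modules of at least 2 OTUs.
#' @param n_modules Number of modules (>= 1).
#' @param within_module_rho Latent correlation inside a module, in (0, 1).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); default 0.5.
#' @param mean_log_mu,sd_log_mu Lognormal parameters of per-OTU mean
#'   abundance.
#' @param taxonomy_labels Optional phylum labels recycled over modules; when
#'   given, a taxonomy map is attached.
#' @param sample_ids,otu_prefix Identifiers.
#' @return An `otu_table` with attribute `module_membership` (named integer
#'   vector, module indices contiguous from 0).
#' @export
generate_otu_table <- function(n_samples, n_otus, n_modules, within_module_rho,
                               seed = 1, dispersion = 0.5,
                               mean_log_mu = log(80), sd_log_mu = 1,
                               taxonomy_labels = NULL,
                               sample_ids = sprintf("S%03d", seq_len(n_samples)),
                               otu_prefix = "OTU") {
  if (n_modules < 1) stop("generate_otu_table: n_modules must be >= 1")
  if (n_otus %% n_modules != 0 || n_otus / n_modules < 2)
    stop("generate_otu_table: n_otus must divide into modules of >= 2 OTUs")
  if (within_module_rho >= 1)
    stop("generate_otu_table: within_module_rho >= 1 gives a ",
         "non-positive-definite block")
  if (within_module_rho <= 0)
    stop("generate_otu_table: within_module_rho must lie in (0, 1)")
  set.seed(as.integer(seed))
  per <- n_otus / n_modules
  membership <- rep(seq_len(n_modules) - 1L, each = per)
  fac <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
  z <- sqrt(within_module_rho) * fac[, membership + 1L, drop = FALSE] +
    sqrt(1 - within_module_rho) *
      matrix(stats::rnorm(n_samples * n_otus), n_samples, n_otus)
  mu <- exp(stats::rnorm(n_otus, mean_log_mu, sd_log_mu))
  counts <- vapply(seq_len(n_otus), function(j)
    stats::qnbinom(stats::pnorm(z[, j]), size = dispersion, mu = mu[j]),
    numeric(n_samples))
  otu_ids <- sprintf("%s%04d", otu_prefix, seq_len(n_otus))
  dimnames(counts) <- list(sample_ids, otu_ids)
  names(membership) <- otu_ids
  taxonomy <- NULL
  if (!is.null(taxonomy_labels)) {
    taxonomy <- stats::setNames(
      taxonomy_labels[(membership %% length(taxonomy_labels)) + 1L], otu_ids)
  }
  out <- otu_table(counts, taxonomy)
  attr(out, "module_membership") <- membership
  out
}

#' Ground-truth record of a synthetic dataset
#'
#' @param path_coefficients data.frame `from`, `to`, `coef` in `[-1, 1]`.
#' @param otu_module_membership Named list of named integer vectors (module
#'   indices contiguous from 0), e.g. one per community.
#' @param n_plots Number of plots (>= 3).
#' @param seed Integer seed the dataset was generated from.
#' @return A `truth_record`.
#' @export
truth_record <- function(path_coefficients, otu_module_membership, n_plots, seed) {
  if (any(abs(path_coefficients$coef) > 1))
    stop("truth_record: coefficients must lie in [-1, 1]")
  if (n_plots < 3) stop("truth_record: n_plots must be >= 3")
  for (mm in otu_module_membership) {
    u <- sort(unique(as.integer(mm)))
    if (!identical(u, seq_along(u) - 1L))
      stop("truth_record: module indices must be contiguous from 0")
  }
  structure(list(path_coefficients = path_coefficients,
                 otu_module_membership = otu_module_membership,
                 n_plots = as.integer(n_plots), seed = as.integer(seed)),
            class = "truth_record")
}

#' Default generator configuration
#'
#' The study conditions emulated by [generate_dataset()]: 75 plots across a
#' tropical-rainforest plot network, a recursive driver model wiring tree and
#' liana richness, environment, microbial diversity and network complexity to
#' a latent EMF driver, four function drivers loading 0.9 on latent EMF, and
#' modular bacterial (120 OTUs, 4 modules) and fungal (80 OTUs, 3 modules)
#' communities. Every entry can be overridden through the `config` argument
#' of [generate_dataset()].
#'
#' @return Named list of generator settings.
#' @export
default_generator_config <- function() {
  list(
    n_plots = 75,
    path = data.frame(
      from = c("TSR", "LSR", "BNC", "FNC", "BSR", "FSR", "SWC", "SBD"),
      to   = c("EMF", "EMF", "EMF", "EMF", "BNC", "FNC", "LSR", "FNC"),
      coef = c(0.306, -0.450, 0.471, -0.20, 0.50, 0.50, -0.30, -0.30),
      stringsAsFactors = FALSE),
    extra_exogenous = "SSR",
    noise_scale = 1,
    function_effects = c(EMF = 0.9),
    function_noise_sd = sqrt(1 - 0.81),
    mean_stems = 55,
    bacteria = list(n_otus = 120, n_modules = 4, within_module_rho = 0.8,
                    dispersion = 0.5,
                    taxonomy_labels = c("Acidobacteria", "Proteobacteria",
                                        "Verrucomicrobia", "Actinobacteria")),
    fungi = list(n_otus = 80, n_modules = 4, within_module_rho = 0.8,
                 dispersion = 0.5,
                 taxonomy_labels = c("Ascomycota", "Basidiomycota",
                                     "Mortierellomycota", "Rozellomycota"))
  )
}

#' Generate a synthetic plot network dataset
#'
#' Draws plot-level variables from the declared recursive linear model
#' ([simulate_recursive()]), then dresses them as observables: richness
#' counts per growth form, soil physico-chemistry, a stem inventory whose
#' per-plot AGB matches its generative target (heights are rescaled, which
#' moves biomass by exactly the allometric height exponent and keeps DBH >= 1
#' valid), and modular bacterial/fungal OTU tables whose sample ids are the
#' plot ids. The four ecosystem-function drivers are linear in the latent
#' variables named by `config$function_effects` plus Gaussian noise.
#' Identical `(config, seed)` reproduces byte-identical output.
#'
#' @param config Partial override of [default_generator_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_dataset`: list with `stems`, `plots`, `latent`,
#'   `function_drivers`, `bacterial_otus`, `fungal_otus`, `truth`, `config`.
#' @export
generate_dataset <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_generator_config(), config)
  # a user-supplied path diagram replaces the default wholesale (modifyList
  # would merge data.frame columns of unequal length)
  if (!is.null(config$path)) cfg$path <- config$path
  if (cfg$n_plots < 10) stop("generate_dataset: n_plots must be >= 10")
  if (any(abs(cfg$path$coef) > 1))
    stop("generate_dataset: path coefficients must lie in [-1, 1]")
  if (!is.numeric(cfg$noise_scale) || cfg$noise_scale <= 0)
    stop("generate_dataset: noise scale must be positive")
  n <- cfg$n_plots
  plot_ids <- sprintf("P%03d", seq_len(n))

  latent <- simulate_recursive(cfg$path, n, seed = .derive_seed(seed, 1),
                               noise_scale = cfg$noise_scale,
                               extra_exogenous = cfg$extra_exogenous)
  rownames(latent) <- plot_ids

  # four ecosystem-function drivers on the latent scale
  set.seed(.derive_seed(seed, 2))
  fe <- cfg$function_effects
  fe <- fe[names(fe) %in% names(latent)]
  base <- if (length(fe)) {
    drop(as.matrix(latent[, names(fe), drop = FALSE]) %*% fe)
  } else rep(0, n)
  drivers <- vapply(c("AGB", "SOCS", "NutrientCycling", "SWHC"),
                    function(k) base + stats::rnorm(n, sd = cfg$function_noise_sd),
                    numeric(n))
  rownames(drivers) <- plot_ids

  set.seed(.derive_seed(seed, 3))
  lat <- function(v) if (v %in% names(latent)) latent[[v]] else rep(0, n)
  nut <- function(mn, sdv) pmax(0.01, mn + sdv * (0.85 * drivers[, "NutrientCycling"] +
                                                    0.527 * stats::rnorm(n)))
  plots <- data.frame(
    plot_id = plot_ids,
    tsr = pmax(0, round(25 + 6 * lat("TSR"))),
    ssr = pmax(0, round(15 + 5 * lat("SSR"))),
    lsr = pmax(0, round(12 + 4 * lat("LSR"))),
    bsr = pmax(0, round(1500 + 200 * lat("BSR"))),
    fsr = pmax(0, round(350 + 60 * lat("FSR"))),
    soc_content = pmax(0.5, 20 + 4 * drivers[, "SOCS"]),
    bulk_density = pmax(0.3, 1.2 + 0.12 * lat("SBD")),
    layer_thickness = 20,
    gravel_fraction = pmin(0.95, stats::rbeta(n, 2, 18)),
    tn = nut(2.5, 0.5), tp = nut(0.6, 0.12), tk = nut(15, 3),
    hn = nut(180, 35), ap = nut(8, 2), ak = nut(120, 25),
    swc = pmax(1, 30 + 5 * lat("SWC")),
    swhc = pmax(1, 45 + 8 * drivers[, "SWHC"]),
    stringsAsFactors = FALSE)
  plots$sbd <- plots$bulk_density

  # stem inventory: random stems, heights rescaled so plot AGB hits its target
  set.seed(.derive_seed(seed, 4))
  target_agb <- 300 * exp(0.25 * drivers[, "AGB"])
  stems <- do.call(rbind, lapply(seq_len(n), function(i) {
    ns <- max(3L, stats::rpois(1, cfg$mean_stems))
    gf <- sample(c("tree", "shrub", "liana"), ns, replace = TRUE,
                 prob = c(0.6, 0.25, 0.15))
    dbh <- 1 + stats::rgamma(ns, shape = 1.2, scale = 6)
    data.frame(plot_id = plot_ids[i], growth_form = gf,
               species_id = sprintf("%s_sp%02d", substr(gf, 1, 2),
                                    sample.int(30, ns, replace = TRUE)),
               dbh = dbh,
               height = 1.5 * dbh^0.6 * exp(stats::rnorm(ns, sd = 0.1)),
               wood_density = stats::runif(ns, 0.35, 0.8),
               stringsAsFactors = FALSE)
  }))
  cur <- plot_agb(stems)
  scale_h <- (target_agb / cur[plot_ids])^(1 / 0.976)
  stems$height <- stems$height * scale_h[match(stems$plot_id, plot_ids)]

  bact <- do.call(generate_otu_table,
                  c(list(n_samples = n, seed = .derive_seed(seed, 5),
                         sample_ids = plot_ids, otu_prefix = "BOTU"),
                    cfg$bacteria))
  fung <- do.call(generate_otu_table,
                  c(list(n_samples = n, seed = .derive_seed(seed, 6),
                         sample_ids = plot_ids, otu_prefix = "FOTU"),
                    cfg$fungi))

  truth <- truth_record(
    cfg$path,
    list(bacteria = attr(bact, "module_membership"),
         fungi = attr(fung, "module_membership")),
    n_plots = n, seed = seed)

  structure(list(stems = stems, plots = plots, latent = latent,
                 function_drivers = drivers,
                 bacterial_otus = bact, fungal_otus = fung,
                 truth = truth, config = cfg, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic plot-network dataset (seed %d): %d plots, ",
                     "%d stems,\n  bacterial OTUs %d, fungal OTUs %d, ",
                     "%d generative path coefficients\n"),
              x$seed, nrow(x$plots), nrow(x$stems),
              ncol(x$bacterial_otus$counts), ncol(x$fungal_otus$counts),
              nrow(x$truth$path_coefficients)))
  invisible(x)
}
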