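#' Per-sample subnetwork metrics and complexity
#'
#' Extracts the induced subnetwork of every sample of an OTU table from the
#' global network, computes its topology and condenses the metrics into the
#' per-sample complexity composite (BNC/FNC). Samples whose subnetwork is
#' empty receive all-zero metrics (no structure present).
#'
#' @param network A `cooccurrence_network`.
#' @param table The `otu_table` the network was built from.
#' @return A `complexity_table` (one row per sample, `composite` column).
#' @export
subnetwork_complexity <- function(network, table) {
  stopifnot(inherits(network, "cooccurrence_network"),
            inherits(table, "otu_table"))
  metric_names <- c("n_nodes", "n_edges", "avg_degree", "clustering",
                    "avg_path_length", "diameter", "density", "modularity")
  rows <- lapply(rownames(table$counts), function(s) {
    sub <- sample_subnetwork(network, table$counts[s, ])
    if (sub$status == "empty")
      return(stats::setNames(as.list(numeric(length(metric_names))), metric_names))
    unclass(topology(sub))
  })
  m <- do.call(rbind, lapply(rows, function(r) unlist(r)[metric_names]))
  rownames(m) <- rownames(table$counts)
  colnames(m) <- metric_names
  complexity_scores(m)
}

#' Default run configuration
#'
#' Settings for [run_pipeline()]: simulate by default (75 plots), threshold
#' grid 1-99 percent step 1 percent, alpha 0.05, RMT scan 0.30--0.99 step 0.01 (set
#' `rmt_fixed` entries, e.g. `list(bacteria = 0.850, fungi = 0.540)`, to
#' bypass the scan), 500-tree random forest. Every stochastic stage draws
#' its seed from the single `seed` entry.
#'
#' @return Named list of defaults; override any entry via the `config`
#'   argument of [run_pipeline()] or a YAML config file.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    out_dir = "emfnet_run",
    simulate = TRUE,
    generator = list(),
    inputs = list(stems = NULL, soils = NULL,
                  bacterial_otus = NULL, bacterial_taxonomy = NULL,
                  fungal_otus = NULL, fungal_taxonomy = NULL),
    stages = list(emf = TRUE, multithreshold = TRUE, conet = TRUE,
                  assoc = TRUE, pathmodel = TRUE),
    grid_start = 0.01, grid_stop = 0.99, grid_step = 0.01,
    alpha = 0.05,
    min_rel_abund = 1e-4,
    rmt_scan = c(0.30, 0.99, 0.01),
    rmt_fixed = list(bacteria = NULL, fungi = NULL),
    predictors = c("tsr", "lsr", "ssr", "bsr", "fsr"),
    n_trees = 500
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  utils::modifyList(default_run_config(), yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> ecosystem functions / EMF ->
#' multithreshold -> co-occurrence networks and per-sample complexity ->
#' associations (OLS, correlation heatmap, random forest) -> path model,
#' writing one TSV per stage output plus a machine-readable `manifest.json`
#' (package version, seed, config echo and an md5 content hash of every
#' output file). Re-running with an identical configuration reproduces
#' byte-identical numeric outputs. Progress is logged to standard error.
#'
#' @param config Partial override of [default_run_config()], or a path to a
#'   YAML file.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config)
  else utils::modifyList(default_run_config(), config)
  log_ <- function(...) if (!quiet) message("[emfnet] ", sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  files <- character(0)
  keep <- function(p) { files <<- c(files, p); p }
  results <- list(config = cfg)

  # ---- inputs: simulate or read --------------------------------------
  if (isTRUE(cfg$simulate)) {
    log_("simulating dataset (seed %d)", cfg$seed)
    ds <- .stage("simulate", generate_dataset(cfg$generator, seed = cfg$seed))
    for (p in write_dataset(ds, cfg$out_dir)) keep(p)
    stems <- ds$stems; soils <- ds$plots
    bact <- ds$bacterial_otus; fung <- ds$fungal_otus
    results$dataset <- ds
  } else {
    log_("reading inputs")
    inp <- cfg$inputs
    for (nm in c("stems", "soils", "bacterial_otus", "fungal_otus")) {
      if (is.null(inp[[nm]]) || !file.exists(inp[[nm]]))
        stop("pipeline stage 'inputs': missing input file for '", nm, "': ",
             if (is.null(inp[[nm]])) "(not configured)" else inp[[nm]],
             call. = FALSE)
    }
    stems <- .stage("inputs", read_stems(inp$stems))
    soils <- .stage("inputs", read_soils(inp$soils))
    bact <- .stage("inputs", read_otu_table(inp$bacterial_otus, inp$bacterial_taxonomy))
    fung <- .stage("inputs", read_otu_table(inp$fungal_otus, inp$fungal_taxonomy))
  }

  # ---- ecosystem functions and EMF -----------------------------------
  fm_raw <- emf_index <- NULL
  if (isTRUE(cfg$stages$emf)) {
    log_("computing ecosystem functions and EMF")
    fm_raw <- .stage("emf", compute_functions(stems, soils))
    fm_std <- standardize_functions(fm_raw)
    emf_index <- emf_average(fm_std)
    keep(.write_tsv(data.frame(plot_id = rownames(fm_raw), unclass(fm_raw)),
                    out("functions_raw.tsv")))
    keep(.write_tsv(data.frame(plot_id = rownames(fm_std), unclass(fm_std)),
                    out("functions_standardized.tsv")))
    keep(.write_tsv(data.frame(plot_id = names(emf_index), emf = emf_index),
                    out("emf_index.tsv")))
    results$functions <- fm_raw; results$emf <- emf_index
  }

  # ---- multithreshold -------------------------------------------------
  if (isTRUE(cfg$stages$multithreshold)) {
    log_("multithreshold analysis")
    grid <- seq(cfg$grid_start, cfg$grid_stop, by = cfg$grid_step)
    preds <- intersect(cfg$predictors, names(soils))
    mt <- .stage("multithreshold", lapply(stats::setNames(preds, preds), function(p)
      multithreshold_analysis(fm_raw, soils[[p]], grid = grid,
                              alpha = cfg$alpha, predictor_name = p)))
    curves <- do.call(rbind, lapply(preds, function(p)
      cbind(predictor = p, mt[[p]]$curve$table)))
    summ <- do.call(rbind, lapply(preds, function(p) {
      s <- mt[[p]]$summary
      data.frame(predictor = p, t_min = s$t_min, t_max = s$t_max,
                 t_mde = s$t_mde, r_mde = s$r_mde)
    }))
    keep(.write_tsv(curves, out("threshold_curves.tsv")))
    keep(.write_tsv(summ, out("threshold_summaries.tsv")))
    results$multithreshold <- mt
  }

  # ---- co-occurrence networks ----------------------------------------
  complexity <- list()
  if (isTRUE(cfg$stages$conet)) {
    scan <- seq(cfg$rmt_scan[1], cfg$rmt_scan[2], by = cfg$rmt_scan[3])
    for (comm in c("bacteria", "fungi")) {
      log_("co-occurrence network: %s", comm)
      tab <- if (comm == "bacteria") bact else fung
      res <- .stage(paste0("conet-", comm), {
        filt <- filter_otus(tab, cfg$min_rel_abund)
        corr <- spearman_matrix(filt)
        fixed <- cfg$rmt_fixed[[comm]]
        if (is.null(fixed)) {
          scanres <- rmt_threshold(corr$rho, scan = scan)
          if (scanres$status != "selected")
            stop("RMT scan found no Poisson-compatible threshold")
          thr <- scanres$threshold
        } else {
          scanres <- NULL; thr <- fixed
        }
        net <- build_network(corr, thr, alpha = cfg$alpha)
        list(filtered = filt, corr = corr, scan = scanres, network = net,
             topology = topology(net),
             complexity = subnetwork_complexity(net, filt),
             phyla = if (!is.null(filt$taxonomy)) dominant_phyla(filt))
      })
      keep(.write_tsv(res$network$edges, out(sprintf("%s_edges.tsv", comm))))
      igraph::write_graph(res$network$graph,
                          keep(out(sprintf("%s_network.graphml", comm))),
                          format = "graphml")
      keep(.write_tsv(data.frame(metric = names(unclass(res$topology)),
                                 value = unlist(unclass(res$topology))),
                      out(sprintf("%s_topology.tsv", comm))))
      if (!is.null(res$scan))
        keep(.write_tsv(res$scan$trace, out(sprintf("%s_rmt_trace.tsv", comm))))
      keep(.write_tsv(res$complexity, out(sprintf("%s_complexity.tsv", comm))))
      if (!is.null(res$phyla))
        keep(.write_tsv(res$phyla, out(sprintf("%s_phyla.tsv", comm))))
      complexity[[comm]] <- res$complexity
      results[[paste0("conet_", comm)]] <- res
    }
  }

  # ---- plot-level predictor table ------------------------------------
  ptab <- data.frame(row.names = soils$plot_id,
                     TSR = soils$tsr, LSR = soils$lsr, SSR = soils$ssr,
                     SWC = soils$swc, SBD = soils$sbd)
  if ("bsr" %in% names(soils)) ptab$BSR <- soils$bsr
  if ("fsr" %in% names(soils)) ptab$FSR <- soils$fsr
  if (length(complexity)) {
    ptab$BNC <- complexity$bacteria$composite[
      match(rownames(ptab), complexity$bacteria$sample_id)]
    ptab$FNC <- complexity$fungi$composite[
      match(rownames(ptab), complexity$fungi$sample_id)]
  }

  # ---- associations ---------------------------------------------------
  if (isTRUE(cfg$stages$assoc)) {
    log_("association analyses")
    res <- .stage("assoc", {
      regs <- do.call(rbind, lapply(colnames(ptab), function(p) {
        b <- ols_both(ptab[[p]], emf_index, predictor_name = p,
                      response_name = "EMF")
        do.call(rbind, lapply(c("linear", "quadratic"), function(d) {
          f <- b[[d]]
          data.frame(predictor = p, response = "EMF", degree = f$degree,
                     slope = f$coefficients[["x"]],
                     quad = if (f$degree == 2) f$coefficients[["x^2"]] else NA,
                     std_slope = f$std_coefficients[["x"]],
                     r_squared = f$r_squared, p_value = f$p_value,
                     aic = f$aic, preferred = b$preferred == d)
        }))
      }))
      heat <- correlation_heatmap(ptab,
                                  cbind(unclass(fm_raw), EMF = emf_index))
      imp <- rf_importance(ptab, emf_index, n_trees = cfg$n_trees,
                           seed = .derive_seed(cfg$seed, 11))
      list(regressions = regs, heatmap = heat, importance = imp)
    })
    keep(.write_tsv(res$regressions, out("regressions.tsv")))
    keep(.write_tsv(res$heatmap, out("heatmap.tsv")))
    keep(.write_tsv(res$importance, out("importance.tsv")))
    results$assoc <- res
  }

  # ---- path model ------------------------------------------------------
  if (isTRUE(cfg$stages$pathmodel)) {
    log_("recursive path model")
    res <- .stage("pathmodel", {
      pdata <- cbind(ptab, EMF = emf_index[rownames(ptab)])
      spec <- default_emf_path_spec()
      spec_vars <- intersect(spec$variables, colnames(pdata))
      if (!setequal(spec_vars, spec$variables))
        stop("path-model variables missing from the plot table: ",
             paste(setdiff(spec$variables, spec_vars), collapse = ", "))
      fit <- fit_path_model(pdata, spec)
      list(fit = fit, effects = effect_decomposition(spec, fit$edges))
    })
    keep(.write_tsv(res$fit$edges, out("path_edges.tsv")))
    keep(.write_tsv(data.frame(chi_square = res$fit$chi_square,
                               df = res$fit$df, p_value = res$fit$p_value,
                               gfi = res$fit$gfi, rmsea = res$fit$rmsea,
                               n = res$fit$n),
                    out("path_fit.tsv")))
    keep(.write_tsv(res$effects, out("path_effects.tsv")))
    results$pathmodel <- res
  }

  # ---- manifest --------------------------------------------------------
  files <- sort(unique(files))
  manifest <- list(package = "emfnet",
                   version = as.character(utils::packageVersion("emfnet")),
                   seed = cfg$seed,
                   config = cfg,
                   files = data.frame(path = basename(files),
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  log_("done: %d output files in %s", length(files) + 1L, cfg$out_dir)
  results$manifest <- manifest
  invisible(results)
}
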