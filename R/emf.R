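#' Above-ground biomass of a single woody stem
#'
#' Evaluates the allometric power law used for tropical woody stems,
#' `AGB = [0.0673 * (WD * DBH^2 * H)^0.976] * 25/1000`, which converts a
#' per-stem biomass (kg, for a 20 m x 20 m plot inventory) to t per hectare.
#' The function is vectorised and strictly increasing in each argument.
#'
#' @param wood_density Wood density in g cm^-3 (> 0).
#' @param dbh Diameter at breast height in cm (> 0).
#' @param height Stem height in m (> 0).
#' @return Biomass contribution in t hm^-2 (numeric, same length as inputs).
#' @examples
#' agb_stem(0.6, 10, 15)
#' @export
agb_stem <- function(wood_density, dbh, height) {
  if (any(!is.finite(wood_density)) || any(wood_density <= 0))
    stop("agb_stem: 'wood_density' must be finite and > 0")
  if (any(!is.finite(dbh)) || any(dbh <= 0))
    stop("agb_stem: 'dbh' must be finite and > 0")
  if (any(!is.finite(height)) || any(height <= 0))
    stop("agb_stem: 'height' must be finite and > 0")
  (0.0673 * (wood_density * dbh^2 * height)^0.976) * 25 / 1000
}

#' Validate a stem inventory table
#'
#' Checks the inventory rules: DBH >= 1 cm (stems below the census limit are
#' not valid records), strictly positive height and wood density, and a known
#' growth form (tree, shrub or liana).
#'
#' @param stems data.frame with columns `plot_id`, `growth_form`, `species_id`,
#'   `dbh`, `height`, `wood_density`.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_stems <- function(stems) {
  req <- c("plot_id", "growth_form", "species_id", "dbh", "height", "wood_density")
  miss <- setdiff(req, names(stems))
  if (length(miss))
    stop("validate_stems: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(stems)) {
    if (any(!is.finite(stems$dbh)) || any(stems$dbh < 1))
      stop("validate_stems: all stems must have DBH >= 1 cm")
    if (any(!is.finite(stems$height)) || any(stems$height <= 0))
      stop("validate_stems: heights must be > 0")
    if (any(!is.finite(stems$wood_density)) || any(stems$wood_density <= 0))
      stop("validate_stems: wood densities must be > 0")
    bad <- setdiff(unique(stems$growth_form), c("tree", "shrub", "liana"))
    if (length(bad))
      stop("validate_stems: unknown growth form(s): ", paste(bad, collapse = ", "))
  }
  invisible(stems)
}

#' Plot-level above-ground biomass
#'
#' Sums [agb_stem()] over the stems of one plot (or of every plot). A plot
#' with no stems contributes 0.
#'
#' @param stems Stem inventory data.frame (see [validate_stems()]).
#' @param plot_id Optional single plot id; when `NULL`, a named vector with
#'   one total per plot id present in `stems` is returned.
#' @return Numeric AGB in t hm^-2 (scalar, or named vector when `plot_id` is
#'   `NULL`).
#' @export
plot_agb <- function(stems, plot_id = NULL) {
  validate_stems(stems)
  if (!is.null(plot_id)) {
    sub <- stems[stems$plot_id == plot_id, , drop = FALSE]
    if (!nrow(sub)) return(0)
    return(sum(agb_stem(sub$wood_density, sub$dbh, sub$height)))
  }
  if (!nrow(stems)) return(numeric(0))
  per_stem <- agb_stem(stems$wood_density, stems$dbh, stems$height)
  v <- tapply(per_stem, stems$plot_id, sum)
  stats::setNames(as.numeric(v), dimnames(v)[[1]])[unique(stems$plot_id)]
}

#' Soil organic carbon stock
#'
#' `SOCS = 0.1 * c * d * r * (1 - D)` in t hm^-2, where `c` is the soil
#' organic carbon content (g kg^-1), `d` the bulk density (g cm^-3), `r` the
#' layer thickness (cm) and `D` the volumetric gravel fraction (> 2 mm).
#'
#' @param c_content Organic carbon content, g kg^-1 (>= 0).
#' @param bulk_density Bulk density, g cm^-3 (>= 0).
#' @param thickness Soil layer thickness, cm (>= 0).
#' @param gravel Gravel volume fraction in `[0, 1]`.
#' @return SOCS in t hm^-2.
#' @examples
#' socs(20, 1.2, 20, 0)  # 48
#' @export
socs <- function(c_content, bulk_density, thickness, gravel) {
  if (any(!is.finite(c_content)) || any(c_content < 0))
    stop("socs: carbon content must be >= 0")
  if (any(!is.finite(bulk_density)) || any(bulk_density < 0))
    stop("socs: bulk density must be >= 0")
  if (any(!is.finite(thickness)) || any(thickness < 0))
    stop("socs: thickness must be >= 0")
  if (any(!is.finite(gravel)) || any(gravel < 0) || any(gravel > 1))
    stop("socs: gravel fraction must lie in [0, 1]")
  0.1 * c_content * bulk_density * thickness * (1 - gravel)
}

#' Column-wise z-score standardisation
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (denominator n - 1). Zero-variance columns are an error naming the column:
#' silently dropping or zeroing them would change any downstream average.
#'
#' @param x Numeric matrix or data.frame (>= 2 rows).
#' @return A numeric matrix of the same dimensions.
#' @export
zscore_columns <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("zscore_columns: input must be numeric")
  if (nrow(m) < 2) stop("zscore_columns: need at least 2 rows")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    stop("zscore_columns: zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Nutrient-cycling composite score
#'
#' Condenses the six soil nutrient pools (TN, TP, TK, HN, AP, AK) into one
#' score per plot: the mean of the six z-scored columns. The resulting column
#' has mean 0 by construction.
#'
#' @param nutrients data.frame or matrix with columns `tn`, `tp`, `tk`, `hn`,
#'   `ap`, `ak` (order-insensitive if named).
#' @return Numeric vector, one composite score per plot.
#' @export
nutrient_cycling_index <- function(nutrients) {
  cols <- c("tn", "tp", "tk", "hn", "ap", "ak")
  d <- as.data.frame(nutrients)
  if (all(cols %in% names(d))) d <- d[, cols]
  m <- as.matrix(d)
  if (ncol(m) != 6)
    stop("nutrient_cycling_index: expected the six nutrient columns ",
         paste(cols, collapse = ", "))
  rowMeans(zscore_columns(m))
}

#' Assemble the plot x function matrix
#'
#' Computes the four ecosystem functions per plot: biomass production (AGB of
#' all woody stems), carbon stock (SOCS), nutrient cycling (composite of six
#' z-scored nutrient pools) and water regulation (soil water-holding
#' capacity). With `composite = FALSE` the six nutrients enter as separate
#' columns (nine functions in total) instead of being condensed first.
#'
#' @param stems Stem inventory (see [validate_stems()]).
#' @param soils Plot soil table with columns `plot_id`, `soc_content`,
#'   `bulk_density`, `layer_thickness`, `gravel_fraction`, `tn`, `tp`, `tk`,
#'   `hn`, `ap`, `ak`, `swc`, `swhc`.
#' @param composite Condense nutrients into one column (default `TRUE`).
#' @return A `function_matrix`: numeric matrix, one row per plot (rownames =
#'   plot ids), with attribute `standardized = FALSE`.
#' @export
compute_functions <- function(stems, soils, composite = TRUE) {
  req <- c("plot_id", "soc_content", "bulk_density", "layer_thickness",
           "gravel_fraction", "tn", "tp", "tk", "hn", "ap", "ak", "swc", "swhc")
  miss <- setdiff(req, names(soils))
  if (length(miss))
    stop("compute_functions: soils table missing: ", paste(miss, collapse = ", "))
  agb <- plot_agb(stems)
  agb_col <- agb[match(soils$plot_id, names(agb))]
  agb_col[is.na(agb_col)] <- 0
  socs_col <- socs(soils$soc_content, soils$bulk_density,
                   soils$layer_thickness, soils$gravel_fraction)
  if (composite) {
    fm <- cbind(AGB = unname(agb_col), SOCS = socs_col,
                NutrientCycling = nutrient_cycling_index(soils),
                SWHC = soils$swhc)
  } else {
    fm <- cbind(AGB = unname(agb_col), SOCS = socs_col,
                TN = soils$tn, TP = soils$tp, TK = soils$tk,
                HN = soils$hn, AP = soils$ap, AK = soils$ak,
                SWHC = soils$swhc)
  }
  rownames(fm) <- soils$plot_id
  function_matrix(fm, standardized = FALSE)
}

#' Construct a function_matrix object
#'
#' @param x Numeric matrix, plots in rows (rownames = plot ids).
#' @param standardized Logical flag: are columns z-scores?
#' @return Object of class `function_matrix`.
#' @export
function_matrix <- function(x, standardized = FALSE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("function_matrix: values must be numeric")
  if (standardized) .check_standardized(m)
  structure(m, standardized = standardized, class = c("function_matrix", class(m)))
}

.check_standardized <- function(m, tol = 1e-8) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  if (any(abs(mu) > tol) || any(abs(sdv - 1) > tol))
    stop("function matrix is not standardized (column means 0, sd 1 required)")
  invisible(TRUE)
}

#' Z-score a function matrix
#'
#' @param fm A `function_matrix` (raw).
#' @return A `function_matrix` with `standardized = TRUE`.
#' @export
standardize_functions <- function(fm) {
  function_matrix(zscore_columns(fm), standardized = TRUE)
}

#' Averaged ecosystem multifunctionality index
#'
#' The averaging approach: the EMF index of a plot is the arithmetic mean of
#' its standardized function scores. Unstandardized input is rejected, both
#' via the `standardized` attribute and by checking the column moments, so an
#' accidentally raw matrix cannot slip through.
#'
#' @param fm A standardized `function_matrix`.
#' @return Named numeric vector of EMF scores (mean 0 across plots).
#' @export
emf_average <- function(fm) {
  if (!inherits(fm, "function_matrix") || !isTRUE(attr(fm, "standardized")))
    stop("emf_average: input must be a standardized function_matrix ",
         "(see standardize_functions())")
  .check_standardized(unclass(fm))
  out <- rowMeans(fm)
  names(out) <- rownames(fm)
  out
}

#' @export
print.function_matrix <- function(x, ...) {
  cat(sprintf("Function matrix: %d plots x %d functions (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) "standardized" else "raw"))
  cat("Functions:", paste(colnames(x), collapse = ", "), "\n")
  print(utils::head(unclass(x), 4), ...)
  if (nrow(x) > 4) cat("...", nrow(x) - 4, "more plots\n")
  invisible(x)
}
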