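# Plain-text readers and writers for the pipeline's on-disk formats:
# stems CSV, soils CSV, OTU TSV (OTUs as rows, first column otu_id),
# taxonomy TSV (otu_id, phylum). UTF-8, "." decimal throughout.

#' Write / read a stem inventory CSV
#'
#' Columns on disk: `plot_id`, `growth_form`, `species_id`, `dbh_cm`,
#' `height_m`, `wood_density_g_cm3` (header required).
#'
#' @param stems Stem data.frame (internal column names, see
#'   [validate_stems()]).
#' @param path File path.
#' @return `read_stems` returns the validated data.frame with internal
#'   column names.
#' @export
write_stems <- function(stems, path) {
  validate_stems(stems)
  out <- stems[, c("plot_id", "growth_form", "species_id",
                   "dbh", "height", "wood_density")]
  names(out) <- c("plot_id", "growth_form", "species_id",
                  "dbh_cm", "height_m", "wood_density_g_cm3")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stems
#' @export
read_stems <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plot_id", "growth_form", "species_id", "dbh_cm", "height_m",
           "wood_density_g_cm3")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("read_stems: ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  names(d)[match(c("dbh_cm", "height_m", "wood_density_g_cm3"), names(d))] <-
    c("dbh", "height", "wood_density")
  validate_stems(d)
  d
}

#' Write / read a plot soil table CSV
#'
#' One row per plot; the column set of the `soils` table consumed by
#' [compute_functions()].
#'
#' @param soils Soil data.frame.
#' @param path File path.
#' @export
write_soils <- function(soils, path) {
  utils::write.csv(soils, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_soils
#' @export
read_soils <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an OTU table TSV
#'
#' On disk: OTUs as rows, samples as columns, first column `otu_id`.
#'
#' @param table An `otu_table`.
#' @param path File path.
#' @param taxonomy_path Optional taxonomy TSV read alongside the counts.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  m <- t(table$counts)
  out <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "otu_id")
    stop("read_otu_table: first column of ", path, " must be 'otu_id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$otu_id
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  otu_table(t(m), taxonomy)
}

#' Write / read an OTU taxonomy TSV
#'
#' Two columns: `otu_id`, `phylum`.
#'
#' @param taxonomy Named character vector (names = OTU ids).
#' @param path File path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(data.frame(otu_id = names(taxonomy),
                                phylum = unname(taxonomy)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$phylum, d$otu_id)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same file formats the readers consume, so the pipeline can be
#' exercised end-to-end from disk: `stems.csv`, `soils.csv`,
#' `bacterial_otus.tsv` / `fungal_otus.tsv` and their taxonomy TSVs.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stems = file.path(dir, "stems.csv"),
             soils = file.path(dir, "soils.csv"),
             bacterial_otus = file.path(dir, "bacterial_otus.tsv"),
             bacterial_taxonomy = file.path(dir, "bacterial_taxonomy.tsv"),
             fungal_otus = file.path(dir, "fungal_otus.tsv"),
             fungal_taxonomy = file.path(dir, "fungal_taxonomy.tsv"))
  write_stems(ds$stems, paths["stems"])
  write_soils(ds$plots, paths["soils"])
  write_otu_table(ds$bacterial_otus, paths["bacterial_otus"])
  write_taxonomy(ds$bacterial_otus$taxonomy, paths["bacterial_taxonomy"])
  write_otu_table(ds$fungal_otus, paths["fungal_otus"])
  write_taxonomy(ds$fungal_otus$taxonomy, paths["fungal_taxonomy"])
  invisible(paths)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
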