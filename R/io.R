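# Delimited-text readers and writers for phenotype, genotype and map
# tables, plus validation shared across modules.

#' Validate a phenotype table
#'
#' @param data Data frame with columns `generation` and `value` (or RGB
#'   triplet columns `value_r`, `value_g`, `value_b`, collapsed to their
#'   mean with a message).
#' @param require_replication Require a `replication` column.
#' @return The validated tibble (generation as factor over the six labels).
#' @export
validate_phenotypes <- function(data, require_replication = FALSE) {
  data <- tibble::as_tibble(data)
  rgb_cols <- c("value_r", "value_g", "value_b")
  if (!"value" %in% names(data) && all(rgb_cols %in% names(data))) {
    rlang::inform("collapsing RGB triplets to their channel mean")
    data$value <- rowMeans(data[, rgb_cols])
  }
  if (!all(c("generation", "value") %in% names(data))) {
    rlang::abort("phenotype data needs columns `generation` and `value`")
  }
  if (require_replication && !"replication" %in% names(data)) {
    rlang::abort("phenotype data needs a `replication` column")
  }
  gen <- as.character(data$generation)
  bad <- setdiff(unique(gen), seg_generations())
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown generation label(s): ",
                        paste(bad, collapse = ", ")))
  }
  if (!is.numeric(data$value) || any(!is.finite(data$value))) {
    rlang::abort("phenotype values must be finite numbers")
  }
  data$generation <- factor(gen, levels = seg_generations())
  data
}

#' Validate a linkage map table
#'
#' @param map Data frame with columns `group`, `marker`, `position` (cM,
#'   group-local, non-decreasing within group).
#' @return The validated tibble.
#' @export
validate_map <- function(map) {
  map <- tibble::as_tibble(map)
  if (!all(c("group", "marker", "position") %in% names(map))) {
    rlang::abort("map needs columns `group`, `marker`, `position`")
  }
  if (nrow(map) == 0) rlang::abort("empty map")
  if (anyDuplicated(map$marker)) {
    rlang::abort(paste0("duplicate marker names: ",
                        paste(unique(map$marker[duplicated(map$marker)]),
                              collapse = ", ")))
  }
  if (!is.numeric(map$position) || any(!is.finite(map$position))) {
    rlang::abort("map positions must be finite numbers")
  }
  for (g in unique(map$group)) {
    pos <- map$position[map$group == g]
    if (is.unsorted(pos)) {
      rlang::abort(paste0("positions not sorted within group '", g, "'"))
    }
  }
  map$group <- as.character(map$group)
  map
}

#' Read a phenotype CSV
#'
#' Expected columns: `generation`, `replication`, `plant_id`, `value` (or
#' `value_r`, `value_g`, `value_b`, averaged on read).
#'
#' @param path File path.
#' @return Validated phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (nrow(data) == 0) rlang::abort("empty phenotype file")
  validate_phenotypes(data)
}

#' Write a phenotype CSV
#'
#' @param data Phenotype tibble.
#' @param path File path.
#' @export
write_phenotypes <- function(data, path) {
  readr::write_csv(validate_phenotypes(data), path)
  invisible(path)
}

#' Read a genotype CSV
#'
#' Expected layout: one row per individual, an `id` column and one column
#' per marker with codes 2/1/0/NA for AA/Aa/aa/missing.
#'
#' @param path File path.
#' @return Tibble `id` + marker columns.
#' @export
read_genotypes <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (nrow(data) == 0 || ncol(data) < 2) {
    rlang::abort("empty genotype file")
  }
  G <- as.matrix(data[, setdiff(names(data), "id"), drop = FALSE])
  if (!all(G %in% c(0, 1, 2) | is.na(G))) {
    rlang::abort("genotype codes must be 2/1/0/NA (AA/Aa/aa/missing)")
  }
  tibble::as_tibble(data)
}

#' Write a genotype CSV
#'
#' @param genotypes Tibble `id` + marker columns (codes 2/1/0/NA).
#' @param path File path.
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_csv(tibble::as_tibble(genotypes), path)
  invisible(path)
}

#' Read a linkage-map TSV
#'
#' Expected columns: `group`, `marker`, `position` (cM).
#'
#' @param path File path.
#' @return Validated map tibble.
#' @export
read_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_map(map)
}

#' Write a linkage-map TSV
#'
#' @param map Map tibble.
#' @param path File path.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(validate_map(map), path)
  invisible(path)
}

#' Write the result tables of a full analysis
#'
#' Emits the model-comparison table, the goodness-of-fit report, the
#' first-/second-order parameter reports and/or the QTL scan profile as
#' TSV files in a directory, depending on which results are supplied.
#'
#' @param results Named list; recognised elements: `model_set`
#'   (`seg_model_set`), `gof` (tibble from [gof_tests()]), `effects`
#'   (tibble), `variances` (tibble), `scan` (`qtl_scan`), `qtl` (tibble
#'   from [declare_qtl()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tibble::as_tibble(x), p)
    paths <<- c(paths, p)
  }
  if (!is.null(results$model_set)) emit(results$model_set, "model_comparison")
  if (!is.null(results$gof)) emit(results$gof, "goodness_of_fit")
  if (!is.null(results$effects)) emit(results$effects, "first_order_effects")
  if (!is.null(results$variances)) emit(results$variances, "variance_components")
  if (!is.null(results$scan)) emit(results$scan, "qtl_scan_profile")
  if (!is.null(results$qtl)) emit(results$qtl, "declared_qtl")
  invisible(paths)
}
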