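# Plain-text dialects shared by all stages: feature tables and count
# matrices as TSV, designs and gas series as CSV, truth labels and run
# manifests as JSON. Truth labels are always written to a separate
# sidecar file, never merged into analysis inputs.

#' Write a feature table to TSV
#'
#' Columns: feature_id, mz, rt, formula, annotation_level, ms2
#' (semicolon-joined fragment m/z), then one intensity column per sample.
#'
#' @param ft a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  meta <- ft$meta
  df <- data.frame(feature_id = meta$feature_id, mz = meta$mz,
                   rt = meta$rt, formula = meta$formula,
                   annotation_level = meta$annotation_level,
                   ms2 = vapply(meta$ms2, paste, character(1),
                                collapse = ";"),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ft$intensities))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' @param path TSV path in the [write_feature_table()] dialect.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("feature_id", "mz", "rt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature TSV missing columns: ",
                         paste(miss, collapse = ", "))
  meta_cols <- intersect(c("feature_id", "mz", "rt", "formula",
                           "annotation_level", "ms2"), names(df))
  meta <- df[meta_cols]
  if ("ms2" %in% names(meta)) meta$ms2 <- as.character(meta$ms2)
  int_cols <- setdiff(names(df), meta_cols)
  x <- as.matrix(df[int_cols])
  rownames(x) <- df$feature_id
  feature_table(x, meta)
}

#' Write / read a gene x sample count matrix (TSV)
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path file path.
#' @return `path` invisibly (write) or the matrix (read).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  x <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(x) <- df$gene_id
  x
}

#' Write / read a gene catalog (TSV: gene_id, mag_id, ko, length_bp)
#'
#' @param catalog gene catalog data frame.
#' @param path file path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_gene_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_catalog
#' @export
read_gene_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "mag_id", "ko", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene catalog missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Write pathway definitions to TSV
#'
#' @param defs data frame with pathway_id, name, category, expression.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pathway_definitions <- function(defs, path) {
  utils::write.table(defs[c("pathway_id", "name", "category",
                            "expression")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a sample design (CSV: sample_id, habitat, day)
#'
#' @param design design data frame.
#' @param path file path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "habitat", "day"), names(df))
  if (length(miss)) stop("design CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Write / read a gas measurement series (CSV)
#'
#' @param gas gas series data frame in the [total_gas_table()] dialect.
#' @param path file path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_gas_series <- function(gas, path) {
  utils::write.csv(gas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gas_series
#' @export
read_gas_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write truth labels to a JSON sidecar
#'
#' @param truth truth-label list from a generator.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
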