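# Plain-text readers and writers for the pipeline's tabular interchange
# formats: counts TSV (first column probe_id), design TSV, plate TSV,
# fold-change TSV and the two-column ortholog map.

#' Write / read a counts matrix as TSV
#'
#' First column `probe_id`, remaining columns one per sample.
#'
#' @param counts gene x sample matrix.
#' @param path file path.
#' @return `path` invisibly (writer); integer matrix (reader).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(probe_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a sample-design table as TSV
#'
#' Columns `sample_id`, `chemical`, `concentration_uM`, `time_h`,
#' `replicate`.
#'
#' @param design design data.frame.
#' @param path file path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an LDH plate table as TSV
#'
#' Columns `well_id`, `chemical`, `concentration_uM`, `role`, `absorbance`.
#'
#' @param plates plate data.frame.
#' @param path file path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_plate_tsv <- function(plates, path) {
  utils::write.table(plates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_tsv
#' @export
read_plate_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a fold-change table / ortholog map TSV
#'
#' Fold-change tables carry `gene`, `log2fc` and optionally `p_adj`,
#' `de_flag`; the ortholog map carries `source_symbol`, `human_symbol`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_fold_change_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc") %in% names(tab))) {
    stop("fold-change table needs columns gene, log2fc")
  }
  tab
}

#' @rdname read_fold_change_tsv
#' @export
read_ortholog_map_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_symbol", "human_symbol") %in% names(tab))) {
    stop("ortholog map needs columns source_symbol, human_symbol")
  }
  tab
}
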