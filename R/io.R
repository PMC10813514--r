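#' OTU count tables
#'
#' A `count_table` holds a taxa-by-samples matrix of sequencing read counts,
#' with optional per-taxon lineage strings. Counts must be whole numbers >= 0
#' and taxon/sample identifiers must be unique.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   rownames (taxon ids) and colnames (sample ids).
#' @param taxonomy optional named character vector of semicolon-delimited
#'   lineage strings, names matching the taxon ids.
#' @return an object of class `count_table` with elements `counts` and
#'   `taxonomy`.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), nrow = 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' count_table(m)
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_qmp("count table needs taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_qmp("duplicated taxon ids: ",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop_qmp("duplicated sample ids: ",
             paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                   collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_qmp("counts must be whole numbers >= 0; offending cell: taxon '",
             rownames(counts)[bad[1, 1]], "', sample '",
             colnames(counts)[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[rownames(counts)]
    names(taxonomy) <- rownames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("OTU count table:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n")
  cat("total reads per sample:",
      paste(utils::head(colSums(x$counts), 6), collapse = ", "),
      if (ncol(x$counts) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read an OTU count table from TSV
#'
#' Expects a tab-separated file whose first column (header literal
#' `taxon_id`) holds taxon identifiers and whose remaining header cells are
#' sample identifiers. An optional final column named `taxonomy` carries
#' lineage strings. Malformed input (ragged rows, duplicate ids, negative or
#' fractional counts) raises an error naming the offending row or cell.
#'
#' @param path file path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "taxon_id") {
    stop_qmp("expected a tab-separated header starting with 'taxon_id': ",
             path)
  }
  if (anyDuplicated(header)) {
    stop_qmp("duplicated sample ids in header of ", path, ": ",
             paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", fill = FALSE,
                          stringsAsFactors = FALSE)
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- stats::setNames(df$taxonomy, df$taxon_id)
    df$taxonomy <- NULL
  }
  sample_ids <- setdiff(names(df), "taxon_id")
  m <- suppressWarnings(
    vapply(df[sample_ids], as.numeric, numeric(nrow(df)))
  )
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(df$taxon_id, sample_ids))
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    stop_qmp("non-numeric count in ", path, ": taxon '",
             rownames(m)[nas[1, 1]], "', sample '",
             colnames(m)[nas[1, 2]], "'")
  }
  count_table(m, taxonomy = tax)
}

#' Write an OTU count table to TSV
#'
#' @param x a [count_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata maps each sample to a donor and an experimental condition.
#' Every `sample_id` must be unique and each (donor, condition) pair may
#' appear at most once (one bioreactor per donor and arm).
#'
#' @param path TSV with columns `sample_id`, `donor_id`, `condition`.
#' @return a data.frame with those three character columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "donor_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_qmp("metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop_qmp("duplicated sample ids in metadata: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
  }
  key <- paste(df$donor_id, df$condition, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop_qmp("duplicated (donor, condition) pair in metadata: ",
             paste(d$donor_id[1], d$condition[1]))
  }
  df[need]
}

#' Read a flow-cytometry total cell density table
#'
#' @param path TSV with columns `sample_id` and `total_cells_per_ml`.
#' @return a data.frame with a character `sample_id` and a strictly positive
#'   numeric `total_cells_per_ml` column.
#' @export
read_density_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "total_cells_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_qmp("density table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$total_cells_per_ml <- as.numeric(df$total_cells_per_ml)
  validate_densities(df)
}

validate_densities <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop_qmp("duplicated sample ids in density table: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
  }
  bad <- !is.finite(df$total_cells_per_ml) | df$total_cells_per_ml <= 0
  if (any(bad)) {
    stop_qmp("non-positive cell density for sample(s): ",
             paste(df$sample_id[bad], collapse = ", "))
  }
  df[c("sample_id", "total_cells_per_ml")]
}

#' Write a per-taxon effect table to TSV
#'
#' Columns: taxon, family, per-treatment mean log2(treatment/control) ratio,
#' p-value, q-value and significance/consistency class — the plain-text
#' counterpart of the usual treatment-effect heatmap.
#'
#' @param x an `effect_table` data.frame (see [effect_table()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(format(x, digits = 15, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an effect table written by [write_effect_table()]
#'
#' @param path file path.
#' @return a data.frame of class `effect_table`.
#' @export
read_effect_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  num <- intersect(c("mean_log2_ratio", "p_value", "q_value"), names(df))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  if ("n_detected" %in% names(df)) df$n_detected <- as.integer(df$n_detected)
  class(df) <- c("effect_table", "data.frame")
  df
}

#' Extract the family rank from a lineage string
#'
#' Lineages are semicolon-delimited rank strings. The rank prefixed `f__`
#' is used when present; otherwise the 5th field (the conventional family
#' position in a 7-rank lineage). Unresolvable lineages map to
#' `"unclassified"`.
#'
#' @param lineage character vector of lineage strings (NAs allowed).
#' @return character vector of family names.
#' @examples
#' family_from_lineage("k__Bacteria;p__;c__;o__;f__Bacteroidaceae;g__;s__")
#' @export
family_from_lineage <- function(lineage) {
  vapply(lineage, function(s) {
    if (is.na(s) || !nzchar(s)) return("unclassified")
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    f <- parts[startsWith(parts, "f__")]
    if (length(f) >= 1) {
      fam <- sub("^f__", "", f[1])
      return(if (nzchar(fam)) fam else "unclassified")
    }
    if (length(parts) >= 5 && nzchar(parts[5])) return(parts[5])
    "unclassified"
  }, character(1), USE.NAMES = FALSE)
}

# Simple TSV writers used by the pipeline for metadata/density outputs.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
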