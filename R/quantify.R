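#' Per-sample relative abundances
#'
#' @param counts a [count_table()] or a taxa x samples numeric matrix.
#' @return taxa x samples matrix of proportions; every column sums to 1.
#' @export
relative_abundances <- function(counts) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  tot <- colSums(m)
  zero <- tot < 1
  if (any(zero)) {
    stop_qmp("sample(s) with zero total reads: ",
             paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2, tot, "/")
}

#' Scale proportions to absolute abundances
#'
#' Each sample's proportions are multiplied by its measured total cell
#' density, so the column sum equals the density.
#'
#' @param proportions taxa x samples matrix of per-sample proportions.
#' @param densities data.frame with `sample_id` and `total_cells_per_ml`
#'   covering every sample.
#' @return taxa x samples matrix of estimated cells/mL.
#' @export
absolute_abundances <- function(proportions, densities) {
  densities <- validate_densities(densities)
  miss <- setdiff(colnames(proportions), densities$sample_id)
  if (length(miss) > 0) {
    stop_qmp("no cell density for sample(s): ", paste(miss, collapse = ", "))
  }
  d <- stats::setNames(densities$total_cells_per_ml, densities$sample_id)
  sweep(proportions, 2, d[colnames(proportions)], "*")
}

#' Detection limit of a sequencing sample, as a percentage
#'
#' One read out of the sample's total corresponds to the least abundant
#' detectable taxon (assuming one 16S rRNA gene copy per cell), i.e. a
#' proportional detection limit of `100 / total_reads` percent.
#'
#' @param total_reads positive read total(s).
#' @return detection limit(s) in percent (exact, unrounded).
#' @seealso [lod_percent()] for the rounded reporting form.
#' @export
lod_fraction <- function(total_reads) {
  if (any(!is.finite(total_reads) | total_reads < 1)) {
    stop_qmp("total_reads must be >= 1")
  }
  100 / total_reads
}

#' Reported detection-limit percentage
#'
#' Rounds the exact detection limit for reporting, to the nearest 0.001
#' percentage point, applying half-up rounding successively at the fourth
#' and then the third decimal (the rule consistent with conventionally
#' transcribed intermediate values: 18,197 reads -> 0.0055 -> 0.006%).
#'
#' @param total_reads positive read total(s).
#' @return rounded detection limit(s) in percent.
#' @export
lod_percent <- function(total_reads) {
  round_half_up(round_half_up(lod_fraction(total_reads), 4), 3)
}

#' Detection limit in cells/mL
#'
#' The absolute abundance carried by a single read:
#' `density / total_reads`, identically `density * lod_fraction / 100`.
#'
#' @param total_reads positive read total(s).
#' @param density positive total cell density (cells/mL).
#' @return detection limit(s) in cells/mL.
#' @export
sample_lod <- function(total_reads, density) {
  if (any(!is.finite(total_reads) | total_reads < 1)) {
    stop_qmp("total_reads must be >= 1")
  }
  if (any(!is.finite(density) | density <= 0)) {
    stop_qmp("density must be > 0")
  }
  density / total_reads
}

#' Quantitative (absolute) abundance profile
#'
#' Joins an OTU count table with flow-cytometry total cell densities:
#' proportions are scaled to cells/mL and each sample's limit of detection
#' (cells/mL equivalent of one read) is recorded. No imputation is applied;
#' see [impute_below_lod()].
#'
#' @param counts a [count_table()].
#' @param densities data.frame with `sample_id`, `total_cells_per_ml`.
#' @return an object of class `qmp_abundance`: `cells_per_ml` (taxa x
#'   samples), `lod` (named, per sample), `total_reads` (named), `imputed`
#'   (logical matrix, all FALSE), `taxonomy`.
#' @export
quantify <- function(counts, densities) {
  stopifnot(inherits(counts, "count_table"))
  prop <- relative_abundances(counts)
  cells <- absolute_abundances(prop, densities)
  reads <- colSums(counts$counts)
  d <- stats::setNames(densities$total_cells_per_ml, densities$sample_id)
  lod <- sample_lod(reads, d[colnames(cells)])
  imputed <- matrix(FALSE, nrow(cells), ncol(cells),
                    dimnames = dimnames(cells))
  structure(list(cells_per_ml = cells, lod = lod, total_reads = reads,
                 imputed = imputed, taxonomy = counts$taxonomy),
            class = "qmp_abundance")
}

#' @export
print.qmp_abundance <- function(x, ...) {
  cat("Quantitative abundance profile:", nrow(x$cells_per_ml), "taxa x",
      ncol(x$cells_per_ml), "samples\n")
  if (all(is.finite(x$lod))) {
    cat(sprintf("LOD range: %.3g - %.3g cells/mL; %d entries imputed\n",
                min(x$lod), max(x$lod), sum(x$imputed)))
  }
  invisible(x)
}

#' @export
dim.qmp_abundance <- function(x) dim(x$cells_per_ml)

#' Impute abundances below the limit of detection
#'
#' Under the default `"overall"` policy the overall LOD is the maximum
#' per-sample LOD of the analysed sample set — the most conservative
#' detectable floor — and every entry below it is set to it. The
#' `"per-sample"` policy instead floors each sample at its own LOD. Imputed
#' entries are flagged.
#'
#' @param x a `qmp_abundance` from [quantify()].
#' @param policy `"overall"` (default) or `"per-sample"`.
#' @return `x` with floored `cells_per_ml`, updated `imputed` flags and an
#'   `lod_applied` record.
#' @export
impute_below_lod <- function(x, policy = c("overall", "per-sample")) {
  stopifnot(inherits(x, "qmp_abundance"))
  policy <- match.arg(policy)
  floorm <- if (policy == "overall") {
    matrix(max(x$lod), nrow(x$cells_per_ml), ncol(x$cells_per_ml))
  } else {
    matrix(x$lod, nrow(x$cells_per_ml), ncol(x$cells_per_ml), byrow = TRUE)
  }
  below <- x$cells_per_ml < floorm
  x$cells_per_ml[below] <- floorm[below]
  x$imputed <- x$imputed | below
  x$lod_applied <- list(policy = policy,
                        overall = max(x$lod))
  x
}

#' Retain the most abundant taxa
#'
#' Taxa are ranked by mean absolute abundance across all samples of the
#' dataset (global ranking); the top `n` are retained, in rank order, with
#' ties broken by lexicographically smaller taxon id. Restricting analyses
#' to the ~100 most abundant OTUs keeps the multiple-testing burden down.
#'
#' @param x a `qmp_abundance`.
#' @param n number of taxa to keep (defaults to 100; if `n` exceeds the
#'   number of taxa, all are kept).
#' @return `x` subset to the selected taxa.
#' @export
select_top_n <- function(x, n = 100) {
  stopifnot(inherits(x, "qmp_abundance"))
  means <- rowMeans(x$cells_per_ml)
  ord <- order(-means, rownames(x$cells_per_ml))
  keep <- ord[seq_len(min(n, length(ord)))]
  x$cells_per_ml <- x$cells_per_ml[keep, , drop = FALSE]
  x$imputed <- x$imputed[keep, , drop = FALSE]
  if (!is.null(x$taxonomy)) x$taxonomy <- x$taxonomy[rownames(x$cells_per_ml)]
  x
}

#' Read a quantitative abundance matrix from TSV
#'
#' Reads a table written by [write_abundance_table()] (first column
#' `taxon_id`, optional final `taxonomy` column). Detection-limit and
#' imputation records are not stored in the TSV, so `lod` is NA and the
#' imputation flags are all FALSE on the returned object.
#'
#' @param path file path.
#' @return a `qmp_abundance`.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) {
    stop_qmp("expected a 'taxon_id' column in ", path)
  }
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- stats::setNames(df$taxonomy, df$taxon_id)
    df$taxonomy <- NULL
  }
  sample_ids <- setdiff(names(df), "taxon_id")
  m <- as.matrix(df[sample_ids])
  rownames(m) <- df$taxon_id
  if (any(!is.finite(m) | m < 0)) {
    stop_qmp("abundances must be finite and >= 0 in ", path)
  }
  structure(list(cells_per_ml = m,
                 lod = stats::setNames(rep(NA_real_, ncol(m)), colnames(m)),
                 total_reads = NULL,
                 imputed = matrix(FALSE, nrow(m), ncol(m),
                                  dimnames = dimnames(m)),
                 taxonomy = tax),
            class = "qmp_abundance")
}

#' Write a quantitative abundance matrix to TSV
#'
#' @param x a `qmp_abundance`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "qmp_abundance"))
  df <- data.frame(taxon_id = rownames(x$cells_per_ml), x$cells_per_ml,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  utils::write.table(format(df, digits = 15, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
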