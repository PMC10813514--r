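scfa_fields <- c("acetate", "propionate", "butyrate", "valerate")
bcfa_fields <- c("isobutyrate", "isocaproate", "isovalerate")

metric_fields <- function(x, fields, what) {
  miss <- setdiff(fields, names(x))
  if (length(miss) > 0) {
    stop_qmp(what, " requires field(s): ", paste(miss, collapse = ", "))
  }
  x[fields]
}

#' Total short-chain fatty acids
#'
#' Acetate + propionate + butyrate + valerate, per sample.
#'
#' @param x data.frame (or named list/vector coercible to one) with the four
#'   SCFA concentration fields.
#' @return numeric vector of totals.
#' @export
total_scfa <- function(x) {
  x <- as.data.frame(as.list(x))[, , drop = FALSE]
  rowSums(metric_fields(x, scfa_fields, "total_scfa"))
}

#' Total branched-chain fatty acids
#'
#' Isobutyrate + isocaproate + isovalerate, per sample.
#'
#' @param x data.frame (or named list/vector) with the three bCFA fields.
#' @return numeric vector of totals.
#' @export
bcfa_sum <- function(x) {
  x <- as.data.frame(as.list(x))[, , drop = FALSE]
  rowSums(metric_fields(x, bcfa_fields, "bcfa_sum"))
}

#' Propionate:acetate ratio
#'
#' A higher ratio is read as a more favourable metabolic profile (less
#' lipogenic acetate per unit propionate).
#'
#' @param x data.frame (or named list/vector) with `propionate` and
#'   `acetate` fields; acetate must be positive.
#' @return numeric vector of ratios.
#' @export
propionate_acetate_ratio <- function(x) {
  x <- as.data.frame(as.list(x))[, , drop = FALSE]
  v <- metric_fields(x, c("propionate", "acetate"), "propionate_acetate_ratio")
  if (any(v$acetate <= 0)) stop_qmp("acetate must be > 0")
  v$propionate / v$acetate
}

#' Percent difference of a metric between two conditions
#'
#' Donors present in both conditions are paired; the statistic is
#' `100 * (mean_a - mean_b) / mean_b` over the paired per-donor values
#' (ratio of cross-donor means, robust to small per-donor denominators).
#'
#' @param table fermentation table with `sample_id` and metric columns.
#' @param metadata sample metadata.
#' @param metric metric column name.
#' @param condition_a,condition_b condition labels (difference is a vs b).
#' @return signed percent difference (scalar).
#' @export
percent_difference <- function(table, metadata, metric, condition_a,
                               condition_b) {
  if (!metric %in% names(table)) {
    stop_qmp("metric '", metric, "' absent from table")
  }
  cols <- paired_columns(metadata, condition_a, condition_b)
  if (length(cols$donors) == 0) {
    stop_qmp("no donor has both '", condition_a, "' and '", condition_b, "'")
  }
  v <- stats::setNames(table[[metric]], table$sample_id)
  a <- v[cols$treatment]
  b <- v[cols$control]
  if (anyNA(a) || anyNA(b)) stop_qmp("table does not cover all paired samples")
  if (mean(b) == 0) stop_qmp("reference mean is zero for '", metric, "'")
  100 * (mean(a) - mean(b)) / mean(b)
}

#' Fermentation metabolite contrast summary
#'
#' For every metric (the table's measured columns plus derived `total_scfa`,
#' `bcfa` and `propionate_acetate_ratio`) and every contrast — each
#' treatment versus the control and, optionally, treatment versus treatment
#' — reports paired means, the percent difference and a donor-paired p/q
#' (the same paired contrast machinery used for taxa, BH-corrected across
#' metrics within a contrast).
#'
#' @param table fermentation table (`sample_id` + metric columns).
#' @param metadata sample metadata.
#' @param control control condition label.
#' @param treatment_pairs also contrast every pair of treatments
#'   (default TRUE).
#' @param fdr FDR level for the discovery flag.
#' @return data.frame of class `metabolite_summary`.
#' @export
metabolite_summary <- function(table, metadata, control = "NSC",
                               treatment_pairs = TRUE, fdr = 0.2) {
  metadata <- validate_metadata(metadata)
  tab <- table
  tab$total_scfa <- total_scfa(table)
  tab$bcfa <- bcfa_sum(table)
  tab$propionate_acetate_ratio <- propionate_acetate_ratio(table)
  metrics <- setdiff(names(tab), "sample_id")
  m <- t(as.matrix(tab[metrics]))
  colnames(m) <- tab$sample_id
  m <- pmax(m, .Machine$double.xmin)  # guard log scale for zero readings

  treatments <- setdiff(unique(metadata$condition), control)
  contrasts <- lapply(treatments, function(tr) c(tr, control))
  if (treatment_pairs && length(treatments) >= 2) {
    cmb <- utils::combn(treatments, 2)
    contrasts <- c(contrasts, lapply(seq_len(ncol(cmb)),
                                     function(j) c(cmb[2, j], cmb[1, j])))
  }
  rows <- lapply(contrasts, function(ab) {
    ct <- paired_contrast(m, metadata, treatment = ab[1], control = ab[2])
    adj <- bh_adjust(ct$p_value, fdr = fdr)
    cols <- paired_columns(metadata, ab[1], ab[2])
    data.frame(
      metric = ct$taxon_id, condition_a = ab[1], condition_b = ab[2],
      mean_a = rowMeans(m[, cols$treatment, drop = FALSE]),
      mean_b = rowMeans(m[, cols$control, drop = FALSE]),
      percent_difference = vapply(ct$taxon_id, function(met) {
        percent_difference(tab, metadata, met, ab[1], ab[2])
      }, numeric(1)),
      p_value = ct$p_value, q_value = adj$q_value,
      significant = adj$significant,
      row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metabolite_summary", "data.frame")
  out
}
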