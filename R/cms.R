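#' The community modulation score fold-change threshold
#'
#' The CMS calls an OTU changed when its quantitative level moves by more
#' than twice the per-OTU technical standard deviation of quantitative
#' sequencing in replicate bioreactors (15%), i.e. a 30% change, giving
#' ~95% certainty that the OTU truly responded.
#'
#' @param technical_sd per-OTU technical SD as a fraction (default 0.15).
#' @return the fold-change threshold as a fraction (default 0.30).
#' @export
cms_threshold <- function(technical_sd = 0.15) {
  stopifnot(technical_sd >= 0)
  2 * technical_sd
}

#' Community modulation score for one donor and treatment
#'
#' Given LOD-imputed absolute abundances of the same top-`n` taxon set in
#' the control (NSC) and treatment arms, counts the taxa that increased
#' (`positive`) or decreased (`negative`, reported as a non-positive count)
#' by more than the threshold:
#' an OTU scores +1 iff `treatment > nsc * (1 + threshold)` and -1 iff
#' `nsc > treatment * (1 + threshold)` (strict inequalities; a change of
#' exactly the threshold does not count). `combined = positive + negative`.
#' Note the two criteria are deliberately asymmetric multiplicative tests
#' (x1.3 each way), not a symmetric log-ratio rule.
#'
#' @param nsc named numeric vector of control-arm abundances (cells/mL).
#' @param treatment named numeric vector of treatment-arm abundances over
#'   the same taxon set.
#' @param threshold fractional change threshold (default [cms_threshold()]).
#' @return list of class `cms_result` with `positive`, `negative`,
#'   `combined`, `n_taxa`, `threshold`.
#' @examples
#' cms_pair(c(a = 100, b = 100, c = 100), c(a = 140, b = 60, c = 120))
#' @export
cms_pair <- function(nsc, treatment, threshold = cms_threshold()) {
  if (length(nsc) != length(treatment)) {
    stop_qmp("mismatched taxon sets: ", length(nsc), " vs ",
             length(treatment), " taxa")
  }
  if (!is.null(names(nsc)) && !is.null(names(treatment))) {
    if (!setequal(names(nsc), names(treatment))) {
      stop_qmp("mismatched taxon sets between control and treatment vectors")
    }
    treatment <- treatment[names(nsc)]
  }
  stopifnot(threshold >= 0, all(nsc >= 0), all(treatment >= 0))
  pos <- sum(treatment > nsc * (1 + threshold))
  neg <- -sum(nsc > treatment * (1 + threshold))
  structure(list(positive = as.integer(pos), negative = as.integer(neg),
                 combined = as.integer(pos + neg),
                 n_taxa = length(nsc), threshold = threshold),
            class = "cms_result")
}

#' @export
print.cms_result <- function(x, ...) {
  cat(sprintf(
    "CMS (n = %d taxa, threshold %.0f%%): positive %d, negative %d, combined %d\n",
    x$n_taxa, 100 * x$threshold, x$positive, x$negative, x$combined))
  invisible(x)
}

#' Community modulation scores for every donor and treatment
#'
#' @param x a LOD-imputed `qmp_abundance`, typically restricted to the top
#'   100 taxa (see [impute_below_lod()], [select_top_n()]).
#' @param metadata sample metadata (`sample_id`, `donor_id`, `condition`).
#' @param control label of the control arm.
#' @param threshold fractional change threshold.
#' @return data.frame of class `cms_table`: one row per donor x treatment
#'   with `positive_cms`, `negative_cms`, `combined_cms`, `n_taxa`,
#'   `threshold`.
#' @export
cms_scores <- function(x, metadata, control = "NSC",
                       threshold = cms_threshold()) {
  stopifnot(inherits(x, "qmp_abundance"))
  metadata <- validate_metadata(metadata)
  if (!control %in% metadata$condition) {
    stop_qmp("control condition '", control, "' absent from metadata")
  }
  treatments <- setdiff(unique(metadata$condition), control)
  rows <- list()
  for (tr in treatments) {
    donors <- intersect(
      metadata$donor_id[metadata$condition == control],
      metadata$donor_id[metadata$condition == tr])
    for (d in donors) {
      sid <- function(cond) {
        metadata$sample_id[metadata$donor_id == d &
                             metadata$condition == cond]
      }
      r <- cms_pair(x$cells_per_ml[, sid(control)],
                    x$cells_per_ml[, sid(tr)], threshold = threshold)
      rows[[length(rows) + 1]] <- data.frame(
        donor_id = d, condition = tr, positive_cms = r$positive,
        negative_cms = r$negative, combined_cms = r$combined,
        n_taxa = r$n_taxa, threshold = r$threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cms_table", "data.frame")
  out
}

#' Cross-donor CMS summary
#'
#' Arithmetic mean and SD of the positive, negative and combined scores
#' across donors, per treatment. Per-donor scores are integers; the
#' cross-donor means are generally not.
#'
#' @param scores a `cms_table` from [cms_scores()].
#' @return data.frame of class `cms_summary`.
#' @export
cms_summary <- function(scores) {
  stopifnot(inherits(scores, "cms_table"), nrow(scores) >= 1)
  sd0 <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v)
  rows <- lapply(split(scores, scores$condition), function(s) {
    data.frame(condition = s$condition[1], n_donors = nrow(s),
               mean_positive = mean(s$positive_cms),
               sd_positive = sd0(s$positive_cms),
               mean_negative = mean(s$negative_cms),
               sd_negative = sd0(s$negative_cms),
               mean_combined = mean(s$combined_cms),
               sd_combined = sd0(s$combined_cms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cms_summary", "data.frame")
  out
}

#' @export
print.cms_summary <- function(x, ...) {
  cat("Community modulation score, cross-donor summary:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %s (n=%d donors): combined %.1f (positive %.1f, negative %.1f)\n",
      x$condition[i], x$n_donors[i], x$mean_combined[i],
      x$mean_positive[i], x$mean_negative[i]))
  }
  invisible(x)
}
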