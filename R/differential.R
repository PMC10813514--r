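# Donor-paired sample columns for a (treatment, control) contrast.
paired_columns <- function(metadata, treatment, control) {
  metadata <- validate_metadata(metadata)
  for (cond in c(treatment, control)) {
    if (!cond %in% metadata$condition) {
      stop_qmp("condition '", cond, "' absent from metadata")
    }
  }
  donors <- intersect(metadata$donor_id[metadata$condition == treatment],
                      metadata$donor_id[metadata$condition == control])
  pick <- function(cond) {
    vapply(donors, function(d) {
      metadata$sample_id[metadata$donor_id == d & metadata$condition == cond]
    }, character(1))
  }
  list(donors = donors, treatment = pick(treatment), control = pick(control))
}

# Paired location test on one vector of within-donor differences.
# Two-condition repeated-measures ANOVA with donor as subject is
# algebraically the paired t-test (F = t^2), which is what is computed.
paired_p <- function(d) {
  n <- length(d)
  if (n < 3) return(list(p = NA_real_, degenerate = FALSE, flag = "too_few_pairs"))
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(p = 1, degenerate = TRUE, flag = "zero_difference"))
    }
    return(list(p = 0, degenerate = TRUE, flag = "zero_variance"))
  }
  list(p = stats::t.test(d)$p.value, degenerate = FALSE, flag = "")
}

#' Paired treatment-versus-control contrast per taxon
#'
#' For each taxon (row), the within-donor differences of log10-transformed
#' LOD-imputed abundances are tested with a paired t-test across donors
#' (equivalently, a two-condition repeated-measures ANOVA with donor as
#' subject). The reported effect size is the mean over donors of
#' log2(treatment / control). Degenerate difference vectors (zero variance)
#' are flagged rather than given a fabricated p-value: all-zero differences
#' report p = 1, constant non-zero differences report p = 0.
#'
#' @param x a LOD-imputed `qmp_abundance`, or a strictly positive numeric
#'   matrix (rows = features, columns = samples).
#' @param metadata sample metadata (`sample_id`, `donor_id`, `condition`).
#' @param treatment treatment condition label.
#' @param control control condition label.
#' @return data.frame with `taxon_id`, `mean_log2_ratio`, `p_value`,
#'   `n_pairs`, `degenerate`, `flag`.
#' @export
paired_contrast <- function(x, metadata, treatment, control = "NSC") {
  m <- if (inherits(x, "qmp_abundance")) x$cells_per_ml else as.matrix(x)
  if (any(m <= 0)) {
    stop_qmp("abundances must be strictly positive (LOD-imputed) for the ",
             "log-scale paired contrast")
  }
  cols <- paired_columns(metadata, treatment, control)
  if (length(cols$donors) == 0) {
    stop_qmp("no donor has both '", treatment, "' and '", control, "' arms")
  }
  mt <- m[, cols$treatment, drop = FALSE]
  mc <- m[, cols$control, drop = FALSE]
  d10 <- log10(mt) - log10(mc)
  res <- apply(d10, 1, paired_p)
  data.frame(
    taxon_id = rownames(m),
    mean_log2_ratio = rowMeans(log2(mt / mc)),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    n_pairs = length(cols$donors),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    flag = vapply(res, `[[`, character(1), "flag"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up q-values (via [stats::p.adjust()], method `"BH"`) with a
#' discovery flag at the given FDR level.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @param fdr FDR level for the flag (default 0.2).
#' @return list with `q_value` and logical `significant`.
#' @export
bh_adjust <- function(p, fdr = 0.2) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)), fdr > 0, fdr <= 1)
  q <- stats::p.adjust(p, method = "BH")
  list(q_value = q, significant = !is.na(q) & q <= fdr)
}

#' Consistency classification for a non-significant taxon
#'
#' A taxon is consistently increasing (decreasing) when it is detected —
#' above the LOD in at least one of the two arms — in at least
#' `min_detected` donors and its treatment/control ratio has the same sign
#' in every donor where it is detected.
#'
#' @param log2_ratios per-donor log2(treatment/control) ratios.
#' @param detected logical per donor: above LOD in either arm.
#' @param min_detected minimum number of detected donors (default 4, the
#'   "four out of six" rule).
#' @return one of `"consistent_up"`, `"consistent_down"`, `"none"`.
#' @export
consistency_classify <- function(log2_ratios, detected, min_detected = 4) {
  stopifnot(length(log2_ratios) == length(detected))
  n_det <- sum(detected)
  if (n_det < min_detected) return("none")
  r <- log2_ratios[detected]
  if (all(r > 0)) return("consistent_up")
  if (all(r < 0)) return("consistent_down")
  "none"
}

#' Per-taxon treatment effect table
#'
#' Runs the paired contrast for every treatment against the control,
#' applies Benjamini-Hochberg correction per treatment across the analysed
#' taxa, and classifies each taxon as `significant_up` / `significant_down`
#' (q <= `fdr`), else `consistent_up` / `consistent_down` (the
#' detection-and-unanimity rule), else `none`. Classification is exclusive
#' and exhaustive.
#'
#' @param x a LOD-imputed `qmp_abundance` (typically top-100 restricted).
#' @param metadata sample metadata.
#' @param control control condition label.
#' @param treatments treatment labels (default: all non-control conditions).
#' @param fdr FDR level for significance (default 0.2).
#' @param min_detected minimum detected donors for consistency (default 4).
#' @return data.frame of class `effect_table`: `taxon_id`, `family`,
#'   `condition`, `mean_log2_ratio`, `p_value`, `q_value`, `class`,
#'   `n_detected`, `n_pairs`, `degenerate`.
#' @export
effect_table <- function(x, metadata, control = "NSC", treatments = NULL,
                         fdr = 0.2, min_detected = 4) {
  stopifnot(inherits(x, "qmp_abundance"))
  metadata <- validate_metadata(metadata)
  treatments <- treatments %||% setdiff(unique(metadata$condition), control)
  fam <- if (!is.null(x$taxonomy)) {
    family_from_lineage(x$taxonomy[rownames(x$cells_per_ml)])
  } else {
    rep("unclassified", nrow(x$cells_per_ml))
  }
  out <- list()
  for (tr in treatments) {
    ct <- paired_contrast(x, metadata, tr, control)
    adj <- bh_adjust(ct$p_value, fdr = fdr)
    cols <- paired_columns(metadata, tr, control)
    ratios <- log2(x$cells_per_ml[, cols$treatment, drop = FALSE] /
                     x$cells_per_ml[, cols$control, drop = FALSE])
    detected <- !(x$imputed[, cols$treatment, drop = FALSE] &
                    x$imputed[, cols$control, drop = FALSE])
    cls <- character(nrow(ct))
    n_det <- integer(nrow(ct))
    for (i in seq_len(nrow(ct))) {
      n_det[i] <- sum(detected[i, ])
      if (adj$significant[i] && ct$mean_log2_ratio[i] != 0) {
        cls[i] <- if (ct$mean_log2_ratio[i] > 0) "significant_up"
                  else "significant_down"
      } else {
        cls[i] <- consistency_classify(ratios[i, ], detected[i, ],
                                       min_detected = min_detected)
      }
    }
    out[[tr]] <- data.frame(
      taxon_id = ct$taxon_id, family = fam, condition = tr,
      mean_log2_ratio = ct$mean_log2_ratio, p_value = ct$p_value,
      q_value = adj$q_value, class = cls, n_detected = n_det,
      n_pairs = ct$n_pairs, degenerate = ct$degenerate,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("effect_table", "data.frame")
  res
}

#' @export
print.effect_table <- function(x, ...) {
  cat("Treatment effect table:", length(unique(x$taxon_id)), "taxa,",
      length(unique(x$condition)), "treatment contrast(s)\n")
  tab <- table(x$condition, x$class)
  print(tab)
  invisible(x)
}

#' Aggregate an abundance profile to family level
#'
#' Family abundance is the sum of member-taxon abundances per sample
#' (column totals are preserved). Taxa without a resolvable family are
#' grouped under `"unclassified"`. A family counts as imputed in a sample
#' only when every member was imputed there, so the detection rule for the
#' consistency classification carries over.
#'
#' @param x a `qmp_abundance`.
#' @param taxonomy optional named lineage vector (defaults to the profile's
#'   own taxonomy).
#' @return a `qmp_abundance` with one row per family.
#' @export
family_rollup <- function(x, taxonomy = NULL) {
  stopifnot(inherits(x, "qmp_abundance"))
  taxonomy <- taxonomy %||% x$taxonomy
  fam <- if (is.null(taxonomy)) {
    rep("unclassified", nrow(x$cells_per_ml))
  } else {
    family_from_lineage(taxonomy[rownames(x$cells_per_ml)])
  }
  fam[is.na(fam)] <- "unclassified"
  cells <- rowsum(x$cells_per_ml, fam)
  detected <- rowsum((!x$imputed) * 1L, fam) > 0
  x$cells_per_ml <- cells
  x$imputed <- !detected
  x$taxonomy <- NULL
  x
}
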