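#' Observed richness of one sample
#'
#' @param x numeric vector of read counts (>= 0).
#' @return number of taxa with at least one read.
#' @export
observed_richness <- function(x) {
  stopifnot(all(x >= 0))
  sum(x >= 1)
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1 and F2
#' are the singleton and doubleton counts; always >= the observed richness
#' and defined when no doubletons occur. Computed via
#' [vegan::estimateR()].
#'
#' @param x integer vector of read counts.
#' @return the Chao1 estimate.
#' @export
chao1 <- function(x) {
  stopifnot(all(x >= 0), all(x == round(x)))
  unname(vegan::estimateR(matrix(as.integer(x), nrow = 1))["S.chao1", 1])
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i log p_i)` over taxa with positive counts (natural log).
#'
#' @param x numeric vector of counts or abundances (>= 0, not all zero).
#' @return Shannon index.
#' @export
shannon_index <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) == 0) stop_qmp("all-zero sample")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Inverse (reciprocal) Simpson diversity of one sample
#'
#' `D = 1 / sum(p_i^2)`; equals the taxon count for a perfectly even
#' community.
#'
#' @param x numeric vector of counts or abundances (>= 0, not all zero).
#' @return inverse Simpson index.
#' @export
inverse_simpson <- function(x) {
  stopifnot(all(x >= 0))
  if (sum(x) == 0) stop_qmp("all-zero sample")
  unname(vegan::diversity(x, index = "invsimpson"))
}

#' Traditional alpha-diversity indices per sample
#'
#' Observed OTUs and Chao1 (richness), Shannon and inverse Simpson
#' (evenness-sensitive), computed on read counts. Note that these
#' proportional-data indices ignore cell density: read depth sets each
#' sample's detection limit, so richness comparisons across arms with
#' different biomass should be interpreted with care.
#'
#' @param counts a [count_table()].
#' @return data.frame of class `diversity_table` with columns `sample_id`,
#'   `observed_otus`, `chao1`, `shannon`, `inverse_simpson`.
#' @export
diversity_indices <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  m <- counts$counts
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop_qmp("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  }
  smp <- t(m)  # vegan convention: samples in rows
  out <- data.frame(
    sample_id = colnames(m),
    observed_otus = as.integer(vegan::specnumber(smp)),
    chao1 = unname(vegan::estimateR(smp)["S.chao1", ]),
    shannon = unname(vegan::diversity(smp, index = "shannon")),
    inverse_simpson = unname(vegan::diversity(smp, index = "invsimpson")),
    stringsAsFactors = FALSE)
  class(out) <- c("diversity_table", "data.frame")
  out
}
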