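#' Enterotype-like family weight templates
#'
#' Three family-level community templates emulating the recurring human gut
#' configurations: one dominated by Lachnospiraceae (with detectable
#' Methanobacteriaceae), one Prevotellaceae-rich and one Bacteroidaceae-rich.
#' Weights per template sum to 1.
#'
#' @return a named list of named numeric family-weight vectors.
#' @export
default_enterotype_templates <- function() {
  fams <- c("Prevotellaceae", "Bacteroidaceae", "Lachnospiraceae",
            "Methanobacteriaceae", "Ruminococcaceae", "Bifidobacteriaceae",
            "Veillonellaceae", "Tannerellaceae", "Coriobacteriaceae",
            "Enterobacteriaceae")
  list(
    Lachnospiraceae_rich = stats::setNames(
      c(0.04, 0.12, 0.32, 0.08, 0.16, 0.08, 0.06, 0.05, 0.05, 0.04), fams),
    Prevotellaceae_rich = stats::setNames(
      c(0.35, 0.08, 0.18, 0.01, 0.14, 0.07, 0.06, 0.03, 0.04, 0.04), fams),
    Bacteroidaceae_rich = stats::setNames(
      c(0.03, 0.35, 0.20, 0.01, 0.12, 0.07, 0.06, 0.06, 0.05, 0.05), fams)
  )
}

#' Planted per-taxon effects
#'
#' Encodes which taxa respond to a treatment and by how much, as a
#' data.frame with one row per (condition, taxon).
#'
#' @param condition treatment label (must not be the control label).
#' @param taxon_ids character vector of taxon ids.
#' @param log2_fold_change signed log2 fold change, recycled over
#'   `taxon_ids`.
#' @return data.frame with columns `condition`, `taxon_id`,
#'   `log2_fold_change`.
#' @export
effect_spec <- function(condition, taxon_ids, log2_fold_change) {
  data.frame(condition = condition, taxon_id = taxon_ids,
             log2_fold_change = rep_len(log2_fold_change, length(taxon_ids)),
             stringsAsFactors = FALSE)
}

#' Default planted responder sets
#'
#' Emulates the observed responder structure of an ex vivo prebiotic
#' comparison: a "broad" substrate (dextran) lifting 22 of the abundant taxa
#' and suppressing 5, and a "narrow" one (inulin) lifting 9 while
#' suppressing 14 — with the suppressed inulin set overlapping the dextran
#' responders, as several taxa disfavoured by inulin are promoted by
#' dextran. All planted |log2 fold changes| are 1.
#'
#' @param n_taxa number of taxa in the community (>= 36).
#' @param taxon_ids optional taxon id vector; defaults to `OTU001`-style ids.
#' @return an effect-spec data.frame (see [effect_spec()]).
#' @export
default_effect_specs <- function(n_taxa, taxon_ids = NULL) {
  if (is.null(taxon_ids)) taxon_ids <- sprintf("OTU%03d", seq_len(n_taxa))
  stopifnot(length(taxon_ids) >= 36)
  rbind(
    effect_spec("dextran", taxon_ids[1:22], 1),
    effect_spec("dextran", taxon_ids[23:27], -1),
    effect_spec("inulin", taxon_ids[1:9], 1),
    effect_spec("inulin", taxon_ids[10:23], -1)
  )
}

#' Configuration for a synthetic ex vivo fermentation experiment
#'
#' Defaults reproduce the reference study design: 6 adult donors spanning
#' three enterotype-like configurations, a no-substrate control (NSC) plus
#' inulin and dextran arms, total cell densities of 3.0e9 (NSC), 7.8e9
#' (inulin) and 8.3e9 (dextran) cells/mL, mean read depths of 18,197 /
#' 32,779 / 25,621 reads, 120 OTUs and 15% multiplicative per-OTU technical
#' variation.
#'
#' @param n_donors number of donors (>= 1).
#' @param n_taxa number of OTUs (>= number of families in the templates).
#' @param enterotype_templates named list of family weight profiles; donors
#'   are assigned templates round-robin.
#' @param control label of the no-substrate control arm.
#' @param nsc_density_mean mean total density of the control arm (cells/mL).
#' @param treatment_density_mean named vector of mean densities per
#'   treatment (cells/mL); the names define the treatment arms. A value of
#'   `NA` makes that arm's density growth-consistent: the total follows the
#'   planted fold changes (non-responders keep their control-arm level)
#'   instead of being drawn independently and renormalised.
#' @param density_cv coefficient of variation of densities (biological draw
#'   and flow-cytometry measurement alike).
#' @param read_depth_mean named vector of mean read depth per condition
#'   (control and treatments), all >= 100.
#' @param read_depth_cv coefficient of variation of per-sample read depth.
#' @param technical_cv per-OTU multiplicative technical noise SD (fraction);
#'   0.15 matches the reported technical variation of quantitative
#'   sequencing in replicate bioreactors.
#' @param baseline_sdlog log-scale SD of within-family per-taxon abundance
#'   draws (biological inter-donor variation; renormalised within family so
#'   the enterotype family structure is preserved).
#' @param family_sdlog log-scale SD of per-donor perturbation of the
#'   template's family weights (mild, so a donor's dominant family remains
#'   the template's).
#' @param effect_specs data.frame of planted effects (see [effect_spec()]),
#'   or NULL for none.
#' @param rng_seed integer seed (< 2^31 - 16) or NULL to use the current RNG
#'   state.
#' @return a validated list of class `qmp_sim_config`.
#' @export
qmp_sim_config <- function(n_donors = 6,
                           n_taxa = 120,
                           enterotype_templates = default_enterotype_templates(),
                           control = "NSC",
                           nsc_density_mean = 3.0e9,
                           treatment_density_mean = c(inulin = 7.8e9,
                                                      dextran = 8.3e9),
                           density_cv = 0.10,
                           read_depth_mean = c(NSC = 18197, inulin = 32779,
                                               dextran = 25621),
                           read_depth_cv = 0.10,
                           technical_cv = 0.15,
                           baseline_sdlog = 1.0,
                           family_sdlog = 0.10,
                           effect_specs = if (n_taxa >= 36)
                             default_effect_specs(n_taxa) else NULL,
                           rng_seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors), n_taxa = as.integer(n_taxa),
              enterotype_templates = enterotype_templates, control = control,
              nsc_density_mean = nsc_density_mean,
              treatment_density_mean = treatment_density_mean,
              density_cv = density_cv, read_depth_mean = read_depth_mean,
              read_depth_cv = read_depth_cv, technical_cv = technical_cv,
              baseline_sdlog = baseline_sdlog, family_sdlog = family_sdlog,
              effect_specs = effect_specs,
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_donors >= 1, cfg$n_taxa >= 1)
  if (cfg$density_cv < 0 || cfg$read_depth_cv < 0 || cfg$technical_cv < 0 ||
      cfg$baseline_sdlog < 0 || cfg$family_sdlog < 0) {
    stop_qmp("coefficients of variation must be >= 0")
  }
  if (cfg$nsc_density_mean <= 0 ||
      any(cfg$treatment_density_mean <= 0, na.rm = TRUE)) {
    stop_qmp("densities must be > 0")
  }
  if (is.null(names(cfg$treatment_density_mean)) ||
      any(!nzchar(names(cfg$treatment_density_mean)))) {
    stop_qmp("treatment_density_mean must be named by treatment")
  }
  if (cfg$control %in% names(cfg$treatment_density_mean)) {
    stop_qmp("control label must not name a treatment arm")
  }
  conds <- c(cfg$control, names(cfg$treatment_density_mean))
  miss <- setdiff(conds, names(cfg$read_depth_mean))
  if (length(miss) > 0) {
    stop_qmp("read_depth_mean lacks condition(s): ",
             paste(miss, collapse = ", "))
  }
  if (any(cfg$read_depth_mean < 100)) {
    stop_qmp("read_depth_mean must be >= 100")
  }
  tpl <- cfg$enterotype_templates
  if (length(tpl) < 1) stop_qmp("at least one enterotype template required")
  fams <- names(tpl[[1]])
  for (t in tpl) {
    if (!identical(sort(names(t)), sort(fams))) {
      stop_qmp("all templates must cover the same family set")
    }
    if (any(t < 0) || abs(sum(t) - 1) > 1e-8) {
      stop_qmp("template weights must be non-negative and sum to 1")
    }
  }
  if (cfg$n_taxa < length(fams)) {
    stop_qmp("n_taxa (", cfg$n_taxa, ") smaller than template support (",
             length(fams), " families)")
  }
  if (!is.null(cfg$effect_specs) && nrow(cfg$effect_specs) > 0) {
    es <- cfg$effect_specs
    ids <- sprintf("OTU%03d", seq_len(cfg$n_taxa))
    if (any(!es$taxon_id %in% ids)) {
      stop_qmp("effect_specs reference taxa outside the generated set")
    }
    if (any(es$condition == cfg$control)) {
      stop_qmp("effect_specs must not target the control arm")
    }
    if (any(!es$condition %in% names(cfg$treatment_density_mean))) {
      stop_qmp("effect_specs reference unknown treatment(s)")
    }
  }
  class(cfg) <- "qmp_sim_config"
  cfg
}

sim_seed <- function(cfg, offset) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed + offset)
  invisible(NULL)
}

#' Generate per-donor baseline relative abundance profiles
#'
#' Donors are assigned enterotype templates round-robin, and taxa are nested
#' under families round-robin. Noise is hierarchical: the template's family
#' weights receive a mild log-normal perturbation (`family_sdlog`,
#' renormalised over families) so a donor's dominant family stays that of
#' its template, and within each family the even per-taxon split receives a
#' log-normal draw (`baseline_sdlog`, renormalised within the family). The
#' resulting per-donor vector sums to 1.
#'
#' @param config a [qmp_sim_config()].
#' @return a list of class `qmp_baseline`: `rel` (taxa x donors relative
#'   abundance matrix), `family` (named character), `taxonomy` (lineage
#'   strings), `template` (template name per donor).
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "qmp_sim_config"))
  sim_seed(config, 0L)
  tpl <- config$enterotype_templates
  fams <- names(tpl[[1]])
  taxa <- sprintf("OTU%03d", seq_len(config$n_taxa))
  fam_of <- stats::setNames(fams[(seq_len(config$n_taxa) - 1) %%
                                   length(fams) + 1], taxa)
  members <- table(fam_of)
  donors <- sprintf("D%d", seq_len(config$n_donors))
  tpl_of <- names(tpl)[(seq_len(config$n_donors) - 1) %% length(tpl) + 1]
  rel <- matrix(NA_real_, config$n_taxa, config$n_donors,
                dimnames = list(taxa, donors))
  for (d in seq_len(config$n_donors)) {
    fw <- tpl[[tpl_of[d]]]
    if (config$family_sdlog > 0) {
      fw <- fw * stats::rlnorm(length(fw), 0, config$family_sdlog)
      fw <- fw / sum(fw)
    }
    within <- rep(1, config$n_taxa)
    if (config$baseline_sdlog > 0) {
      within <- stats::rlnorm(config$n_taxa, 0, config$baseline_sdlog)
    }
    within <- within / as.numeric(rowsum(within, fam_of)[fam_of, 1])
    w <- fw[fam_of] * within
    rel[, d] <- w / sum(w)
  }
  taxonomy <- stats::setNames(
    paste0("k__Bacteria;p__;c__;o__;f__", fam_of, ";g__;s__", taxa), taxa)
  structure(list(rel = rel, family = fam_of, taxonomy = taxonomy,
                 template = stats::setNames(tpl_of, donors)),
            class = "qmp_baseline")
}

#' Apply planted effects and densities to obtain ground truth
#'
#' The control arm's true abundance is the baseline profile scaled by the
#' donor's control density draw. For a treatment arm with an explicit mean
#' density, planted taxa are multiplied by `2^log2_fold_change`, the column
#' is renormalised, and the result is scaled to that arm's independent
#' density draw; non-planted taxa then change only through the density
#' ratio and the renormalisation. For an arm with `NA` density the planted
#' fold changes act directly on the control-arm absolute levels and the
#' total density follows the resulting growth (non-responders keep their
#' control level exactly).
#'
#' @param baseline a `qmp_baseline` from [generate_baseline()].
#' @param config the [qmp_sim_config()] used to generate it.
#' @return a list of class `qmp_truth`: `true_abundance` (taxa x samples,
#'   cells/mL), `true_density` (named per sample), `metadata` (sample to
#'   donor/condition map), `planted_effects` (per treatment, named log2 fold
#'   changes), plus the baseline's `family` and `taxonomy`.
#' @export
apply_effects <- function(baseline, config) {
  stopifnot(inherits(baseline, "qmp_baseline"),
            inherits(config, "qmp_sim_config"))
  sim_seed(config, 1L)
  donors <- colnames(baseline$rel)
  treatments <- names(config$treatment_density_mean)
  conds <- c(config$control, treatments)
  meta <- expand.grid(donor_id = donors, condition = conds,
                      stringsAsFactors = FALSE)
  meta <- meta[order(match(meta$donor_id, donors),
                     match(meta$condition, conds)), ]
  meta$sample_id <- paste(meta$donor_id, meta$condition, sep = "_")
  rownames(meta) <- NULL
  meta <- meta[c("sample_id", "donor_id", "condition")]

  fc <- sapply(treatments, function(tr) {
    v <- stats::setNames(rep(0, nrow(baseline$rel)), rownames(baseline$rel))
    es <- config$effect_specs
    if (!is.null(es) && nrow(es) > 0) {
      es <- es[es$condition == tr, , drop = FALSE]
      v[es$taxon_id] <- es$log2_fold_change
    }
    v
  }, simplify = FALSE)

  # Control densities are drawn per donor; each treatment arm either draws
  # its own density (explicit mean, column renormalised to it) or inherits
  # a growth-consistent one (NA mean, fold changes act on absolute levels).
  ctrl_density <- stats::setNames(
    rlnorm_mean_cv(length(donors), config$nsc_density_mean,
                   config$density_cv), donors)
  dens_mean <- config$treatment_density_mean
  true_density <- stats::setNames(numeric(nrow(meta)), meta$sample_id)
  abund <- matrix(NA_real_, nrow(baseline$rel), nrow(meta),
                  dimnames = list(rownames(baseline$rel), meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    b <- baseline$rel[, meta$donor_id[i]]
    cond <- meta$condition[i]
    if (cond == config$control) {
      dens <- ctrl_density[meta$donor_id[i]]
      col <- b * dens
    } else if (is.na(dens_mean[[cond]])) {
      col <- b * 2^fc[[cond]] * ctrl_density[meta$donor_id[i]]
      dens <- sum(col)
    } else {
      m <- b * 2^fc[[cond]]
      dens <- rlnorm_mean_cv(1, dens_mean[[cond]], config$density_cv)
      col <- m / sum(m) * dens
    }
    true_density[meta$sample_id[i]] <- dens
    abund[, i] <- col
  }
  structure(list(true_abundance = abund, true_density = true_density,
                 metadata = meta, planted_effects = fc,
                 family = baseline$family, taxonomy = baseline$taxonomy),
            class = "qmp_truth")
}

#' True quantitative fold change of a treatment versus the control
#'
#' @param truth a `qmp_truth`.
#' @param condition treatment label.
#' @param config the generating [qmp_sim_config()] (for the control label).
#' @return taxa x donors matrix of true abundance ratios
#'   (treatment / control).
#' @export
true_fold_change <- function(truth, condition, config) {
  meta <- truth$metadata
  donors <- unique(meta$donor_id)
  t_id <- paste(donors, condition, sep = "_")
  c_id <- paste(donors, config$control, sep = "_")
  m <- truth$true_abundance[, t_id, drop = FALSE] /
    truth$true_abundance[, c_id, drop = FALSE]
  colnames(m) <- donors
  m
}

# Negative-binomial-ish read depth with mean mu and CV cv (cv^2 > 1/mu
# required for a proper NB; degenerates to round(mu) otherwise).
draw_depth <- function(n, mu, cv) {
  if (cv == 0 || cv^2 <= 1 / mu) {
    return(rep_len(as.integer(round(mu)), n))
  }
  size <- 1 / (cv^2 - 1 / mu)
  pmax(1L, stats::rnbinom(n, mu = mu, size = size))
}

#' Simulate 16S sequencing of a ground-truth experiment
#'
#' Per sample, true relative abundances are perturbed taxon-wise by
#' multiplicative log-normal technical noise (CV `technical_cv`),
#' renormalised, and reads are drawn multinomially at a depth drawn around
#' the condition's mean read depth. Column sums equal the realised depths.
#'
#' @param truth a `qmp_truth` from [apply_effects()].
#' @param config the generating [qmp_sim_config()].
#' @return a [count_table()] with the truth's taxonomy attached.
#' @export
simulate_sequencing <- function(truth, config) {
  stopifnot(inherits(truth, "qmp_truth"), inherits(config, "qmp_sim_config"))
  sim_seed(config, 2L)
  meta <- truth$metadata
  n_taxa <- nrow(truth$true_abundance)
  counts <- matrix(0L, n_taxa, nrow(meta),
                   dimnames = dimnames(truth$true_abundance))
  for (i in seq_len(nrow(meta))) {
    p <- truth$true_abundance[, i] / truth$true_density[i]
    p <- p * lnorm_noise(n_taxa, config$technical_cv)
    p <- p / sum(p)
    depth <- draw_depth(1, config$read_depth_mean[[meta$condition[i]]],
                        config$read_depth_cv)
    counts[, i] <- stats::rmultinom(1, depth, p)[, 1]
  }
  count_table(counts, taxonomy = truth$taxonomy)
}

#' Simulate flow-cytometry total cell counts
#'
#' Measured density is the true per-sample density perturbed by
#' multiplicative log-normal noise with CV `density_cv`.
#'
#' @param truth a `qmp_truth`.
#' @param config the generating [qmp_sim_config()].
#' @return data.frame with `sample_id` and `total_cells_per_ml`.
#' @export
simulate_cell_counts <- function(truth, config) {
  stopifnot(inherits(truth, "qmp_truth"), inherits(config, "qmp_sim_config"))
  sim_seed(config, 3L)
  data.frame(
    sample_id = truth$metadata$sample_id,
    total_cells_per_ml = unname(truth$true_density) *
      lnorm_noise(length(truth$true_density), config$density_cv),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic fermentation experiment
#'
#' Composes [generate_baseline()], [apply_effects()],
#' [simulate_sequencing()] and [simulate_cell_counts()]. Deterministic for a
#' fixed `rng_seed`: each stage seeds its own stream from the config seed,
#' so calling the stages individually reproduces the composed result.
#'
#' @param config a [qmp_sim_config()].
#' @return a list of class `qmp_experiment`: `counts` ([count_table()]),
#'   `metadata`, `densities` (measured), `truth` (`qmp_truth`) and `config`.
#' @examples
#' ex <- generate_experiment(qmp_sim_config(rng_seed = 7))
#' ex$counts
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "qmp_sim_config"))
  baseline <- generate_baseline(config)
  truth <- apply_effects(baseline, config)
  counts <- simulate_sequencing(truth, config)
  densities <- simulate_cell_counts(truth, config)
  structure(list(counts = counts, metadata = truth$metadata,
                 densities = densities, truth = truth, config = config),
            class = "qmp_experiment")
}

#' @export
print.qmp_experiment <- function(x, ...) {
  cat("Synthetic fermentation experiment:",
      length(unique(x$metadata$donor_id)), "donors x",
      length(unique(x$metadata$condition)), "conditions,",
      nrow(x$counts$counts), "taxa\n")
  invisible(x)
}

#' Default metabolite condition profile
#'
#' Per-condition means (and a common 8% CV) of the fermentation metrics the
#' generator emits. Chosen to emulate the qualitative metabolite shifts of a
#' dextran-versus-inulin ex vivo comparison: both treatments raise SCFA and
#' gas and lower pH and bCFA versus the no-substrate control; dextran yields
#' 25% more propionate than inulin and 31% less gas.
#'
#' @return list with `means` (condition x metric matrix) and `cv`.
#' @export
default_metabolite_profile <- function() {
  metrics <- c("acetate", "propionate", "butyrate", "valerate",
               "isobutyrate", "isocaproate", "isovalerate",
               "gas_pressure", "pH")
  means <- rbind(
    NSC     = c(20, 10, 8, 2.0, 1.0, 0.3, 1.2, 50.0, 6.8),
    inulin  = c(46, 16, 14, 1.2, 0.5, 0.15, 0.6, 130.0, 5.9),
    dextran = c(42, 20, 14, 2.2, 0.5, 0.15, 0.6, 89.7, 6.0))
  colnames(means) <- metrics
  list(means = means, cv = 0.08)
}

#' Generate synthetic fermentation metabolite measurements
#'
#' Condition-shifted Gaussian draws per metric (no production kinetics are
#' modelled). Concentrations are floored at 0.01 mM (a reporting floor) and
#' pH is clamped to (0, 14).
#'
#' @param metadata sample metadata (columns `sample_id`, `donor_id`,
#'   `condition`).
#' @param profile a profile as returned by [default_metabolite_profile()];
#'   its `means` rows must cover every condition in `metadata`.
#' @param seed optional integer seed.
#' @return data.frame with `sample_id` and one column per metric.
#' @export
generate_metabolites <- function(metadata,
                                 profile = default_metabolite_profile(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  miss <- setdiff(unique(metadata$condition), rownames(profile$means))
  if (length(miss) > 0) {
    stop_qmp("metabolite profile lacks condition(s): ",
             paste(miss, collapse = ", "))
  }
  mu <- profile$means[metadata$condition, , drop = FALSE]
  draws <- lapply(colnames(mu), function(met) {
    stats::rnorm(nrow(mu), mean = mu[, met], sd = profile$cv * mu[, met])
  })
  names(draws) <- colnames(mu)
  out <- as.data.frame(draws, optional = TRUE)
  conc <- setdiff(colnames(out), "pH")
  out[conc] <- lapply(out[conc], function(v) pmax(v, 0.01))
  out$pH <- pmin(pmax(out$pH, 0.01), 13.99)
  cbind(data.frame(sample_id = metadata$sample_id,
                   stringsAsFactors = FALSE), out)
}
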