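#' Run the quantitative profiling + CMS pipeline end to end
#'
#' Stages, in order: quantification (proportions x densities, per-sample
#' LOD), alpha-diversity on read counts, LOD imputation, top-n restriction,
#' community modulation scores with cross-donor summary, per-taxon paired
#' effect table (OTU and family level), and, when a fermentation table is
#' supplied or simulated, the metabolite contrast summary. Inputs are either
#' the three observed tables (`counts`, `densities`, `metadata`) or a
#' synthetic `config` — exactly one of the two.
#'
#' Defaults follow the reference analysis: 30% CMS threshold, top 100 OTUs,
#' FDR 0.2, consistency rule "detected in at least 4 donors".
#'
#' @param counts a [count_table()] (with `densities` and `metadata`).
#' @param densities density table (`sample_id`, `total_cells_per_ml`).
#' @param metadata sample metadata (`sample_id`, `donor_id`, `condition`).
#' @param metabolites optional fermentation table (`sample_id` + metrics).
#' @param config alternatively, a [qmp_sim_config()]; the experiment (and a
#'   metabolite table) are simulated from it.
#' @param control control condition label.
#' @param threshold CMS fractional change threshold.
#' @param top_n number of most abundant OTUs retained.
#' @param fdr FDR level.
#' @param min_detected consistency rule detection minimum.
#' @param impute_policy LOD imputation policy (see [impute_below_lod()]).
#' @param outdir optional directory: all result tables plus a plain-text run
#'   report are written there as TSV.
#' @return an object of class `qmp_run` bundling all stage outputs.
#' @examples
#' run <- run_qmp_pipeline(config = qmp_sim_config(rng_seed = 11))
#' run$cms_summary
#' @export
run_qmp_pipeline <- function(counts = NULL, densities = NULL, metadata = NULL,
                             metabolites = NULL, config = NULL,
                             control = "NSC", threshold = cms_threshold(),
                             top_n = 100, fdr = 0.2, min_detected = 4,
                             impute_policy = "overall", outdir = NULL) {
  have_tables <- !is.null(counts)
  if (have_tables == !is.null(config)) {
    stop_qmp("provide either (counts, densities, metadata) or a synthetic ",
             "config, not both")
  }
  stopifnot(threshold >= 0, top_n >= 1, fdr > 0, fdr <= 1, min_detected >= 1)
  if (!is.null(config)) {
    control <- config$control
    ex <- generate_experiment(config)
    counts <- ex$counts
    densities <- ex$densities
    metadata <- ex$metadata
    if (is.null(metabolites)) {
      seed <- if (is.null(config$rng_seed)) NULL else config$rng_seed + 4L
      metabolites <- generate_metabolites(metadata, seed = seed)
    }
  } else {
    if (is.null(densities) || is.null(metadata)) {
      stop_qmp("counts require matching densities and metadata")
    }
    ex <- NULL
  }
  metadata <- validate_metadata(metadata)
  if (!control %in% metadata$condition) {
    stop_qmp("pipeline stage 'setup': control condition '", control,
             "' absent from metadata")
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_qmp("pipeline stage '", stage, "': ", conditionMessage(e))
    })
  }
  abundance <- run_stage("quantify", quantify(counts, densities))
  diversity <- run_stage("diversity", diversity_indices(counts))
  imputed <- run_stage("impute",
                       impute_below_lod(abundance, policy = impute_policy))
  top <- run_stage("top_n", select_top_n(imputed, n = top_n))
  cms <- run_stage("cms", cms_scores(top, metadata, control = control,
                                     threshold = threshold))
  cms_sum <- cms_summary(cms)
  effects <- run_stage("differential",
                       effect_table(top, metadata, control = control,
                                    fdr = fdr, min_detected = min_detected))
  fam_effects <- run_stage("family_rollup", {
    fam <- family_rollup(imputed)
    effect_table(fam, metadata, control = control, fdr = fdr,
                 min_detected = min_detected)
  })
  metab <- if (!is.null(metabolites)) {
    run_stage("metabolites",
              metabolite_summary(metabolites, metadata, control = control,
                                 fdr = fdr))
  }
  log <- list(
    n_taxa_in = nrow(counts$counts),
    n_taxa_retained = nrow(top$cells_per_ml),
    n_taxa_dropped_by_top_n = nrow(counts$counts) - nrow(top$cells_per_ml),
    n_entries_imputed = sum(imputed$imputed),
    overall_lod_cells_per_ml = max(abundance$lod))
  run <- structure(
    list(counts = counts, densities = densities, metadata = metadata,
         metabolites = metabolites, abundance = abundance,
         imputed = imputed, top = top, diversity = diversity,
         cms = cms, cms_summary = cms_sum, effects = effects,
         family_effects = fam_effects, metabolite_summary = metab,
         experiment = ex, log = log,
         params = list(control = control, threshold = threshold,
                       top_n = top_n, fdr = fdr,
                       min_detected = min_detected,
                       impute_policy = impute_policy,
                       seed = if (!is.null(config)) config$rng_seed)),
    class = "qmp_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.qmp_run <- function(x, ...) {
  cat("Quantitative microbiome profiling run\n")
  cat(sprintf("  %d samples, %d taxa (%d retained for testing), %d donors\n",
              ncol(x$counts$counts), x$log$n_taxa_in, x$log$n_taxa_retained,
              length(unique(x$metadata$donor_id))))
  cat(sprintf("  overall LOD %.3g cells/mL; %d entries imputed\n",
              x$log$overall_lod_cells_per_ml, x$log$n_entries_imputed))
  print(x$cms_summary)
  invisible(x)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_count_table(run$counts, p("counts.tsv"))
  write_tsv(run$densities, p("densities.tsv"))
  write_tsv(run$metadata, p("metadata.tsv"))
  write_abundance_table(run$imputed, p("abundance_imputed.tsv"))
  write_tsv(run$diversity, p("diversity.tsv"))
  write_tsv(run$cms, p("cms.tsv"))
  write_tsv(run$cms_summary, p("cms_summary.tsv"))
  write_effect_table(run$effects, p("effects.tsv"))
  write_effect_table(run$family_effects, p("family_effects.tsv"))
  if (!is.null(run$metabolite_summary)) {
    write_tsv(format(run$metabolite_summary, digits = 15, trim = TRUE),
              p("metabolite_summary.tsv"))
    write_tsv(run$metabolites, p("metabolites.tsv"))
  }
  rpt <- c(
    "qmpcms run report",
    paste0("package version: ",
           as.character(utils::packageVersion("qmpcms"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", run$params$seed %||% "none"),
    paste0("control: ", run$params$control),
    paste0("cms threshold: ", run$params$threshold),
    paste0("top_n: ", run$params$top_n),
    paste0("fdr: ", run$params$fdr),
    paste0("min_detected: ", run$params$min_detected),
    paste0("impute policy: ", run$params$impute_policy),
    paste0("taxa in/retained/dropped: ", run$log$n_taxa_in, "/",
           run$log$n_taxa_retained, "/", run$log$n_taxa_dropped_by_top_n),
    paste0("entries imputed: ", run$log$n_entries_imputed),
    sprintf("overall LOD (cells/mL): %.6g", run$log$overall_lod_cells_per_ml))
  writeLines(rpt, p("report.txt"))
  invisible(outdir)
}
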