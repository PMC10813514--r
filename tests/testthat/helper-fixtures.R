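# Shared fixture builders for the suite. Everything is generated in code;
# no data files.

tiny_counts <- function() {
  count_table(matrix(c(3L, 1L, 0L, 2L), nrow = 2,
                     dimnames = list(c("OTU1", "OTU2"), c("S1", "S2"))),
              taxonomy = c(OTU1 = "k__B;p__;c__;o__;f__Bacteroidaceae;g__;s__x",
                           OTU2 = "k__B;p__;c__;o__;f__Lachnospiraceae;g__;s__y"))
}

densities_for <- function(counts, value = 1e9) {
  data.frame(sample_id = colnames(counts$counts),
             total_cells_per_ml = rep_len(value, ncol(counts$counts)),
             stringsAsFactors = FALSE)
}

# A deterministic small config: one treatment, no noise anywhere unless
# asked for, uniform two-family community.
quiet_config <- function(n_donors = 2, n_taxa = 4, depth = 1000,
                         density = 1e9, treatment_density = density,
                         effect_specs = NULL, technical_cv = 0,
                         density_cv = 0, seed = 1) {
  qmp_sim_config(
    n_donors = n_donors, n_taxa = n_taxa,
    enterotype_templates = list(even = c(FamA = 0.5, FamB = 0.5)),
    nsc_density_mean = density,
    treatment_density_mean = c(trt = treatment_density),
    density_cv = density_cv,
    read_depth_mean = c(NSC = depth, trt = depth),
    read_depth_cv = 0, technical_cv = technical_cv,
    baseline_sdlog = 0, family_sdlog = 0,
    effect_specs = effect_specs, rng_seed = seed)
}

# Study-emulating config with planted responder sets on a single treatment
# arm; the arm's density is growth-consistent (NA mean: the total follows
# the planted fold changes), so the responder counts set the CMS sign.
recovery_config <- function(n_donors, n_up, n_down, depth, condition = "trt",
                            seed = 1) {
  n_taxa <- 100
  ids <- sprintf("OTU%03d", seq_len(n_taxa))
  specs <- rbind(
    if (n_up > 0) effect_spec(condition, ids[seq_len(n_up)], 1),
    if (n_down > 0) effect_spec(condition, ids[n_up + seq_len(n_down)], -1))
  qmp_sim_config(
    n_donors = n_donors, n_taxa = n_taxa,
    nsc_density_mean = 3.0e9,
    treatment_density_mean = stats::setNames(NA_real_, condition),
    density_cv = 0.10,
    read_depth_mean = stats::setNames(c(18197, depth), c("NSC", condition)),
    read_depth_cv = 0.10, technical_cv = 0.15,
    effect_specs = specs, rng_seed = seed)
}

# Run the quantitative CMS pipeline stages on an experiment and return the
# per-donor score table.
cms_from_experiment <- function(ex, top_n = 100) {
  ab <- quantify(ex$counts, ex$densities)
  ab <- impute_below_lod(ab, policy = "overall")
  top <- select_top_n(ab, n = top_n)
  cms_scores(top, ex$metadata, control = ex$config$control)
}

# Independent brute-force CMS: per-taxon loop, no vectorisation shared with
# the implementation.
cms_brute <- function(nsc, treatment, threshold = 0.3) {
  pos <- 0L
  neg <- 0L
  for (i in seq_along(nsc)) {
    if (treatment[i] > nsc[i] * (1 + threshold)) {
      pos <- pos + 1L
    } else if (nsc[i] > treatment[i] * (1 + threshold)) {
      neg <- neg - 1L
    }
  }
  list(positive = pos, negative = neg, combined = pos + neg)
}

# Exhaustive two-sided sign-flip permutation p-value of the paired t
# statistic for n = 6 differences.
signflip_p <- function(d) {
  stopifnot(length(d) == 6)
  tstat <- function(x) abs(mean(x) / (stats::sd(x) / sqrt(length(x))))
  t0 <- tstat(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  ts <- apply(signs, 1, function(s) tstat(s * d))
  mean(ts >= t0 - 1e-12)
}

# Donor-paired metadata over a set of conditions.
md_pairs <- function(n = 6, conds = c("C", "T")) {
  data.frame(
    sample_id = as.vector(outer(sprintf("D%d", 1:n), conds, paste, sep = "_")),
    donor_id = rep(sprintf("D%d", 1:n), length(conds)),
    condition = rep(conds, each = n), stringsAsFactors = FALSE)
}

# One-feature abundance matrix whose within-donor log10 differences equal d.
mat_from_diffs <- function(d, base = 1e6) {
  n <- length(d)
  matrix(c(rep(base, n), base * 10^d), nrow = 1,
         dimnames = list("m1", md_pairs(n)$sample_id))
}

# Hand-computed Benjamini-Hochberg step-up q-values.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
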