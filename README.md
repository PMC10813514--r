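# qmpcms

Quantitative microbiome profiling (QMP) and community modulation scores
for ex vivo gut fermentation experiments.

## What it does, and for whom

Sequencing yields proportions; fermentation treatments change total
biomass. For anyone analysing donor-paired ex vivo incubations (e.g.
prebiotic screens against a no-substrate control, NSC), `qmpcms` converts
OTU read counts plus flow-cytometry total cell counts into estimated
absolute abundances (cells/mL), models each sample's limit of detection
(LOD), and computes:

* **Traditional α-diversity** — observed OTUs, Chao1, Shannon, inverse
  Simpson — together with the per-sample LOD that qualifies richness
  comparisons: a sample with total reads $R$ and density $D$ can only
  reveal taxa above $1/R$ proportionally, i.e. $D/R$ cells/mL. Treatments
  that raise density raise the detection floor, so richness losses under
  treatment can be detection artefacts.
* **The community modulation score (CMS)** over the 100 most abundant
  OTUs, per donor:

  $$\mathrm{CMS}^{+} = \#\{i : x^{T}_i > 1.3\,x^{C}_i\},\quad
    \mathrm{CMS}^{-} = -\#\{i : x^{C}_i > 1.3\,x^{T}_i\},\quad
    \mathrm{CMS} = \mathrm{CMS}^{+} + \mathrm{CMS}^{-}$$

  on LOD-imputed absolute abundances $x^T$ (treatment) and $x^C$
  (control); the 30% threshold is twice the 15% technical SD of
  quantitative sequencing in replicate bioreactors. A positive combined
  score says more taxa grew than declined.
* **Donor-paired differential testing** per taxon on log10 abundances
  (paired t-test ≡ two-condition repeated-measures ANOVA), effects as mean
  log2(treatment/NSC), Benjamini–Hochberg FDR (0.20) per contrast, plus a
  consistency class for non-significant taxa (detected in ≥ 4 donors,
  unanimous direction), at OTU and family level.
* **Fermentation metabolite summaries** — total SCFA, bCFA, the
  propionate:acetate ratio, and donor-paired percent differences between
  conditions with the same paired testing.
* **A synthetic experiment generator** (donors × conditions, enterotype
  templates, planted per-taxon fold changes, technical and density noise,
  ground truth) used throughout the tests for recovery analyses.

## Worked example

```r
library(qmpcms)
run <- run_qmp_pipeline(config = qmp_sim_config(rng_seed = 1))
print(run)
#> Quantitative microbiome profiling run
#>   18 samples, 120 taxa (100 retained for testing), 6 donors
#>   overall LOD 4.66e+05 cells/mL; 15 entries imputed
#> Community modulation score, cross-donor summary:
#>   dextran (n=6 donors): combined 93.8 (positive 94.3, negative -0.5)
#>   inulin (n=6 donors): combined 93.8 (positive 94.5, negative -0.7)
```

The default configuration emulates a 6-donor × {NSC, inulin, dextran}
study at the published densities and read depths. Both treatment arms
carry ~2.6–2.8× the control's total density, so nearly every abundant
taxon is genuinely above 1.3× its control level — the strongly positive
combined scores for both arms report that density gain. The responder
*structure* (which taxa, how many up versus down) is what distinguishes
substrates when arm densities are comparable; see the recovery analyses
in the vignette and acceptance script.

```r
lod_percent(c(18197, 32779, 25621))
#> [1] 0.006 0.003 0.004
```

These are the proportional detection limits implied by the three
conditions' mean read depths: 0.006%, 0.003% and 0.004% — i.e. at
3.0 × 10⁹ cells/mL a taxon needs ~1.6 × 10⁵ cells/mL to be seen at all.

The per-stage functions are exported individually (`quantify()`,
`impute_below_lod()`, `select_top_n()`, `cms_scores()`, `effect_table()`,
`metabolite_summary()`, …); `vignettes/quantitative-cms.Rmd` documents the
model, the parameter choices and the generator's scope.

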