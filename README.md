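# clonevasc

Quantitative analysis of **clonal neovascularization by resident cardiac
endothelial cells** after myocardial infarction, and of the **single-cell
transcriptional states** that carry it.

The package is aimed at groups using multicolour (Brainbow2.1/"Confetti")
lineage tracing of endothelium together with droplet scRNA-seq. It has two
arms:

1. **Lineage tracing.** A calibrated stochastic simulator of Confetti-labelled
   tissue (`simulate_tissue()`, presets for healthy myocardium and the
   7-day infarct border), connected-component clone calling under 6-connected
   lattice adjacency (`call_clones()`), clone-size / founder-event / vessel
   clonality / EdU statistics (`clonal_stats()`, `classify_vessels()`), and
   merger-versus-expansion inference (`merger_test()`,
   `colour_collision_probability()`).

   A *clone* is two or more adjacent cells expressing the same fluorophore
   c ∈ {YFP, RFP, nGFP, mCFP}; a labelled singleton or a clone is one
   *founder event*. The analytic merger null is the colour-collision
   probability for k independent adjacent founders,
   P(collision) = Σ_c p_c^k, and the statistical merger test asks whether
   clone size S increases with the frequency p_c of its colour
   (one-sided permutation test on the Spearman association, with a
   permutation Kruskal–Wallis of S across colours reported alongside).
   Clone sizes for dividing founders follow a shifted negative binomial
   S = 2 + X, moment-matched to the target mean ± SD (healthy 4.0 ± 2.1;
   border zone 10.3 ± 10.6).

2. **Single-cell EC states.** A negative-binomial UMI simulator with ten
   endothelial archetypes, an MI-exclusive state, a haematopoietic
   (Ptprc⁺Pecam1⁻Kdr⁻) contaminant population and QC artefacts
   (`simulate_counts()`); QC filtering (<400 detected genes, >20%
   mitochondrial fraction; `qc_filter()`); PCA + Leiden clustering with a
   display-only 3D t-SNE (`embed_and_cluster()`); contaminant-cluster
   removal (`remove_contaminant_cluster()`); one-vs-rest rank-sum marker
   detection with BH adjustment (`cluster_markers()`); per-cluster group
   composition tests (`composition_test()`); expression-bin-matched
   gene-signature scoring for EndMT (`score_signature()`, shipped
   reconstructed panel via `endmt_panel()`); and per-gene queries
   (`gene_query()`, e.g. `Plvap`).

`run_pipeline()` chains both arms from a seeded configuration and writes all
tables plus a JSON report. See the methods vignette
(`vignettes/clonal-neovascularization.Rmd`) for the model, its assumptions
and the calibration details.

## Worked example

```r
library(clonevasc)

tissue <- simulate_tissue(tissue_preset("healthy"), sections = 30, seed = 1)
clones <- call_clones(tissue)
clonal_stats(clones, tissue)
#> Clonal statistics
#>   clones 393 (mean size 3.91, SD 2.14); singletons 1781
#>   founder events/section 72.5; singleton cell fraction 0.537
#>   colour fractions: YFP=0.495 RFP=0.266 nGFP=0.114 mCFP=0.124
#>   monoclonal vessels 0.738; EdU+ | labelled 0.271; EdU+ | all 0.1552
#>   recovered recombination efficiency 0.466
```

One seeded healthy-heart run of 30 wholemount sections: ~72.5 founding
recombination events per section, clones averaging 3.91 cells, 53.7% of
labelled cells still single (undivided), 73.8% of classifiable vessels
monoclonal, 27.1% of labelled cells in S phase within the EdU window, and a
recovered recombination efficiency of 46.6% — each estimate falling on its
preset's generating value up to Monte-Carlo error.

```r
merger_test(clones, n_resamples = 2000, seed = 1)
#> Merger-versus-expansion test
#>   393 clones; trend rho = -0.022, one-sided permutation p = 0.6667
#>   Kruskal-Wallis H = 2.197, permutation p = 0.5577 (2000 resamples)
```

Clone size shows no association with colour frequency, as expected under
pure clonal expansion: patches are clones, not chance mergers.

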