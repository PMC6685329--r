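---
title: "Modelling clonal neovascularization and endothelial states in the infarcted heart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clonal neovascularization and endothelial states in the infarcted heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonevasc)
```

## The biological question

After myocardial infarction (MI), new blood vessels form in the border zone
flanking the scar. Multicolour lineage tracing with an endothelial-restricted
inducible Cre and the Brainbow2.1 ("Confetti") reporter marks individual
endothelial cells (ECs) with one of four heritable fluorophores (YFP, RFP,
nuclear GFP, membrane CFP) at a defined induction time. If a labelled cell
proliferates clonally, its progeny form a spatially contiguous patch of one
colour; a patch of two or more adjacent same-coloured cells is read as a
*clone*, and a labelled cell or clone is one *founder event* (one
recombination). Comparing clone statistics between healthy myocardium and the
infarct border, together with a single-cell RNA-seq atlas of the same
Confetti+ EC population, addresses (i) whether neovascularization proceeds by
clonal expansion of resident ECs rather than by merger of independently
labelled neighbours or by influx of bone-marrow cells, and (ii) which
transcriptional EC states carry it.

`clonevasc` implements both arms as a reusable, fully testable pipeline. The
real imaging and sequencing data are not redistributed; instead a calibrated
stochastic simulator generates tissue maps and count matrices whose summary
statistics are, by construction, those published for the system, so that
every estimator in the package can be exercised and validated end to end.

## The tissue simulator and its calibration

`sim_tissue_params()` / `tissue_preset()` encode the study conditions:

| quantity | healthy | infarct border |
|---|---|---|
| Cre-recombination efficiency | 0.466 | 0.466 |
| colour probabilities (YFP/RFP/nGFP/mCFP) | 0.519/0.257/0.113/0.118 | 0.529/0.188/0.265/0.088 |
| founder events per 100 um section | 72.3 | 67.3 |
| clone size, mean (SD), cells | 4.0 (2.1) | 10.3 (10.6) |
| labelled cells present as single cells | 54.6% | 63.4% |
| EdU+ among labelled cells | 28.5% | 58.5% |
| polychromatic fraction of classified vessels | 25.5% | 9.3% |

The printed colour fractions sum to 100.7% (healthy) and 107% (MI); the
presets store the normalized vectors.

Three internal calibrations deserve explanation.

**Per-founder versus per-cell singletons.** The published "single cell"
fractions are fractions of labelled *cells*. A founder that divides yields on
average `mu` cells (the clone-size mean), while an undivided founder yields
one, so the per-founder non-division probability is derived as
`s_f = sigma*mu/(1 - sigma + sigma*mu)` from the per-cell target `sigma`
(healthy: 0.828; MI: 0.947). The clone-size law for dividing founders is
`S = 2 + X` with `X` negative-binomial, moment-matched to the target mean and
SD; the negative binomial accommodates the strongly over-dispersed border
zone (SD larger than the mean), and collapses to a Poisson if a
non-over-dispersed target is requested.

**EdU marking.** EdU administered one hour before tissue collection marks
cells in S phase at the endpoint, which is not conditional on a division
having completed within the chase window (a cell may be in S phase of its
first division). EdU status is therefore assigned per labelled cell at the
group's Confetti+EdU+ rate, not only among clone members — under the border
zone's parameters a clone-member-only rule could not reach the observed 58.5%
at all. Unlabelled cells carry a background S-phase rate; note that the
published total-cell EdU rates (0.09%/1.9%) refer to *all* cardiac cells,
most of which are non-endothelial and outside the simulation, so
`edu_total_fraction` on a simulated map is not comparable to them.

**Vessel clonality.** Per-cell Bernoulli labelling at efficiency 0.466 cannot
simultaneously reproduce ~72 founder events per section and a 25.5%
polychromatic vessel fraction in any homogeneous geometry — the published
constants come from different measurement modalities (flow cytometry versus
imaging of selected fields). The simulator therefore seeds a configured
fraction of founder events as *pairs* sharing a vessel; the pair rate is
derived in closed form from the polychromatic target, the colour-collision
probability `1 - sum(p_c^2)` and the derived division probability, so that
the expected polychromatic fraction among classifiable vessels (those with
at least two labelled cells) equals the target. Unlabelled eligible cells are
interspersed at `round(F*(1/eps - 1))` per section so that founder events
divided by eligible cells recovers the recombination efficiency through the
analysis path.

**Geometry.** Vessels are laid out as parallel two-lane strips (an axis lane
plus a lateral spill lane) on a 3D integer lattice, spaced at least two
lattice steps apart; sections are non-overlapping z-slabs. Adjacency is the
6-connected lattice neighbourhood, the simplest 3D contiguity notion
consistent with "adjacent cells", and it makes the brute-force flood-fill
oracle exact. Clones grow as connected patches by uniformly sampling frontier
sites within their strip, which produces the elongated patches seen along
vessels without modelling angiogenic geometry. With `merger_regime = "off"`,
founder territories are separated by gaps of at least three columns, so
ground-truth founders and monochromatic connected components correspond
one-to-one — the basis of the founder-conservation tests. With
`merger_regime = "on"`, paired founders are planted at adjacent sites, so
same-colour pairs fuse into one apparent clone; this is the generative model
behind the merger power analysis. Oversized requests (too many vessels for
the slab, or a clone that cannot fit along its vessel) raise explicit
capacity errors rather than silently truncating, since truncation would bias
clone-size statistics.

```{r}
params <- tissue_preset("healthy")
tissue <- simulate_tissue(params, sections = 5, seed = 1)
stats <- clonal_stats(call_clones(tissue), tissue)
stats
```

## Clone calling and the merger question

`call_clones()` partitions labelled cells into maximal connected
monochromatic components (clones at size >= 2, retained singletons below);
it is verified against an independent flood-fill oracle on random lattices.
Singletons are excluded from clone-size statistics but counted in founder
events and in the singleton fraction. Vessels are classified monoclonal or
polychromatic only when they carry at least `min_labelled = 2` labelled
cells — one labelled cell cannot exhibit polyclonality.

Could large patches instead arise from merger of independently labelled
neighbours that happen to share a colour? Two signatures distinguish the
hypotheses. Analytically, `k` independent adjacent founders share one colour
with probability `sum(p_c^k)` (`colour_collision_probability()`).
Statistically, under merger the *expected apparent clone size increases with
a colour's frequency* (common colours collide more often), whereas under
pure expansion clone size is independent of colour. `merger_test()` uses the
one-sided permutation trend test (Spearman association of clone size with
its colour's frequency, colour labels permuted over clones, add-one p-value)
as the primary test, and reports alongside it a permutation Kruskal-Wallis
test of clone size across colours — the direct analogue of asking whether
clone size differs between fluorophores. The trend test was chosen as
primary because it is directional for the merger alternative; combining the
two by taking the minimum would inflate the type-I error. The acceptance
suite verifies the nominal level (500 null replicates) and power above 0.8
when the most common colour gains 50% expected size at 200 clones.

Group contrasts (`compare_groups()`) treat sections as the sampling unit and
default to the Mann-Whitney test, with Welch and permutation options;
p-values are reported raw, without multiplicity correction, matching how the
source statistics are reported.

## The single-cell arm

`simulate_counts()` draws a sparse negative-binomial UMI matrix over ten EC
archetypes whose marker sets follow the published per-cluster markers
(homeostatic; interferon; cardiomyocyte-marker-bearing; killer-cell lectin
receptor; Notch; Plvap+/remodelling; stalk-cell — exclusive to the MI group;
extracellular matrix; serpin; proliferative). `Plvap` is planted in
archetypes 6–8 and `Bgn` is shared between 6 and 8, so marker-specificity
logic is exercised by construction. Beyond the discrete markers, each
archetype modulates a broad 400-gene "program" (log-normal multipliers,
sdlog 0.5) — real transcriptional states differ across hundreds of genes,
and with marker-only differences the observed complete group-exclusivity of
the stalk state could not survive clustering noise. Group depths follow the
published UMI scales (about 2.2k healthy, 5k MI); the NB size parameter is
2. The generator also plants a haematopoietic contaminant population
(Ptprc-high, endothelial genes near zero), rare Ptprc+Pecam1+ double
positives in the MI group (0.29% of cells), per-cell mitochondrial fractions
with a tail beyond 20%, and a low-depth cell fraction falling under the
400-gene threshold.

The pipeline follows standard practice:

* `qc_filter()` removes cells with fewer than 400 detected genes or a
  mitochondrial fraction above 20%. Both bounds are strict as documented:
  a 400-gene or exactly-20% cell is retained; the spelled-out "<400" fixes
  the gene rule and the mitochondrial rule is chosen symmetric.
  Mitochondrial genes are identified by prefix (`"mt-"`, mouse nomenclature)
  or an explicit list; if none are identifiable the filter is skipped with a
  warning and flagged in the QC report.
* `embed_and_cluster()` normalizes to the median depth with `log1p`,
  selects highly variable genes by binned dispersion (variance/mean of
  depth-normalized counts, z-scored within 20 mean bins — plain
  log-variance ranking favours abundant noisy genes), computes a PCA
  (30 components by default; set `n_hvg = Inf` for the whole transcriptome),
  builds a shared-nearest-neighbour graph (k = 15, Jaccard weights, pruned
  at 1/15) and partitions it with Leiden community detection under the
  modularity objective. The published analysis names no clustering
  algorithm; graph clustering in PCA space with a display-only 3D t-SNE is
  the deterministic, standard choice, and a `n_clusters_hint` performs a
  bisection on the resolution when a target cluster count is known. The
  default resolution (0.5) leaves a homogeneous population in a single
  cluster. All stages are seeded.
* `remove_contaminant_cluster()` flags clusters with mean Ptprc above the
  global upper decile and mean Pecam1 and Kdr below the global lower
  quartiles, removes them, and reports the double-positive fraction among
  retained cells.
* `cluster_markers()` runs one-vs-rest Wilcoxon rank-sum tests (normal
  approximation with tie correction) per gene per cluster with
  Benjamini-Hochberg adjustment within cluster, and flags genes that are a
  significant marker of exactly one cluster as specific.
* `composition_test()` tests each cluster's group mix against the global
  ratio with an exact binomial test conditioned on cluster size (the
  simplest exact choice absent a replicate-aware model), and flags clusters
  composed exclusively of one group.
* `gene_query()` summarizes one gene per cluster and group — e.g. `Plvap`,
  which under the shipped archetypes tops the MI-enriched clusters.

## Signature scoring and the unit of inference

`score_signature()` computes the standard module score: mean log-normalized
expression of the panel minus the mean of control genes drawn from matched
average-expression bins (25 bins, 50 controls per panel gene). The shipped
EndMT panel is a *reconstruction*: the named EndMT genes (Icam1, Vcam1, Vim,
Fn1, Smtn) plus canonical early transcription factors and late mesenchymal
markers; the original supplementary panel is not redistributed.

Group inference on the score is performed on replicate (animal) means with a
Welch t-test whenever replicate labels exist, while the per-gene breakdown
uses cell-level rank-sum tests. This split is deliberate. Cells from one
animal are not independent; testing an aggregate score across thousands of
cells treats them as if they were and declares biologically trivial shifts
significant, because averaging a panel shrinks noise at least as fast as it
concentrates signal. Animals are the exchangeable unit for a group-level
claim. With per-animal variability in the EndMT program (log-normal,
sdlog 0.4 in the generator — without real animal-to-animal variation of
this order, any marker-level change would drag the aggregate score to
significance at n = 7 animals), the package reproduces the reported
dissociation: individually elevated markers with an unchanged overall
signature.

## What the synthetic data do and do not establish

The generator reproduces the statistical structure the estimators assume:
biased colour assignment, contiguous monochromatic patches with known
founders, vessel-segment membership, NB counts with archetype structure,
QC-relevant artefacts. It does not emulate optical-section truncation of
clones at slab boundaries (flagged as a non-goal; no correction is applied),
image segmentation errors, doublets, ambient RNA, batch effects between
animals beyond the scalar program effect, or spatial transcriptional
gradients. Passing tests therefore validate the *estimators and their
calibration*, not the biological claims on real tissue; on real data the
clone caller additionally supports a metric-distance adjacency for imported
segmentations, and sections clipped by imaging should be interpreted with
the truncation caveat in mind.

Problem sizes used throughout the test-suite and the acceptance script —
30 sections x 10 seeds per preset for the lineage arm, about 3,000 cells and
2,000 genes for the single-cell arm, 500 null replicates for the merger
calibration — were chosen as the smallest sizes at which the Monte-Carlo
error of every checked statistic is comfortably below its acceptance band.

## Reproducing the numbers

```r
# full chained run with a report
run_pipeline(list(seed = 1, out_dir = "out"))

# the published-statistics sweep
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
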