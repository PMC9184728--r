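# cohesintools

Cohesin, the ring-shaped complex that holds sister chromatids together, also
anchors chromatin loops and regulates transcription. When cells are given a
transcriptional stimulus (e.g. estradiol in MCF-7 cells), a subset of cohesin
peaks *inside gene bodies* loses intensity specifically within the genes that
respond — these are **decreased intragenic cohesin sites (DICs)**. DICs split
into two behaviours: **LC-DICs** (low co-bound CTCF, enhancer-like, marked by
H3K27ac/P300/Med1) and **HC-DICs** (high CTCF, architecture-like, tied to
loops and domain boundaries).

`cohesintools` implements the full quantitative workflow for finding and
characterizing DICs from two-condition ChIP-seq, Hi-C and annotation data:

* **diffpeaks** — MA-based differential binding. For peak densities
  `c1, c2`, `A = (log2 c1 + log2 c2)/2` and `M_raw = log2(c2/c1)`; a robust
  (Theil–Sen) fit of `M_raw = a + b·A` on matched common peaks is subtracted
  to give the normalized `M`. Peaks change class by `M > 0.5` (increased) or
  `M < −0.5` (decreased).
* **sitecalls** — the DIC cascade: intragenic regions (gene body minus 10-kb
  TSS/TES flanks, genes > 20 kb only), responsive genes (elongation-signal
  ratio > 1.2 validated by expression), DIC = decreased ∧ intragenic ∧
  responsive host ∧ width ≤ 3 kb; LC/HC split by two-component clustering of
  log CTCF density; metaprofiles and cross-sample presence/absence.
* **hicmetrics** — contact-map balancing, distal-to-local ratio
  `DLR = log2(distal/local)` and its condition delta (positive ΔDLR =
  de-compaction), inter-chromosomal fraction `ICF = inter/(inter+intra)`,
  insulation score `IS = log2(observed square / distance-expected)` with
  boundary calling, and aggregate peak analysis (APA) with a paired-t
  condition comparison.
* **loopstats** — loop-occurrence probabilities per site category with
  Fisher exact comparisons, distal-anchor annotation
  (promoter > enhancer > gene body > intergenic), Mann–Whitney U (exact
  permutation for small samples), paired t, hypergeometric overlap,
  Benjamini–Hochberg adjustment.
* **mlfeat** — sites × features matrices (0/1 co-localization + z-scored
  signals), k-means clustering, SMOTE over-sampling, logistic classification
  `P(Y=1|X) = 1/(1+exp(−(β0+Σβj Xij)))` with chromosome-held-out evaluation
  and signed-coefficient importance, elastic-net feature selection
  (`RSS/(2n) + λ[(1−α)/2‖β‖² + α‖β‖₁]`, α = 0.5, λ by cross-validation) with
  univariate follow-up, and cross-cell-type DIC prediction scored by a
  hypergeometric overlap test.
* **synthio** — a synthetic-scene generator (genome, two-condition
  negative-binomial peak counts with planted DICs, bimodal CTCF mixture,
  class-dependent TF co-binding, expression/elongation summaries,
  distance-decay contact maps with planted loops, boundaries and
  de-compaction) that emits planted ground truth so every stage is testable
  without external sequencing data.

## Worked example

```r
library(cohesintools)

scene <- simulate_scene(sim_params(seed = 1))   # 2 x 20 Mb, ~3,000 sites

peaks     <- diff_peaks(scene$sites)                 # MA normalization
regions   <- derive_intragenic_regions(scene$genes)  # 10-kb flanks, >20-kb genes
locations <- classify_site_location(scene$sites, scene$genes, regions)
resp      <- call_responsive_genes(scene$elongation, scene$expression)
dics      <- extract_dics(peaks, locations, resp)

table(peaks$change)
#> increased decreased unchanged
#>         5       112      2883
sum(resp$responsive)   #> 90 responsive genes
sum(dics$is_dic)       #> 101 DICs called (100 planted)

cof <- scene$cofactors[match(dics$name[dics$is_dic], scene$cofactors$name), ]
table(split_lc_hc(cof$name, cof$ctcf_density, cof$rad21_density)$subtype)
#>  LC  HC none
#>  75  26    0

run_apa(scene$hic$map_a, scene$hic$loops, radius = 5)$score
#> 4.25   (loop pixels ~4x enriched over the local background)
compare_apa(scene$hic$map_a, scene$hic$map_b,
            scene$hic$loops[scene$hic$loops$at_dic, ], radius = 5)
#> t = -6.05, p = 2.1e-07  (DIC-anchored loops are lost in condition B)
```

Of the 112 decreased peaks, 101 satisfy every DIC predicate; against the 100
planted DICs that is sensitivity 1.00 and precision 0.99. The LC/HC split
recovers the planted CTCF mixture exactly on this scene, and APA shows the
planted loop enrichment in condition A together with its loss at DIC anchors
in condition B.

`run_pipeline(list(seed = 1, output_dir = "out"))` runs the whole chain
(simulate → diffpeaks → classify → extract-dics → LC/HC → Hi-C metrics →
loops → features → train) and writes a DIC BED, responsive-gene TSV, feature
matrix and a manifest with per-stage checksums; identical config + seed give
byte-identical outputs.

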