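# lysoseq

Quantitative analysis of lysosomal RNA degradation. Cells deliver
specific RNAs — 7SL/SRP RNA, Y RNAs, 5' TOP mRNAs, membrane- and
secretory-protein mRNAs, certain tRNAs — into lysosomes via autophagy,
where lysosomal ribonucleases destroy them. Measuring this flux takes
two experiments, and `lysoseq` implements the analysis for both:

* **LysoIP fractionation RNA-seq.** Intact lysosomes are
  immunopurified alongside whole-cell samples; ERCC/SIRV spike-ins put
  both on an absolute scale. The package performs fractional
  multimapping read counting (a read mapping to N loci contributes
  1/N), sequential-reference deduplication (keep the first instance),
  RPK length normalization, spike-in filtering (10+ reads in ≥75% of
  samples) and per-sample standard-curve regression, and
  capture-efficiency correction, yielding the per-gene **lysosomal
  enrichment**

  `E = mean(normalized lyso reps) / mean(normalized whole-cell reps)`

  and, between genotypes, the **dependence ratio** `D = E_ko /
  E_control` (D < 1: the gene needs that factor for lysosomal entry).

* **5EU pulse-chase RNA-seq.** Nascent RNA is metabolically labeled,
  chased, and sampled at 0, 1, 2, 4, 8 and 28 h. Per gene and
  replicate the package fits the background-corrected exponential

  `y = log2(C·e^(−kx)) + z`,  C, k ∈ [0, ∞)

  by bounded Levenberg–Marquardt least squares (starting values
  `2^max(y)` and 1; `z` from mock-IP samples with a 5·10⁻⁶ floor;
  for Torin1-treated series C is fixed to the untreated replicate's
  estimate). Fits with Wald `Pr(>|t|) < 0.05` for k (and C, when
  free) are kept; half-life is `ln(2)/k` capped at 50 h; synthesis is
  `S = C·k`; replicate half-lives are averaged. Across the four
  conditions WT/KO × ±Torin1 the **autophagy-dependent Torin1-induced
  stability value** is

  `A = (t½_WT,Torin / t½_WT) / (t½_KO,Torin / t½_KO)`

  with A < 1 meaning autophagy destabilizes the RNA upon mTORC1
  inhibition.

A seeded synthetic-data generator emulates both designs with known
ground truth (class-structured enrichments, negative-binomial counts,
spike-ins linear in concentration, single-exponential decay with a
background plateau and mock-IP samples), so the whole pipeline is
validated by parameter recovery — no external data needed.

## Worked example

```r
library(lysoseq)

cfg    <- simConfig(n_genes = 2000, seed = 1)
truth  <- simulateTranscriptome(cfg)
design <- simDesign(cfg, genotypes = "WT", treatments = "none")
sim    <- simulateFractionCounts(truth, design, cfg)

lx <- spikeinNormalize(sim$counts, sim$spikes, assay = "counts")
E  <- lysosomalEnrichment(lx, "WT", "none")
classSummary(E, truth, grouping = "class")
```

```
            group   n median    q25    q75
6         SRP_RNA  20 25.594 21.325 34.838
10          Y_RNA  40 12.814  8.023 16.300
7        TOP_mRNA 100  8.691  6.243 12.032
2   membrane_mRNA 200  4.570  3.017  6.350
4  secretory_mRNA 160  4.427  2.920  6.578
8            tRNA 300  3.003  2.196  4.282
9       vault_RNA  20  1.670  1.301  2.137
1       bulk_mRNA 900  1.041  0.725  1.474
3        mito_RNA 100  0.503  0.402  0.694
5           snRNA 160  0.219  0.148  0.282
```

Each row is one RNA class: `n` genes, median and quartiles of the
estimated lysosomal enrichment. SRP/7SL RNA comes out most enriched
(~26-fold over whole cell), Y RNAs and 5' TOP mRNAs next, nuclear
snRNAs depleted — the medians recover the generator's true class
multipliers (30, 12, 8, … 0.2), and per gene
`spearmanRho(E, truth$E_true)` is 0.95 here.

Half-lives and stability from a pulse-chase simulation:

```r
pc <- simulatePulseChase(truth[1:300, ], cfg)
dk <- fitDecayTable(pc$timecourse, pc$mock,
                    background_mode = "linear_plateau")
st <- stabilityTable(dk$halflives)
head(st[is.finite(st$stability), ], 3)
```

```
  gene_id halflife_wt halflife_wt_torin halflife_ko halflife_ko_torin stability
1  G00001       0.849             0.849       0.845             0.846     0.999
2  G00002       0.839             0.838       0.844             0.846     0.996
3  G00003      11.892            12.137      11.784            12.216     0.985
```

Four averaged half-lives (hours) per gene and the stability value A;
with no simulated Torin1 effect the median A is 1, as it should be.

`runPipeline(pipelineConfig(...))` chains
simulate → quantify → normalize → enrich → decay → stability and
writes TSVs plus a `report.yaml` of effective parameters and
filter-survival counts; `inst/scripts/lysoseq-cli.R` exposes the same
stages as shell subcommands.

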