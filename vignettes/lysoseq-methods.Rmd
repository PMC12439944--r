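---
title: "lysoseq: models and methods"
author: "lysoseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lysoseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lysoseq` quantifies lysosomal RNA degradation from two experimental
designs:

1. **LysoIP fractionation**: RNA-seq of immunopurified lysosomes and
   matched whole-cell samples, with ERCC/SIRV spike-ins, yielding a
   per-gene *lysosomal enrichment* score `E` and, between genotypes, a
   *dependence ratio* `D`.
2. **5EU pulse-chase**: metabolic labeling followed by a chase time
   course, yielding per-gene decay rates, capped half-lives, synthesis
   rates, and the *autophagy-dependent Torin1-induced stability value*
   `A`.

Everything downstream of read-to-feature assignment is implemented
here; alignment itself is out of scope and enters through a plain
assignment table (`read_id`, `sample_id`, `feature_id`, `n_locations`,
`reference_tier`).

# Quantification

Reads are assigned against a cascade of references (rRNA, tRNA,
mitochondrial, abundant ncRNA, whole transcriptome); a read belongs to
the first reference it maps to. Within a reference, a read mapping to
`N` loci contributes `1/N` to each (`fractionalCount()`), so per-sample
fractional counts sum exactly to the number of reads — an invariant the
tests assert to 1e-9. Genes annotated in several references keep only
their earliest row (`mergeSequentialReferences()`, "keep first"), and
counts are length-normalized to RPK (`count / (length_nt/1000)`)
for the fractionation libraries. The pulse-chase libraries are *not*
length-normalized (`rpkNormalize(skip = TRUE)`), since only
within-gene changes over time matter there.

# Spike-in normalization

Spike-ins are filtered to those with at least 10 reads in at least 75%
of samples (`filterSpikeins()`; the fraction generalizes an
18-of-24 / 16-of-16 design rule). Per sample, an ordinary
least-squares regression of spike signal on known concentration
(`fitSpikeSlope()`) gives a slope — signal per unit concentration, in
effect the sample's sequencing depth on an absolute scale. The
regression includes an intercept so additive background cannot bias the
slope; only the slope is used. Every value is then divided by the
sample's slope and multiplied by its capture factor `f_s`
(`normalizeSample()`), which corrects lysosome recovery efficiency
(measured experimentally, e.g. by LAMP2 immunoblot) and input
dilution. Two design notes:

* The regression is run on the same scale the division is applied to
  (RPK when RPK mode is on, raw counts otherwise); whether reads or
  RPK are regressed is configurable because the field uses both.
* Zeros propagate as zeros; no pseudocounts anywhere.

# Enrichment and stratification

`E = mean(normalized lyso replicates) / mean(normalized whole-cell
replicates)` (`lysosomalEnrichment()`); genes with a zero whole-cell
mean are flagged undefined rather than pseudocounted, because a
pseudocount would fabricate enrichment for lysosome-only detections.
Replicates are averaged *before* the ratio (mean-of-values, not
mean-of-ratios). The knockout dependence ratio is
`D = E_ko / E_control` (`dependenceRatio()`); `D < 1` means the gene
needs the knocked-out factor to reach the lysosome.

`classSummary()` reports n, median and quartiles per RNA class,
protein-localization class, or TOPscore bin (default bin edges keep
3.0 as a boundary, the conventional threshold for a strong 5' TOP
motif). tRNA loci with identical mature sequences are summed before
analysis (`collapseIdenticalTrnas()`), since sequencing cannot
distinguish them; the retained id is the lexicographically first
member. Rank correlations (e.g. tRNA enrichment versus the
Kyte-Doolittle hydropathicity of the carried amino acid) use
`spearmanRho()`, Pearson correlation of average ranks with mean-rank
ties. Reporter RT-qPCR is summarized by `deltaDeltaCt()`
(`2^-ddCT` with an internal control such as 18S rRNA).

# The decay model

Each pulse-chase series (one gene, genotype, treatment, replicate) is
normalized to the nLuc spike of its sample (`nlucNormalize()`) and then
to its own time-0 value (`t0Normalize()`), so every series starts at 1.
The fit is

`y = log2(C * exp(-k * x)) + z`

with `y` the log2 normalized signal, `x` the chase time (h), `C > 0`
the initial level, `k >= 0` the decay rate (per h), and `z` a fixed
per-gene background term. `backgroundZ()` computes
`z = max(max(4 mock-IP values), 5e-6) / t0 spike-normalized reads`;
the phrasing of that rule admits a second parse (only the floor
divided), available via `reading = "divide_floor_only"` — both are
implemented, neither is asserted as the uniquely correct reading.

Two background placements are supported:

* `background_mode = "log_offset"` (default): `z` added in log2 space,
  the formula exactly as printed above. Note an additive log2 term is
  a multiplicative factor `2^z`, not a plateau.
* `background_mode = "linear_plateau"`:
  `y = log2(C * exp(-k*x) + z)`, background as a linear-scale floor —
  the physically motivated form when the assay has a pulldown
  background, and the form matched to this package's generator, whose
  mock-IP background is a linear plateau. Truth-recovery tests
  therefore pair the generator with this mode; the log-offset form is
  validated on plateau-free data. On real data, choose by whether the
  series level off at a floor.

Fitting is bounded Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`), `C, k` in `[0, Inf)`, starting values
`C = 2^max(y)`, `k = 1`. The formulas are written as
`(log(C) - k*x)/log(2) + z` so the Jacobian is analytic; if the
standard start fails, one deterministic fallback start (`k` from the
OLS log-linear slope, floored at 1e-3) is tried — no random restarts.
Convergence tolerances are 1e-10 on cost and parameters. Standard
errors and two-sided Wald `Pr(>|t|)` come from the asymptotic
covariance with `n - n_free` residual degrees of freedom; a `k`
estimate at the 0 boundary gets `p_k = 1`, because a boundary estimate
is not evidence of decay. Fits are kept when `p_k < 0.05` and
(unless C was fixed) `p_C < 0.05` (`filterFits()`).

Half-life is `min(ln(2)/k, 50 h)` (`halfLife()`); the 50 h ceiling
reflects the longest chase point (28 h) — slower decay is not
measurable on this design. The synthesis rate is `S = C * k`.
Half-lives are fit per replicate and then averaged
(`averageReplicates()`), not pooled.

## Fixed C for treated series

For Torin1-treated series, `C` is fixed to the untreated replicate's
fitted value (`c_fixed`), because the initial level predates the
treatment: the t0 sample is collected before Torin1 is added, and the
generator accordingly shares one t0 observation between the two arms
of a replicate. The returned `C` is bit-exactly the supplied value.

A caution worth recording: on t0-normalized series the two schemes are
statistically equivalent. In the log-linear model, fixing the
intercept at an equally noisy independent estimate gives exactly the
same slope variance as estimating it freely (the algebra reduces
`1/Q + m/(QS)` to `1/S` with `Q = sum(x^2)`, `S = Sxx`,
`m = n*mean(x)^2`). The benefit of sharing C is real precisely where
the model is nonlinear: when accelerated decay pushes a treated
series' late points onto the background plateau, that series alone
determines `C` poorly, and the untreated arm's estimate rescues the
rate. The tests exercise exactly that regime.

## The stability value

`A = (t1/2_WT,Torin / t1/2_WT) / (t1/2_KO,Torin / t1/2_KO)`
(`stabilityMetric()`): normalizing within genotype removes clonal
baseline differences, comparing across genotypes isolates autophagy
from other mTORC1 effects. `A < 1` means autophagy destabilizes the
RNA after mTORC1 inhibition. `A` is undefined unless all four
half-lives exist; swapping the WT and KO pairs maps `A` to `1/A`.

# The synthetic-data generator

The generator exists so every stage can be validated by parameter
recovery. It emulates:

* a transcriptome of 10 RNA classes (bulk/TOP/membrane/secretory
  mRNAs, tRNA, Y RNA, SRP/7SL, vault, snRNA, mitochondrial) with
  largest-remainder class allocation (ties by class name) and
  lognormal abundances (sdlog 1.2);
* true enrichments `E_true = baseline x class multiplier x lognormal
  jitter`. Default multipliers (SRP 30, Y 12, TOP 8,
  membrane/secretory 4, tRNA 3, vault 1.5, bulk 1, mito 0.5,
  snRNA 0.2) reproduce the observed ordering of lysosomal RNA types;
  jitter sd 0.4 gives the within-class spread a realistic order of
  magnitude;
* fraction counts from the physical model *tube content =
  abundance x enrichment / f_s*, a per-sample depth factor setting the
  mean gene count, and one global spike amount per spike (equal
  across samples, as spikes are added), scaled so spike reads sit at
  ~0.05% of a typical sample and within the 0.01-0.2% window across
  samples. Gene counts are negative binomial (dispersion 0.1,
  biological overdispersion); spike reads are Poisson, since spikes
  are pipetted aliquots of one stock with technical noise only;
* pulse-chase signal `R_g * (exp(-k_eff * x) + background_fraction)`
  at 0/1/2/4/8/28 h, with true half-lives log-uniform in 0.5-30 h,
  multiplicative lognormal noise (0.1 log2 units), per-genotype Torin1
  multipliers on `k`, an nLuc spike row per sample, 4 mock-IP
  background samples, and a single shared t0 observation per
  genotype/replicate (treatment starts at t0).

Determinism: one seed; the three stages draw from `seed`, `seed + 1`,
`seed + 2` in documented order, so each stage is reproducible alone
and a fixed seed reproduces byte-identical outputs.

What the generator does *not* emulate — and hence what passing
recovery tests cannot show about real data: GC/positional coverage
bias, UMI structure, mitochondrial contamination of purified
lysosomes, multi-exponential decay (real 7SL and rRNA kinetics are
excluded from half-life analysis for this reason), 5EU incorporation
lag, and library-size variation beyond the depth factor. The
dispersion and depth defaults are chosen for testability; the study
does not report them.

# Problem sizes and numerical choices

The validation suite runs recovery at 2,000 genes for enrichment
(balanced classes, multipliers 0.2-30, NB dispersion 0.1, whole-cell
mean 5,000 counts) and 500 genes x 2 replicates for decay; the
optimizer is cross-checked against a 400 x 400 log-spaced grid search
on random noisy series. Desk-scale caveat: per-sample spike
standard curves need enough depth that several spikes clear the
10-read filter; at a few hundred genes use `wc_mean_counts >= 5000`
or expect `fitSpikeSlope()` to refuse degenerate curves (it errors on
nonpositive slopes rather than normalizing with a meaningless one).

Degenerate inputs are handled explicitly: empty gene sets only at
`n_genes = 0`; series with zero t0 are excluded and listed; flat
series converge to `k = 0` with `p_k = 1` and the capped half-life;
underdetermined series (2 points, 2 free parameters) return
`converged = FALSE` and are dropped by the filter.

# Limitations

* The enrichment score inherits any inaccuracy in the supplied capture
  factors; they are inputs, not estimated.
* The log-offset background form is implemented as printed, but a
  log2-additive constant cannot model a plateau; for plateau-shaped
  data use `linear_plateau`.
* No correction for mitochondrial contamination of lysosomal fractions
  is attempted (none is described for the assay).
* TOPscore is an input annotation; the package does not derive it from
  5' end sequencing.
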