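test_that("enrichment is the ratio of replicate-averaged fractions", {
  ly <- matrix(c(4, 6), 1, 2, dimnames = list("g1", c("l1", "l2")))
  wc <- matrix(c(2, 3), 1, 2, dimnames = list("g1", c("w1", "w2")))
  expect_equal(unname(lysosomalEnrichment(ly, wc)), 2)

  m <- matrix(runif(12, 1, 10), 4, 3,
              dimnames = list(sprintf("g%d", 1:4), NULL))
  expect_equal(unname(lysosomalEnrichment(m, m)), rep(1, 4))

  wc0 <- wc; wc0[1, ] <- 0
  expect_true(is.na(lysosomalEnrichment(ly, wc0)))

  ly2 <- ly; rownames(ly2) <- "other"
  expect_error(lysosomalEnrichment(ly2, wc), "mismatched gene sets")
})

test_that("enrichment is scale-invariant and monotone in true enrichment", {
  cfg <- simConfig(n_genes = 60, seed = 12)
  truth <- simulateTranscriptome(cfg)
  des <- simDesign(cfg, genotypes = "WT", treatments = "none")
  fr <- simulateFractionCounts(truth, des, cfg, noise = FALSE)
  lx <- spikeinNormalize(fr$counts, fr$spikes, assay = "counts",
                         min_reads = 0, min_sample_fraction = 1)
  E1 <- lysosomalEnrichment(lx, "WT", "none")

  # common rescaling of every sample leaves E untouched
  lx2 <- lx
  SummarizedExperiment::assay(lx2, "normalized") <-
    SummarizedExperiment::assay(lx, "normalized") * 7.3
  expect_equal(lysosomalEnrichment(lx2, "WT", "none"), E1)

  # raising one gene's true enrichment never lowers its estimate
  truth_up <- truth
  truth_up$E_true[5] <- truth$E_true[5] * 3
  fr_up <- simulateFractionCounts(truth_up, des, cfg, noise = FALSE)
  lx_up <- spikeinNormalize(fr_up$counts, fr_up$spikes, assay = "counts",
                            min_reads = 0, min_sample_fraction = 1)
  E_up <- lysosomalEnrichment(lx_up, "WT", "none")
  expect_gte(E_up[[truth$gene_id[5]]], E1[[truth$gene_id[5]]])
})

test_that("dependence ratio behaves as a per-gene fold change", {
  e <- setNames(c(2, 5, 0.4), c("a", "b", "c"))
  expect_equal(unname(dependenceRatio(e, e)), rep(1, 3))
  expect_equal(unname(dependenceRatio(e / 2, e)), rep(0.5, 3))
  e0 <- e; e0["b"] <- 0
  expect_true(is.na(dependenceRatio(e, e0)["b"]))
  expect_error(dependenceRatio(e, e[1:2]), "gene set|equal length")
})

test_that("a knockout that blocks lysosomal flux shows up as D near the flux drop", {
  # autophagy-dependent class: lyso delivery cut to 20% in the KO
  cfg <- simConfig(n_genes = 300, wc_mean_counts = 5000, seed = 21)
  truth <- simulateTranscriptome(cfg)
  des <- simDesign(cfg, genotypes = c("CTRL", "KO"),
                   treatments = "none")
  truth_ko <- truth; truth_ko$E_true <- truth$E_true * 0.2
  # simulate the two genotypes from their own truths, same design rows
  frC <- simulateFractionCounts(truth, des[des$genotype == "CTRL", ],
                                cfg)
  cfg2 <- simConfig(n_genes = 300, wc_mean_counts = 5000, seed = 22)
  frK <- simulateFractionCounts(truth_ko, des[des$genotype == "KO", ],
                                cfg2)
  lxC <- spikeinNormalize(frC$counts, frC$spikes, assay = "counts")
  lxK <- spikeinNormalize(frK$counts, frK$spikes, assay = "counts")
  D <- dependenceRatio(lysosomalEnrichment(lxK, "KO", "none"),
                       lysosomalEnrichment(lxC, "CTRL", "none"))
  expect_lt(abs(median(D, na.rm = TRUE) - 0.2) / 0.2, 0.15)
})

test_that("class summaries match brute-force per-group statistics", {
  set.seed(3)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    class = sample(c("tRNA", "Y_RNA", "snRNA"), 40,
                                   replace = TRUE),
                    topscore = runif(40, 0, 8),
                    stringsAsFactors = FALSE)
  v <- setNames(rlnorm(40), ann$gene_id)
  sm <- classSummary(v, ann, grouping = "class")
  for (cl in unique(ann$class)) {
    vals <- sort(v[ann$class == cl])           # brute force sort-and-pick
    n <- length(vals)
    med <- if (n %% 2 == 1) vals[(n + 1) / 2]
           else mean(vals[n / 2 + 0:1])
    expect_equal(sm$median[sm$group == cl], unname(med))
    expect_equal(sm$n[sm$group == cl], n)
  }

  # one group: summary equals the overall summary
  ann1 <- ann; ann1$class <- "all"
  sm1 <- classSummary(v, ann1, grouping = "class")
  expect_equal(sm1$median, unname(median(v)))

  # a TOPscore boundary at 3.0 splits genes exactly as direct comparison
  smT <- classSummary(v, ann, grouping = "topscore_bin",
                      topscore_edges = c(-Inf, 3, Inf))
  expect_equal(sort(smT$n), sort(unname(c(sum(ann$topscore <= 3),
                                          sum(ann$topscore > 3)))))
  expect_equal(sum(smT$n), 40)
})

test_that("identical tRNA sequences collapse with exact count conservation", {
  cnt <- data.frame(gene_id = c("tB", "tA", "tC"), biotype = "tRNA",
                    length_nt = 76, s1 = c(5, 3, 11),
                    stringsAsFactors = FALSE)
  seqs <- data.frame(gene_id = c("tA", "tB", "tC"),
                     sequence = c("ACGU", "ACGU", "GGGG"),
                     stringsAsFactors = FALSE)
  out <- collapseIdenticalTrnas(cnt, seqs)
  expect_equal(nrow(out), 2)
  expect_equal(out$s1[out$gene_id == "tA"], 8)   # 3 + 5, id = first
  expect_equal(out$members[out$gene_id == "tA"], "tA,tB")
  expect_equal(sum(out$s1), sum(cnt$s1))

  # all-unique sequences: identity up to the members column
  sequ <- data.frame(gene_id = cnt$gene_id,
                     sequence = c("AA", "CC", "GG"),
                     stringsAsFactors = FALSE)
  ident <- collapseIdenticalTrnas(cnt, sequ)
  expect_setequal(ident$gene_id, cnt$gene_id)
  expect_equal(ident$s1[match(cnt$gene_id, ident$gene_id)], cnt$s1)

  # missing sequence: warn, pass through
  expect_warning(collapseIdenticalTrnas(cnt, seqs[1:2, ]),
                 "no sequence")
})

test_that("Spearman correlation handles monotone, antitone and tied data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearmanRho(x, x^3), 1)
  expect_equal(spearmanRho(x, -x), -1)
  expect_warning(r <- spearmanRho(x, rep(2, 5)), "constant")
  expect_true(is.na(r))
  expect_error(spearmanRho(1:2, 2:1), ">=3")
})

test_that("collapsed tRNA enrichment vs hydropathicity uses consistent ranks", {
  # tie-heavy vectors against the brute-force average-rank oracle
  for (seed in 1:30) {
    set.seed(seed)
    x <- sample(1:5, 20, replace = TRUE)
    y <- sample(1:5, 20, replace = TRUE) + 0.1 * x
    expect_equal(spearmanRho(x, y), spearmanOracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("delta-delta-CT gives the expected fold changes", {
  expect_equal(deltaDeltaCt(20, 10, 25, 15), 1)      # ddCT = 0
  expect_equal(deltaDeltaCt(18, 10, 25, 15), 4)      # ddCT = -2
  for (seed in 1:20) {
    set.seed(seed)
    ct <- runif(4, 10, 30)
    expect_equal(deltaDeltaCt(ct[1], ct[2], ct[3], ct[4]),
                 2^-((ct[1] - ct[2]) - (ct[3] - ct[4])))
  }
  expect_error(deltaDeltaCt(NA, 1, 1, 1), "finite")
})
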