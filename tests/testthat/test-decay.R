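test_that("nLuc normalization divides each sample by its spike count", {
  tc <- expand.grid(gene_id = c("g1", "nLuc"), time_h = c(0, 2),
                    stringsAsFactors = FALSE)
  tc$genotype <- "WT"; tc$treatment <- "none"; tc$replicate <- 1L
  tc$count <- ifelse(tc$gene_id == "nLuc", 5, 10)
  out <- nlucNormalize(tc)
  expect_equal(out$count, c(2, 2))
  expect_false("nLuc" %in% out$gene_id)

  # nLuc of 1 everywhere: identity
  tc1 <- tc; tc1$count[tc1$gene_id == "nLuc"] <- 1
  expect_equal(nlucNormalize(tc1)$count, c(10, 10))

  # scaling one sample's raw column leaves its normalized values alone
  tc2 <- tc; sel <- tc2$time_h == 2
  tc2$count[sel] <- tc2$count[sel] * 11
  expect_equal(nlucNormalize(tc2)$count, out$count)

  tc$count[tc$gene_id == "nLuc" & tc$time_h == 0] <- 0
  expect_error(nlucNormalize(tc), "zero/invalid in sample")
})

test_that("t0 normalization starts every series at 1 and lists exclusions", {
  tc <- data.frame(gene_id = rep(c("g1", "g2"), each = 3),
                   genotype = "WT", treatment = "none", replicate = 1L,
                   time_h = rep(c(0, 1, 2), 2),
                   count = c(8, 4, 2, 0, 5, 5),
                   stringsAsFactors = FALSE)
  out <- t0Normalize(tc)
  expect_equal(out$count[out$gene_id == "g1"], c(1, 0.5, 0.25))
  # zero-t0 series excluded; matches a brute-force scan
  zero_t0 <- unique(tc$gene_id[tc$time_h == 0 & tc$count <= 0])
  expect_false(any(out$gene_id %in% zero_t0))
  expect_true(all(grepl(zero_t0, attr(out, "excluded"))))
  # constant series normalizes to all ones
  const <- tc[tc$gene_id == "g1", ]; const$count <- 7
  expect_equal(t0Normalize(const)$count, c(1, 1, 1))
})

test_that("background z follows the max/floor/divide rule", {
  expect_equal(backgroundZ(c(0, 0, 0, 0), t0_reads = 0.001), 0.005)
  expect_equal(backgroundZ(rep(0.01, 4), t0_reads = 1), 0.01)
  for (seed in 1:25) {
    set.seed(seed)
    mocks <- runif(4, 0, 1e-3); t0 <- runif(1, 1e-4, 10)
    expect_equal(backgroundZ(mocks, t0),
                 max(max(mocks), 5e-6) / t0)
    expect_equal(backgroundZ(mocks, t0, reading = "divide_floor_only"),
                 max(max(mocks), 5e-6 / t0))
  }
  expect_error(backgroundZ(c(0, 0, 0, 0), t0_reads = 0), "positive")
})

test_that("the decay fit recovers exact-model parameters", {
  t <- c(0, 1, 2, 4, 8, 28)
  f <- fitDecay(t, exp(-0.3 * t), z = 0)
  expect_lt(abs(f$C - 1), 1e-6)
  expect_lt(abs(f$k - 0.3) / 0.3, 1e-6)
  expect_true(f$converged)
  expect_equal(f$S, f$C * f$k)
  expect_equal(f$halflife, log(2) / f$k)

  # fixed C is returned bit-exactly, whatever the data say
  ff <- fitDecay(t, exp(-0.3 * t), z = 0, c_fixed = 0.87)
  expect_identical(ff$C, 0.87)
  expect_true(ff$c_was_fixed)
  expect_true(is.na(ff$p_C))

  # linear-plateau mode recovers data generated with a plateau
  z <- 0.01
  fp <- fitDecay(t, (exp(-0.5 * t) + z) / (1 + z), z = z / (1 + z),
                 background_mode = "linear_plateau")
  expect_lt(abs(fp$k - 0.5) / 0.5, 1e-3)
})

test_that("flat data hit the k = 0 boundary with p = 1 and capped half-life", {
  t <- c(0, 1, 2, 4, 8, 28)
  f <- fitDecay(t, rep(1, 6), z = 0)
  expect_equal(f$k, 0)
  expect_equal(f$p_k, 1)
  expect_equal(f$halflife, 50)
})

test_that("underdetermined or empty series come back unconverged", {
  f <- fitDecay(c(0, 1), c(1, 0.5), z = 0)  # 2 points, 2 free params
  expect_false(f$converged)
  # but 2 points are enough when C is fixed
  f2 <- fitDecay(c(0, 1), c(1, 0.5), z = 0, c_fixed = 1)
  expect_true(f2$converged)
  expect_equal(f2$k, log(2), tolerance = 1e-6)
})

test_that("the significance filter matches a brute-force row scan", {
  keep <- filterFits(data.frame(p_k = 0.01, p_C = 0.01,
                                c_was_fixed = FALSE, converged = TRUE))
  expect_equal(nrow(keep), 1)
  expect_equal(nrow(filterFits(data.frame(p_k = 0.2, p_C = 0.01,
                                          c_was_fixed = FALSE,
                                          converged = TRUE))), 0)
  set.seed(9)
  fits <- data.frame(p_k = runif(200), p_C = runif(200),
                     c_was_fixed = sample(c(TRUE, FALSE), 200, TRUE),
                     converged = sample(c(TRUE, FALSE), 200, TRUE,
                                        prob = c(0.9, 0.1)))
  fits$p_C[sample(200, 10)] <- NA
  got <- filterFits(fits, alpha = 0.05)
  want <- fits[vapply(seq_len(200), function(i) {
    with(fits[i, ], isTRUE(converged) && isTRUE(p_k < 0.05) &&
      (c_was_fixed || isTRUE(p_C < 0.05)))
  }, logical(1)), ]
  rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("half-life is ln(2)/k with a 50-hour ceiling", {
  expect_equal(halfLife(log(2)), 1)
  expect_equal(halfLife(1e-6), 50)
  expect_equal(halfLife(0), 50)
  expect_equal(halfLife(log(2) / 10, cap_h = 5), 5)
  expect_error(halfLife(-1), "negative")
})

test_that("near-stable transcripts always report exactly the ceiling", {
  set.seed(14)
  t <- c(0, 1, 2, 4, 8, 28)
  for (i in 1:10) {
    k_true <- log(2) / runif(1, 500, 5000)
    v <- exp(-k_true * t) * 2^rnorm(6, 0, 0.1)
    f <- fitDecay(t, v / v[1], z = 0)
    expect_identical(f$halflife, 50)
  }
})

test_that("replicate half-lives average arithmetically", {
  fits <- data.frame(gene_id = c("g1", "g1", "g2"),
                     genotype = "WT", treatment = "none",
                     halflife = c(4, 6, 9),
                     stringsAsFactors = FALSE)
  avg <- averageReplicates(fits)
  expect_equal(avg$halflife[avg$gene_id == "g1"], 5)
  expect_equal(avg$halflife[avg$gene_id == "g2"], 9)
  expect_equal(avg$n_replicates[avg$gene_id == "g1"], 2L)
  set.seed(2)
  big <- data.frame(gene_id = sample(sprintf("g%d", 1:20), 100, TRUE),
                    genotype = "WT", treatment = "none",
                    halflife = runif(100, 1, 50),
                    stringsAsFactors = FALSE)
  avg2 <- averageReplicates(big)
  for (g in unique(big$gene_id))
    expect_equal(avg2$halflife[avg2$gene_id == g],
                 mean(big$halflife[big$gene_id == g]))
})

test_that("the stability value compares Torin1 responses across genotypes", {
  expect_equal(stabilityMetric(7, 7, 7, 7), 1)
  expect_equal(stabilityMetric(10, 5, 10, 10), 0.5)
  expect_true(is.na(stabilityMetric(10, NA, 10, 10)))
  # relabeling symmetry is exact on dyadic inputs
  a <- stabilityMetric(8, 2, 16, 4)
  b <- stabilityMetric(16, 4, 8, 2)
  expect_identical(a, 1 / b)
  # and within a couple of ulps in general
  set.seed(5)
  h <- matrix(runif(400, 0.5, 50), ncol = 4)
  A <- stabilityMetric(h[, 1], h[, 2], h[, 3], h[, 4])
  Ar <- stabilityMetric(h[, 3], h[, 4], h[, 1], h[, 2])
  expect_equal(A * Ar, rep(1, 100), tolerance = 1e-14)
})

test_that("fitDecayTable shares C from the untreated arm bit-exactly", {
  cfg <- simConfig(n_genes = 25, torin_effect_by_genotype = c(WT = 2),
                   seed = 31)
  truth <- simulateTranscriptome(cfg)
  pc <- simulatePulseChase(truth, cfg)
  dk <- fitDecayTable(pc$timecourse, pc$mock,
                      background_mode = "linear_plateau")
  fits <- dk$fits
  to <- fits[fits$treatment == "torin1", ]
  un <- fits[fits$treatment == "none", ]
  expect_true(all(to$c_was_fixed))
  key <- function(df) paste(df$gene_id, df$genotype, df$replicate)
  expect_identical(to$C, un$C[match(key(to), key(un))])
  # untreated fits estimated both parameters
  expect_false(any(un$c_was_fixed))
})
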