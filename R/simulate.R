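#' RNA classes known to the simulator
#'
#' Class labels used by the synthetic transcriptome, chosen to span the
#' biology of lysosomal RNA delivery: highly enriched noncoding RNAs
#' (SRP/7SL, Y RNAs), 5' TOP and membrane/secretory mRNAs, tRNAs, and
#' relatively depleted nuclear and mitochondrial species.
#' @export
SIM_CLASSES <- c("bulk_mRNA", "TOP_mRNA", "membrane_mRNA",
                 "secretory_mRNA", "tRNA", "Y_RNA", "SRP_RNA",
                 "vault_RNA", "snRNA", "mito_RNA")

.DEFAULT_PROPORTIONS <- c(
  bulk_mRNA = 0.45, TOP_mRNA = 0.05, membrane_mRNA = 0.10,
  secretory_mRNA = 0.08, tRNA = 0.15, Y_RNA = 0.02, SRP_RNA = 0.01,
  vault_RNA = 0.01, snRNA = 0.08, mito_RNA = 0.05)

## Defaults echo the observed ordering: 7SL/SRP most enriched, then
## Y RNAs, 5' TOP and membrane/secretory mRNAs; snRNAs depleted.
.DEFAULT_MULTIPLIERS <- c(
  bulk_mRNA = 1, TOP_mRNA = 8, membrane_mRNA = 4, secretory_mRNA = 4,
  tRNA = 3, Y_RNA = 12, SRP_RNA = 30, vault_RNA = 1.5, snRNA = 0.2,
  mito_RNA = 0.5)

.DEFAULT_LENGTHS <- c(
  bulk_mRNA = 1500, TOP_mRNA = 1200, membrane_mRNA = 2000,
  secretory_mRNA = 1800, tRNA = 76, Y_RNA = 100, SRP_RNA = 300,
  vault_RNA = 100, snRNA = 150, mito_RNA = 1000)

## Mock-IP pulldown background, as a fraction of whole-cell abundance.
.MOCK_IP_LEVEL <- 0.02

#' Simulation configuration
#'
#' Holds every parameter of the synthetic LysoIP fractionation and 5EU
#' pulse-chase experiments. Defaults are the study conditions the
#' package is validated under: 6 chase timepoints (0, 1, 2, 4, 8, 28 h),
#' spike-ins at ~0.01-0.2% of reads, 2 biological replicates, class
#' enrichment multipliers spanning 0.2-30.
#'
#' @slot n_genes Number of genes to simulate.
#' @slot class_proportions Named fractions over [SIM_CLASSES], sum 1.
#' @slot class_enrichment Named positive multipliers on the baseline
#'   lysosomal enrichment, one per class.
#' @slot baseline_enrichment Lysosomal enrichment of an unremarkable
#'   bulk mRNA (dimensionless lyso/whole-cell ratio).
#' @slot enrichment_jitter_sd Log-scale sd of per-gene lognormal jitter
#'   on true enrichment (0 = all genes at their class value).
#' @slot wc_mean_counts Mean expected read count per gene per sample.
#' @slot nb_dispersion Negative-binomial dispersion of fraction counts
#'   (0 = Poisson).
#' @slot spikein_concentrations Known spike-in concentrations
#'   (attomole-scale, arbitrary units).
#' @slot spikein_target_fraction Target fraction of reads from
#'   spike-ins (must lie in [1e-4, 2e-3]).
#' @slot capture_factors Named positive multipliers keyed by
#'   `whole_cell`, `lyso_<replicate>` (fallback `lyso`) and `mock`;
#'   the per-sample capture/dilution correction factor f_s.
#' @slot timepoints_h Chase timepoints in hours, ascending, first 0.
#' @slot true_halflife_range_h Range (lo, hi) of true half-lives in
#'   hours; true decay rates are drawn log-uniformly within it.
#' @slot torin_effect_by_genotype Named multiplier applied to the decay
#'   rate k under Torin1, per genotype (1 = no effect).
#' @slot background_fraction Pulse-chase background plateau as a
#'   fraction of the time-0 signal.
#' @slot log2_noise_sd sd (in log2 units) of multiplicative replicate
#'   noise on time-course signal.
#' @slot nluc_reads Reads assigned to the nLuc spike row per sample.
#' @slot pulse_mean_reads Mean time-0 read level per gene in the
#'   pulse-chase libraries.
#' @slot n_replicates Biological replicates per condition.
#' @slot seed Integer seed; the three generator stages use
#'   `seed`, `seed + 1`, `seed + 2` so each is reproducible alone.
#' @seealso [simConfig()]
#' @export
setClass("SimulationConfig", representation(
  n_genes = "numeric",
  class_proportions = "numeric",
  class_enrichment = "numeric",
  baseline_enrichment = "numeric",
  enrichment_jitter_sd = "numeric",
  wc_mean_counts = "numeric",
  nb_dispersion = "numeric",
  spikein_concentrations = "numeric",
  spikein_target_fraction = "numeric",
  capture_factors = "numeric",
  timepoints_h = "numeric",
  true_halflife_range_h = "numeric",
  torin_effect_by_genotype = "numeric",
  background_fraction = "numeric",
  log2_noise_sd = "numeric",
  nluc_reads = "numeric",
  pulse_mean_reads = "numeric",
  n_replicates = "numeric",
  seed = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  p <- object@class_proportions
  if (!setequal(names(p), SIM_CLASSES))
    msg <- c(msg, "class_proportions must be named by SIM_CLASSES")
  if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "class_proportions must sum to 1 within 1e-9")
  if (any(p < 0)) msg <- c(msg, "class_proportions must be nonnegative")
  if (!setequal(names(object@class_enrichment), SIM_CLASSES) ||
      any(object@class_enrichment <= 0))
    msg <- c(msg, "class_enrichment must be positive, named by SIM_CLASSES")
  for (nm in c("baseline_enrichment", "wc_mean_counts", "nluc_reads",
               "pulse_mean_reads"))
    if (slot(object, nm) <= 0)
      msg <- c(msg, sprintf("%s must be strictly positive", nm))
  for (nm in c("nb_dispersion", "background_fraction", "log2_noise_sd",
               "enrichment_jitter_sd"))
    if (slot(object, nm) < 0)
      msg <- c(msg, sprintf("%s must be nonnegative", nm))
  if (any(object@spikein_concentrations <= 0))
    msg <- c(msg, "spikein_concentrations must be strictly positive")
  tf <- object@spikein_target_fraction
  if (tf < 1e-4 || tf > 2e-3)
    msg <- c(msg, "spikein_target_fraction must lie in [1e-4, 2e-3]")
  if (any(object@capture_factors <= 0))
    msg <- c(msg, "capture_factors must be strictly positive")
  tp <- object@timepoints_h
  if (length(tp) < 2 || tp[1] != 0 || is.unsorted(tp, strictly = TRUE) ||
      any(tp < 0))
    msg <- c(msg, "timepoints_h must be ascending, nonnegative, starting at 0")
  hr <- object@true_halflife_range_h
  if (length(hr) != 2 || any(hr <= 0) || hr[1] > hr[2])
    msg <- c(msg, "true_halflife_range_h must be a positive (lo, hi) pair")
  if (any(object@torin_effect_by_genotype <= 0) ||
      is.null(names(object@torin_effect_by_genotype)))
    msg <- c(msg, "torin_effect_by_genotype must be positive and named")
  if (object@n_genes < 0 || object@n_genes != round(object@n_genes))
    msg <- c(msg, "n_genes must be a nonnegative integer")
  if (object@n_replicates < 1)
    msg <- c(msg, "n_replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' All arguments default to the study conditions described in
#' [SimulationConfig]; override any subset.
#'
#' @param n_genes,class_proportions,class_enrichment,baseline_enrichment
#'   See [SimulationConfig].
#' @param enrichment_jitter_sd,wc_mean_counts,nb_dispersion See
#'   [SimulationConfig].
#' @param spikein_concentrations,spikein_target_fraction,capture_factors
#'   See [SimulationConfig].
#' @param timepoints_h,true_halflife_range_h,torin_effect_by_genotype
#'   See [SimulationConfig].
#' @param background_fraction,log2_noise_sd,nluc_reads,pulse_mean_reads
#'   See [SimulationConfig].
#' @param n_replicates,seed See [SimulationConfig].
#' @return A validated [SimulationConfig].
#' @examples
#' cfg <- simConfig(n_genes = 100, seed = 7)
#' truth <- simulateTranscriptome(cfg)
#' head(truth)
#' @export
simConfig <- function(n_genes = 2000,
                      class_proportions = .DEFAULT_PROPORTIONS,
                      class_enrichment = .DEFAULT_MULTIPLIERS,
                      baseline_enrichment = 1,
                      enrichment_jitter_sd = 0.4,
                      wc_mean_counts = 1000,
                      nb_dispersion = 0.1,
                      spikein_concentrations = 10^seq(0, 2,
                                                      length.out = 24),
                      spikein_target_fraction = 5e-4,
                      capture_factors = c(whole_cell = 50, lyso_1 = 30,
                                          lyso_2 = 45, lyso = 40,
                                          mock = 40),
                      timepoints_h = c(0, 1, 2, 4, 8, 28),
                      true_halflife_range_h = c(0.5, 30),
                      torin_effect_by_genotype = c(WT = 1, ATG7KO = 1),
                      background_fraction = 1e-4,
                      log2_noise_sd = 0.1,
                      nluc_reads = 1e4,
                      pulse_mean_reads = 200,
                      n_replicates = 2,
                      seed = 1L) {
  new("SimulationConfig",
      n_genes = n_genes,
      class_proportions = class_proportions[SIM_CLASSES],
      class_enrichment = class_enrichment[SIM_CLASSES],
      baseline_enrichment = baseline_enrichment,
      enrichment_jitter_sd = enrichment_jitter_sd,
      wc_mean_counts = wc_mean_counts,
      nb_dispersion = nb_dispersion,
      spikein_concentrations = spikein_concentrations,
      spikein_target_fraction = spikein_target_fraction,
      capture_factors = capture_factors,
      timepoints_h = timepoints_h,
      true_halflife_range_h = true_halflife_range_h,
      torin_effect_by_genotype = torin_effect_by_genotype,
      background_fraction = background_fraction,
      log2_noise_sd = log2_noise_sd,
      nluc_reads = nluc_reads,
      pulse_mean_reads = pulse_mean_reads,
      n_replicates = n_replicates,
      seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_genes, "genes,",
      object@n_replicates, "replicates, seed", object@seed, "\n")
  cat("  timepoints (h):", paste(object@timepoints_h, collapse = ", "),
      "\n")
  cat("  half-life range (h):",
      paste(object@true_halflife_range_h, collapse = "-"), "\n")
  cat("  spike-ins:", length(object@spikein_concentrations),
      "at target read fraction", object@spikein_target_fraction, "\n")
})

#' Simulate a ground-truthed transcriptome
#'
#' Draws per-gene truth for both downstream experiments: RNA class
#' (largest-remainder allocation of `n_genes` across
#' `class_proportions`, ties broken by class name), relative abundance,
#' true lysosomal enrichment `E_true` (baseline x class multiplier x
#' lognormal jitter), true decay rate `true_k` (half-life log-uniform
#' in the configured range), the t0-normalized decay amplitude
#' `true_C` and background plateau `true_z`, TOPscore, and for tRNAs
#' the carried amino acid, its Kyte-Doolittle hydropathicity, and a
#' synthetic sequence (identical within sequence-duplicate groups).
#'
#' @param config A [SimulationConfig].
#' @return `data.frame` with one row per gene: `gene_id`, `class`,
#'   `abundance`, `E_true`, `true_k`, `true_C`, `true_z`, `topscore`,
#'   `trna_amino_acid`, `hydropathicity`, `trna_sequence`, `length_nt`.
#' @export
simulateTranscriptome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- as.integer(config@n_genes)
  alloc <- largestRemainder(n, config@class_proportions)
  if (n == 0L) {
    return(data.frame(gene_id = character(), class = character(),
                      abundance = numeric(), E_true = numeric(),
                      true_k = numeric(), true_C = numeric(),
                      true_z = numeric(), topscore = numeric(),
                      trna_amino_acid = character(),
                      hydropathicity = numeric(),
                      trna_sequence = character(),
                      length_nt = integer()))
  }
  cls <- rep(names(alloc), alloc)
  gene_id <- sprintf("G%05d", seq_len(n))
  abundance <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  jitter <- if (config@enrichment_jitter_sd > 0)
    rlnorm(n, 0, config@enrichment_jitter_sd) else rep(1, n)
  E_true <- config@baseline_enrichment *
    unname(config@class_enrichment[cls]) * jitter
  hr <- config@true_halflife_range_h
  t_half <- exp(runif(n, log(hr[1]), log(hr[2])))
  true_k <- log(2) / t_half
  bf <- config@background_fraction
  true_C <- rep(1 / (1 + bf), n)
  true_z <- rep(bf / (1 + bf), n)
  topscore <- ifelse(cls == "TOP_mRNA", runif(n, 3.2, 9), runif(n, 0, 3))
  length_nt <- as.integer(round(.DEFAULT_LENGTHS[cls] *
                                runif(n, 0.8, 1.2)))
  trna_amino_acid <- rep(NA_character_, n)
  hydropathicity <- rep(NA_real_, n)
  trna_sequence <- rep(NA_character_, n)
  itr <- which(cls == "tRNA")
  if (length(itr)) {
    aa <- sample(names(KD_HYDROPATHICITY), length(itr), replace = TRUE)
    trna_amino_acid[itr] <- aa
    hydropathicity[itr] <- unname(KD_HYDROPATHICITY[aa])
    ## isodecoder pools: ~2/3 as many distinct sequences as genes, so
    ## some tRNA genes share a sequence and collapse downstream
    n_seq <- max(1L, ceiling(length(itr) * 2 / 3))
    pool <- vapply(seq_len(n_seq), function(i)
      paste(sample(c("A", "C", "G", "U"), 76, replace = TRUE),
            collapse = ""), character(1))
    trna_sequence[itr] <- pool[sample.int(n_seq, length(itr),
                                          replace = TRUE)]
    length_nt[itr] <- 76L
  }
  data.frame(gene_id = gene_id, class = cls, abundance = abundance,
             E_true = E_true, true_k = true_k, true_C = true_C,
             true_z = true_z, topscore = topscore,
             trna_amino_acid = trna_amino_acid,
             hydropathicity = hydropathicity,
             trna_sequence = trna_sequence, length_nt = length_nt,
             stringsAsFactors = FALSE)
}

#' Build a fractionation sample design
#'
#' One row per sequencing sample of the LysoIP experiment, crossing
#' genotypes, treatments, fractions and replicates, with capture
#' factors looked up in `config@capture_factors` (key
#' `lyso_<replicate>` for lysosomal samples, falling back to `lyso`).
#'
#' @param config A [SimulationConfig].
#' @param genotypes,treatments,fractions Character vectors of levels.
#' @return `data.frame` with columns `sample_id`, `genotype`,
#'   `treatment`, `fraction`, `replicate`, `capture_factor`.
#' @export
simDesign <- function(config,
                      genotypes = c("WT", "RNASET2KO", "tKO"),
                      treatments = c("none", "torin1"),
                      fractions = c("whole_cell", "lyso")) {
  stopifnot(all(fractions %in% .FRACTIONS))
  d <- expand.grid(replicate = seq_len(config@n_replicates),
                   fraction = fractions, treatment = treatments,
                   genotype = genotypes, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("genotype", "treatment", "fraction", "replicate")]
  cf <- config@capture_factors
  key <- ifelse(d$fraction == "lyso",
                paste0("lyso_", d$replicate), d$fraction)
  key[key %in% setdiff(key, names(cf)) & d$fraction == "lyso"] <- "lyso"
  if (!all(key %in% names(cf)))
    stop("missing capture factor for: ",
         paste(unique(key[!key %in% names(cf)]), collapse = ", "))
  d$capture_factor <- unname(cf[key])
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$genotype, d$treatment,
                         d$fraction, d$replicate)
  d[, c("sample_id", "genotype", "treatment", "fraction", "replicate",
        "capture_factor")]
}

#' Simulate LysoIP fractionation counts with spike-ins
#'
#' Expected counts are built from the physical model of the experiment:
#' each sample's sequencing tube contains gene material
#' `abundance x enrichment / f_s` (enrichment 1 for whole-cell,
#' `E_true` for lyso, a small constant background for mock-IP) plus a
#' fixed amount of each spike-in (equal across samples, scaled so
#' spike reads land at `spikein_target_fraction` of the
#' geometric-mean sample). A per-sample depth factor sets the mean
#' gene count to `wc_mean_counts`. Gene counts are drawn
#' negative-binomially with `nb_dispersion` (Poisson at 0), modelling
#' biological replicate overdispersion; spike-in reads are Poisson,
#' since spikes are pipetted aliquots of a single stock and carry only
#' technical noise. With `noise = FALSE` the exact expected means are
#' returned.
#'
#' Dividing a sample by its fitted spike slope and multiplying by
#' `f_s` (see [spikeinNormalize()]) therefore recovers
#' `abundance x enrichment` exactly in expectation.
#'
#' @param truth Output of [simulateTranscriptome()].
#' @param design Output of [simDesign()] (or an equivalent table with
#'   `sample_id`, `genotype`, `treatment`, `fraction`, `replicate`,
#'   `capture_factor`).
#' @param config The [SimulationConfig] used for `truth`.
#' @param noise Draw counts (`TRUE`) or return exact means (`FALSE`).
#' @return List with `counts` (a [LysoExperiment], genes only) and
#'   `spikes` (`data.frame`: `spike_id`, `concentration`, one read
#'   column per sample).
#' @export
simulateFractionCounts <- function(truth, design, config, noise = TRUE) {
  validObject(config)
  set.seed(config@seed + 1)
  need <- c("sample_id", "genotype", "treatment", "fraction",
            "replicate", "capture_factor")
  if (!all(need %in% names(design)))
    stop("design must contain columns: ", paste(need, collapse = ", "))
  if (any(is.na(design$capture_factor) | design$capture_factor <= 0))
    stop("missing capture factor for sample(s): ",
         paste(design$sample_id[is.na(design$capture_factor) |
                                design$capture_factor <= 0],
               collapse = ", "))
  for (gt in unique(design$genotype)) for (tr in unique(design$treatment)) {
    sub <- design[design$genotype == gt & design$treatment == tr, ]
    if (nrow(sub) && (!any(sub$fraction == "whole_cell") ||
                      !any(sub$fraction == "lyso")))
      stop("design needs >=1 whole_cell and >=1 lyso sample for ",
           gt, "/", tr)
  }
  n <- nrow(truth)
  q <- truth$abundance / sum(truth$abundance)
  enr <- cbind(whole_cell = rep(1, n), lyso = truth$E_true,
               mock = rep(.MOCK_IP_LEVEL, n))
  tube <- vapply(seq_len(nrow(design)), function(j)
    q * enr[, design$fraction[j]] / design$capture_factor[j],
    numeric(n))
  colnames(tube) <- design$sample_id
  tubeTotal <- colSums(tube)
  depth <- config@wc_mean_counts * n / tubeTotal
  mu <- sweep(tube, 2, depth, `*`)
  conc <- config@spikein_concentrations
  tf <- config@spikein_target_fraction
  kappa <- tf / (1 - tf) * exp(mean(log(tubeTotal))) / sum(conc)
  muSpike <- outer(kappa * conc, depth)
  dimnames(muSpike) <- list(sprintf("SPIKE%03d", seq_along(conc)),
                            design$sample_id)
  draw <- function(m, technical = FALSE) {
    if (!noise) return(m)
    ## genes carry biological overdispersion; spike-ins are pipetted
    ## aliquots of one stock, so their counts are Poisson (technical)
    out <- if (technical || config@nb_dispersion == 0)
      rpois(length(m), lambda = m)
    else
      rnbinom(length(m), mu = m, size = 1 / config@nb_dispersion)
    matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  counts <- draw(mu)
  rownames(counts) <- truth$gene_id
  spikeReads <- draw(muSpike, technical = TRUE)
  se <- lysoExperiment(counts, biotype = truth$class,
                       length_nt = truth$length_nt, design = design)
  spikes <- data.frame(spike_id = rownames(muSpike),
                       concentration = conc,
                       as.data.frame(spikeReads), row.names = NULL,
                       check.names = FALSE)
  list(counts = se, spikes = spikes)
}

#' Simulate a 5EU pulse-chase time course
#'
#' Per gene, genotype, treatment and replicate, the expected signal at
#' chase time `x` is `R_g * (exp(-k_eff * x) + background_fraction)`,
#' where `R_g` is the gene's time-0 read level and `k_eff` is the true
#' decay rate times the genotype's Torin1 multiplier when treated.
#' Torin1 series share their initial level with the untreated series
#' of the same replicate by construction. Observed values get
#' multiplicative lognormal noise of `log2_noise_sd` log2 units. Each
#' sample carries an `nLuc` spike row, and 4 mock-IP background
#' samples are emitted on the same read scale.
#'
#' @param truth Output of [simulateTranscriptome()].
#' @param config The [SimulationConfig] used for `truth`.
#' @param genotypes Genotypes to simulate; must all have an entry in
#'   `config@torin_effect_by_genotype`.
#' @param treatments Subset of `c("none", "torin1")`.
#' @param noise Add replicate noise (`TRUE`) or emit exact means.
#' @param nluc_id Gene id used for the nLuc spike row.
#' @return List with `timecourse` (long `data.frame`: `gene_id`,
#'   `genotype`, `treatment`, `replicate`, `time_h`, `count`;
#'   includes nLuc rows) and `mock` (`data.frame`: `gene_id`,
#'   `mock_1` .. `mock_4`).
#' @export
simulatePulseChase <- function(truth, config,
                               genotypes =
                                 names(config@torin_effect_by_genotype),
                               treatments = c("none", "torin1"),
                               noise = TRUE, nluc_id = "nLuc") {
  validObject(config)
  set.seed(config@seed + 2)
  if (any(config@timepoints_h < 0)) stop("negative timepoints")
  eff <- config@torin_effect_by_genotype
  if (!all(genotypes %in% names(eff)))
    stop("no Torin1 effect configured for genotype(s): ",
         paste(setdiff(genotypes, names(eff)), collapse = ", "))
  stopifnot(all(treatments %in% c("none", "torin1")))
  n <- nrow(truth)
  q <- truth$abundance / mean(truth$abundance)
  R <- q * config@pulse_mean_reads
  bf <- config@background_fraction
  tp <- config@timepoints_h
  sd2 <- config@log2_noise_sd
  rows <- list()
  ## Torin1 treatment starts at the chase t0, so the time-0 sample is
  ## collected before treatment and is common to both arms of a
  ## replicate: one t0 observation is drawn per genotype/replicate and
  ## shared across treatments (this is what makes fixing C from the
  ## untreated fit informative for the treated one).
  for (gt in genotypes) for (rep_i in seq_len(config@n_replicates)) {
    mu0 <- R * (1 + bf)
    val0 <- if (noise && sd2 > 0) mu0 * 2^rnorm(n, 0, sd2) else mu0
    for (tr in treatments) {
      k_eff <- truth$true_k * if (tr == "torin1") eff[[gt]] else 1
      for (x in tp) {
        if (x == 0) {
          val <- val0
        } else {
          mu <- R * (exp(-k_eff * x) + bf)
          val <- if (noise && sd2 > 0) mu * 2^rnorm(n, 0, sd2) else mu
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = c(truth$gene_id, nluc_id),
          genotype = gt, treatment = tr, replicate = rep_i,
          time_h = x, count = c(val, config@nluc_reads),
          stringsAsFactors = FALSE)
      }
    }
  }
  tc <- do.call(rbind, rows)
  mock <- matrix(0, n, 4,
                 dimnames = list(truth$gene_id, paste0("mock_", 1:4)))
  for (j in 1:4) {
    mu <- bf * R
    mock[, j] <- if (noise && sd2 > 0) mu * 2^rnorm(n, 0, sd2) else mu
  }
  list(timecourse = tc,
       mock = data.frame(gene_id = truth$gene_id, mock,
                         row.names = NULL, check.names = FALSE))
}

#' Write a full simulation to TSV files
#'
#' Emits `truth.tsv`, `design.tsv`, `counts.tsv`, `spikein_reads.tsv`,
#' `timecourse.tsv` and `mock.tsv` under `outdir` (created if needed).
#'
#' @param config A [SimulationConfig].
#' @param outdir Output directory.
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeSimulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulateTranscriptome(config)
  design <- simDesign(config)
  frac <- simulateFractionCounts(truth, design, config)
  pc <- simulatePulseChase(truth, config)
  paths <- c(
    truth = file.path(outdir, "truth.tsv"),
    design = file.path(outdir, "design.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    spikein_reads = file.path(outdir, "spikein_reads.tsv"),
    timecourse = file.path(outdir, "timecourse.tsv"),
    mock = file.path(outdir, "mock.tsv"))
  writeTsv(truth, paths["truth"])
  writeTsv(design, paths["design"])
  writeTsv(asCountTable(frac$counts), paths["counts"])
  writeTsv(frac$spikes, paths["spikein_reads"])
  writeTsv(pc$timecourse, paths["timecourse"])
  writeTsv(pc$mock, paths["mock"])
  invisible(paths)
}
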