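# Shared fixture builders. Everything is generated in code; no files.

# tiny fractionation experiment built by hand (not via the generator)
tinyCountTable <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             biotype = c("mRNA", "tRNA", "mRNA"),
             length_nt = c(1000, 76, 2000),
             s1 = c(10, 5, 40), s2 = c(20, 0, 80),
             stringsAsFactors = FALSE)
}

tinyDesign <- function() {
  data.frame(sample_id = c("s1", "s2"),
             genotype = "WT", treatment = "none",
             fraction = c("lyso", "whole_cell"),
             replicate = 1L, capture_factor = c(30, 50),
             stringsAsFactors = FALSE)
}

# spike table with reads exactly proportional to concentration
# (per-sample proportionality alpha), all spikes well-supported
proportionalSpikes <- function(alpha = c(s1 = 2, s2 = 5),
                               conc = c(10, 20, 40, 80)) {
  tab <- data.frame(spike_id = sprintf("SP%d", seq_along(conc)),
                    concentration = conc, stringsAsFactors = FALSE)
  for (s in names(alpha)) tab[[s]] <- alpha[[s]] * conc
  tab
}

# random read-assignment table respecting the tier/multiplicity rules
randomAssignments <- function(n_reads = 50, n_features = 8,
                              n_samples = 2, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_reads)) {
    s <- sample(sprintf("s%d", seq_len(n_samples)), 1)
    tier <- sample(0:4, 1)
    nl <- sample(1:3, 1)
    feats <- sample(sprintf("f%02d", seq_len(n_features)), nl)
    rows[[i]] <- data.frame(read_id = sprintf("r%04d", i), sample_id = s,
                            feature_id = feats, n_locations = nl,
                            reference_tier = tier,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# independent largest-remainder oracle: greedy, one seat at a time
allocOracle <- function(n, props) {
  out <- floor(n * props)
  while (sum(out) < n) {
    rem <- n * props - out
    best <- which(rem == max(rem))
    best <- best[order(names(props)[best])][1]
    out[best] <- out[best] + 1
  }
  out
}

# independent Spearman oracle: average ranks, then explicit Pearson
spearmanOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
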