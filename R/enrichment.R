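#' Per-gene lysosomal enrichment
#'
#' `E = mean(normalized lyso replicates) / mean(normalized whole-cell
#' replicates)`: the average spike- and capture-normalized lysosomal
#' signal across biological replicates divided by the corresponding
#' whole-cell average. Genes whose whole-cell mean is zero get `NA`
#' (flagged undefined) rather than a pseudocount, since a pseudocount
#' would fabricate enrichment for lysosome-only detections.
#'
#' @param x Matrix (genes x lyso replicates) of normalized lysosomal
#'   values, with rownames, or a [LysoExperiment] (then `wc` is
#'   ignored and replicate columns are selected from the design).
#' @param wc Matrix (genes x whole-cell replicates) of normalized
#'   whole-cell values, same rownames as `x`.
#' @param genotype,treatment For the `LysoExperiment` method: which
#'   condition to score.
#' @param assay Assay holding normalized values.
#' @param ... Passed between methods.
#' @return Named numeric vector of enrichments E (NA where undefined).
#' @export
setGeneric("lysosomalEnrichment", function(x, ...)
  standardGeneric("lysosomalEnrichment"))

#' @rdname lysosomalEnrichment
#' @export
setMethod("lysosomalEnrichment", "matrix", function(x, wc, ...) {
  wc <- as.matrix(wc)
  if (is.null(rownames(x)) || is.null(rownames(wc)))
    stop("both matrices need gene rownames")
  if (!identical(sort(rownames(x)), sort(rownames(wc)))) {
    d <- union(setdiff(rownames(x), rownames(wc)),
               setdiff(rownames(wc), rownames(x)))
    stop("mismatched gene sets; symmetric difference: ",
         paste(utils::head(d, 10), collapse = ", "))
  }
  wc <- wc[rownames(x), , drop = FALSE]
  mw <- rowMeans(wc)
  e <- rowMeans(x) / mw
  e[mw == 0] <- NA_real_
  e
})

#' @rdname lysosomalEnrichment
#' @export
setMethod("lysosomalEnrichment", "LysoExperiment",
          function(x, genotype, treatment, assay = "normalized", ...) {
  cd <- colData(x)
  need <- c("genotype", "treatment", "fraction")
  if (!all(need %in% names(cd)))
    stop("colData must contain: ", paste(need, collapse = ", "))
  sel <- cd$genotype == genotype & cd$treatment == treatment
  ly <- which(sel & cd$fraction == "lyso")
  wcI <- which(sel & cd$fraction == "whole_cell")
  if (!length(ly) || !length(wcI))
    stop("need >=1 lyso and >=1 whole_cell sample for ", genotype,
         "/", treatment)
  m <- SummarizedExperiment::assay(x, assay)
  lysosomalEnrichment(m[, ly, drop = FALSE], m[, wcI, drop = FALSE])
})

#' Enrichment for every genotype/treatment condition
#'
#' @param x A normalized [LysoExperiment].
#' @param assay Assay holding normalized values.
#' @return `data.frame`: `gene_id` plus one enrichment column
#'   `E_<genotype>_<treatment>` per condition present in the design.
#' @export
enrichmentTable <- function(x, assay = "normalized") {
  cd <- colData(x)
  conds <- unique(data.frame(genotype = cd$genotype,
                             treatment = cd$treatment))
  out <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(conds))) {
    e <- lysosomalEnrichment(x, conds$genotype[i], conds$treatment[i],
                             assay = assay)
    out[[sprintf("E_%s_%s", conds$genotype[i], conds$treatment[i])]] <- e
  }
  out
}

#' Knockout dependence ratio
#'
#' `D = E_ko / E_control`, the gene's lysosomal enrichment in a
#' factor-knockout line divided by its enrichment in the matched
#' control line. `D < 1` means the gene depends on the knocked-out
#' factor for lysosomal entry. Undefined (`NA`) when either enrichment
#' is undefined or the control enrichment is zero.
#'
#' @param e_ko,e_control Named enrichment vectors on the same gene set.
#' @return Named numeric vector of dependence ratios D.
#' @export
dependenceRatio <- function(e_ko, e_control) {
  if (!is.null(names(e_ko)) && !is.null(names(e_control))) {
    if (!identical(sort(names(e_ko)), sort(names(e_control))))
      stop("enrichment vectors must share one gene set")
    e_control <- e_control[names(e_ko)]
  } else if (length(e_ko) != length(e_control)) {
    stop("enrichment vectors must have equal length")
  }
  d <- e_ko / e_control
  d[!is.finite(d) | is.na(e_control) | e_control == 0] <- NA_real_
  d
}

#' Stratified group summaries of a per-gene statistic
#'
#' Summarizes a statistic (enrichment, dependence ratio, stability
#' value, ...) within groups defined by RNA class, protein-localization
#' class, or TOPscore bin. Reports n per group alongside the median
#' and quartiles, as the violin-plot figures do; empty groups are kept
#' with `n = 0` and `NA` statistics.
#'
#' @param values Named per-gene numeric vector.
#' @param annotation `data.frame` with `gene_id` plus the grouping
#'   columns (`class`, `localization`, `topscore`).
#' @param grouping One of `"class"`, `"localization"`,
#'   `"topscore_bin"`.
#' @param topscore_edges Bin edges for TOPscore binning; the default
#'   keeps 3.0 as a boundary (scores above 3 mark strong 5' TOP
#'   motifs).
#' @return `data.frame`: `group`, `n`, `median`, `q25`, `q75`.
#' @export
classSummary <- function(values, annotation,
                         grouping = c("class", "localization",
                                      "topscore_bin"),
                         topscore_edges = c(-Inf, 1, 2, 3, Inf)) {
  grouping <- match.arg(grouping)
  if (is.null(names(values)))
    stop("'values' must be named by gene_id")
  i <- match(names(values), annotation$gene_id)
  if (anyNA(i))
    stop("annotation is missing gene(s): ",
         paste(utils::head(names(values)[is.na(i)], 5), collapse = ", "))
  g <- switch(grouping,
    class = annotation$class[i],
    localization = annotation$localization[i],
    topscore_bin = as.character(cut(annotation$topscore[i],
                                    breaks = topscore_edges,
                                    include.lowest = TRUE)))
  if (is.null(g)) stop("annotation lacks the '", grouping, "' column")
  g <- factor(g)
  qs <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  }
  stats <- vapply(levels(g), function(lv) qs(values[g == lv]),
                  numeric(3))
  data.frame(group = levels(g),
             n = as.integer(table(g)),
             median = stats[1, ], q25 = stats[2, ], q75 = stats[3, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse tRNA genes with identical sequences
#'
#' tRNA loci encoding the same mature sequence are indistinguishable
#' to sequencing; their counts are summed into one row. The retained
#' row id is the lexicographically first member and a `members`
#' column records the collapsed set. Genes without a sequence are
#' passed through uncollapsed with a warning.
#'
#' @param counts Count table `data.frame` (interchange layout).
#' @param sequences `data.frame` with `gene_id`, `sequence` covering
#'   the tRNA genes.
#' @return The collapsed count table with a `members` column.
#' @export
collapseIdenticalTrnas <- function(counts, sequences) {
  seqs <- sequences$sequence[match(counts$gene_id, sequences$gene_id)]
  if (any(is.na(seqs)))
    warning("no sequence for gene(s): ",
            paste(utils::head(counts$gene_id[is.na(seqs)], 5),
                  collapse = ", "), "; passed through uncollapsed",
            call. = FALSE)
  key <- ifelse(is.na(seqs), paste0("\rNOSEQ\r", counts$gene_id), seqs)
  samp <- .sampleColumns(counts, c("gene_id", "biotype", "length_nt",
                                   "members"))
  ord <- order(key, counts$gene_id)
  counts <- counts[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- counts[first, , drop = FALSE]
  grp <- match(key, key[first])
  for (s in samp)
    out[[s]] <- as.numeric(rowsum(counts[[s]], grp))
  out$members <- vapply(split(counts$gene_id, grp), paste, "",
                        collapse = ",")
  out <- out[order(match(out$gene_id, counts$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean
#' rank). Non-finite pairs are dropped; at least 3 complete pairs are
#' required; a constant vector yields `NA` with a warning (rank
#' correlation undefined).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in [-1, 1], or `NA` when undefined.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >=3 paired finite values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: Spearman correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Relative quantification by the delta-delta-CT method
#'
#' `fold = 2^-((ct_target_s - ct_ref_s) - (ct_target_cal -
#' ct_ref_cal))`: the target's CT in the sample, normalized to an
#' internal-control CT (e.g. 18S rRNA), relative to the same
#' difference in the calibrator condition.
#'
#' @param ct_target_s,ct_ref_s Target/reference CT in the sample.
#' @param ct_target_cal,ct_ref_cal Target/reference CT in the
#'   calibrator.
#' @return Fold change (vectorized).
#' @export
deltaDeltaCt <- function(ct_target_s, ct_ref_s, ct_target_cal,
                         ct_ref_cal) {
  ddct <- (ct_target_s - ct_ref_s) - (ct_target_cal - ct_ref_cal)
  if (any(!is.finite(ddct)))
    stop("CT values must be finite")
  2^(-ddct)
}
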