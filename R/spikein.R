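#' Filter spike-ins by read support
#'
#' Keeps a spike-in if it has at least `min_reads` reads in at least
#' `ceiling(min_sample_fraction * n_samples)` samples. The default
#' fraction 0.75 generalizes the 18-of-24 / 16-of-16 rule used for the
#' fractionation libraries to arbitrary designs.
#'
#' @param spikes Spike-in table: `spike_id`, `concentration`, one
#'   numeric read (or RPK) column per sample.
#' @param min_reads Minimum reads per sample to count as supported.
#' @param min_sample_fraction Required fraction of supporting samples.
#' @return The filtered spike table. Errors if nothing survives, since
#'   the standard-curve regression would be impossible.
#' @export
filterSpikeins <- function(spikes, min_reads = 10,
                           min_sample_fraction = 0.75) {
  stopifnot(min_reads >= 0, min_sample_fraction > 0,
            min_sample_fraction <= 1)
  samp <- .sampleColumns(spikes, c("spike_id", "concentration"))
  if (!length(samp)) stop("spike table has no sample columns")
  supp <- rowSums(as.matrix(spikes[, samp, drop = FALSE]) >= min_reads)
  need <- ceiling(min_sample_fraction * length(samp))
  out <- spikes[supp >= need, , drop = FALSE]
  if (!nrow(out))
    stop("no spike-ins pass the filter (", min_reads, "+ reads in >=",
         need, " samples); relax min_reads or min_sample_fraction")
  rownames(out) <- NULL
  out
}

#' Fit a per-sample spike-in standard-curve slope
#'
#' Ordinary least squares of the sample's spike signal on the known
#' concentrations (regression with intercept; only the slope is used,
#' the intercept absorbs additive background). Dividing a sample's
#' expression values by this slope places them on the absolute
#' concentration scale of the spike-ins.
#'
#' @param spikes (Filtered) spike-in table.
#' @param sample_id Which sample column to fit.
#' @return The positive slope (signal units per concentration unit).
#'   Errors on fewer than 2 distinct concentrations or a nonpositive
#'   slope (degenerate or inverted standard curve).
#' @export
fitSpikeSlope <- function(spikes, sample_id) {
  if (!sample_id %in% names(spikes))
    stop("no such sample column: ", sample_id)
  x <- spikes$concentration
  y <- spikes[[sample_id]]
  if (length(unique(x)) < 2)
    stop("need >=2 spike-ins with distinct concentrations")
  beta <- unname(coef(lm(y ~ x))[2L])
  if (!is.finite(beta) || beta <= 0)
    stop("degenerate or inverted standard curve for sample '",
         sample_id, "' (slope ", format(beta), ")")
  beta
}

#' Normalize one expression column to absolute scale
#'
#' `value / slope * capture_factor`: division by the spike slope puts
#' the sample on the spike-ins' concentration scale; multiplication by
#' the capture factor corrects lysosomal capture efficiency and input
#' dilution.
#'
#' @param values Numeric expression column (counts or RPK).
#' @param slope Positive spike-curve slope for the sample.
#' @param capture_factor Positive per-sample correction factor f_s.
#' @return Normalized values, same length as `values`.
#' @examples
#' normalizeSample(10, slope = 2, capture_factor = 14285)  # 71425
#' @export
normalizeSample <- function(values, slope, capture_factor) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  if (!is.finite(capture_factor) || capture_factor <= 0)
    stop("capture_factor must be positive")
  values / slope * capture_factor
}

#' Spike-in normalize a whole experiment
#'
#' Filters the spike table, fits one standard-curve slope per sample,
#' and normalizes every sample column: `value / slope * f_s`. By
#' default the regression and the division are performed on the same
#' scale the experiment is analyzed on (RPK when present, raw counts
#' otherwise); the spike table must be on that same scale.
#'
#' @param x A [LysoExperiment] whose `colData` carries
#'   `capture_factor`, or a count table `data.frame` plus a `design`.
#' @param spikes Spike-in table (`spike_id`, `concentration`, read/RPK
#'   columns matching the experiment's samples).
#' @param assay For the `LysoExperiment` method: which assay to
#'   normalize (default `"rpk"` if present, else `"counts"`).
#' @param min_reads,min_sample_fraction Passed to [filterSpikeins()].
#' @param design For the `data.frame` method: sample design with
#'   `sample_id` and `capture_factor`.
#' @param ... Passed between methods.
#' @return For `LysoExperiment`: the object with a `"normalized"`
#'   assay added and per-sample slopes in
#'   `metadata(x)$spike_slopes`. For `data.frame`: a list with
#'   `normalized` (table), `slopes`, and `spikes_normalized` (the
#'   retained spikes on the normalized scale).
#' @export
setGeneric("spikeinNormalize", function(x, spikes, ...)
  standardGeneric("spikeinNormalize"))

#' @rdname spikeinNormalize
#' @export
setMethod("spikeinNormalize", "LysoExperiment",
          function(x, spikes, assay = NULL, min_reads = 10,
                   min_sample_fraction = 0.75, ...) {
  if (is.null(assay))
    assay <- if ("rpk" %in% assayNames(x)) "rpk" else "counts"
  if (!"capture_factor" %in% names(colData(x)))
    stop("colData must contain 'capture_factor'")
  kept <- filterSpikeins(spikes, min_reads, min_sample_fraction)
  m <- SummarizedExperiment::assay(x, assay)
  missing <- setdiff(colnames(m), names(kept))
  if (length(missing))
    stop("spike table lacks sample column(s): ",
         paste(missing, collapse = ", "))
  slopes <- vapply(colnames(m), function(s) fitSpikeSlope(kept, s),
                   numeric(1))
  f <- colData(x)$capture_factor
  norm <- sweep(sweep(m, 2, slopes, `/`), 2, f, `*`)
  SummarizedExperiment::assay(x, "normalized") <- norm
  metadata(x)$spike_slopes <- slopes
  metadata(x)$spikes_retained <- kept$spike_id
  validObject(x)
  x
})

#' @rdname spikeinNormalize
#' @export
setMethod("spikeinNormalize", "data.frame",
          function(x, spikes, design, min_reads = 10,
                   min_sample_fraction = 0.75, ...) {
  kept <- filterSpikeins(spikes, min_reads, min_sample_fraction)
  samp <- .sampleColumns(x, c("gene_id", "biotype", "length_nt",
                              "is_spike"))
  i <- match(samp, design$sample_id)
  if (anyNA(i))
    stop("design is missing sample(s): ",
         paste(samp[is.na(i)], collapse = ", "))
  f <- design$capture_factor[i]
  slopes <- vapply(samp, function(s) fitSpikeSlope(kept, s), numeric(1))
  out <- x
  sp <- kept
  for (j in seq_along(samp)) {
    out[[samp[j]]] <- normalizeSample(x[[samp[j]]], slopes[j], f[j])
    sp[[samp[j]]] <- normalizeSample(kept[[samp[j]]], slopes[j], f[j])
  }
  list(normalized = out, slopes = slopes, spikes_normalized = sp)
})
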