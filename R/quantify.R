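#' Validate a read-assignment table
#'
#' Assignment tables are the post-alignment interchange format: one row
#' per (read, feature) assignment with columns `read_id`, `sample_id`,
#' `feature_id`, `n_locations` (number of loci the read maps to) and
#' `reference_tier` (0 = rRNA, 1 = tRNA, 2 = mitochondrial, 3 = ncRNA,
#' 4 = whole transcriptome; mapping is sequential, so a read belongs to
#' exactly one tier).
#'
#' @param assignments `data.frame` in assignment-table layout.
#' @return The table, invisibly, if valid; otherwise an error naming
#'   the offending reads.
#' @export
validateAssignments <- function(assignments) {
  need <- c("read_id", "sample_id", "feature_id", "n_locations",
            "reference_tier")
  if (!all(need %in% names(assignments)))
    stop("assignment table must contain columns: ",
         paste(need, collapse = ", "))
  if (any(assignments$n_locations < 1 |
          assignments$n_locations != round(assignments$n_locations)))
    stop("n_locations must be positive integers")
  key <- paste(assignments$read_id, assignments$sample_id, sep = "\r")
  tiers <- tapply(assignments$reference_tier, key,
                  function(x) length(unique(x)))
  if (any(tiers > 1L))
    stop("read(s) assigned to multiple reference tiers: ",
         paste(utils::head(sub("\r.*", "", names(tiers)[tiers > 1L]), 5),
               collapse = ", "))
  mult <- table(key)
  nl <- tapply(assignments$n_locations, key, unique)
  bad <- names(mult)[mult != unlist(nl[names(mult)])]
  if (length(bad))
    stop("n_locations inconsistent with row multiplicity for read(s): ",
         paste(utils::head(sub("\r.*", "", bad), 5), collapse = ", "))
  invisible(assignments)
}

#' Fractional multimapping read counting
#'
#' Each assignment row contributes `1 / n_locations` to its
#' (feature, sample) cell, so a uniquely mapped read adds 1 and a read
#' mapping to N loci adds 1/N to each. Per sample, fractional counts
#' sum exactly to the number of distinct reads.
#'
#' @param assignments Assignment table (see [validateAssignments()],
#'   which is applied first).
#' @param features Optional `data.frame` with `feature_id`, `biotype`,
#'   `length_nt` used to annotate the result; features absent from the
#'   assignments get zero rows only if listed here.
#' @return Count table `data.frame`: `gene_id`, `biotype`, `length_nt`,
#'   one fractional-count column per sample.
#' @export
fractionalCount <- function(assignments, features = NULL) {
  validateAssignments(assignments)
  feats <- if (is.null(features)) {
    data.frame(feature_id = sort(unique(assignments$feature_id)),
               biotype = NA_character_, length_nt = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("feature_id") %in% names(features)))
    if (!"biotype" %in% names(features)) features$biotype <- NA_character_
    if (!"length_nt" %in% names(features)) features$length_nt <- NA_real_
    features
  }
  samples <- sort(unique(assignments$sample_id))
  w <- 1 / assignments$n_locations
  m <- matrix(0, nrow(feats), length(samples),
              dimnames = list(feats$feature_id, samples))
  tab <- rowsum(w, group = paste(assignments$feature_id,
                                 assignments$sample_id, sep = "\r"))
  ij <- strsplit(rownames(tab), "\r", fixed = TRUE)
  fi <- match(vapply(ij, `[`, "", 1L), feats$feature_id)
  si <- match(vapply(ij, `[`, "", 2L), samples)
  if (anyNA(fi))
    stop("assignments contain features missing from 'features' table")
  m[cbind(fi, si)] <- tab[, 1L]
  data.frame(gene_id = feats$feature_id, biotype = feats$biotype,
             length_nt = feats$length_nt, as.data.frame(m),
             row.names = NULL, check.names = FALSE)
}

#' Merge sequentially mapped reference tiers, keeping the first
#'
#' Reads are mapped to references in a fixed order (rRNA, tRNA,
#' mitochondrial, ncRNA, whole transcriptome); genes annotated in more
#' than one reference keep only the row from the earliest tier in
#' which they appear, so no gene is double counted.
#'
#' @param per_tier_counts List of count tables (as from
#'   [fractionalCount()]), ordered by reference tier.
#' @return A single merged count table.
#' @export
mergeSequentialReferences <- function(per_tier_counts) {
  stopifnot(is.list(per_tier_counts), length(per_tier_counts) >= 1)
  cols <- lapply(per_tier_counts, names)
  if (length(unique(vapply(cols, paste, "", collapse = "\r"))) != 1L)
    stop("all tiers must share identical column layout")
  merged <- do.call(rbind, per_tier_counts)
  dup <- duplicated(merged$gene_id)
  if (any(dup)) {
    for (id in unique(merged$gene_id[dup])) {
      len <- unique(merged$length_nt[merged$gene_id == id])
      len <- len[!is.na(len)]
      if (length(len) > 1L)
        warning("conflicting lengths for '", id,
                "' across tiers; keeping earliest", call. = FALSE)
    }
  }
  out <- merged[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length normalization to reads per kilobase (RPK)
#'
#' Divides every sample column by `length_nt / 1000`. Used for the
#' fractionation libraries; the pulse-chase pipeline skips it
#' (`skip = TRUE` returns the input unchanged, keeping the call site
#' uniform).
#'
#' @param x A count table `data.frame` (interchange layout) or a
#'   [LysoExperiment].
#' @param skip If `TRUE`, return `x` unchanged.
#' @param ... Passed between methods.
#' @return Same shape as `x` with counts replaced by RPK values (for
#'   [LysoExperiment], adds an `"rpk"` assay instead).
#' @examples
#' tab <- data.frame(gene_id = "g", biotype = "mRNA", length_nt = 2000,
#'                   s1 = 100)
#' rpkNormalize(tab)$s1  # 50
#' @export
setGeneric("rpkNormalize", function(x, skip = FALSE, ...)
  standardGeneric("rpkNormalize"))

#' @rdname rpkNormalize
#' @export
setMethod("rpkNormalize", "data.frame", function(x, skip = FALSE, ...) {
  if (skip) return(x)
  bad <- is.na(x$length_nt) | x$length_nt <= 0
  if (any(bad))
    stop("zero/negative/missing length for gene(s): ",
         paste(utils::head(x$gene_id[bad], 10), collapse = ", "))
  samp <- .sampleColumns(x, c("gene_id", "biotype", "length_nt",
                              "is_spike"))
  x[samp] <- x[samp] / (x$length_nt / 1000)
  x
})

#' @rdname rpkNormalize
#' @export
setMethod("rpkNormalize", "LysoExperiment", function(x, skip = FALSE,
                                                     ...) {
  if (skip) return(x)
  len <- geneLengths(x)
  bad <- is.na(len) | len <= 0
  if (any(bad))
    stop("zero/negative/missing length for gene(s): ",
         paste(utils::head(names(len)[bad], 10), collapse = ", "))
  assay(x, "rpk") <- assay(x, "counts") / (len / 1000)
  x
})
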