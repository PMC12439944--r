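#' LysoExperiment: container for fractionation RNA-seq counts
#'
#' An S4 class extending [SummarizedExperiment::SummarizedExperiment]
#' that holds a genes-by-samples matrix of (possibly fractional) read
#' counts together with the per-gene annotation needed downstream
#' (`biotype`, `length_nt`, `is_spike` in `rowData`) and the sample
#' design (`genotype`, `treatment`, `fraction`, `replicate`,
#' `capture_factor` in `colData`). The first assay is `"counts"`;
#' normalization adds further assays (`"rpk"`, `"normalized"`) without
#' touching the raw counts.
#'
#' `fraction` takes the values `"whole_cell"`, `"lyso"` or `"mock"`;
#' `capture_factor` is the per-sample multiplier correcting lysosomal
#' capture efficiency and input dilution (applied after spike-slope
#' division).
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [lysoExperiment()] for construction, [spikeinNormalize()],
#'   [lysosomalEnrichment()]
#' @export
setClass("LysoExperiment", contains = "SummarizedExperiment")

.FRACTIONS <- c("whole_cell", "lyso", "mock")

setValidity("LysoExperiment", function(object) {
  msg <- character()
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "rownames (gene ids) must be present and unique")
  rd <- rowData(object)
  for (col in c("biotype", "length_nt"))
    if (!col %in% names(rd))
      msg <- c(msg, sprintf("rowData must contain '%s'", col))
  if ("length_nt" %in% names(rd)) {
    len <- rd$length_nt
    if (any(!is.na(len) & len <= 0))
      msg <- c(msg, "length_nt must be positive where defined")
  }
  cd <- colData(object)
  if ("fraction" %in% names(cd) &&
      !all(cd$fraction %in% .FRACTIONS))
    msg <- c(msg, sprintf("fraction must be one of %s",
                          paste(.FRACTIONS, collapse = "/")))
  if ("capture_factor" %in% names(cd) &&
      any(!is.na(cd$capture_factor) & cd$capture_factor <= 0))
    msg <- c(msg, "capture_factor must be positive")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "first assay must be named 'counts'")
  if (length(msg)) msg else TRUE
})

#' Construct a LysoExperiment
#'
#' @param counts Numeric genes-by-samples matrix (fractional counts
#'   allowed) with rownames (gene ids) and colnames (sample ids).
#' @param biotype Character vector of per-gene biotypes/classes.
#' @param length_nt Numeric vector of feature lengths in nucleotides.
#' @param design Optional `data.frame` of sample metadata, one row per
#'   column of `counts`; matched by its `sample_id` column if present,
#'   otherwise by row order.
#' @param is_spike Logical vector flagging spike-in rows (default all
#'   `FALSE`).
#' @return A [LysoExperiment] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' lysoExperiment(m, biotype = c("mRNA", "tRNA"), length_nt = c(1000, 75))
#' @export
lysoExperiment <- function(counts, biotype = NA_character_,
                           length_nt = NA_real_, design = NULL,
                           is_spike = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  rd <- DataFrame(biotype = rep_len(as.character(biotype), n),
                  length_nt = rep_len(as.numeric(length_nt), n),
                  is_spike = rep_len(as.logical(is_spike), n),
                  row.names = rownames(counts))
  cd <- if (is.null(design)) {
    DataFrame(row.names = colnames(counts))
  } else {
    design <- as.data.frame(design)
    if ("sample_id" %in% names(design)) {
      i <- match(colnames(counts), design$sample_id)
      if (anyNA(i))
        stop("design is missing samples: ",
             paste(colnames(counts)[is.na(i)], collapse = ", "))
      design <- design[i, , drop = FALSE]
    } else if (nrow(design) != ncol(counts)) {
      stop("design must have one row per sample")
    }
    DataFrame(design, row.names = colnames(counts))
  }
  new("LysoExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rd, colData = cd))
}

#' Accessors for LysoExperiment annotation
#'
#' @param object A [LysoExperiment].
#' @return `geneLengths`: numeric vector of lengths (nt); `biotypes`:
#'   character vector; `isSpike`: logical vector; `sampleDesign`: the
#'   sample table as a base `data.frame` with a `sample_id` column.
#' @name lysoAccessors
NULL

#' @rdname lysoAccessors
#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))

#' @rdname lysoAccessors
#' @export
setMethod("geneLengths", "LysoExperiment", function(object)
  setNames(rowData(object)$length_nt, rownames(object)))

#' @rdname lysoAccessors
#' @export
setGeneric("biotypes", function(object) standardGeneric("biotypes"))

#' @rdname lysoAccessors
#' @export
setMethod("biotypes", "LysoExperiment", function(object)
  setNames(rowData(object)$biotype, rownames(object)))

#' @rdname lysoAccessors
#' @export
setGeneric("isSpike", function(object) standardGeneric("isSpike"))

#' @rdname lysoAccessors
#' @export
setMethod("isSpike", "LysoExperiment", function(object)
  setNames(rowData(object)$is_spike, rownames(object)))

#' @rdname lysoAccessors
#' @export
setGeneric("sampleDesign", function(object) standardGeneric("sampleDesign"))

#' @rdname lysoAccessors
#' @export
setMethod("sampleDesign", "LysoExperiment", function(object) {
  cd <- as.data.frame(colData(object))
  data.frame(sample_id = colnames(object), cd, row.names = NULL,
             check.names = FALSE)
})

setMethod("show", "LysoExperiment", function(object) {
  cat("LysoExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  bt <- table(rowData(object)$biotype, useNA = "no")
  if (length(bt))
    cat("  biotypes:", paste(sprintf("%s(%d)", names(bt), bt),
                             collapse = " "), "\n")
  if (any(rowData(object)$is_spike))
    cat("  spike-in rows:", sum(rowData(object)$is_spike), "\n")
  cd <- colData(object)
  if ("fraction" %in% names(cd)) {
    fr <- table(cd$fraction)
    cat("  fractions:", paste(sprintf("%s(%d)", names(fr), fr),
                              collapse = " "), "\n")
  }
})

#' Convert between LysoExperiment and the on-disk count-table layout
#'
#' The TSV interchange layout is `gene_id`, `biotype`, `length_nt`,
#' then one numeric column per sample.
#'
#' @param object A [LysoExperiment] (for `asCountTable`) or a count
#'   `data.frame` in interchange layout (for `countTableToLyso`).
#' @param assay Name of the assay to export.
#' @param design Optional design `data.frame` passed to
#'   [lysoExperiment()].
#' @return `asCountTable`: a `data.frame`; `countTableToLyso`: a
#'   [LysoExperiment].
#' @export
asCountTable <- function(object, assay = "counts") {
  stopifnot(is(object, "LysoExperiment"))
  data.frame(gene_id = rownames(object),
             biotype = rowData(object)$biotype,
             length_nt = rowData(object)$length_nt,
             as.data.frame(assay(object, assay)),
             row.names = NULL, check.names = FALSE)
}

#' @rdname asCountTable
#' @export
countTableToLyso <- function(object, design = NULL) {
  need <- c("gene_id", "biotype", "length_nt")
  if (!all(need %in% names(object)))
    stop("count table must contain columns: ", paste(need, collapse = ", "))
  samp <- .sampleColumns(object, c(need, "is_spike"))
  m <- as.matrix(object[, samp, drop = FALSE])
  rownames(m) <- object$gene_id
  lysoExperiment(m, biotype = object$biotype,
                 length_nt = object$length_nt, design = design,
                 is_spike = if ("is_spike" %in% names(object))
                   object$is_spike else FALSE)
}
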