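#' Largest-remainder integer allocation
#'
#' Splits `n` items across groups proportionally to `proportions`,
#' rounding with the largest-remainder (Hamilton) rule so the allocated
#' counts always sum to `n` exactly. Ties in fractional remainder are
#' broken deterministically by group name (ascending).
#'
#' @param n Total number of items (nonnegative integer).
#' @param proportions Named numeric vector of nonnegative fractions
#'   summing to 1 (within 1e-9).
#' @return Named integer vector of allocated counts summing to `n`.
#' @examples
#' largestRemainder(10, c(a = 0.55, b = 0.25, c = 0.2))
#' @export
largestRemainder <- function(n, proportions) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  if (is.null(names(proportions)) || anyDuplicated(names(proportions)))
    stop("'proportions' must have unique names")
  if (any(proportions < 0))
    stop("'proportions' must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("'proportions' must sum to 1 (got ", format(sum(proportions)), ")")
  quota <- n * proportions
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0L) {
    frac <- quota - base
    ord <- order(-frac, names(proportions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(proportions)
  out
}

## Kyte-Doolittle hydropathicity of the amino acid carried by a tRNA.
KD_HYDROPATHICITY <- c(
  Ala =  1.8, Arg = -4.5, Asn = -3.5, Asp = -3.5, Cys =  2.5,
  Gln = -3.5, Glu = -3.5, Gly = -0.4, His = -3.2, Ile =  4.5,
  Leu =  3.8, Lys = -3.9, Met =  1.9, Phe =  2.8, Pro = -1.6,
  Ser = -0.8, Thr = -0.7, Trp = -0.9, Tyr = -1.3, Val =  4.2
)

## Identify the numeric per-sample columns of a tabular count/spike table.
.sampleColumns <- function(df, exclude) {
  setdiff(names(df), exclude)
}

.assertFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  invisible(path)
}

#' Read / write the package's tab-separated tables
#'
#' All on-disk interchange is plain TSV: header row, tab delimiter,
#' '.' decimal, UTF-8, LF newlines, no quoting, no row names.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `readTsv` returns a `data.frame`; `writeTsv` returns `path`
#'   invisibly.
#' @export
readTsv <- function(path) {
  .assertFile(path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @rdname readTsv
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8",
              eol = "\n")
  invisible(path)
}
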