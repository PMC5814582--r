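# Internal helpers shared across modules.

#' @importFrom stats median rbinom rnorm runif setNames aggregate
#' @importFrom utils write.table read.table head tail
NULL

siteKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## lower median: for even n the smaller of the two central values
lowerMedian <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

## deterministic, locale-independent TSV writer
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## collapse / expand sample-id sets for serialization
collapseIds <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))
expandIds <- function(x) strsplit(x, ",", fixed = TRUE)
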