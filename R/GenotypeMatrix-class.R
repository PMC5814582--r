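#' GenotypeMatrix: sites-by-samples diploid genotype codes
#'
#' Container shared by the concordance, imputation, LD and heterozygosity
#' analyses. Genotypes are unphased diploid codes: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternative, NA = missing. Rows are sites
#' keyed by (chrom, pos, ref, alt); columns are samples.
#'
#' @slot geno integer matrix of codes (sites x samples), NA = missing.
#' @slot sites data.frame with columns chrom, pos, ref, alt (one row per site,
#'   same order as \code{geno} rows).
#' @slot provenance character scalar: one of "wgs", "array", "gbs", "imputed",
#'   or "synthetic".
#'
#' @export
setClass("GenotypeMatrix",
  representation(geno = "matrix", sites = "data.frame", provenance = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  g <- object@geno
  s <- object@sites
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(s)))
    msg <- c(msg, "sites must have columns chrom, pos, ref, alt")
  if (nrow(s) != nrow(g))
    msg <- c(msg, "nrow(sites) must equal nrow(geno)")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msg <- c(msg, "geno must have unique sample ids as colnames")
  keys <- siteKey(s$chrom, s$pos, s$ref, s$alt)
  if (anyDuplicated(keys))
    msg <- c(msg, "site keys (chrom,pos,ref,alt) must be unique")
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param geno numeric/integer matrix of codes 0/1/2/NA, samples as colnames.
#' @param sites data.frame with chrom, pos, ref, alt.
#' @param provenance data source tag ("wgs", "array", "gbs", "imputed",
#'   "synthetic").
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(geno, sites, provenance = "wgs") {
  storage.mode(geno) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  rownames(geno) <- siteKey(sites$chrom, sites$pos, sites$ref, sites$alt)
  rownames(sites) <- NULL
  new("GenotypeMatrix", geno = geno, sites = sites, provenance = provenance)
}

#' @describeIn GenotypeMatrix-class genotype code matrix
#' @param x a GenotypeMatrix
#' @export
genoCodes <- function(x) x@geno

#' @describeIn GenotypeMatrix-class site table (chrom, pos, ref, alt)
#' @export
siteInfo <- function(x) x@sites

#' @describeIn GenotypeMatrix-class site keys ("chrom:pos:ref:alt")
#' @export
siteKeys <- function(x) rownames(x@geno)

#' @describeIn GenotypeMatrix-class sample identifiers
#' @export
sampleIds <- function(x) colnames(x@geno)

#' @describeIn GenotypeMatrix-class data-source tag
#' @export
provenance <- function(x) x@provenance

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@geno
  het <- mean(g == 1L, na.rm = TRUE)
  mis <- mean(is.na(g))
  cat(sprintf("GenotypeMatrix [%s]: %d sites x %d samples (het %.2f%%, missing %.2f%%)\n",
              object@provenance, nrow(g), ncol(g), 100 * het, 100 * mis))
})

#' Subset a GenotypeMatrix by site and/or sample
#'
#' @param x GenotypeMatrix.
#' @param i site index (logical/integer/character keys).
#' @param j sample index.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  if (is.character(i)) i <- match(i, rownames(x@geno))
  g <- x@geno[i, j, drop = FALSE]
  new("GenotypeMatrix", geno = g, sites = x@sites[i, , drop = FALSE],
      provenance = x@provenance)
})
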