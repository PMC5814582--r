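## VCF 4.2 and tab-delimited genotype I/O for nucleotide variants.

GT_TO_CODE <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "./." = NA_integer_, "." = NA_integer_)

codeToGt <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Write a multi-sample VCF 4.2 of nucleotide variants
#'
#' Site QC fields (QUAL; INFO MQ, DP and per-allele strand support SAF/SAR)
#' are taken from \code{qc}; absent fields are written as missing.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @param qc optional data.frame with columns qual, mq, depth, saf_ref,
#'   sar_ref, saf_alt, sar_alt (one row per site).
#' @param contigs optional named vector of chromosome lengths for the header.
#' @param header_lines extra header lines to preserve (e.g. from an input
#'   file), written verbatim before the column header.
#' @param provenance_line optional "##..." line recording how the file was
#'   produced.
#' @return The path, invisibly.
#' @export
writeVariantVcf <- function(gm, path, qc = NULL, contigs = NULL,
                            header_lines = NULL, provenance_line = NULL) {
  s <- siteInfo(gm)
  g <- genoCodes(gm)
  n_sites <- nrow(s)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=inbredvar")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr,
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=DP,Number=1,Type=Float,Description="Mean read depth">',
    '##INFO=<ID=SAF,Number=R,Type=Integer,Description="Forward-strand read support per allele">',
    '##INFO=<ID=SAR,Number=R,Type=Integer,Description="Reverse-strand read support per allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(header_lines)) hdr <- c(hdr, header_lines)
  if (!is.null(provenance_line)) hdr <- c(hdr, provenance_line)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  if (is.null(qc)) {
    qual <- rep(".", n_sites)
    info <- rep(".", n_sites)
  } else {
    qual <- format(qc$qual, trim = TRUE, scientific = FALSE)
    info <- sprintf("MQ=%s;DP=%s;SAF=%d,%d;SAR=%d,%d",
                    format(qc$mq, trim = TRUE, scientific = FALSE),
                    format(qc$depth, trim = TRUE, scientific = FALSE),
                    qc$saf_ref, qc$saf_alt, qc$sar_ref, qc$sar_alt)
  }
  gt <- apply(g, 2, codeToGt)
  if (n_sites == 1L) gt <- matrix(gt, nrow = 1L)
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, qual, ".", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF of nucleotide variants
#'
#' Parses genotypes into code 0/1/2/NA and derives the per-record fields the
#' site filters need: allele count, variant class (SNP/MNP/indel by allele
#' lengths), QUAL, MQ, depth and whether every called allele has read support
#' on both strands.
#'
#' @param path VCF file (plain or bgzipped).
#' @param strand_fields INFO keys holding per-allele forward/reverse read
#'   support counts (Number=R convention: reference allele first).
#' @return list with elements \code{variants} (data.frame: chrom, pos, ref,
#'   alt, n_alleles, variant_class, qual, mq, depth, both_strands, maf) and
#'   \code{genotypes} (a \linkS4class{GenotypeMatrix}; genotypes that
#'   reference alleles beyond the first alternative are set missing).
#' @export
readVariantVcf <- function(path, strand_fields = c("SAF", "SAR")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  mq <- suppressWarnings(vcfR::extract.info(v, "MQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
  saf <- vcfR::extract.info(v, strand_fields[1])
  sar <- vcfR::extract.info(v, strand_fields[2])

  gt <- vcfR::extract.gt(v, element = "GT")
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(GT_TO_CODE[gt], nrow = nrow(gt),
                  dimnames = dimnames(gt))
  ## genotypes referencing alleles >1 are not representable as 0/1/2
  codes[!is.na(gt) & !(gt %in% names(GT_TO_CODE))] <- NA_integer_

  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n_alleles <- 1L + lengths(alt_list)
  variant_class <- vapply(seq_along(ref), function(i) {
    rl <- nchar(ref[i]); al <- nchar(alt_list[[i]])
    if (any(al != rl)) "indel" else if (rl == 1L) "SNP" else "MNP"
  }, character(1))

  ## called alleles per record (from all genotype strings)
  both_strands <- vapply(seq_along(ref), function(i) {
    gts <- gt[i, ]
    alleles <- unique(unlist(strsplit(gts[!is.na(gts)], "/", fixed = TRUE)))
    alleles <- suppressWarnings(as.integer(alleles[alleles != "."]))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) return(NA)
    f <- suppressWarnings(as.integer(strsplit(saf[i], ",")[[1]]))
    r <- suppressWarnings(as.integer(strsplit(sar[i], ",")[[1]]))
    if (!length(f) || !length(r) || anyNA(f) || anyNA(r)) return(NA)
    all(alleles + 1L <= length(f)) &&
      all(f[alleles + 1L] > 0L & r[alleles + 1L] > 0L)
  }, logical(1))

  maf <- apply(codes, 1, function(z) {
    if (all(is.na(z))) NA_real_ else computeMaf(z)
  })

  variants <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    n_alleles = n_alleles, variant_class = variant_class,
    qual = qual, mq = mq, depth = dp, both_strands = both_strands,
    maf = maf, stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(codes, variants[, c("chrom", "pos", "ref", "alt")],
                       provenance = "wgs")
  list(variants = variants, genotypes = gm)
}

#' Write an array-genotype table (site x sample, tab-delimited)
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeArrayTable <- function(gm, path) {
  s <- siteInfo(gm)
  g <- genoCodes(gm)
  df <- data.frame(site_id = siteKeys(gm), chrom = s$chrom, pos = s$pos,
                   ref = s$ref, alt = s$alt, stringsAsFactors = FALSE)
  for (smp in colnames(g)) df[[smp]] <- codeToGt(g[, smp])
  writeTsv(df, path)
}

#' Read an array-genotype table written by \code{\link{writeArrayTable}}
#'
#' @param path tab-delimited table with columns site_id, chrom, pos, ref,
#'   alt, then one genotype column per sample.
#' @param provenance provenance tag for the result.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readArrayTable <- function(path, provenance = "array") {
  df <- readTsv(path)
  fixed <- c("site_id", "chrom", "pos", "ref", "alt")
  samples <- setdiff(names(df), fixed)
  codes <- vapply(samples, function(smp) GT_TO_CODE[df[[smp]]],
                  integer(nrow(df)))
  if (nrow(df) == 1L) codes <- matrix(codes, nrow = 1L,
                                      dimnames = list(NULL, samples))
  GenotypeMatrix(codes, df[, c("chrom", "pos", "ref", "alt")],
                 provenance = provenance)
}

#' Read per-sample BED-graph depth tracks
#'
#' @param files character vector of BED-graph files, named by sample id.
#' @return data.frame with columns sample, chrom, start, end, depth
#'   (0-based half-open windows).
#' @export
readDepthTracks <- function(files) {
  if (is.null(names(files)) || any(names(files) == ""))
    stop("files must be named by sample id")
  out <- lapply(names(files), function(s) {
    d <- read.table(files[[s]], sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "depth"),
                    stringsAsFactors = FALSE)
    cbind(sample = s, d, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
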