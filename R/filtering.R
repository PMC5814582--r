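#' Minor allele frequency from genotype codes
#'
#' Minor-allele count divided by total called allele count; missing genotypes
#' are excluded from the denominator. For diploid codes the allele counts are
#' 2 x hom + het.
#'
#' @param codes integer vector of genotype codes (0/1/2, NA missing).
#' @return Fraction in [0, 0.5].
#' @export
computeMaf <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("MAF undefined: all genotypes missing")
  total <- 2L * length(codes)
  alt <- sum(codes)
  min(alt, total - alt) / total
}

#' Assign a MAF to one of five frequency bins
#'
#' Bins are [0,0.1), [0.1,0.2), [0.2,0.3), [0.3,0.4), [0.4,0.5] —
#' left-closed, right-open, except the final bin which is closed at 0.5.
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @return Integer bin index 1..5.
#' @export
mafBin <- function(maf) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("MAF must be in [0, 0.5]")
  findInterval(maf, c(0.1, 0.2, 0.3, 0.4)) + 1L
}

#' Site filter thresholds
#'
#' Defaults follow the removal rules: more than two alleles; an allele not
#' supported by reads on both strands; QUAL < 32; MQ < 20; read depth < 2;
#' MAF < 0.02. The stated removals are strict inequalities, so retention is
#' inclusive at the thresholds.
#'
#' @param max_alleles,min_qual,min_mq,min_depth,min_maf thresholds.
#' @param require_both_strands logical.
#' @return A named list of class \code{FilterConfig}.
#' @export
filterConfig <- function(max_alleles = 2L, require_both_strands = TRUE,
                         min_qual = 32, min_mq = 20, min_depth = 2,
                         min_maf = 0.02) {
  stopifnot(max_alleles >= 1, min_qual >= 0, min_mq >= 0, min_depth >= 0,
            min_maf >= 0)
  structure(list(max_alleles = max_alleles,
                 require_both_strands = require_both_strands,
                 min_qual = min_qual, min_mq = min_mq,
                 min_depth = min_depth, min_maf = min_maf),
            class = "FilterConfig")
}

FILTER_RULES <- c("max_alleles", "strand", "qual", "mq", "depth", "maf")

#' Apply the six nucleotide-variant site filters
#'
#' A record is retained iff it has at most two alleles AND every called
#' allele has forward and reverse read support AND QUAL >= min_qual AND
#' MQ >= min_mq AND depth >= min_depth AND MAF >= min_maf. The removal tally
#' reports the first failing rule per removed record, in the order
#' max_alleles, strand, qual, mq, depth, maf.
#'
#' Depth is site-level mean read depth by default. With
#' \code{depth_mode = "sample"} per-sample depths (a sites-x-samples matrix
#' in \code{sample_depth}) are screened instead: genotypes below the
#' threshold are treated as missing and the site-level rule passes when at
#' least one genotype survives; MAF is then recomputed on the surviving
#' genotypes.
#'
#' @param variants data.frame as returned by \code{\link{readVariantVcf}}
#'   (columns n_alleles, both_strands, qual, mq, depth, maf).
#' @param cfg a \code{\link{filterConfig}}.
#' @param depth_mode "site" (default) or "sample".
#' @param sample_depth optional per-sample depth matrix (sample mode).
#' @param genotypes optional \linkS4class{GenotypeMatrix} (sample mode MAF
#'   recomputation).
#' @return list with \code{retained} (data.frame), \code{removed}
#'   (data.frame with a \code{rule} column), and \code{tally} (named integer
#'   vector over the six rules).
#' @export
applySiteFilters <- function(variants, cfg = filterConfig(),
                             depth_mode = c("site", "sample"),
                             sample_depth = NULL, genotypes = NULL) {
  depth_mode <- match.arg(depth_mode)
  need <- c("n_alleles", "both_strands", "qual", "mq", "depth", "maf")
  for (f in need) {
    if (!(f %in% names(variants)))
      stop("variants table is missing QC field '", f, "'")
  }
  n <- nrow(variants)
  maf <- variants$maf
  depth_ok <- variants$depth >= cfg$min_depth
  if (depth_mode == "sample") {
    if (is.null(sample_depth) || is.null(genotypes))
      stop("sample depth mode needs sample_depth and genotypes")
    g <- genoCodes(genotypes)
    g[sample_depth < cfg$min_depth] <- NA_integer_
    keep_any <- rowSums(!is.na(g)) > 0
    maf <- ifelse(keep_any, apply(g, 1, function(z)
      if (all(is.na(z))) NA_real_ else computeMaf(z)), NA_real_)
    depth_ok <- keep_any
  }
  na_false <- function(x) !is.na(x) & x
  pass <- cbind(
    max_alleles = variants$n_alleles <= cfg$max_alleles,
    strand = if (cfg$require_both_strands) na_false(variants$both_strands)
             else rep(TRUE, n),
    qual = na_false(variants$qual >= cfg$min_qual),
    mq = na_false(variants$mq >= cfg$min_mq),
    depth = na_false(depth_ok),
    maf = na_false(maf >= cfg$min_maf))
  first_fail <- apply(pass, 1, function(z) {
    w <- which(!z)
    if (length(w)) FILTER_RULES[w[1]] else NA_character_
  })
  retained <- variants[is.na(first_fail), , drop = FALSE]
  removed <- variants[!is.na(first_fail), , drop = FALSE]
  removed$rule <- first_fail[!is.na(first_fail)]
  tally <- setNames(integer(length(FILTER_RULES)), FILTER_RULES)
  tb <- table(removed$rule)
  tally[names(tb)] <- as.integer(tb)
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed, tally = tally)
}

#' Write the per-rule removal tally as TSV
#'
#' @param tally named integer vector from \code{\link{applySiteFilters}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeFilterTally <- function(tally, path) {
  writeTsv(data.frame(rule = names(tally), removed = as.integer(tally)), path)
}
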