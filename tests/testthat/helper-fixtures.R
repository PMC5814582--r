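# Shared fixtures, built once per test run.

# small default-style cohort used by several test files
sharedCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- syntheticSpec(
        seed = 11, n_samples = 40, n_snp_sites = 400, n_genes = 10,
        chrom_length = 5e5,
        sv_truth_counts = c(DEL = 30, INS = 10, DUP = 5, INV = 5, CNV = 4,
                            TRA_intra = 3, TRA_inter = 2))
      cache <<- generateCohort(spec, file.path(tempdir(), "shared_cohort"))
    }
    cache
  }
})

# genotype matrix with inbred codes from explicit haplotype carrier sets
gmFromCarriers <- function(carrier_list, n_samples, chrom = "Chr01",
                           pos = NULL) {
  n_sites <- length(carrier_list)
  if (is.null(pos)) pos <- seq_len(n_sites) * 1000L
  g <- matrix(0L, n_sites, n_samples,
              dimnames = list(NULL, sprintf("S%03d", seq_len(n_samples))))
  for (i in seq_len(n_sites)) g[i, carrier_list[[i]]] <- 2L
  GenotypeMatrix(g, data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                               stringsAsFactors = FALSE), "wgs")
}

# a single-exon forward-strand toy gene plus its reference chromosome
toyGene <- function(cds, promoter = 100L, strand = "+", chrom = "ChrT") {
  stopifnot(nchar(cds) %% 3 == 0)
  upstream <- paste(rep("C", promoter), collapse = "")
  downstream <- paste(rep("G", promoter), collapse = "")
  if (strand == "-") {
    body <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  } else body <- cds
  ref <- Biostrings::DNAStringSet(paste0(upstream, body, downstream))
  names(ref) <- chrom
  start <- promoter + 1L
  end <- promoter + nchar(cds)
  df <- data.frame(gene_id = "toy1", chrom = chrom, strand = strand,
                   start = start, end = end, stringsAsFactors = FALSE)
  ex <- cbind(df[, c("gene_id", "chrom", "strand", "start", "end")], rank = 1L)
  list(genes = GeneModelSet(df, ex, ex), ref = ref, start = start, end = end)
}

# independent translation oracle: codon-by-codon lookup table
oracleTranslate <- function(nt) {
  codons <- substring(paste(nt, collapse = ""),
                      seq(1, length(nt) - 2, 3), seq(3, length(nt), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# build an SV call data.frame row
svCall <- function(id, caller, type, chrom, start, end, chrom2 = chrom,
                   length = end - start, gq = 60, pe = 30, rd = NA,
                   gr = NA, cf = NA, carriers = "") {
  data.frame(id = id, caller = caller, sv_type = type, chrom = chrom,
             start = start, end = end, chrom2 = chrom2, length = length,
             gq = gq, pe = pe, rd_ratio = rd, genotyped_ratio = gr,
             carrier_pair_fraction = cf, carriers = carriers,
             stringsAsFactors = FALSE)
}
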