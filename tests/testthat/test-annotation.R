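# Genomic-context and functional-impact classification.

test_that("context labels follow the stated precedence", {
  # two-exon gene at 10000..12000: exons 10000-10800 and 11500-12000
  gdf <- data.frame(gene_id = "gC", chrom = "ChrC", strand = "+",
                    start = 10000L, end = 12000L, stringsAsFactors = FALSE)
  ex <- data.frame(gene_id = "gC", chrom = "ChrC", strand = "+",
                   start = c(10000L, 11500L), end = c(10800L, 12000L),
                   rank = 1:2, stringsAsFactors = FALSE)
  genes <- GeneModelSet(gdf, ex, ex)
  v <- data.frame(chrom = "ChrC",
                  pos = c(10500L,  # inside an exon
                          5001L,   # 4999 bp 5' of the gene: flank boundary
                          4999L,   # just beyond the 5-kb flank
                          11000L,  # mid-intron
                          10801L,  # first intron bp: splice donor side
                          11499L,  # last intron bp: splice acceptor side
                          17000L,  # 5000 bp past the gene end
                          17001L), # beyond the 3' flank
                  stringsAsFactors = FALSE)
  ctx <- as.character(classifyContext(v, genes))
  expect_equal(ctx, c("exonic", "up_downstream", "intergenic", "intronic",
                      "splice_site", "splice_site", "up_downstream",
                      "intergenic"))
  expect_error(classifyContext(data.frame(chrom = "ChrC", pos = 30000L),
                               genes, chrom_lengths = c(ChrC = 20000)),
               "bounds")
})

test_that("context labels equal a brute-force per-position scan", {
  ts <- sharedCohort()
  genes <- ts$gene_models
  g <- geneTable(genes)
  ex <- exonTable(genes)
  set.seed(21)
  v <- data.frame(chrom = sample(names(ts$chrom_lengths), 1000, TRUE),
                  pos = sample.int(min(ts$chrom_lengths), 1000),
                  stringsAsFactors = FALSE)
  ctx <- as.character(classifyContext(v, genes))
  oracle <- vapply(seq_len(nrow(v)), function(i) {
    ch <- v$chrom[i]; p <- v$pos[i]
    lab <- "intergenic"
    for (k in seq_len(nrow(g))) {
      if (g$chrom[k] != ch) next
      if (p >= g$start[k] - 5000 && p <= g$end[k] + 5000 &&
          lab == "intergenic") lab <- "up_downstream"
      if (p >= g$start[k] && p <= g$end[k]) {
        exk <- ex[ex$gene_id == g$gene_id[k], , drop = FALSE]
        in_exon <- any(p >= exk$start & p <= exk$end)
        lab2 <- if (in_exon) "exonic" else "intronic"
        exk <- exk[order(exk$start), ]
        if (nrow(exk) > 1) {
          istart <- exk$end[-nrow(exk)] + 1; iend <- exk$start[-1] - 1
          near <- any((p >= istart & p <= pmin(istart + 1, iend)) |
                        (p >= pmax(iend - 1, istart) & p <= iend))
          if (near) lab2 <- "splice_site"
        }
        pri <- c(splice_site = 1, exonic = 2, intronic = 3,
                 up_downstream = 4, intergenic = 5)
        if (pri[lab2] < pri[lab]) lab <- lab2
      }
    }
    lab
  }, character(1))
  expect_equal(ctx, oracle)
})

test_that("CDS indels and canonical splice variants classify by rule", {
  toy <- toyGene(paste0("ATG", strrep("GCT", 8), "TAA"))
  del <- data.frame(chrom = "ChrT", pos = toy$start + 4L, ref = "CT",
                    alt = "C", stringsAsFactors = FALSE)
  expect_equal(classifyImpact(del, "toy1", toy$genes, toy$ref)$effect,
               "frameshift")
  del3 <- data.frame(chrom = "ChrT", pos = toy$start + 3L, ref = "TGCT",
                     alt = "T", stringsAsFactors = FALSE)
  res3 <- classifyImpact(del3, "toy1", toy$genes, toy$ref)
  expect_equal(res3$effect, "inframe_indel")
  expect_equal(res3$impact, "moderate")
})

test_that("splice-site variants are donor/acceptor by strand", {
  # two-exon gene: exon1 30 bp, intron 20 bp, exon2 30 bp
  cds <- paste0("ATG", strrep("GCT", 18), "TAA")
  ref_nt <- paste0(strrep("C", 50), substr(cds, 1, 30), strrep("A", 20),
                   substr(cds, 31, 60), strrep("C", 50))
  ref <- Biostrings::DNAStringSet(ref_nt); names(ref) <- "ChrT"
  gdf <- data.frame(gene_id = "g2", chrom = "ChrT", strand = "+",
                    start = 51L, end = 130L, stringsAsFactors = FALSE)
  ex <- data.frame(gene_id = "g2", chrom = "ChrT", strand = "+",
                   start = c(51L, 101L), end = c(80L, 130L), rank = 1:2,
                   stringsAsFactors = FALSE)
  genes <- GeneModelSet(gdf, ex, ex)
  donor <- data.frame(chrom = "ChrT", pos = 81L, ref = "A", alt = "G")
  acceptor <- data.frame(chrom = "ChrT", pos = 100L, ref = "A", alt = "G")
  expect_equal(classifyImpact(donor, "g2", genes, ref)$effect, "splice_donor")
  expect_equal(classifyImpact(acceptor, "g2", genes, ref)$effect,
               "splice_acceptor")
  expect_equal(classifyImpact(donor, "g2", genes, ref)$impact, "high")
  # minus strand: same positions swap roles
  gdf$strand <- ex$strand <- "-"
  genes_m <- GeneModelSet(gdf, ex, ex)
  expect_equal(classifyImpact(donor, "g2", genes_m, ref)$effect,
               "splice_acceptor")
})

test_that("every SNP across a toy CDS matches a retranslation oracle", {
  for (strand in c("+", "-")) {
    cds <- paste0("ATG",
                  "GCTCGTAATGATTGCGAGGGGCATATTAAGCTGATGTTCCCGAGTACGTGG",
                  "TATGTC", strrep("GAA", 40), "TGA")
    stopifnot(nchar(cds) %% 3 == 0)
    toy <- toyGene(cds, strand = strand)
    ref_chr <- strsplit(as.character(toy$ref[[1]]), "")[[1]]
    p_ref <- oracleTranslate(strsplit(cds, "")[[1]])
    results <- character(0); oracle <- character(0)
    for (p in toy$start:toy$end) {
      for (alt in setdiff(c("A", "C", "G", "T"), ref_chr[p])) {
        v <- data.frame(chrom = "ChrT", pos = p, ref = ref_chr[p], alt = alt,
                        stringsAsFactors = FALSE)
        results <- c(results,
                     classifyImpact(v, "toy1", toy$genes, toy$ref)$effect)
        ## oracle: rebuild the mutated chromosome, re-extract the CDS
        mut_chr <- ref_chr; mut_chr[p] <- alt
        cds_nt <- mut_chr[toy$start:toy$end]
        if (strand == "-") cds_nt <- rev(chartr("ACGT", "TGCA", cds_nt))
        p_mut <- oracleTranslate(cds_nt)
        pr <- strsplit(p_ref, "")[[1]]; pm <- strsplit(p_mut, "")[[1]]
        ch <- which(pr != pm)
        oracle <- c(oracle, if (!length(ch)) "synonymous"
          else if (1 %in% ch && pr[1] == "M") "start_lost"
          else if (any(pr[ch] == "*")) "stop_lost"
          else if (any(pm[ch] == "*")) "stop_gained"
          else "missense")
      }
    }
    expect_equal(results, oracle, info = paste("strand", strand))
    expect_true(all(c("synonymous", "missense", "stop_gained", "start_lost",
                      "stop_lost") %in% unique(results)))
  }
})

test_that("mirrored forward/reverse genes give identical effects", {
  cds <- paste0("ATG", strrep("CGT", 10), "TAA")
  fwd <- toyGene(cds, strand = "+")
  rev_ <- toyGene(cds, strand = "-")
  ref_f <- strsplit(as.character(fwd$ref[[1]]), "")[[1]]
  ref_r <- strsplit(as.character(rev_$ref[[1]]), "")[[1]]
  L <- nchar(cds)
  for (off in c(0L, 4L, 7L, L - 1L)) {
    pf <- fwd$start + off
    pr <- rev_$end - off # mirrored position
    alt_f <- setdiff(c("A", "C", "G", "T"), ref_f[pf])[1]
    alt_r <- chartr("ACGT", "TGCA", alt_f)
    ef <- classifyImpact(data.frame(chrom = "ChrT", pos = pf,
                                    ref = ref_f[pf], alt = alt_f),
                         "toy1", fwd$genes, fwd$ref)$effect
    er <- classifyImpact(data.frame(chrom = "ChrT", pos = pr,
                                    ref = ref_r[pr], alt = alt_r),
                         "toy1", rev_$genes, rev_$ref)$effect
    expect_equal(ef, er)
  }
})

test_that("summary spectra recover planted counts and handle empty input", {
  ann <- data.frame(
    chrom = "Chr01", pos = 1:8, ref = "A", alt = "T",
    context = factor(rep("exonic", 8),
                     levels = c("splice_site", "exonic", "intronic",
                                "up_downstream", "intergenic")),
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g4", "g5", "g5"),
    effect = c(rep("stop_gained", 5), rep("synonymous", 3)),
    impact = factor(c(rep("high", 5), rep("low", 3)),
                    levels = c("high", "moderate", "low", "modifier")),
    stringsAsFactors = FALSE)
  s <- summarizeSpectra(ann, alt_freq = runif(8))
  expect_equal(unname(s$impact_counts["high"]), 5)
  expect_equal(s$high_impact_genes, c("g1", "g2", "g3"))
  expect_equal(sum(s$context_proportions), 1)
  empty <- summarizeSpectra(ann[0, ])
  expect_equal(sum(empty$impact_counts), 0)
  expect_equal(length(empty$high_impact_genes), 0L)
})

test_that("all-intergenic input gives a pure intergenic context table", {
  ts <- sharedCohort()
  genes <- ts$gene_models
  g <- geneTable(genes)
  # positions far from every gene
  pos <- ts$chrom_lengths[["Chr01"]] - c(10L, 20L, 30L)
  near_gene <- any(g$chrom == "Chr01" & g$end + 5000 >= min(pos))
  v <- data.frame(chrom = "Chr01", pos = pos)
  ctx <- classifyContext(v, genes)
  if (!near_gene) {
    ann <- data.frame(context = ctx,
                      impact = factor("modifier",
                                      levels = c("high", "moderate", "low",
                                                 "modifier")),
                      gene_id = NA_character_)
    s <- summarizeSpectra(ann)
    expect_equal(unname(s$context_proportions["intergenic"]), 1)
  }
  expect_true(all(as.character(ctx) %in% c("intergenic", "up_downstream")))
})
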