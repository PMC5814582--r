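## Genomic-context and functional-impact classification of nucleotide
## variants against single-transcript gene models (a deliberately compact
## effect predictor: canonical splice sites, CDS translation via the
## standard codon table, frameshift/in-frame logic for indels).

CONTEXT_LEVELS <- c("splice_site", "exonic", "intronic", "up_downstream",
                    "intergenic")

EFFECT_IMPACT <- c(
  frameshift = "high", splice_acceptor = "high", splice_donor = "high",
  stop_gained = "high", start_lost = "high", stop_lost = "high",
  missense = "moderate", inframe_indel = "moderate",
  synonymous = "low", noncoding = "modifier")

IMPACT_LEVELS <- c("high", "moderate", "low", "modifier")

## intron intervals of a gene (1-based inclusive), from ordered exons
intronRanges <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Classify variants by genomic context
#'
#' Assigns exactly one label per variant with precedence
#' splice_site > exonic > intronic > up_downstream > intergenic.
#' Splice sites are the first/last 2 bp of an intron; up_downstream means
#' within \code{flank} bp of a gene (strand-aware 5-kb flanks by default,
#' pooled into one label) but not inside any gene.
#'
#' @param variants data.frame with chrom, pos (1-based).
#' @param genes a \linkS4class{GeneModelSet}.
#' @param flank flank size in bp (default 5000).
#' @param chrom_lengths optional named vector; positions beyond a chromosome
#'   end raise an error.
#' @return factor of context labels.
#' @export
classifyContext <- function(variants, genes, flank = 5000,
                            chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[variants$chrom]
    if (any(is.na(lim)) || any(variants$pos < 1 | variants$pos > lim))
      stop("variant position beyond chromosome bounds")
  }
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  g <- geneTable(genes)
  ex <- exonTable(genes)
  gene_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  exon_gr <- GenomicRanges::GRanges(ex$chrom,
                                    IRanges::IRanges(ex$start, ex$end))
  spl <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    intr <- intronRanges(ex[ex$gene_id == g$gene_id[i], , drop = FALSE])
    if (!nrow(intr)) return(NULL)
    data.frame(chrom = g$chrom[i],
               start = c(intr$start, pmax(intr$end - 1L, intr$start)),
               end = c(pmin(intr$start + 1L, intr$end), intr$end))
  }))
  splice_gr <- if (is.null(spl)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(spl$chrom, IRanges::IRanges(spl$start, spl$end))
  flank_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(g$start - flank, 1L), g$end + flank))

  hit <- function(gr) IRanges::overlapsAny(vr, gr)
  ctx <- rep("intergenic", nrow(variants))
  ctx[hit(flank_gr)] <- "up_downstream"
  in_gene <- hit(gene_gr)
  ctx[in_gene] <- "intronic"
  ctx[in_gene & hit(exon_gr)] <- "exonic"
  ctx[hit(splice_gr)] <- "splice_site"
  factor(ctx, levels = CONTEXT_LEVELS)
}

## spliced CDS sequence (transcription order) and the genomic -> CDS map
cdsCoordinates <- function(gene_id, genes) {
  cc <- cdsTable(genes)
  cc <- cc[cc$gene_id == gene_id, , drop = FALSE]
  cc <- cc[order(cc$start), , drop = FALSE]
  strand <- cc$strand[1]
  gpos <- unlist(lapply(seq_len(nrow(cc)), function(i) cc$start[i]:cc$end[i]))
  if (strand == "-") gpos <- rev(gpos)
  gpos # gpos[k] = genomic position of CDS base k (transcription order)
}

extractCds <- function(gene_id, genes, ref) {
  g <- geneTable(genes)
  row <- g[g$gene_id == gene_id, , drop = FALSE]
  gpos <- cdsCoordinates(gene_id, genes)
  chrom_seq <- ref[[row$chrom]]
  nt <- strsplit(as.character(chrom_seq), "")[[1]][gpos]
  if (row$strand == "-") nt <- chartr("ACGT", "TGCA", nt)
  list(seq = nt, gpos = gpos, strand = row$strand, chrom = row$chrom)
}

translateNt <- function(nt) {
  n <- 3 * (length(nt) %/% 3)
  as.character(Biostrings::translate(
    Biostrings::DNAString(paste(nt[seq_len(n)], collapse = "")),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

#' Classify the functional impact of a variant on one gene
#'
#' SNP/MNP substitutions inside the CDS are translated with the standard
#' codon table and compared to the reference protein (synonymous / missense /
#' stop_gained / start_lost / stop_lost); CDS indels are frameshift when the
#' length difference is not a multiple of 3, else inframe_indel; variants in
#' the canonical 2-bp intron termini are splice_acceptor/splice_donor
#' (strand-aware); anything else is noncoding. Effects map to impact classes
#' high/moderate/low/modifier.
#'
#' @param variant one-row data.frame (chrom, pos, ref, alt).
#' @param gene_id gene identifier in \code{genes}.
#' @param genes a \linkS4class{GeneModelSet}.
#' @param ref reference genome (\code{DNAStringSet} or named character).
#' @return list(effect, impact).
#' @export
classifyImpact <- function(variant, gene_id, genes, ref) {
  g <- geneTable(genes)
  grow <- g[g$gene_id == gene_id, , drop = FALSE]
  if (!nrow(grow)) stop("unknown gene ", gene_id)
  ex <- exonTable(genes)
  ex <- ex[ex$gene_id == gene_id, , drop = FALSE]
  pos <- variant$pos
  ref_al <- variant$ref
  alt_al <- variant$alt

  ## canonical splice sites: 2-bp intron termini; donor is the intron end
  ## adjacent to the upstream exon (5'), acceptor the 3' end
  intr <- intronRanges(ex)
  if (nrow(intr)) {
    left <- pos >= intr$start & pos <= pmin(intr$start + 1L, intr$end)
    right <- pos >= pmax(intr$end - 1L, intr$start) & pos <= intr$end
    if (any(left | right)) {
      donor_side <- if (grow$strand == "+") any(left) else any(right)
      eff <- if (donor_side) "splice_donor" else "splice_acceptor"
      return(list(effect = eff, impact = unname(EFFECT_IMPACT[eff])))
    }
  }

  is_indel <- nchar(ref_al) != nchar(alt_al)
  span <- pos:(pos + nchar(ref_al) - 1L)
  cds <- extractCds(gene_id, genes, ref)
  in_cds <- span %in% cds$gpos
  if (!any(in_cds))
    return(list(effect = "noncoding", impact = "modifier"))

  if (length(cds$seq) %% 3 != 0)
    warning("CDS length of ", gene_id,
            " is not a multiple of 3; using available frame")

  if (is_indel) {
    eff <- if (abs(nchar(ref_al) - nchar(alt_al)) %% 3 != 0)
      "frameshift" else "inframe_indel"
    return(list(effect = eff, impact = unname(EFFECT_IMPACT[eff])))
  }

  ## substitution: apply (strand-aware) and retranslate
  idx <- match(span, cds$gpos)
  ref_nt <- strsplit(ref_al, "")[[1]]
  alt_nt <- strsplit(alt_al, "")[[1]]
  if (cds$strand == "-") {
    ref_nt <- chartr("ACGT", "TGCA", ref_nt)
    alt_nt <- chartr("ACGT", "TGCA", alt_nt)
  }
  mut <- cds$seq
  keep <- !is.na(idx)
  if (!all(mut[idx[keep]] == ref_nt[keep]))
    warning("reference allele mismatch at ", variant$chrom, ":", pos)
  mut[idx[keep]] <- alt_nt[keep]
  p_ref <- strsplit(translateNt(cds$seq), "")[[1]]
  p_mut <- strsplit(translateNt(mut), "")[[1]]
  changed <- which(p_ref != p_mut)
  eff <- if (!length(changed)) "synonymous"
    else if (1 %in% changed && p_ref[1] == "M") "start_lost"
    else if (any(p_ref[changed] == "*")) "stop_lost"
    else if (any(p_mut[changed] == "*")) "stop_gained"
    else "missense"
  list(effect = eff, impact = unname(EFFECT_IMPACT[eff]))
}

#' Annotate variants with context, effect and impact
#'
#' Classifies every variant against every overlapping gene (gene body plus
#' splice sites) and reports the most severe effect as the variant's summary
#' label, together with its single context label.
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param genes a \linkS4class{GeneModelSet}.
#' @param ref reference genome (DNAStringSet or named character vector).
#' @param flank flank size for the up_downstream context (bp).
#' @param chrom_lengths optional bounds check.
#' @return data.frame: chrom, pos, ref, alt, context, gene_id, effect,
#'   impact.
#' @export
annotateVariants <- function(variants, genes, ref, flank = 5000,
                             chrom_lengths = NULL) {
  ctx <- classifyContext(variants, genes, flank, chrom_lengths)
  g <- geneTable(genes)
  severity <- seq_along(names(EFFECT_IMPACT))
  names(severity) <- names(EFFECT_IMPACT)
  vr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L))
  ## splice sites sit in introns, inside the gene span, so gene-span overlap
  ## finds all impact candidates
  gene_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  ov <- GenomicRanges::findOverlaps(vr, gene_gr)
  eff <- rep("noncoding", nrow(variants))
  gid <- rep(NA_character_, nrow(variants))
  for (k in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[k]
    j <- S4Vectors::subjectHits(ov)[k]
    res <- classifyImpact(variants[i, , drop = FALSE], g$gene_id[j], genes, ref)
    if (is.na(gid[i]) || severity[res$effect] < severity[eff[i]]) {
      eff[i] <- res$effect
      gid[i] <- g$gene_id[j]
    }
  }
  data.frame(chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
             alt = variants$alt, context = ctx, gene_id = gid, effect = eff,
             impact = factor(unname(EFFECT_IMPACT[eff]),
                             levels = IMPACT_LEVELS),
             stringsAsFactors = FALSE)
}

#' Summarize annotation spectra
#'
#' Context proportions, impact-category counts, per-impact alternative
#' ("mutant") allele-frequency histograms, and the deduplicated list of
#' genes carrying high-impact variants.
#'
#' @param annotated data.frame from \code{\link{annotateVariants}}.
#' @param alt_freq optional numeric vector of alternative-allele frequencies
#'   (in [0, 1]) parallel to \code{annotated}.
#' @param af_breaks histogram breaks for the allele-frequency spectra.
#' @return list(context_proportions, impact_counts, af_histograms,
#'   high_impact_genes).
#' @export
summarizeSpectra <- function(annotated, alt_freq = NULL,
                             af_breaks = seq(0, 1, by = 0.2)) {
  n <- nrow(annotated)
  ctx <- table(factor(annotated$context, levels = CONTEXT_LEVELS))
  imp <- table(factor(annotated$impact, levels = IMPACT_LEVELS))
  hists <- NULL
  if (!is.null(alt_freq) && n) {
    hists <- lapply(setNames(IMPACT_LEVELS, IMPACT_LEVELS), function(lv) {
      x <- alt_freq[annotated$impact == lv]
      if (!length(x)) return(rep(0L, length(af_breaks) - 1L))
      as.integer(table(cut(x, af_breaks, include.lowest = TRUE,
                           right = FALSE)))
    })
  }
  high_genes <- sort(unique(annotated$gene_id[
    annotated$impact == "high" & !is.na(annotated$gene_id)]))
  list(context_proportions = if (n) ctx / n else ctx,
       impact_counts = imp,
       af_histograms = hists,
       high_impact_genes = high_genes)
}
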