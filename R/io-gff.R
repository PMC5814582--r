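#' GeneModelSet: protein-coding gene models with exon/CDS structure
#'
#' Holds gene spans, exon spans and CDS spans (all 1-based inclusive) for a
#' set of single-transcript protein-coding models, as read from GFF3 or built
#' by the cohort simulator. Strand-aware 5-kb flanks are derived on demand by
#' the annotation functions.
#'
#' @slot genes data.frame: gene_id, chrom, strand, start, end (and optionally
#'   cds_seq for simulated models).
#' @slot exons data.frame: gene_id, chrom, strand, start, end, rank.
#' @slot cds data.frame: same shape as exons.
#' @export
setClass("GeneModelSet",
  representation(genes = "data.frame", exons = "data.frame", cds = "data.frame"))

setValidity("GeneModelSet", function(object) {
  msg <- character(0)
  g <- object@genes; e <- object@exons
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(g))) msg <- c(msg, "genes missing required columns")
  if (!all(need %in% names(e))) msg <- c(msg, "exons missing required columns")
  if (nrow(e)) {
    m <- match(e$gene_id, g$gene_id)
    if (anyNA(m)) msg <- c(msg, "exon with unknown gene_id")
    else if (any(e$start < g$start[m] | e$end > g$end[m]))
      msg <- c(msg, "exons must lie within their gene span")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#' @param genes,exons,cds data.frames (see class slots).
#' @return A \linkS4class{GeneModelSet}.
#' @export
GeneModelSet <- function(genes, exons, cds = exons) {
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  new("GeneModelSet", genes = genes, exons = exons, cds = cds)
}

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d genes, %d exons on %d chromosome(s)\n",
              nrow(object@genes), nrow(object@exons),
              length(unique(object@genes$chrom))))
})

#' @describeIn GeneModelSet-class gene table
#' @param x a GeneModelSet
#' @export
geneTable <- function(x) x@genes

#' @describeIn GeneModelSet-class exon table
#' @export
exonTable <- function(x) x@exons

#' @describeIn GeneModelSet-class CDS table
#' @export
cdsTable <- function(x) x@cds

## GFF3 writer: gene -> mRNA -> exon/CDS, 1-based inclusive, deterministic
writeGeneModelsGff3 <- function(models, path, contigs = NULL) {
  g <- models@genes; e <- models@exons; cd <- models@cds
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(contigs))
    for (ch in names(contigs))
      writeLines(sprintf("##sequence-region %s 1 %d", ch,
                         as.integer(contigs[ch])), con)
  rows <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    mid <- paste0(gid, ".t1")
    rows <- c(rows,
      sprintf("%s\tinbredvar\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], gid),
      sprintf("%s\tinbredvar\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], mid, gid))
    ex <- e[e$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    rows <- c(rows, sprintf(
      "%s\tinbredvar\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
      ex$chrom, ex$start, ex$end, ex$strand, gid, seq_len(nrow(ex)), mid))
    cc <- cd[cd$gene_id == gid, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    ## phase in transcription order
    ord <- if (g$strand[i] == "+") seq_len(nrow(cc)) else rev(seq_len(nrow(cc)))
    lens <- cc$end - cc$start + 1L
    phase <- integer(nrow(cc))
    run <- 0L
    for (j in ord) {
      phase[j] <- (3L - run %% 3L) %% 3L
      run <- run + lens[j]
    }
    rows <- c(rows, sprintf(
      "%s\tinbredvar\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
      cc$chrom, cc$start, cc$end, cc$strand, phase, gid, mid))
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon/CDS features and assembles a
#' \linkS4class{GeneModelSet}. Assumes single-transcript models (the first
#' mRNA per gene is used).
#'
#' @param path GFF3 file.
#' @return A \linkS4class{GeneModelSet}.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  genes <- df[df$type == "gene", ]
  mrna <- df[df$type == "mRNA", ]
  mrna_parent <- vapply(mrna$Parent, function(p) as.character(p)[1], character(1))
  mrna2gene <- setNames(mrna_parent, mrna$ID)
  pick <- function(type) {
    x <- df[df$type == type, ]
    if (!nrow(x)) return(data.frame(gene_id = character(0), chrom = character(0),
                                    strand = character(0), start = integer(0),
                                    end = integer(0), rank = integer(0)))
    par <- vapply(x$Parent, function(p) as.character(p)[1], character(1))
    gid <- unname(mrna2gene[par])
    gid[is.na(gid)] <- par[is.na(gid)] # exon attached directly to gene
    out <- data.frame(gene_id = gid, chrom = x$seqnames, strand = x$strand,
                      start = x$start, end = x$end, stringsAsFactors = FALSE)
    out <- out[order(out$gene_id, out$start), ]
    out$rank <- stats::ave(out$start, out$gene_id, FUN = seq_along)
    out
  }
  gtab <- data.frame(gene_id = genes$ID, chrom = genes$seqnames,
                     strand = genes$strand, start = genes$start,
                     end = genes$end, stringsAsFactors = FALSE)
  GeneModelSet(genes = gtab, exons = pick("exon"), cds = pick("CDS"))
}
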