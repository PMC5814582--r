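## SV-versus-gene overlap scenarios and Table-style summary.
##
## Four scenarios relate an SV to a gene: inside the gene (in_gene);
## starting upstream and ending inside (upstream_and_gene); starting inside
## and ending downstream (downstream_and_gene); spanning the whole gene
## (whole_gene). "Upstream"/"downstream" are positional (left/right on the
## reference), not strand-aware: the scenarios describe SV geometry, not
## regulation. Spanned types (DEL/DUP/CNV and, behind a flag, interval-form
## INS) are compared by interval; INV/TRA are compared by breakpoints: a
## breakpoint inside a gene gives in_gene, and a gene wholly inside an
## inversion without breakpoint contact is not counted.

SV_SCENARIOS <- c("in_gene", "upstream_and_gene", "downstream_and_gene",
                  "whole_gene")

## scenario for one spanned SV interval vs one gene span (1-based inclusive)
spanScenario <- function(s1, e1, gs, ge) {
  if (e1 < gs || s1 > ge) return(NA_character_)
  if (s1 <= gs && e1 >= ge) return("whole_gene")
  if (s1 >= gs && e1 <= ge) return("in_gene")
  if (s1 < gs) return("upstream_and_gene")
  "downstream_and_gene"
}

#' Classify SV-gene overlap scenarios
#'
#' @param svs consensus-site data.frame (site_id, sv_type, chrom, chrom2,
#'   start, end; internal 0-based half-open).
#' @param genes a \linkS4class{GeneModelSet}.
#' @param ins_as_interval treat insertions as reference intervals instead of
#'   single breakpoints (default FALSE: a point insertion can only realize
#'   in_gene).
#' @return data.frame: site_id, sv_type, gene_id, scenario (one row per
#'   (SV, gene) pair with a non-none scenario).
#' @export
classifySvGeneOverlap <- function(svs, genes, ins_as_interval = FALSE) {
  g <- geneTable(genes)
  known <- unique(g$chrom)
  bad <- setdiff(unique(c(svs$chrom, svs$chrom2)), known)
  if (length(bad))
    stop("SV on chromosome absent from annotation: ",
         paste(bad, collapse = ", "))
  gene_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  out <- list()
  spanned <- svs$sv_type %in% c("DEL", "DUP", "CNV") |
    (svs$sv_type == "INS" & ins_as_interval)
  ## spanned types: interval comparison
  if (any(spanned)) {
    sv <- svs[spanned, , drop = FALSE]
    s1 <- sv$start + 1 # 1-based inclusive
    e1 <- ifelse(sv$sv_type == "INS", sv$start + sv$length, sv$end)
    sr <- GenomicRanges::GRanges(sv$chrom, IRanges::IRanges(s1, e1))
    ov <- GenomicRanges::findOverlaps(sr, gene_gr)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
      scen <- vapply(seq_along(qi), function(k)
        spanScenario(s1[qi[k]], e1[qi[k]], g$start[sj[k]], g$end[sj[k]]),
        character(1))
      out[[length(out) + 1L]] <- data.frame(
        site_id = sv$site_id[qi], sv_type = sv$sv_type[qi],
        gene_id = g$gene_id[sj], scenario = scen, stringsAsFactors = FALSE)
    }
  }
  ## breakpoint types: INS (point), INV, TRA
  bp_types <- !spanned
  if (any(bp_types)) {
    sv <- svs[bp_types, , drop = FALSE]
    is_point <- sv$sv_type == "INS"
    bp <- rbind(
      data.frame(site_id = sv$site_id, sv_type = sv$sv_type,
                 chrom = sv$chrom, pos = sv$start + 1,
                 stringsAsFactors = FALSE),
      data.frame(site_id = sv$site_id[!is_point],
                 sv_type = sv$sv_type[!is_point],
                 chrom = sv$chrom2[!is_point], pos = sv$end[!is_point],
                 stringsAsFactors = FALSE))
    br <- GenomicRanges::GRanges(bp$chrom, IRanges::IRanges(bp$pos, bp$pos))
    ov <- GenomicRanges::findOverlaps(br, gene_gr)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
      hits <- unique(data.frame(
        site_id = bp$site_id[qi], sv_type = bp$sv_type[qi],
        gene_id = g$gene_id[sj], scenario = "in_gene",
        stringsAsFactors = FALSE))
      out[[length(out) + 1L]] <- hits
    }
  }
  if (!length(out))
    return(data.frame(site_id = character(0), sv_type = character(0),
                      gene_id = character(0), scenario = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$site_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Table-style summary of SV gene impact
#'
#' Counts per SV type and scenario; a site hitting several genes contributes
#' one count per (SV, gene) pair to the scenario counts but only once to the
#' percentage of sites affecting genes.
#'
#' @param scenarios data.frame from \code{\link{classifySvGeneOverlap}}.
#' @param catalogue the consensus-site catalogue the scenarios were computed
#'   on (for per-type totals).
#' @return list: \code{counts} (scenario x type matrix), \code{totals}
#'   (scenario-count totals per type), \code{affected_sites},
#'   \code{percent_affecting} (one decimal, per type).
#' @export
summarizeGeneImpact <- function(scenarios, catalogue) {
  types <- sort(unique(catalogue$sv_type))
  counts <- matrix(0L, length(SV_SCENARIOS), length(types),
                   dimnames = list(SV_SCENARIOS, types))
  if (nrow(scenarios)) {
    tb <- table(factor(scenarios$scenario, levels = SV_SCENARIOS),
                factor(scenarios$sv_type, levels = types))
    counts[] <- as.integer(tb)
  }
  totals <- colSums(counts)
  affected <- vapply(types, function(ty) {
    length(unique(scenarios$site_id[scenarios$sv_type == ty]))
  }, integer(1))
  n_sites <- vapply(types, function(ty) sum(catalogue$sv_type == ty),
                    integer(1))
  pct <- round(100 * affected / n_sites, 1)
  list(counts = counts, totals = totals, affected_sites = affected,
       percent_affecting = pct)
}
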