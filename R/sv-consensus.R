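#' Raw SV call filter thresholds
#'
#' Defaults follow the raw-call filtering rules: read-depth ratio (< 0.75
#' for deletions, mirrored > 1/0.75 for duplications/CNVs; balanced and
#' point events are exempt), > 10 spanning read pairs, breakpoints clear of
#' centromeres (+/- 1 kb) and assembly gaps (+/- 50 bp), genotype quality
#' > 30; inversions additionally need a genotyped/ungenotyped sample ratio
#' > 0.4 and a carrier supporting-pair fraction > 0.3; translocations in
#' syntenic regions are removed. Clustering uses an 80% reciprocal-overlap
#' threshold and a 250-bp maximum breakpoint offset.
#'
#' @param rd_ratio_max_del,min_spanning_pairs,centromere_pad,gap_pad,min_gq
#'   filter thresholds.
#' @param ro_threshold,max_breakpoint_offset clustering thresholds.
#' @param inv_min_genotyped_ratio,inv_min_carrier_pair_fraction inversion
#'   thresholds.
#' @param inv_ratio_mode "ungenotyped" (genotyped/ungenotyped, default) or
#'   "total" (genotyped/total).
#' @return named list of class \code{SVFilterConfig}.
#' @export
svFilterConfig <- function(rd_ratio_max_del = 0.75, min_spanning_pairs = 10,
                           centromere_pad = 1000, gap_pad = 50, min_gq = 30,
                           ro_threshold = 0.80, max_breakpoint_offset = 250,
                           inv_min_genotyped_ratio = 0.4,
                           inv_min_carrier_pair_fraction = 0.3,
                           inv_ratio_mode = c("ungenotyped", "total")) {
  stopifnot(ro_threshold > 0, ro_threshold <= 1, centromere_pad >= 0,
            gap_pad >= 0)
  structure(list(rd_ratio_max_del = rd_ratio_max_del,
                 min_spanning_pairs = min_spanning_pairs,
                 centromere_pad = centromere_pad, gap_pad = gap_pad,
                 min_gq = min_gq, ro_threshold = ro_threshold,
                 max_breakpoint_offset = max_breakpoint_offset,
                 inv_min_genotyped_ratio = inv_min_genotyped_ratio,
                 inv_min_carrier_pair_fraction = inv_min_carrier_pair_fraction,
                 inv_ratio_mode = match.arg(inv_ratio_mode)),
            class = "SVFilterConfig")
}

SV_FILTER_RULES <- c("rd_ratio", "rd_missing", "spanning_pairs", "centromere",
                     "gap", "gq", "inv_genotyped_ratio",
                     "inv_carrier_fraction", "syntenic")

## is any breakpoint of each call within a padded mask?
breakpointInMask <- function(calls, mask, pad) {
  if (is.null(mask) || !nrow(mask)) return(rep(FALSE, nrow(calls)))
  mr <- GenomicRanges::GRanges(mask$chrom,
                               IRanges::IRanges(pmax(mask$start - pad, 0),
                                                mask$end + pad))
  bp1 <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$start))
  bp2 <- GenomicRanges::GRanges(calls$chrom2,
                                IRanges::IRanges(calls$end, calls$end))
  IRanges::overlapsAny(bp1, mr) | IRanges::overlapsAny(bp2, mr)
}

## whole-interval overlap with a mask (syntenic-region removal for TRA)
intervalInMask <- function(calls, mask) {
  if (is.null(mask) || !nrow(mask)) return(rep(FALSE, nrow(calls)))
  mr <- GenomicRanges::GRanges(mask$chrom,
                               IRanges::IRanges(mask$start, mask$end))
  bp1 <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$start))
  bp2 <- GenomicRanges::GRanges(calls$chrom2,
                                IRanges::IRanges(calls$end, calls$end))
  IRanges::overlapsAny(bp1, mr) & IRanges::overlapsAny(bp2, mr)
}

#' Apply raw-call filters to an SV call set
#'
#' Retention requires: spanning read pairs > threshold AND genotype quality
#' > threshold AND no breakpoint within a padded centromere or assembly-gap
#' region AND the read-depth-ratio rule for the call's type (DEL:
#' rd_ratio < 0.75; DUP/CNV: rd_ratio > 1/0.75; INS/INV/TRA exempt).
#' Inversions additionally require the genotyped-sample ratio and carrier
#' supporting-pair fraction thresholds; translocations inside supplied
#' syntenic blocks are removed. DEL/DUP/CNV calls without an rd_ratio are
#' unevaluable and tallied separately ("rd_missing").
#'
#' @param calls SV call data.frame (internal 0-based coordinates).
#' @param cfg an \code{\link{svFilterConfig}}.
#' @param centromeres,gaps,syntenic optional BED-like data.frames (chrom,
#'   start, end; 0-based half-open).
#' @return list(retained, removed (with rule column), tally).
#' @export
applyRawFilters <- function(calls, cfg = svFilterConfig(),
                            centromeres = NULL, gaps = NULL, syntenic = NULL) {
  n <- nrow(calls)
  rd_needed <- calls$sv_type %in% c("DEL", "DUP", "CNV")
  rd_missing <- rd_needed & is.na(calls$rd_ratio)
  rd_ok <- !rd_needed |
    (calls$sv_type == "DEL" & !is.na(calls$rd_ratio) &
       calls$rd_ratio < cfg$rd_ratio_max_del) |
    (calls$sv_type %in% c("DUP", "CNV") & !is.na(calls$rd_ratio) &
       calls$rd_ratio > 1 / cfg$rd_ratio_max_del)
  pairs_ok <- !is.na(calls$pe) & calls$pe > cfg$min_spanning_pairs
  gq_ok <- !is.na(calls$gq) & calls$gq > cfg$min_gq
  cen_hit <- breakpointInMask(calls, centromeres, cfg$centromere_pad)
  gap_hit <- breakpointInMask(calls, gaps, cfg$gap_pad)
  is_inv <- calls$sv_type == "INV"
  gr <- calls$genotyped_ratio
  if (cfg$inv_ratio_mode == "total") gr <- gr / (1 + gr)
  inv_gr_ok <- !is_inv | (!is.na(gr) & gr > cfg$inv_min_genotyped_ratio)
  inv_cf_ok <- !is_inv |
    (!is.na(calls$carrier_pair_fraction) &
       calls$carrier_pair_fraction > cfg$inv_min_carrier_pair_fraction)
  is_tra <- calls$sv_type %in% c("TRA_intra", "TRA_inter")
  syn_hit <- is_tra & intervalInMask(calls, syntenic)

  pass <- cbind(rd_ratio = rd_ok | rd_missing, rd_missing = !rd_missing,
                spanning_pairs = pairs_ok, centromere = !cen_hit,
                gap = !gap_hit, gq = gq_ok,
                inv_genotyped_ratio = inv_gr_ok,
                inv_carrier_fraction = inv_cf_ok, syntenic = !syn_hit)
  first_fail <- apply(pass, 1, function(z) {
    w <- which(!z)
    if (length(w)) SV_FILTER_RULES[w[1]] else NA_character_
  })
  retained <- calls[is.na(first_fail), , drop = FALSE]
  removed <- calls[!is.na(first_fail), , drop = FALSE]
  removed$rule <- first_fail[!is.na(first_fail)]
  tally <- setNames(integer(length(SV_FILTER_RULES)), SV_FILTER_RULES)
  tb <- table(removed$rule)
  tally[names(tb)] <- as.integer(tb)
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed, tally = tally)
}

#' Reciprocal overlap of two intervals
#'
#' min(overlap / length_a, overlap / length_b); symmetric, in [0, 1].
#'
#' @param a_start,a_end,b_start,b_end interval coordinates (0-based
#'   half-open), vectorized.
#' @return numeric fraction(s).
#' @export
reciprocalOverlap <- function(a_start, a_end, b_start, b_end) {
  la <- a_end - a_start
  lb <- b_end - b_start
  if (any(la <= 0 | lb <= 0)) stop("zero-length interval")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  pmin(ov / la, ov / lb)
}

#' Cluster SV calls across tools into consensus sites
#'
#' Builds a graph over calls of the same type and chromosome (chromosome
#' pair for interchromosomal translocations) with an edge when two calls
#' satisfy the merge criteria — intervallic types: reciprocal overlap >=
#' ro_threshold AND both breakpoint offsets <= max offset; insertions and
#' translocations: both breakpoint offsets <= max offset — and takes
#' connected components (single linkage) as consensus sites. The
#' representative interval is the per-coordinate lower median of the
#' members; support is the number of distinct tools.
#'
#' @param calls SV call data.frame.
#' @param cfg an \code{\link{svFilterConfig}} (ro_threshold,
#'   max_breakpoint_offset).
#' @return data.frame of consensus sites: site_id, sv_type, chrom, chrom2,
#'   start, end, length, n_members, support, tools, precision, member_ids.
#' @export
clusterCalls <- function(calls, cfg = svFilterConfig()) {
  if (!nrow(calls)) {
    return(data.frame(site_id = character(0), sv_type = character(0),
                      chrom = character(0), chrom2 = character(0),
                      start = numeric(0), end = numeric(0),
                      length = numeric(0), n_members = integer(0),
                      support = integer(0), tools = character(0),
                      precision = numeric(0), member_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  ro_min <- cfg$ro_threshold
  off_max <- cfg$max_breakpoint_offset
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  grp <- paste(calls$sv_type, calls$chrom, calls$chrom2, sep = "|")
  point_types <- c("INS", "TRA_intra", "TRA_inter")
  for (gkey in unique(grp)) {
    idx <- which(grp == gkey)
    idx <- idx[order(calls$start[idx])]
    pointlike <- calls$sv_type[idx[1]] %in% point_types
    for (a in seq_along(idx)) {
      i <- idx[a]
      b <- a + 1L
      while (b <= length(idx)) {
        j <- idx[b]
        if (calls$start[j] - calls$start[i] > off_max) break
        off_ok <- abs(calls$end[i] - calls$end[j]) <= off_max
        if (off_ok) {
          if (pointlike) {
            unite(i, j)
          } else {
            ro <- reciprocalOverlap(calls$start[i], calls$end[i],
                                    calls$start[j], calls$end[j])
            if (ro >= ro_min) unite(i, j)
          }
        }
        b <- b + 1L
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  sites <- lapply(comp, function(members) {
    m <- calls[members, , drop = FALSE]
    rep_start <- lowerMedian(m$start)
    rep_end <- lowerMedian(m$end)
    data.frame(
      sv_type = m$sv_type[1], chrom = m$chrom[1], chrom2 = m$chrom2[1],
      start = rep_start, end = rep_end,
      length = if (m$sv_type[1] == "INS") lowerMedian(m$length)
               else rep_end - rep_start,
      n_members = nrow(m), support = length(unique(m$caller)),
      tools = paste(sort(unique(m$caller)), collapse = ","),
      precision = max(abs(m$start - rep_start), abs(m$end - rep_end)),
      member_ids = paste(m$id, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sites)
  out <- out[order(out$sv_type, out$chrom, out$start), , drop = FALSE]
  out$site_id <- sprintf("CS%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("site_id", "sv_type", "chrom", "chrom2", "start", "end", "length",
          "n_members", "support", "tools", "precision", "member_ids")]
}

#' Unified catalogue and cross-tool concordance statistics
#'
#' The unified catalogue keeps consensus sites supported by at least two
#' distinct tools. Concordance is reported per type both at call level
#' (fraction of calls belonging to a >= 2-tool component) and at site level
#' (fraction of consensus sites with >= 2-tool support), with a
#' count-weighted mean over deletions, insertions, inversions and
#' duplications.
#'
#' @param sites consensus sites from \code{\link{clusterCalls}}.
#' @param min_support minimum distinct tools for the unified catalogue
#'   (default 2).
#' @return list: \code{catalogue} (sites with support >= min_support),
#'   \code{concordance} (per type: n_calls, n_sites, call_fraction,
#'   site_fraction), \code{weighted_call_concordance},
#'   \code{weighted_site_concordance}, \code{summary} (Table-style per-type
#'   catalogue summary: count, size range, median size, median/max
#'   breakpoint precision).
#' @export
unifyAndScore <- function(sites, min_support = 2L) {
  catalogue <- sites[sites$support >= min_support, , drop = FALSE]
  rownames(catalogue) <- NULL
  types <- unique(sites$sv_type)
  conc <- do.call(rbind, lapply(types, function(ty) {
    st <- sites[sites$sv_type == ty, , drop = FALSE]
    n_calls <- sum(st$n_members)
    n_sites <- nrow(st)
    multi <- st$support >= min_support
    data.frame(sv_type = ty, n_calls = n_calls, n_sites = n_sites,
               call_fraction = sum(st$n_members[multi]) / n_calls,
               site_fraction = mean(multi), stringsAsFactors = FALSE)
  }))
  wtypes <- c("DEL", "INS", "INV", "DUP")
  cw <- conc[conc$sv_type %in% wtypes, , drop = FALSE]
  weighted <- function(frac, wts) {
    if (!nrow(cw) || sum(wts) == 0) return(NA_real_)
    sum(frac * wts) / sum(wts)
  }
  summ <- do.call(rbind, lapply(split(catalogue, catalogue$sv_type),
    function(st) {
      data.frame(sv_type = st$sv_type[1], n_sites = nrow(st),
                 min_size = min(st$length), max_size = max(st$length),
                 median_size = median(st$length),
                 median_precision = median(st$precision),
                 max_precision = max(st$precision),
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(summ)) rownames(summ) <- NULL
  list(catalogue = catalogue, concordance = conc,
       weighted_call_concordance = weighted(cw$call_fraction, cw$n_calls),
       weighted_site_concordance = weighted(cw$site_fraction, cw$n_calls),
       summary = summ)
}

#' Write a unified SV catalogue as VCF with symbolic alleles
#'
#' @param catalogue consensus-site data.frame (support >= 2).
#' @param path output file.
#' @param contigs optional named chromosome lengths.
#' @return The path, invisibly.
#' @export
writeCatalogueVcf <- function(catalogue, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=inbredvar")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr,
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End (1-based inclusive)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Second chromosome">',
    '##INFO=<ID=SUPP,Number=1,Type=Integer,Description="Supporting tool count">',
    '##INFO=<ID=SUPP_SET,Number=1,Type=String,Description="Supporting tools">',
    '##INFO=<ID=CIPOS,Number=2,Type=Integer,Description="Member spread around POS">',
    '##INFO=<ID=CIEND,Number=2,Type=Integer,Description="Member spread around END">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  alt_sym <- sub("_.*", "", catalogue$sv_type)
  ci <- round(catalogue$precision)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SUPP=%d;SUPP_SET=%s;CIPOS=-%d,%d;CIEND=-%d,%d",
                  catalogue$sv_type, as.integer(catalogue$end),
                  as.integer(catalogue$length), catalogue$support,
                  gsub(",", "|", catalogue$tools), ci, ci, ci, ci)
  diff_chr <- catalogue$chrom2 != catalogue$chrom
  info[diff_chr] <- paste0(info[diff_chr], ";CHR2=",
                           catalogue$chrom2[diff_chr])
  body <- paste(catalogue$chrom, as.integer(catalogue$start + 1),
                catalogue$site_id, "N", paste0("<", alt_sym, ">"),
                ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
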