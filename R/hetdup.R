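## Clustered residual heterozygosity and its concordance with duplication /
## CNV calls. In a fully inbred panel heterozygous calls should be rare and
## dispersed; collapsed duplications produce windows of clustered
## heterozygosity with elevated read depth in the carrier samples.

#' Per-sample sliding-window heterozygosity profile
#'
#' @param gm \linkS4class{GenotypeMatrix}.
#' @param window,step window and step in bp (window >= step > 0; default
#'   100 kb / 50 kb).
#' @param min_sites windows with fewer called variants are flagged
#'   uninformative.
#' @param chrom_lengths optional named vector; defaults to the last variant
#'   position per chromosome.
#' @return data.frame: sample, chrom, start, end (0-based half-open),
#'   n_sites, n_het, het_rate, informative. Attribute \code{step} records
#'   the step size.
#' @export
hetProfile <- function(gm, window = 1e5, step = 5e4, min_sites = 5L,
                       chrom_lengths = NULL) {
  stopifnot(window >= step, step > 0)
  s <- siteInfo(gm)
  g <- genoCodes(gm)
  samples <- colnames(g)
  out <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(s$pos[idx])
    starts <- seq(0, max(0, L - 1), by = step)
    ends <- pmin(starts + window, L)
    pos <- s$pos[idx]
    called <- !is.na(g[idx, , drop = FALSE])
    het <- !is.na(g[idx, , drop = FALSE]) & g[idx, , drop = FALSE] == 1L
    for (w in seq_along(starts)) {
      in_w <- pos > starts[w] & pos <= ends[w]
      if (!any(in_w)) {
        n_sites <- rep(0L, length(samples))
        n_het <- rep(0L, length(samples))
      } else {
        n_sites <- colSums(called[in_w, , drop = FALSE])
        n_het <- colSums(het[in_w, , drop = FALSE])
      }
      out[[length(out) + 1L]] <- data.frame(
        sample = samples, chrom = ch, start = starts[w], end = ends[w],
        n_sites = n_sites, n_het = n_het,
        het_rate = ifelse(n_sites > 0, n_het / n_sites, NA_real_),
        informative = n_sites >= min_sites, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "step") <- step
  res
}

#' Attach normalized depth ratios to a window profile
#'
#' depth_ratio = mean depth of the profile window / the sample's genome-wide
#' median depth, computed from BED-graph style depth tracks.
#'
#' @param profiles window profile from \code{\link{hetProfile}}.
#' @param depth data.frame with sample, chrom, start, end, depth
#'   (\code{\link{readDepthTracks}}).
#' @return The profile with a \code{depth_ratio} column.
#' @export
addDepthRatio <- function(profiles, depth) {
  med <- tapply(depth$depth, depth$sample, median)
  ratio <- rep(NA_real_, nrow(profiles))
  for (smp in unique(profiles$sample)) {
    d <- depth[depth$sample == smp, , drop = FALSE]
    pr <- which(profiles$sample == smp)
    for (k in pr) {
      sel <- d$chrom == profiles$chrom[k] & d$start < profiles$end[k] &
        d$end > profiles$start[k]
      if (any(sel))
        ratio[k] <- mean(d$depth[sel]) / med[[smp]]
    }
  }
  profiles$depth_ratio <- ratio
  profiles
}

#' Detect clusters of heterozygous calls
#'
#' Informative windows with het_rate >= threshold are merged (per sample and
#' chromosome) when at most \code{merge_gap} bp apart; merged runs with at
#' least \code{min_windows} windows become clusters. The default threshold
#' is 10 x the background rate with an absolute floor of 0.05.
#'
#' @param profiles window profile from \code{\link{hetProfile}}.
#' @param het_threshold absolute het-rate threshold; if NULL, derived from
#'   \code{background_rate} (which must then be > 0).
#' @param background_rate per-genotype background heterozygosity.
#' @param min_windows minimum qualifying windows per cluster.
#' @param merge_gap maximum gap (bp) between merged windows; defaults to the
#'   profile step.
#' @return data.frame: sample, chrom, start, end, n_windows, mean_het.
#' @export
detectHetClusters <- function(profiles, het_threshold = NULL,
                              background_rate = NULL, min_windows = 3L,
                              merge_gap = NULL) {
  if (is.null(het_threshold)) {
    if (is.null(background_rate) || background_rate <= 0)
      stop("background_rate is zero/unknown: an absolute het_threshold is required")
    het_threshold <- max(10 * background_rate, 0.05)
  }
  if (is.null(merge_gap)) merge_gap <- attr(profiles, "step") %||% 5e4
  qual <- profiles$informative & !is.na(profiles$het_rate) &
    profiles$het_rate >= het_threshold
  q <- profiles[qual, , drop = FALSE]
  out <- list()
  if (nrow(q)) {
    q <- q[order(q$sample, q$chrom, q$start), , drop = FALSE]
    grp <- paste(q$sample, q$chrom, sep = "|")
    for (gkey in unique(grp)) {
      z <- q[grp == gkey, , drop = FALSE]
      run_start <- z$start[1]; run_end <- z$end[1]
      members <- 1L
      hets <- z$n_het[1]; sites <- z$n_sites[1]
      flush <- function(re, rs, m, h, st) {
        if (m >= min_windows)
          out[[length(out) + 1L]] <<- data.frame(
            sample = z$sample[1], chrom = z$chrom[1], start = rs, end = re,
            n_windows = m, mean_het = h / st, stringsAsFactors = FALSE)
      }
      if (nrow(z) > 1) for (k in 2:nrow(z)) {
        if (z$start[k] - run_end <= merge_gap) {
          run_end <- max(run_end, z$end[k])
          members <- members + 1L
          hets <- hets + z$n_het[k]; sites <- sites + z$n_sites[k]
        } else {
          flush(run_end, run_start, members, hets, sites)
          run_start <- z$start[k]; run_end <- z$end[k]
          members <- 1L; hets <- z$n_het[k]; sites <- z$n_sites[k]
        }
      }
      flush(run_end, run_start, members, hets, sites)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_windows = integer(0), mean_het = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance between duplication calls and heterozygosity clusters
#'
#' A duplication/CNV call is concordant iff, for at least one carrier
#' sample, a het cluster of that same sample overlaps the call interval
#' (any overlap). The fraction of concordant calls over all DUP+CNV calls
#' quantifies how often called duplications coincide with clustered
#' heterozygosity in the same accessions.
#'
#' @param clusters data.frame from \code{\link{detectHetClusters}}.
#' @param dup_calls data.frame of DUP/CNV calls with chrom, start, end
#'   (0-based half-open) and carriers (comma-separated sample ids); other
#'   types are ignored with a message.
#' @param mode "call" (default: each call is one unit) or "region" (calls
#'   merged into carrier-shared regions first).
#' @return list: \code{fraction} (NA with \code{undefined = TRUE} when there
#'   are no duplication calls), \code{per_call} evidence table.
#' @export
duplicationHetConcordance <- function(clusters, dup_calls,
                                      mode = c("call", "region")) {
  mode <- match.arg(mode)
  keep <- dup_calls$sv_type %in% c("DUP", "CNV")
  if (!all(keep)) {
    message(sum(!keep), " non-DUP/CNV call(s) ignored")
    dup_calls <- dup_calls[keep, , drop = FALSE]
  }
  if (!nrow(dup_calls)) {
    return(list(fraction = NA_real_, undefined = TRUE, per_call = NULL))
  }
  if (mode == "region") {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      dup_calls$chrom, IRanges::IRanges(dup_calls$start + 1, dup_calls$end)))
    hit <- GenomicRanges::findOverlaps(GenomicRanges::GRanges(
      dup_calls$chrom, IRanges::IRanges(dup_calls$start + 1, dup_calls$end)),
      gr)
    region_id <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  }
  per <- lapply(seq_len(nrow(dup_calls)), function(i) {
    call <- dup_calls[i, ]
    carr <- expandIds(call$carriers)[[1]]
    ev <- clusters[clusters$sample %in% carr &
                     clusters$chrom == call$chrom &
                     clusters$start < call$end &
                     clusters$end > call$start, , drop = FALSE]
    data.frame(id = call$id %||% as.character(i), chrom = call$chrom,
               start = call$start, end = call$end,
               n_carriers = length(carr), n_cluster_hits = nrow(ev),
               concordant = nrow(ev) > 0,
               evidence_samples = paste(unique(ev$sample), collapse = ","),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  fraction <- if (mode == "call") mean(per$concordant)
    else mean(tapply(per$concordant, region_id, any))
  list(fraction = fraction, undefined = FALSE, per_call = per)
}
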