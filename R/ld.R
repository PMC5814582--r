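## Pairwise linkage disequilibrium, window-based tag-SNP pruning, LD decay
## and saturation curves.
##
## Haplotype frequencies are estimated directly from homozygous genotypes:
## in a highly inbred cohort each homozygous individual contributes one
## observable haplotype, so heterozygous and missing genotypes are excluded
## pairwise instead of running an EM phaser.

#' Pairwise r-squared and D-prime between two sites
#'
#' @param gi,gj integer genotype code vectors (0/1/2/NA) over the same
#'   samples.
#' @return named numeric vector c(r2, dprime, n) — NA values (with attribute
#'   \code{reason}) when either site is monomorphic among the jointly
#'   homozygous samples.
#' @export
computeR2Dprime <- function(gi, gj) {
  keep <- !is.na(gi) & !is.na(gj) & gi != 1L & gj != 1L
  a <- gi[keep] / 2L # 0 = ref haplotype, 1 = alt
  b <- gj[keep] / 2L
  n <- length(a)
  pA <- mean(a == 0); pB <- mean(b == 0)
  if (n == 0 || pA %in% c(0, 1) || pB %in% c(0, 1)) {
    out <- c(r2 = NA_real_, dprime = NA_real_, n = n)
    attr(out, "reason") <- "monomorphic"
    return(out)
  }
  pAB <- mean(a == 0 & b == 0)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else abs(D) / Dmax
  c(r2 = r2, dprime = dprime, n = n)
}

## r2 of site i against a block of sites J, vectorized (same exclusion rules)
r2Block <- function(g, i, J) {
  gi <- g[i, ]
  gJ <- g[J, , drop = FALSE]
  vi <- !is.na(gi) & gi != 1L
  vJ <- !is.na(gJ) & gJ != 1L
  valid <- vJ & matrix(vi, nrow(gJ), ncol(gJ), byrow = TRUE)
  ai <- matrix(gi == 0L, nrow(gJ), ncol(gJ), byrow = TRUE)
  aJ <- gJ == 0L
  n <- rowSums(valid)
  nA <- rowSums(valid & ai)
  nB <- rowSums(valid & aJ)
  nAB <- rowSums(valid & ai & aJ)
  pA <- nA / n; pB <- nB / n
  D <- nAB / n - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(n > 0 & denom > 0, D^2 / denom, NA_real_)
  r2
}

#' Window-based tag-SNP pruning
#'
#' Within sliding windows of \code{window} consecutive sites (step 1 SNP,
#' per chromosome), sites in perfect LD (r-squared = 1 within floating
#' tolerance) are grouped by transitive closure; all but the left-most site
#' of each group are pruned, and the left-most is deemed the tag SNP.
#'
#' @param gm \linkS4class{GenotypeMatrix} with sites sorted by (chrom, pos).
#' @param window window size in SNPs (default 50).
#' @param tol tolerance on r-squared = 1 (default 1e-9).
#' @return list of class \code{TagSNPSet}: \code{tags} (retained site keys),
#'   \code{map} (data.frame pruned -> tag), \code{n_input}.
#' @export
windowPrune <- function(gm, window = 50L, tol = 1e-9) {
  s <- siteInfo(gm)
  if (any(order(s$chrom, s$pos) != seq_len(nrow(s))))
    stop("sites must be sorted by (chrom, pos)")
  g <- genoCodes(gm)
  n <- nrow(g)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    for (k in seq_along(idx)) {
      if (k == 1L) next
      i <- idx[k]
      J <- idx[max(1L, k - window + 1L):(k - 1L)]
      r2 <- r2Block(g, i, J)
      hit <- J[!is.na(r2) & r2 >= 1 - tol]
      for (j in hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keys <- siteKeys(gm)
  tags <- keys[sort(unique(root))]
  pruned <- which(root != seq_len(n))
  map <- data.frame(pruned = keys[pruned], tag = keys[root[pruned]],
                    stringsAsFactors = FALSE)
  structure(list(tags = tags, map = map, n_input = n), class = "TagSNPSet")
}

#' @export
print.TagSNPSet <- function(x, ...) {
  cat(sprintf("TagSNPSet: %d tag SNPs from %d sites (%d pruned)\n",
              length(x$tags), x$n_input, nrow(x$map)))
  invisible(x)
}

#' All pairwise LD within a site-distance window
#'
#' @param gm \linkS4class{GenotypeMatrix} (sites sorted by chrom, pos).
#' @param max_sites_apart compute pairs at most this many sites apart.
#' @param max_dist keep pairs at most this many bp apart (default Inf).
#' @return data.frame: site_i, site_j, dist, r2 (undefined pairs dropped).
#' @export
computeLdPairs <- function(gm, max_sites_apart = 300L, max_dist = Inf) {
  s <- siteInfo(gm)
  g <- genoCodes(gm)
  keys <- siteKeys(gm)
  out <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    for (k in seq_along(idx)) {
      if (k == 1L) next
      i <- idx[k]
      J <- idx[max(1L, k - max_sites_apart):(k - 1L)]
      d <- s$pos[i] - s$pos[J]
      J <- J[d <= max_dist]
      if (!length(J)) next
      r2 <- r2Block(g, i, J)
      ok <- !is.na(r2)
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        site_i = keys[J[ok]], site_j = keys[i],
        dist = s$pos[i] - s$pos[J[ok]], r2 = r2[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(site_i = character(0),
                                      site_j = character(0),
                                      dist = numeric(0), r2 = numeric(0)))
  do.call(rbind, out)
}

#' LD decay distance
#'
#' Bins pairs by distance, averages r-squared per bin, and reports the
#' midpoint of the first bin whose mean falls below the threshold with all
#' subsequent occupied bins also below it.
#'
#' @param pairs data.frame from \code{\link{computeLdPairs}} (columns dist,
#'   r2).
#' @param bin_width distance bin width in bp.
#' @param threshold r-squared threshold (default 0.2).
#' @return list: \code{decay_bp} (NA when LD never decays in range),
#'   \code{open_ended} flag, \code{profile} (per-bin mean r2).
#' @export
ldDecay <- function(pairs, bin_width = 5e4, threshold = 0.2) {
  if (!nrow(pairs)) stop("no LD pairs supplied")
  bin <- floor(pairs$dist / bin_width)
  prof <- aggregate(list(mean_r2 = pairs$r2), list(bin = bin), mean)
  prof <- prof[order(prof$bin), ]
  prof$mid_bp <- (prof$bin + 0.5) * bin_width
  below <- prof$mean_r2 < threshold
  ## first bin below threshold with all later occupied bins also below
  ok <- rev(cumprod(rev(below))) == 1
  if (!any(ok)) {
    return(list(decay_bp = NA_real_, open_ended = TRUE, profile = prof))
  }
  list(decay_bp = prof$mid_bp[which(ok)[1]], open_ended = FALSE,
       profile = prof)
}

#' Variant and tag-SNP saturation curves
#'
#' For random sample subsets of increasing size, counts segregating variants
#' and tag SNPs within the subset, averaged over replicates. Within one
#' replicate the subsets are nested (a random sample order is drawn and each
#' size takes its prefix), the usual accumulation-curve design: every subset
#' is still a uniform draw without replacement, and per-replicate curves are
#' non-decreasing by construction, so replicate means estimate the expected
#' curve without crossing noise between adjacent sizes.
#'
#' @param gm \linkS4class{GenotypeMatrix}.
#' @param sizes subset sizes (each <= number of samples).
#' @param replicates random sample orders (default 10).
#' @param seed RNG seed.
#' @param window pruning window in SNPs.
#' @return list of class \code{SaturationCurve}: \code{curve} (data.frame
#'   size/mean_variants/mean_tags), \code{replicates}, \code{seed}.
#' @export
saturationAnalysis <- function(gm, sizes, replicates = 10L, seed = 1L,
                               window = 50L) {
  g <- genoCodes(gm)
  if (max(sizes) > ncol(g)) stop("subset size exceeds the number of samples")
  set.seed(seed)
  sizes <- sort(sizes)
  vt <- array(NA_real_, c(replicates, length(sizes), 2))
  for (r in seq_len(replicates)) {
    ord <- sample(colnames(g))
    for (si in seq_along(sizes)) {
      smp <- ord[seq_len(sizes[si])]
      sub <- g[, smp, drop = FALSE]
      seg <- segregatingSites(sub)
      vt[r, si, 1] <- sum(seg)
      vt[r, si, 2] <- if (any(seg))
        length(windowPrune(gm[which(seg), smp], window = window)$tags)
      else 0
    }
  }
  curve <- data.frame(size = sizes,
                      mean_variants = apply(vt[, , 1, drop = FALSE], 2, mean),
                      mean_tags = apply(vt[, , 2, drop = FALSE], 2, mean))
  structure(list(curve = curve, replicates = replicates, seed = seed),
            class = "SaturationCurve")
}

## a site segregates in a subset iff >= 2 distinct alleles among called
## genotypes (any heterozygote segregates by itself)
segregatingSites <- function(g) {
  any_het <- rowSums(g == 1L, na.rm = TRUE) > 0
  has_ref <- rowSums(g == 0L, na.rm = TRUE) > 0
  has_alt <- rowSums(g == 2L, na.rm = TRUE) > 0
  any_het | (has_ref & has_alt)
}
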