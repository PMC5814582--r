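#' Align two genotype matrices on shared loci and samples
#'
#' Intersects sites by (chrom, pos) with an allele-identity check: sites with
#' swapped ref/alt are reconciled by flipping platform-b codes (0 <-> 2);
#' sites whose alleles cannot be reconciled are dropped and logged. Samples
#' are intersected by id.
#'
#' @param a,b \linkS4class{GenotypeMatrix} objects.
#' @return list of class \code{PairedGenotypes}: \code{a}, \code{b} (code
#'   matrices on the shared sites x samples), \code{sites} (with an
#'   \code{is_indel} flag from platform-a alleles and a \code{flipped} flag),
#'   \code{samples}, \code{n_flipped}, \code{dropped} (site keys).
#' @export
alignLoci <- function(a, b) {
  sa <- siteInfo(a); sb <- siteInfo(b)
  ka <- paste(sa$chrom, sa$pos, sep = ":")
  kb <- paste(sb$chrom, sb$pos, sep = ":")
  shared <- intersect(ka, kb)
  samples <- intersect(sampleIds(a), sampleIds(b))
  if (!length(shared) || !length(samples)) {
    warning("no shared loci/samples between the two platforms")
    return(structure(list(a = matrix(integer(0), 0, length(samples)),
                          b = matrix(integer(0), 0, length(samples)),
                          sites = sa[0, ], samples = samples,
                          n_flipped = 0L, dropped = character(0)),
                     class = "PairedGenotypes"))
  }
  ia <- match(shared, ka); ib <- match(shared, kb)
  ga <- genoCodes(a)[ia, samples, drop = FALSE]
  gb <- genoCodes(b)[ib, samples, drop = FALSE]
  same <- sa$ref[ia] == sb$ref[ib] & sa$alt[ia] == sb$alt[ib]
  swapped <- sa$ref[ia] == sb$alt[ib] & sa$alt[ia] == sb$ref[ib] & !same
  bad <- !(same | swapped)
  if (any(swapped))
    gb[swapped, ] <- 2L - gb[swapped, , drop = FALSE]
  if (any(bad)) {
    message(sum(bad), " site(s) dropped: alleles not resolvable by swap")
  }
  keep <- !bad
  sites <- sa[ia, , drop = FALSE][keep, , drop = FALSE]
  sites$is_indel <- nchar(sites$ref) != nchar(sites$alt)
  sites$flipped <- swapped[keep]
  rownames(sites) <- NULL
  structure(list(a = ga[keep, , drop = FALSE], b = gb[keep, , drop = FALSE],
                 sites = sites, samples = samples,
                 n_flipped = sum(swapped),
                 dropped = shared[bad]),
            class = "PairedGenotypes")
}

#' Genotype concordance between two platforms
#'
#' A comparison is concordant iff codes are identical after reconciliation.
#' Comparisons are classed as homozygous or heterozygous from the platform-a
#' call, or as indel when the site is an indel. Comparisons missing in either
#' platform are excluded from the denominators and counted separately —
#' except, when \code{indel_surrogate = TRUE}, those where platform b is
#' missing while platform a has a call: these emulate an array that leaves
#' indel loci uncalled, are routed to the indel class, and count as
#' concordant iff platform a carries the alternative allele.
#'
#' @param paired a \code{PairedGenotypes} from \code{\link{alignLoci}}.
#' @param indel_surrogate route a-called/b-missing comparisons to the indel
#'   class (default FALSE).
#' @return list of class \code{ConcordanceReport}: \code{shared} (compared
#'   genotype count), \code{by_class} (data.frame class/n/concordant/
#'   concordance), \code{overall}, \code{excluded}, \code{no_comparable}.
#' @export
computeConcordance <- function(paired, indel_surrogate = FALSE) {
  ga <- paired$a; gb <- paired$b
  if (!length(ga)) {
    return(structure(list(shared = 0L,
                          by_class = data.frame(class = character(0)),
                          overall = NA_real_, excluded = 0L,
                          no_comparable = TRUE), class = "ConcordanceReport"))
  }
  is_indel <- paired$sites$is_indel
  indel_m <- matrix(is_indel, nrow(ga), ncol(ga))
  surrogate <- indel_surrogate & !is.na(ga) & is.na(gb)
  comparable <- (!is.na(ga) & !is.na(gb)) | surrogate

  cls <- matrix(NA_character_, nrow(ga), ncol(ga))
  cls[comparable] <- ifelse(indel_m[comparable] | surrogate[comparable],
                            "indel",
                            ifelse(ga[comparable] == 1L, "heterozygous",
                                   "homozygous"))
  conc <- matrix(NA, nrow(ga), ncol(ga))
  both <- !is.na(ga) & !is.na(gb)
  conc[both] <- ga[both] == gb[both]
  conc[surrogate] <- ga[surrogate] >= 1L # platform a sees the variant

  classes <- c("homozygous", "heterozygous", "indel")
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    sel <- !is.na(cls) & cls == cl
    n <- sum(sel)
    k <- sum(conc[sel])
    data.frame(class = cl, n = n, concordant = k,
               concordance = if (n) k / n else NA_real_)
  }))
  n_all <- sum(comparable)
  k_all <- sum(conc[comparable])
  structure(list(shared = n_all, by_class = by_class,
                 overall = if (n_all) k_all / n_all else NA_real_,
                 excluded = sum(!comparable),
                 no_comparable = n_all == 0L),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  if (x$no_comparable) {
    cat("ConcordanceReport: no comparable calls\n")
    return(invisible(x))
  }
  cat(sprintf("ConcordanceReport: %d shared genotypes, overall %.2f%% (%d excluded)\n",
              x$shared, 100 * x$overall, x$excluded))
  for (i in seq_len(nrow(x$by_class)))
    cat(sprintf("  %-13s n=%8d concordance %s\n", x$by_class$class[i],
                x$by_class$n[i],
                ifelse(is.na(x$by_class$concordance[i]), "NA",
                       sprintf("%.2f%%", 100 * x$by_class$concordance[i]))))
  invisible(x)
}

## nearest w typed flanking site indices for one missing site (same chrom)
nearestFlanking <- function(pos_all, chrom_all, typed_idx, m, w) {
  same <- typed_idx[chrom_all[typed_idx] == chrom_all[m]]
  if (!length(same)) return(integer(0))
  d <- abs(pos_all[same] - pos_all[m])
  same[order(d)][seq_len(min(w, length(same)))]
}

#' Simple k-nearest-neighbour genotype imputation
#'
#' For each missing/untyped genotype, the k panel samples with the smallest
#' Hamming distance to the target sample — computed over the nearest w typed
#' flanking sites on the same chromosome — vote by majority; ties break
#' toward the panel major genotype at the site. Panel samples matching the
#' target exactly over the window (distance zero) dominate the vote: when
#' any exist, only they vote, so a target identical to a panel haplotype is
#' reproduced exactly. A deliberately transparent
#' stand-in for a haplotype-model imputer, adequate for protocol testing on
#' block-haplotype cohorts.
#'
#' @param panel reference \linkS4class{GenotypeMatrix}.
#' @param target \linkS4class{GenotypeMatrix} on the same site set (missing
#'   codes are imputed).
#' @param k number of nearest panel neighbours (default 5).
#' @param w number of typed flanking sites for the distance (default 50).
#' @return The target with imputed codes, provenance "imputed", and an
#'   attribute \code{n_unimputable} (genotypes left missing for lack of
#'   typed flanking sites).
#' @export
imputeMissingSimple <- function(panel, target, k = 5L, w = 50L) {
  if (!identical(siteKeys(panel), siteKeys(target)))
    stop("panel and target must share an identical site set")
  gp <- genoCodes(panel)
  gt <- genoCodes(target)
  s <- siteInfo(panel)
  ## panel major genotype per site (ties toward the smaller code)
  major <- apply(gp, 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_integer_)
    tb <- table(factor(z, levels = 0:2))
    as.integer(names(tb)[which.max(tb)])
  })
  n_unimputable <- 0L
  out <- gt
  for (smp in seq_len(ncol(gt))) {
    missing_idx <- which(is.na(gt[, smp]))
    typed_idx <- which(!is.na(gt[, smp]))
    if (!length(missing_idx)) next
    for (m in missing_idx) {
      fl <- nearestFlanking(s$pos, s$chrom, typed_idx, m, w)
      if (!length(fl)) {
        n_unimputable <- n_unimputable + 1L
        next
      }
      tv <- gt[fl, smp]
      pm <- gp[fl, , drop = FALSE]
      cmp <- !is.na(pm) & !is.na(tv)
      mism <- colSums((pm != tv) & cmp)
      ncmp <- colSums(cmp)
      d <- ifelse(ncmp > 0, mism / ncmp, Inf)
      ## exact matches over the window dominate approximate neighbours
      nb <- if (any(d == 0)) which(d == 0)
            else order(d)[seq_len(min(k, length(d)))]
      votes <- gp[m, nb]
      votes <- votes[!is.na(votes)]
      if (!length(votes)) {
        out[m, smp] <- major[m]
        next
      }
      tb <- table(factor(votes, levels = 0:2))
      top <- which(tb == max(tb))
      out[m, smp] <- if (length(top) > 1L && !is.na(major[m]))
        major[m] else as.integer(names(tb)[top[1]])
    }
  }
  res <- GenotypeMatrix(out, s, provenance = "imputed")
  attr(res, "n_unimputable") <- n_unimputable
  res
}

#' Leave-one-out untyped-locus imputation accuracy
#'
#' Emulates the protocol used to validate imputation at untyped loci: per
#' permutation one accession is removed from the dense (WGS) reference
#' panel; its genotypes at the untyped loci (present in the panel, absent
#' from the low-density set) are imputed from its low-density genotypes and
#' the remaining panel, then compared to the withheld dense truth.
#'
#' @param wgs_panel dense \linkS4class{GenotypeMatrix} (all loci, all
#'   accessions).
#' @param lowdensity \linkS4class{GenotypeMatrix} on a subset of loci; every
#'   low-density sample must be present in the panel.
#' @param n_permutations accessions to withhold (sampled without
#'   replacement; default 5).
#' @param seed RNG seed for the permutation draw.
#' @param k,w imputer parameters (see \code{\link{imputeMissingSimple}}).
#' @return list: \code{per_permutation} (data.frame sample/n_untyped/
#'   n_imputed/accuracy/het_accuracy/hom_accuracy), \code{mean_accuracy},
#'   \code{n_untyped}; \code{no_untyped = TRUE} when the low-density set
#'   already covers every panel locus.
#' @export
evaluateUntypedImputation <- function(wgs_panel, lowdensity,
                                      n_permutations = 5L, seed = 1L,
                                      k = 5L, w = 50L) {
  if (n_permutations > ncol(genoCodes(wgs_panel)))
    stop("n_permutations exceeds the number of panel samples")
  if (!all(sampleIds(lowdensity) %in% sampleIds(wgs_panel)))
    stop("every low-density sample must be present in the WGS panel")
  typed <- siteKeys(wgs_panel) %in% siteKeys(lowdensity)
  untyped_keys <- siteKeys(wgs_panel)[!typed]
  if (!length(untyped_keys)) {
    return(list(per_permutation = NULL, mean_accuracy = NA_real_,
                n_untyped = 0L, no_untyped = TRUE))
  }
  set.seed(seed)
  held <- sample(intersect(sampleIds(lowdensity), sampleIds(wgs_panel)),
                 n_permutations)
  rows <- lapply(held, function(smp) {
    panel <- wgs_panel[, setdiff(sampleIds(wgs_panel), smp)]
    tg <- matrix(NA_integer_, nrow(genoCodes(wgs_panel)), 1,
                 dimnames = list(NULL, smp))
    ld_idx <- match(siteKeys(wgs_panel), siteKeys(lowdensity))
    has_ld <- !is.na(ld_idx)
    tg[has_ld, 1] <- genoCodes(lowdensity)[ld_idx[has_ld], smp]
    target <- GenotypeMatrix(tg, siteInfo(wgs_panel), provenance = "gbs")
    imp <- imputeMissingSimple(panel, target, k = k, w = w)
    truth <- genoCodes(wgs_panel)[!typed, smp]
    est <- genoCodes(imp)[!typed, 1]
    ok <- !is.na(truth) & !is.na(est)
    acc_of <- function(sel) {
      sel <- sel & ok
      if (!sum(sel)) NA_real_ else mean(est[sel] == truth[sel])
    }
    data.frame(sample = smp, n_untyped = sum(!typed), n_imputed = sum(ok),
               accuracy = acc_of(rep(TRUE, length(ok))),
               het_accuracy = acc_of(truth == 1L),
               hom_accuracy = acc_of(truth != 1L),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_permutation = per, mean_accuracy = mean(per$accuracy, na.rm = TRUE),
       n_untyped = sum(!typed), no_untyped = FALSE)
}
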