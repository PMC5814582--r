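#' Specification for a synthetic resequencing cohort
#'
#' Describes a fully self-contained toy cohort: a reference genome, gene
#' models, an inbred diploid genotype matrix with subpopulation structure and
#' a realistic minor-allele-frequency spectrum, planted duplicated segments
#' that produce clustered heterozygous calls plus elevated read depth, a
#' structural-variant truth set with mock multi-caller outputs, and an
#' array-genotype subset of the sequenced loci.
#'
#' Genotypes follow a block-haplotype model: each chromosome is divided into
#' blocks of \code{block_length} bp; within a block every sample carries one
#' of a small number of founder haplotypes (inbred lines are homozygous for
#' their haplotype). Sites are assigned minor-allele carriers as unions of
#' founder groups. Under the default \code{haplotype_scheme = "binary"} the
#' founder group sizes are 1, 2, 4, ... plus a remainder, so any minor-allele
#' sample count is an exact subset sum and the realized MAF spectrum matches
#' \code{maf_spectrum} exactly (up to multinomial bin sampling). The
#' \code{"balanced"} scheme uses \code{n_founders} near-equal groups, which is
#' the natural choice when every haplotype must be shared by several samples
#' (e.g. imputation experiments).
#'
#' @param seed integer; fixed seed implies byte-identical outputs.
#' @param n_chromosomes,chrom_length genome shape (chromosome count, bp each).
#' @param n_samples,n_subpopulations cohort size and subpopulation count.
#' @param n_snp_sites number of biallelic SNP sites to plant.
#' @param maf_spectrum weights of the five MAF bins
#'   [0,0.1), [0.1,0.2), [0.2,0.3), [0.3,0.4), [0.4,0.5]; must sum to 1.
#' @param background_het_rate per-genotype probability of a spurious
#'   heterozygous call outside duplicated segments (fraction in [0,1)).
#' @param missing_rate per-genotype missing-data probability.
#' @param n_genes number of protein-coding gene models to plant.
#' @param block_length haplotype block length in bp.
#' @param haplotype_scheme "binary" or "balanced" (see Details).
#' @param n_founders founder haplotypes per block (balanced scheme).
#' @param structure_noise admixture of the founder-to-subpopulation
#'   assignment; 0 = founders nested perfectly in subpopulations.
#' @param duplication_segments data.frame with columns chrom, start, end
#'   (1-based bp), carriers (comma-separated sample ids), depth_multiplier
#'   (>= 1.5) and het_rate (artefactual heterozygosity rate inside the
#'   segment for carriers; 0 or > 10 x background_het_rate). The string
#'   "default" plants two stock segments; NULL plants none.
#' @param sv_truth_counts named integer vector of true SV counts per type
#'   (DEL, INS, DUP, INV, CNV, TRA_intra, TRA_inter).
#' @param caller_profiles list of mock caller profiles; see
#'   \code{\link{defaultCallerProfiles}}.
#' @param array_fraction fraction of SNP sites also typed on the mock array.
#' @param array_error_rate per-genotype array error rate.
#' @param array_missing_rate per-genotype array missing rate.
#' @param depth_mean genome-wide mean sequencing depth (x coverage).
#' @param depth_window window size (bp) of the emitted depth track.
#' @param flip_alt_prob probability that the reference allele is the minor
#'   allele at a site (alt-allele frequency > 0.5).
#'
#' @return An object of class \code{SyntheticSpec} (a validated list).
#' @export
syntheticSpec <- function(seed = 1L,
                          n_chromosomes = 2L,
                          chrom_length = 1e6,
                          n_samples = 102L,
                          n_subpopulations = 5L,
                          n_snp_sites = 2000L,
                          maf_spectrum = c(0.35, 0.19, 0.17, 0.15, 0.14),
                          background_het_rate = 0.005,
                          missing_rate = 0.02,
                          n_genes = 40L,
                          block_length = 1e5,
                          haplotype_scheme = c("binary", "balanced"),
                          n_founders = 8L,
                          structure_noise = 1.5,
                          duplication_segments = "default",
                          sv_truth_counts = c(DEL = 120L, INS = 40L, DUP = 15L,
                                              INV = 15L, CNV = 10L,
                                              TRA_intra = 8L, TRA_inter = 4L),
                          caller_profiles = defaultCallerProfiles(),
                          array_fraction = 0.15,
                          array_error_rate = 0.003,
                          array_missing_rate = 0.01,
                          depth_mean = 11,
                          depth_window = 1e4,
                          flip_alt_prob = 0.2) {
  haplotype_scheme <- match.arg(haplotype_scheme)
  samples <- sprintf("S%03d", seq_len(n_samples))
  if (identical(duplication_segments, "default")) {
    duplication_segments <- data.frame(
      chrom = "Chr01",
      start = c(2e5, 6e5),
      end = c(3e5, 7e5),
      carriers = c(paste(samples[1:3], collapse = ","),
                   paste(samples[4:6], collapse = ",")),
      depth_multiplier = 2.0,
      het_rate = 0.4,
      stringsAsFactors = FALSE)
    duplication_segments <- duplication_segments[
      duplication_segments$end <= chrom_length, , drop = FALSE]
  }
  spec <- structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, n_samples = as.integer(n_samples),
    n_subpopulations = as.integer(n_subpopulations),
    n_snp_sites = as.integer(n_snp_sites), maf_spectrum = maf_spectrum,
    background_het_rate = background_het_rate, missing_rate = missing_rate,
    n_genes = as.integer(n_genes), block_length = block_length,
    haplotype_scheme = haplotype_scheme, n_founders = as.integer(n_founders),
    structure_noise = structure_noise,
    duplication_segments = duplication_segments,
    sv_truth_counts = sv_truth_counts, caller_profiles = caller_profiles,
    array_fraction = array_fraction, array_error_rate = array_error_rate,
    array_missing_rate = array_missing_rate,
    depth_mean = depth_mean, depth_window = depth_window,
    flip_alt_prob = flip_alt_prob,
    samples = samples), class = "SyntheticSpec")
  validateSyntheticSpec(spec)
  spec
}

validateSyntheticSpec <- function(spec) {
  if (abs(sum(spec$maf_spectrum) - 1) > 1e-8)
    stop("maf_spectrum weights must sum to 1")
  if (length(spec$maf_spectrum) != 5L)
    stop("maf_spectrum must have 5 bin weights")
  if (spec$background_het_rate < 0 || spec$background_het_rate >= 1)
    stop("background_het_rate must be in [0, 1)")
  seg <- spec$duplication_segments
  if (!is.null(seg) && nrow(seg)) {
    if (any(seg$start < 1 | seg$end > spec$chrom_length | seg$start >= seg$end))
      stop("duplication segments must lie within chromosome bounds")
    if (any(seg$depth_multiplier < 1.5))
      stop("duplication depth_multiplier must be >= 1.5")
    bad_rate <- seg$het_rate != 0 &
      seg$het_rate <= 10 * spec$background_het_rate
    if (any(bad_rate))
      stop("artefact het_rate must be 0 or > 10 x background_het_rate")
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping duplication segments on ", ch)
    }
    unk <- setdiff(unlist(expandIds(seg$carriers)), spec$samples)
    if (length(unk))
      stop("unknown carrier samples: ", paste(unk, collapse = ", "))
  }
  bad <- setdiff(names(spec$sv_truth_counts),
                 c("DEL", "INS", "DUP", "INV", "CNV", "TRA_intra", "TRA_inter"))
  if (length(bad)) stop("unknown SV types in sv_truth_counts: ",
                        paste(bad, collapse = ", "))
  for (p in spec$caller_profiles) {
    if (p$fn_rate < 0 || p$fn_rate > 1)
      stop("caller fn_rate must be in [0, 1]")
    if (p$breakpoint_jitter_sd < 0)
      stop("breakpoint_jitter_sd must be >= 0")
  }
  invisible(spec)
}

#' Default mock caller profiles
#'
#' Three profiles emulating the behaviour of a multi-signal caller, a
#' paired-end caller and a read-depth caller: per-tool false-negative rates,
#' false-positive counts, breakpoint jitter, and SV types a tool cannot emit
#' (the paired-end tool misses tandem duplications; the read-depth tool sees
#' only copy-number-changing events; the multi-signal tool misses
#' interchromosomal translocations).
#'
#' @param fn_rates,fp_counts,jitter_sds numeric length-3 overrides, in the
#'   order (pairsplit, pairedend, readdepth).
#' @return list of caller profile lists with fields name, fn_rate, fp_count,
#'   breakpoint_jitter_sd, cannot_types, dialect.
#' @export
defaultCallerProfiles <- function(fn_rates = c(0.05, 0.15, 0.20),
                                  fp_counts = c(8L, 12L, 10L),
                                  jitter_sds = c(20, 60, 80)) {
  list(
    list(name = "pairsplit", fn_rate = fn_rates[1], fp_count = fp_counts[1],
         breakpoint_jitter_sd = jitter_sds[1],
         cannot_types = "TRA_inter", dialect = "vcf"),
    list(name = "pairedend", fn_rate = fn_rates[2], fp_count = fp_counts[2],
         breakpoint_jitter_sd = jitter_sds[2],
         cannot_types = "CNV", dialect = "bedpe"),
    list(name = "readdepth", fn_rate = fn_rates[3], fp_count = fp_counts[3],
         breakpoint_jitter_sd = jitter_sds[3],
         cannot_types = c("INV", "TRA_intra", "TRA_inter"), dialect = "vcf"))
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf(
    "SyntheticSpec: %d samples (%d subpops), %d chrom x %s bp, %d SNP sites, %d genes\n",
    x$n_samples, x$n_subpopulations, x$n_chromosomes,
    format(x$chrom_length, big.mark = ","), x$n_snp_sites, x$n_genes))
  cat(sprintf("  het background %.3g, %d duplication segments, %d true SVs, %d mock callers\n",
              x$background_het_rate,
              if (is.null(x$duplication_segments)) 0L else nrow(x$duplication_segments),
              sum(x$sv_truth_counts), length(x$caller_profiles)))
  invisible(x)
}

## founder group sizes: binary scheme gives exact subset sums for any c <= n
founderCounts <- function(n, scheme, n_founders) {
  if (scheme == "balanced") {
    return(diff(round(seq(0, n, length.out = n_founders + 1))))
  }
  k <- 0L
  while (2^(k + 1) - 1 <= n) k <- k + 1L
  powers <- 2^(seq_len(k) - 1)          # 1, 2, ..., 2^(k-1); sum = 2^k - 1
  r <- n - (2^k - 1)
  if (r > 0) c(powers, r) else powers
}

## deterministic founder subset whose group sizes sum (near-)exactly to c
founderSubset <- function(c_target, counts, scheme) {
  nf <- length(counts)
  if (scheme == "binary") {
    powers_sum <- sum(counts[-nf]) # counts are powers plus optional remainder
    has_rem <- counts[nf] != 2^(nf - 1)
    sel <- logical(nf)
    c_left <- c_target
    if (has_rem && c_left > powers_sum) {
      sel[nf] <- TRUE
      c_left <- c_left - counts[nf]
    }
    np <- if (has_rem) nf - 1L else nf
    for (i in rev(seq_len(np))) {
      if (counts[i] <= c_left) {
        sel[i] <- TRUE
        c_left <- c_left - counts[i]
      }
    }
    return(which(sel))
  }
  ## balanced: greedy in random order, never overshooting
  ord <- sample.int(nf)
  sel <- integer(0)
  run <- 0
  for (i in ord) {
    if (run + counts[i] <= c_target) {
      sel <- c(sel, i)
      run <- run + counts[i]
    }
  }
  sort(sel)
}
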