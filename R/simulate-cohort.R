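#' Generate a synthetic cohort with known ground truth
#'
#' Builds the complete toy data set described by a \code{\link{syntheticSpec}}
#' and writes it to disk: reference FASTA, GFF3 gene models, a multi-sample
#' VCF of SNP genotypes, per-caller SV call sets (VCF or BEDPE dialect), an
#' array-genotype table and per-sample BED-graph depth tracks. All
#' randomness is driven by \code{spec$seed}; the same spec yields
#' byte-identical files.
#'
#' @param spec a \code{SyntheticSpec}.
#' @param dir output directory (created if missing).
#' @return A \code{TruthSet}: a list with the emitted file paths and the
#'   ground truth for every downstream stage (genotype matrix as emitted,
#'   pre-noise haplotype genotypes, site table, gene models, SV truth set,
#'   per-caller call tables, duplication segments, array matrix).
#' @export
generateCohort <- function(spec, dir = tempfile("cohort")) {
  validateSyntheticSpec(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "callers"), showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), showWarnings = FALSE)
  set.seed(spec$seed)

  chroms <- sprintf("Chr%02d", seq_len(spec$n_chromosomes))
  chrom_len <- setNames(rep(spec$chrom_length, spec$n_chromosomes), chroms)

  ## --- reference sequence -------------------------------------------------
  bases <- c("A", "C", "G", "T")
  ref_seq <- lapply(chrom_len, function(L)
    sample(bases, L, replace = TRUE))

  ## --- gene models (CDS built codon-aware, patched into the reference) ----
  genes <- simulateGeneModels(spec, chroms, chrom_len)
  ref_seq <- patchCdsSequence(ref_seq, genes)
  ref_char <- vapply(ref_seq, paste, character(1), collapse = "")
  ref <- Biostrings::DNAStringSet(ref_char)
  names(ref) <- chroms

  fa_path <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref, fa_path, width = 80L)
  gff_path <- file.path(dir, "genes.gff3")
  writeGeneModelsGff3(genes, gff_path, chrom_len)

  ## --- genotype matrix ----------------------------------------------------
  gt <- simulateGenotypes(spec, chroms, chrom_len, ref_seq)

  vcf_path <- file.path(dir, "variants.vcf")
  writeVariantVcf(gt$gm, vcf_path, qc = gt$site_qc, contigs = chrom_len)

  ## --- SV truth set and mock caller outputs -------------------------------
  svs <- simulateSvTruth(spec, chroms, chrom_len)
  calls <- simulateCallerOutputs(svs, spec$caller_profiles, chrom_len)
  caller_files <- character(0)
  for (p in spec$caller_profiles) {
    cs <- calls[[p$name]]
    if (identical(p$dialect, "bedpe")) {
      f <- file.path(dir, "callers", paste0(p$name, ".bedpe"))
      writeCallsetBedpe(cs, f)
    } else {
      f <- file.path(dir, "callers", paste0(p$name, ".vcf"))
      writeCallsetVcf(cs, f, contigs = chrom_len)
    }
    caller_files[p$name] <- f
  }

  ## --- array subset -------------------------------------------------------
  arr <- simulateArraySubset(spec, gt$gm)
  array_path <- file.path(dir, "array_genotypes.tsv")
  writeArrayTable(arr, array_path)

  ## --- depth tracks -------------------------------------------------------
  depth <- simulateDepthTrack(spec, chroms, chrom_len)
  depth_files <- vapply(spec$samples, function(s) {
    f <- file.path(dir, "depth", paste0(s, ".bedgraph"))
    d <- depth[depth$sample == s, c("chrom", "start", "end", "depth")]
    write.table(format(d, scientific = FALSE, trim = TRUE), f, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    f
  }, character(1))

  ## --- truth TSVs (so a pipeline run is inspectable from disk) ------------
  truth_sv_path <- file.path(dir, "truth_svs.tsv")
  writeTsv(svs, truth_sv_path)
  seg <- spec$duplication_segments
  dup_path <- file.path(dir, "duplication_segments.tsv")
  if (!is.null(seg)) writeTsv(seg, dup_path)

  structure(list(
    spec = spec, dir = dir,
    files = c(reference = fa_path, genes = gff_path, variants = vcf_path,
              array = array_path, truth_svs = truth_sv_path,
              duplications = dup_path, caller_files, depth_files),
    genotypes = gt$gm, truth_geno = gt$truth_geno, site_qc = gt$site_qc,
    sites = siteInfo(gt$gm), subpop = gt$subpop,
    gene_models = genes, true_svs = svs, caller_calls = calls,
    duplication_segments = seg, array = arr, depth = depth,
    chrom_lengths = chrom_len), class = "TruthSet")
}

#' @export
print.TruthSet <- function(x, ...) {
  cat(sprintf("TruthSet in %s\n", x$dir))
  cat(sprintf("  %d SNP sites x %d samples; %d genes; %d true SVs; %d callers\n",
              nrow(genoCodes(x$genotypes)), ncol(genoCodes(x$genotypes)),
              nrow(x$gene_models@genes), nrow(x$true_svs),
              length(x$caller_calls)))
  invisible(x)
}

## ---- gene models ----------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

simulateGeneModels <- function(spec, chroms, chrom_len) {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense_codons <- setdiff(all_codons, STOP_CODONS)
  genes <- list(); exons <- list(); cds <- list()
  gi <- 0L
  per_chrom <- diff(round(seq(0, spec$n_genes, length.out = length(chroms) + 1)))
  for (ci in seq_along(chroms)) {
    pos <- 2000
    for (k in seq_len(per_chrom[ci])) {
      n_ex <- sample(1:3, 1)
      ex_len <- 3 * sample(40:120, n_ex, replace = TRUE)
      intron_len <- if (n_ex > 1) sample(120:400, n_ex - 1, replace = TRUE) else integer(0)
      width <- sum(ex_len) + sum(intron_len)
      start <- pos + sample(2000:15000, 1)
      end <- start + width - 1
      if (end > chrom_len[ci] - 2000) break
      pos <- end
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      strand <- sample(c("+", "-"), 1)
      ex_start <- start + c(0, cumsum(ex_len[-n_ex] + intron_len))
      ex_end <- ex_start + ex_len - 1
      ncod <- sum(ex_len) / 3
      cds_seq <- paste0("ATG",
                        paste(sample(sense_codons, ncod - 2, replace = TRUE),
                              collapse = ""),
                        sample(STOP_CODONS, 1))
      genes[[gi]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                strand = strand, start = start, end = end,
                                cds_seq = cds_seq, stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                strand = strand, start = ex_start, end = ex_end,
                                rank = seq_len(n_ex), stringsAsFactors = FALSE)
    }
  }
  empty_g <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), cds_seq = character(0),
                        stringsAsFactors = FALSE)
  empty_e <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), rank = integer(0),
                        stringsAsFactors = FALSE)
  genes <- if (length(genes)) do.call(rbind, genes) else empty_g
  exons <- if (length(exons)) do.call(rbind, exons) else empty_e
  cds <- exons # single-transcript models: CDS == exons
  GeneModelSet(genes = genes, exons = exons, cds = cds)
}

## write each gene's codon-aware CDS into the reference (strand-aware)
patchCdsSequence <- function(ref_seq, models) {
  genes <- models@genes
  cds <- models@cds
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- cds[cds$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    seq_nt <- strsplit(g$cds_seq, "")[[1]]
    if (g$strand == "-") {
      seq_nt <- rev(chartr("ACGT", "TGCA", seq_nt))
    }
    offset <- 0L
    for (e in seq_len(nrow(ex))) {
      len <- ex$end[e] - ex$start[e] + 1L
      ref_seq[[g$chrom]][ex$start[e]:ex$end[e]] <-
        seq_nt[(offset + 1):(offset + len)]
      offset <- offset + len
    }
  }
  ref_seq
}

## ---- genotypes ------------------------------------------------------------

simulateGenotypes <- function(spec, chroms, chrom_len, ref_seq) {
  n <- spec$n_samples
  samples <- spec$samples
  subpop <- sort(rep(seq_len(spec$n_subpopulations), length.out = n))

  ## site positions, proportional to chromosome length
  per_chrom <- diff(round(seq(0, spec$n_snp_sites,
                              length.out = length(chroms) + 1)))
  site_chrom <- rep(chroms, per_chrom)
  site_pos <- unlist(lapply(seq_along(chroms), function(ci)
    sort(sample.int(chrom_len[ci] - 1, per_chrom[ci]))))
  n_sites <- length(site_pos)

  ref_al <- vapply(seq_len(n_sites), function(i)
    ref_seq[[site_chrom[i]]][site_pos[i]], character(1))
  alt_al <- vapply(ref_al, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
    USE.NAMES = FALSE)

  ## founder assignment per (chrom, block)
  block <- paste(site_chrom, (site_pos - 1) %/% spec$block_length, sep = "_")
  blocks <- unique(block)
  counts <- founderCounts(n, spec$haplotype_scheme, spec$n_founders)
  founder_of <- list()
  for (b in blocks) {
    ord <- order(subpop + runif(n) * spec$structure_noise)
    f <- integer(n)
    f[ord] <- rep(seq_along(counts), counts)
    founder_of[[b]] <- f
  }

  ## per-site minor-allele carriers as founder subsets
  bin_lo <- c(0, 0.1, 0.2, 0.3, 0.4)
  bin_hi <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  bin_idx <- sample.int(5L, n_sites, replace = TRUE, prob = spec$maf_spectrum)
  maf_target <- runif(n_sites, bin_lo[bin_idx], bin_hi[bin_idx])
  c_target <- pmin(pmax(round(maf_target * n), 1L), floor(n / 2))

  geno <- matrix(0L, n_sites, n, dimnames = list(NULL, samples))
  flip <- runif(n_sites) < spec$flip_alt_prob
  for (i in seq_len(n_sites)) {
    sel <- founderSubset(c_target[i], counts, spec$haplotype_scheme)
    carrier <- founder_of[[block[i]]] %in% sel
    geno[i, carrier] <- 2L
    if (flip[i]) geno[i, ] <- 2L - geno[i, ]
  }
  truth_geno <- geno

  ## background heterozygosity
  if (spec$background_het_rate > 0) {
    hit <- matrix(runif(n_sites * n) < spec$background_het_rate, n_sites, n)
    geno[hit] <- 1L
  }
  ## artefactual heterozygosity inside duplicated segments (carriers only)
  seg <- spec$duplication_segments
  if (!is.null(seg) && nrow(seg)) {
    for (k in seq_len(nrow(seg))) {
      if (seg$het_rate[k] <= 0) next
      in_seg <- site_chrom == seg$chrom[k] &
        site_pos >= seg$start[k] & site_pos <= seg$end[k]
      carr <- match(expandIds(seg$carriers[k])[[1]], samples)
      for (s in carr) {
        hit <- in_seg & runif(n_sites) < seg$het_rate[k]
        geno[hit, s] <- 1L
      }
    }
  }
  ## missing data
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(n_sites * n) < spec$missing_rate, n_sites, n)
    geno[miss] <- NA_integer_
  }

  sites <- data.frame(chrom = site_chrom, pos = site_pos,
                      ref = ref_al, alt = alt_al, stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(geno, sites, provenance = "wgs")

  ## per-site QC fields for the emitted VCF (clean by construction)
  dp_site <- pmax(2, round(rnorm(n_sites, spec$depth_mean, 1.2), 1))
  site_qc <- data.frame(
    qual = round(runif(n_sites, 40, 90), 1),
    mq = round(runif(n_sites, 30, 60), 1),
    depth = dp_site,
    saf_ref = pmax(1L, round(dp_site * n / 4)),
    sar_ref = pmax(1L, round(dp_site * n / 4)),
    saf_alt = pmax(1L, round(dp_site * n / 8)),
    sar_alt = pmax(1L, round(dp_site * n / 8)))

  list(gm = gm, truth_geno = truth_geno, site_qc = site_qc, subpop = subpop)
}

## ---- SV truth -------------------------------------------------------------

svSizeRange <- function(type) {
  switch(type,
         DEL = c(2, 3.7), INS = c(1.5, 3), DUP = c(2.7, 4),
         INV = c(2, 3.5), CNV = c(2.7, 4), TRA_intra = c(3, 5),
         TRA_inter = c(2, 3.5))
}

simulateSvTruth <- function(spec, chroms, chrom_len, min_gap = 500) {
  counts <- spec$sv_truth_counts
  types <- rep(names(counts), counts)
  occupied <- lapply(chroms, function(x) data.frame(start = numeric(0),
                                                    end = numeric(0)))
  names(occupied) <- chroms
  place <- function(chrom, width) {
    w <- width
    for (try in 1:600) {
      occ <- occupied[[chrom]]
      if (chrom_len[chrom] - w - 1 >= 1) {
        s <- sample.int(chrom_len[chrom] - w - 1, 1)
        e <- s + w
        if (!nrow(occ) ||
            all(e + min_gap <= occ$start | s - min_gap >= occ$end)) {
          occupied[[chrom]] <<- rbind(occ, data.frame(start = s, end = e))
          return(list(chrom = chrom, s = s, e = e))
        }
      }
      ## crowded: progressively shrink and allow any chromosome
      if (try %% 100 == 0) w <- max(50, round(w / 2))
      if (try %% 25 == 0) chrom <- sample(names(chrom_len), 1)
    }
    stop("could not place SV; genome too crowded")
  }
  out <- vector("list", length(types))
  for (i in seq_along(types)) {
    ty <- types[i]
    rng <- svSizeRange(ty)
    ## cap widths so that many SVs always fit on toy-sized chromosomes
    hi <- min(rng[2], log10(min(chrom_len) / 10))
    width <- round(10^runif(1, rng[1], max(rng[1], hi)))
    chrom <- sample(chroms, 1)
    if (ty == "INS") {
      at <- place(chrom, 1)
      chrom <- at$chrom
      s <- at$s; e <- at$s + 1; chrom2 <- chrom; len <- width
    } else if (ty == "TRA_inter" && length(chroms) > 1) {
      at <- place(chrom, 1)
      chrom <- at$chrom
      chrom2 <- sample(setdiff(chroms, chrom), 1)
      at2 <- place(chrom2, 1)
      if (at2$chrom != chrom2) chrom2 <- at2$chrom
      s <- at$s; e <- at2$s; len <- width
    } else {
      at <- place(chrom, width)
      chrom <- at$chrom
      s <- at$s; e <- at$e; chrom2 <- chrom; len <- at$e - at$s
    }
    carr <- sort(sample(spec$samples, sample(2:min(10, spec$n_samples), 1)))
    rd <- switch(ty, DEL = runif(1, 0.3, 0.6),
                 DUP = runif(1, 1.6, 2.4), CNV = runif(1, 1.6, 2.4),
                 NA_real_)
    out[[i]] <- data.frame(
      id = sprintf("SV%04d", i), sv_type = ty, chrom = chrom,
      start = s, end = e, chrom2 = chrom2, length = len,
      gq = round(runif(1, 40, 90)), pe = round(runif(1, 15, 60)),
      rd_ratio = round(rd, 3),
      genotyped_ratio = if (ty == "INV") round(runif(1, 0.6, 3), 2) else NA_real_,
      carrier_pair_fraction = if (ty == "INV") round(runif(1, 0.4, 0.9), 2) else NA_real_,
      carriers = paste(carr, collapse = ","), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## ---- array subset ---------------------------------------------------------

simulateArraySubset <- function(spec, gm) {
  g <- genoCodes(gm)
  n_sites <- nrow(g)
  idx <- sort(sample.int(n_sites, round(spec$array_fraction * n_sites)))
  a <- g[idx, , drop = FALSE]
  if (spec$array_error_rate > 0) {
    err <- which(!is.na(a) & matrix(runif(length(a)) < spec$array_error_rate,
                                    nrow(a)))
    if (length(err))
      a[err] <- (a[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
  }
  if (spec$array_missing_rate > 0) {
    a[matrix(runif(length(a)) < spec$array_missing_rate, nrow(a))] <- NA_integer_
  }
  GenotypeMatrix(a, siteInfo(gm)[idx, , drop = FALSE], provenance = "array")
}

## ---- depth track ----------------------------------------------------------

simulateDepthTrack <- function(spec, chroms, chrom_len) {
  seg <- spec$duplication_segments
  out <- list()
  sample_mean <- rnorm(spec$n_samples, spec$depth_mean, 1.2)
  for (si in seq_along(spec$samples)) {
    s <- spec$samples[si]
    for (ch in chroms) {
      starts <- seq(0, chrom_len[ch] - 1, by = spec$depth_window)
      ends <- pmin(starts + spec$depth_window, chrom_len[ch])
      d <- pmax(0.5, rnorm(length(starts), sample_mean[si], 0.7))
      if (!is.null(seg) && nrow(seg)) {
        for (k in seq_len(nrow(seg))) {
          if (seg$chrom[k] != ch) next
          if (!(s %in% expandIds(seg$carriers[k])[[1]])) next
          ov <- pmax(0, pmin(ends, seg$end[k]) - pmax(starts, seg$start[k] - 1))
          f <- ov / (ends - starts)
          d <- d * (1 + (seg$depth_multiplier[k] - 1) * f)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = ch, start = starts, end = ends,
        depth = round(d, 2), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
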