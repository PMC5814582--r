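# Cross-platform genotype concordance and the imputation protocol.

mkGM <- function(codes, pos = NULL, ref = "A", alt = "T", prov = "wgs",
                 chrom = "Chr01") {
  n_sites <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  GenotypeMatrix(codes, data.frame(chrom = chrom, pos = pos, ref = ref,
                                   alt = alt, stringsAsFactors = FALSE), prov)
}

test_that("identical matrices pair fully and are 100% concordant", {
  set.seed(2)
  g <- matrix(sample(c(0L, 1L, 2L), 200, TRUE), 20, 10,
              dimnames = list(NULL, sprintf("S%03d", 1:10)))
  a <- mkGM(g)
  b <- mkGM(g, prov = "array")
  p <- alignLoci(a, b)
  expect_equal(nrow(p$sites), 20L)
  rep_ <- computeConcordance(p)
  expect_equal(rep_$overall, 1)
  expect_true(all(rep_$by_class$concordance[rep_$by_class$n > 0] == 1))
})

test_that("disjoint site sets warn and give an empty pairing", {
  g <- matrix(0L, 5, 3, dimnames = list(NULL, c("S001", "S002", "S003")))
  a <- mkGM(g, pos = 1:5 * 10L)
  b <- mkGM(g, pos = 1:5 * 10L + 1L)
  expect_warning(p <- alignLoci(a, b), "no shared")
  rep_ <- computeConcordance(p)
  expect_true(rep_$no_comparable)
})

test_that("ref/alt swaps are reconciled by flipping codes", {
  set.seed(3)
  g <- matrix(sample(c(0L, 1L, 2L), 1000, TRUE), 100, 10,
              dimnames = list(NULL, sprintf("S%03d", 1:10)))
  a <- mkGM(g)
  swap <- sample(100, 10)
  ref_b <- rep("A", 100); alt_b <- rep("T", 100)
  ref_b[swap] <- "T"; alt_b[swap] <- "A"
  gb <- g
  gb[swap, ] <- 2L - gb[swap, , drop = FALSE]
  b <- GenotypeMatrix(gb, data.frame(chrom = "Chr01", pos = 1:100 * 100L,
                                     ref = ref_b, alt = alt_b), "array")
  p <- alignLoci(a, b)
  expect_equal(nrow(p$sites), 100L)
  expect_equal(p$n_flipped, 10L)
  expect_equal(computeConcordance(p)$overall, 1)
  # an unresolvable allele mismatch is dropped and logged
  bad <- b
  bad@sites$alt[1] <- "G"
  expect_message(p2 <- alignLoci(a, bad), "dropped")
  expect_equal(nrow(p2$sites), 99L)
})

test_that("planted discordances give the expected overall concordance", {
  g <- matrix(0L, 100, 10, dimnames = list(NULL, sprintf("S%03d", 1:10)))
  g[sample(length(g), 300)] <- 2L
  a <- mkGM(g)
  gb <- g
  flip_idx <- sample(length(g), 14)
  gb[flip_idx] <- ifelse(gb[flip_idx] == 0L, 2L, 0L)
  b <- mkGM(gb, prov = "array")
  rep_ <- computeConcordance(alignLoci(a, b))
  expect_equal(rep_$shared, 1000L)
  expect_equal(rep_$overall, 0.986)
})

test_that("concordance is symmetric in the platform roles", {
  set.seed(5)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 500, TRUE), 50, 10,
              dimnames = list(NULL, sprintf("S%03d", 1:10)))
  gb <- g
  gb[sample(length(gb), 30)] <- sample(c(0L, 1L, 2L), 30, TRUE)
  a <- mkGM(g); b <- mkGM(gb, prov = "array")
  r1 <- computeConcordance(alignLoci(a, b))
  r2 <- computeConcordance(alignLoci(b, a))
  expect_equal(r1$overall, r2$overall)
  expect_equal(r1$shared, r2$shared)
})

test_that("report conserves comparisons: concordant + discordant + excluded", {
  set.seed(6)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 400, TRUE), 40, 10,
              dimnames = list(NULL, sprintf("S%03d", 1:10)))
  gb <- matrix(sample(c(0L, 1L, 2L, NA), 400, TRUE), 40, 10,
               dimnames = list(NULL, sprintf("S%03d", 1:10)))
  a <- mkGM(g); b <- mkGM(gb, prov = "array")
  rep_ <- computeConcordance(alignLoci(a, b))
  expect_equal(rep_$shared + rep_$excluded, 400L)
  expect_equal(sum(rep_$by_class$n), rep_$shared)
})

test_that("indel-surrogate routing counts WGS-supported missing array calls", {
  g <- matrix(c(2L, 2L, 0L, 0L), 4, 1, dimnames = list(NULL, "S001"))
  gb <- matrix(NA_integer_, 4, 1, dimnames = list(NULL, "S001"))
  a <- mkGM(g); b <- mkGM(gb, prov = "array")
  rep_ <- computeConcordance(alignLoci(a, b), indel_surrogate = TRUE)
  expect_equal(rep_$by_class$n[rep_$by_class$class == "indel"], 4L)
  expect_equal(rep_$by_class$concordant[rep_$by_class$class == "indel"], 2L)
  # without surrogate routing these are simply excluded
  rep0 <- computeConcordance(alignLoci(a, b))
  expect_true(rep0$no_comparable)
  expect_equal(rep0$excluded, 4L)
})

test_that("a target identical to a panel sample is reproduced exactly", {
  ts <- sharedCohort()
  v <- readVariantVcf(ts$files[["variants"]])
  panel <- v$genotypes
  smp <- sampleIds(panel)[5]
  tg <- genoCodes(panel)[, smp, drop = FALSE]
  full <- tg
  mask <- which(!is.na(tg))[seq(1, sum(!is.na(tg)), by = 4)]
  tg[mask] <- NA_integer_
  target <- GenotypeMatrix(tg, siteInfo(panel), "gbs")
  imp <- imputeMissingSimple(panel, target)
  expect_equal(genoCodes(imp)[mask, 1], full[mask, 1])
})

test_that("monomorphic panel sites impute to the panel allele", {
  g <- matrix(2L, 10, 6, dimnames = list(NULL, sprintf("S%03d", 1:6)))
  panel <- mkGM(g)
  tg <- matrix(c(rep(2L, 9), NA), 10, 1, dimnames = list(NULL, "T1"))
  target <- mkGM(tg)
  imp <- imputeMissingSimple(panel, target)
  expect_equal(genoCodes(imp)[10, 1], 2L)
})

test_that("block-haplotype masking recovery exceeds 95%", {
  spec <- syntheticSpec(seed = 31, n_samples = 36, n_snp_sites = 600,
                        n_genes = 2, chrom_length = 5e5,
                        haplotype_scheme = "balanced", n_founders = 6,
                        background_het_rate = 0, missing_rate = 0,
                        duplication_segments = NULL,
                        sv_truth_counts = c(DEL = 2L))
  ts <- generateCohort(spec, file.path(tempdir(), "imp_block"))
  panel <- ts$genotypes
  set.seed(7)
  tg <- genoCodes(panel)[, 1:4, drop = FALSE]
  truth <- tg
  mask <- matrix(runif(length(tg)) < 0.05, nrow(tg))
  tg[mask] <- NA_integer_
  target <- GenotypeMatrix(tg, siteInfo(panel), "gbs")
  imp <- imputeMissingSimple(panel[, 5:36], target, k = 5, w = 50)
  acc <- mean(genoCodes(imp)[mask] == truth[mask], na.rm = TRUE)
  expect_gt(acc, 0.95)
})

test_that("leave-one-out protocol: degenerate and noiseless cases", {
  spec <- syntheticSpec(seed = 13, n_samples = 30, n_snp_sites = 500,
                        n_genes = 2, chrom_length = 4e5,
                        block_length = 4e5, # whole-chromosome blocks
                        haplotype_scheme = "balanced", n_founders = 5,
                        background_het_rate = 0, missing_rate = 0,
                        duplication_segments = NULL,
                        sv_truth_counts = c(DEL = 2L))
  ts <- generateCohort(spec, file.path(tempdir(), "loo_noiseless"))
  wgs <- ts$genotypes
  # low-density set equal to the full set: no untyped loci
  ev0 <- evaluateUntypedImputation(wgs, wgs, n_permutations = 2, seed = 1)
  expect_true(ev0$no_untyped)
  # 10% typed subset, perfect blocks: accuracy must be exactly 1
  typed <- seq(1, nrow(genoCodes(wgs)), by = 10)
  low <- wgs[typed, ]
  ev <- evaluateUntypedImputation(wgs, low, n_permutations = 3, seed = 2)
  expect_equal(ev$mean_accuracy, 1)
  expect_error(evaluateUntypedImputation(wgs, low, n_permutations = 99),
               "exceeds")
})

test_that("accuracy is non-increasing as haplotype blocks shrink", {
  accs <- vapply(c(4e5, 2e4), function(L) {
    spec <- syntheticSpec(seed = 17, n_samples = 30, n_snp_sites = 500,
                          n_genes = 2, chrom_length = 4e5, block_length = L,
                          haplotype_scheme = "balanced", n_founders = 5,
                          background_het_rate = 0, missing_rate = 0,
                          duplication_segments = NULL,
                          sv_truth_counts = c(DEL = 2L))
    ts <- generateCohort(spec, tempfile("blocklen"))
    wgs <- ts$genotypes
    typed <- seq(1, nrow(genoCodes(wgs)), by = 10)
    evaluateUntypedImputation(wgs, wgs[typed, ], n_permutations = 3,
                              seed = 3)$mean_accuracy
  }, numeric(1))
  expect_gte(accs[1], accs[2])
})
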