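# SV call ingestion, raw filters, reciprocal-overlap clustering and the
# unified catalogue.

test_that("VCF and BEDPE ingestion normalize coordinate conventions", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "Chr01\t1001\tD1\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=2000;SVLEN=1000;PE=20;GQ=50",
    "Chr01\t500\tX1\tN\t<FOO>\t.\t.\tSVTYPE=FOO;END=600",
    "Chr01\t700\tT1\tN\t<TRA>\t.\t.\tSVTYPE=TRA;END=900;CHR2=Chr02;PE=15;GQ=40"),
    vcf)
  expect_message(calls <- ingestCallset(vcf, "c1", "vcf_svtype"), "unknown")
  expect_equal(nrow(calls), 2L)
  d1 <- calls[calls$id == "D1", ]
  expect_equal(d1$start, 1000)
  expect_equal(d1$end, 2000)
  expect_equal(d1$length, 1000)
  expect_equal(calls$sv_type[calls$id == "T1"], "TRA_inter")

  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c(
    "Chr01\t100\t101\tChr02\t199\t200\tB1\t60\t+\t+\tTYPE=DEL;PE=12;GQ=35",
    "Chr01\t100\t101\tChr01\t499\t500\tB2\t60\t+\t+\tTYPE=DEL;PE=12;GQ=35"),
    bedpe)
  b <- ingestCallset(bedpe, "c2", "bedpe")
  expect_equal(b$sv_type, c("TRA_inter", "DEL"))
  expect_equal(b$start, c(100, 100))
  expect_equal(b$end, c(200, 500))
  expect_error(ingestCallset(vcf, "c1", "bedpe"), "malformed")
})

test_that("call sets round-trip through both serializations", {
  ts <- sharedCohort()
  calls <- ts$caller_calls[["pairsplit"]]
  calls <- calls[, setdiff(names(calls), "truth_id")]
  for (fmt in c("vcf", "bedpe")) {
    f <- tempfile(fileext = paste0(".", fmt))
    if (fmt == "vcf") writeCallsetVcf(calls, f) else
      writeCallsetBedpe(calls, f)
    back <- ingestCallset(f, "pairsplit",
                          if (fmt == "vcf") "vcf_svtype" else "bedpe")
    m <- match(calls$id, back$id)
    expect_false(anyNA(m))
    for (col in c("sv_type", "chrom", "start", "end", "chrom2", "length",
                  "gq", "pe", "carriers"))
      expect_equal(back[[col]][m], calls[[col]],
                   info = paste(fmt, col), tolerance = 1e-9)
  }
})

test_that("raw filters retain and remove by the stated rules", {
  ok <- svCall("a", "c1", "DEL", "Chr01", 1000, 2000, rd = 0.5)
  expect_equal(nrow(applyRawFilters(ok)$retained), 1L)
  bad_rd <- svCall("b", "c1", "DEL", "Chr01", 1000, 2000, rd = 0.8)
  res <- applyRawFilters(bad_rd)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(res$removed$rule, "rd_ratio")
  # duplications need the mirrored bound
  dup_lo <- svCall("c", "c1", "DUP", "Chr01", 1000, 3000, rd = 1.1)
  expect_equal(applyRawFilters(dup_lo)$removed$rule, "rd_ratio")
  dup_ok <- svCall("d", "c1", "DUP", "Chr01", 1000, 3000, rd = 2.0)
  expect_equal(nrow(applyRawFilters(dup_ok)$retained), 1L)
  # balanced/point events are exempt from the depth-ratio rule
  inv <- svCall("e", "c1", "INV", "Chr01", 1000, 3000, gr = 1.0, cf = 0.5)
  expect_equal(nrow(applyRawFilters(inv)$retained), 1L)
  # missing rd_ratio on a CNV is unevaluable
  cnv_na <- svCall("f", "c1", "CNV", "Chr01", 1000, 3000)
  expect_equal(applyRawFilters(cnv_na)$removed$rule, "rd_missing")
})

test_that("planted single-rule violations are tallied by construction", {
  clean <- lapply(1:10, function(i)
    svCall(sprintf("ok%02d", i), "c1", "DEL", "Chr01",
           i * 10000, i * 10000 + 1000, rd = 0.5))
  viol <- list(
    svCall("v1", "c1", "DEL", "Chr01", 200000, 201000, rd = 0.9),
    svCall("v2", "c1", "DEL", "Chr01", 210000, 211000, rd = 0.5, pe = 5),
    svCall("v3", "c1", "DEL", "Chr01", 300500, 301500, rd = 0.5), # centromere
    svCall("v4", "c1", "DEL", "Chr01", 400010, 401000, rd = 0.5), # gap
    svCall("v5", "c1", "DEL", "Chr01", 220000, 221000, rd = 0.5, gq = 20),
    svCall("v6", "c1", "INV", "Chr01", 230000, 231000, gr = 0.2, cf = 0.5),
    svCall("v7", "c1", "INV", "Chr01", 240000, 241000, gr = 1.0, cf = 0.1),
    svCall("v8", "c1", "TRA_intra", "Chr01", 500100, 500900))
  calls <- do.call(rbind, c(clean, viol))
  centromeres <- data.frame(chrom = "Chr01", start = 299000, end = 300000)
  gaps <- data.frame(chrom = "Chr01", start = 400000, end = 400005)
  syntenic <- data.frame(chrom = "Chr01", start = 500000, end = 501000)
  res <- applyRawFilters(calls, centromeres = centromeres, gaps = gaps,
                         syntenic = syntenic)
  expect_equal(nrow(res$retained), 10L)
  expect_equal(unname(res$tally[c("rd_ratio", "spanning_pairs", "centromere",
                                  "gap", "gq", "inv_genotyped_ratio",
                                  "inv_carrier_fraction", "syntenic")]),
               rep(1L, 8))
  expect_equal(nrow(res$retained) + sum(res$tally), nrow(calls))
})

test_that("reciprocal overlap is symmetric arithmetic", {
  expect_equal(reciprocalOverlap(1000, 2000, 1000, 2000), 1.0)
  expect_equal(reciprocalOverlap(1000, 2000, 1100, 2100), 0.9)
  expect_equal(reciprocalOverlap(0, 1000, 5000, 6000), 0)
  expect_equal(reciprocalOverlap(0, 1000, 0, 10000), 0.1)
  expect_error(reciprocalOverlap(5, 5, 0, 10), "zero-length")
})

test_that("identical calls from two tools merge; poor overlap does not", {
  two <- rbind(svCall("a", "t1", "DEL", "Chr01", 1000, 2000),
               svCall("b", "t2", "DEL", "Chr01", 1000, 2000))
  sites <- clusterCalls(two)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$support, 2L)
  expect_equal(sites$precision, 0)
  far <- rbind(svCall("a", "t1", "DEL", "Chr01", 0, 1000),
               svCall("b", "t2", "DEL", "Chr01", 0, 10000))
  expect_equal(nrow(clusterCalls(far)), 2L)
  # offsets beyond 250 bp block merging even at high reciprocal overlap
  off <- rbind(svCall("a", "t1", "DEL", "Chr01", 0, 100000),
               svCall("b", "t2", "DEL", "Chr01", 300, 100300))
  expect_equal(nrow(clusterCalls(off)), 2L)
  # insertions merge on breakpoint offset alone
  ins <- rbind(svCall("a", "t1", "INS", "Chr01", 5000, 5001, length = 300),
               svCall("b", "t2", "INS", "Chr01", 5100, 5101, length = 280))
  expect_equal(nrow(clusterCalls(ins)), 1L)
  # different types never merge
  mix <- rbind(svCall("a", "t1", "DEL", "Chr01", 1000, 2000),
               svCall("b", "t2", "DUP", "Chr01", 1000, 2000))
  expect_equal(nrow(clusterCalls(mix)), 2L)
})

test_that("clustering equals an all-pairs union-find oracle on jittered calls", {
  ts <- sharedCohort()
  set.seed(33)
  calls <- do.call(rbind, ts$caller_calls)
  calls <- calls[calls$sv_type %in% c("DEL", "DUP", "INV", "CNV", "INS"), ]
  rownames(calls) <- NULL
  cfg <- svFilterConfig()
  sites <- clusterCalls(calls, cfg)
  # oracle: igraph over all pairs
  n <- nrow(calls)
  edges <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (calls$sv_type[i] != calls$sv_type[j]) next
    if (calls$chrom[i] != calls$chrom[j]) next
    off_ok <- abs(calls$start[i] - calls$start[j]) <= 250 &&
      abs(calls$end[i] - calls$end[j]) <= 250
    if (!off_ok) next
    if (calls$sv_type[i] == "INS") {
      edges[[length(edges) + 1L]] <- c(i, j)
    } else {
      ov <- max(0, min(calls$end[i], calls$end[j]) -
                   max(calls$start[i], calls$start[j]))
      ro <- min(ov / (calls$end[i] - calls$start[i]),
                ov / (calls$end[j] - calls$start[j]))
      if (ro >= 0.8) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  edge_vec <- if (length(edges)) as.integer(t(do.call(rbind, edges)))
              else integer(0)
  gr <- igraph::make_graph(edges = edge_vec, n = n, directed = FALSE)
  memb <- igraph::components(gr)$membership
  expect_equal(nrow(sites), max(memb))
  # identical partition: member id sets agree
  oracle_sets <- sort(vapply(split(calls$id, memb), function(x)
    paste(sort(x), collapse = ","), character(1)))
  got_sets <- sort(vapply(strsplit(sites$member_ids, ","), function(x)
    paste(sort(x), collapse = ","), character(1)))
  expect_equal(got_sets, unname(oracle_sets))
  # conservation: every input call in exactly one component
  expect_equal(sum(sites$n_members), n)
  # permutation invariance
  perm <- sample(n)
  sites2 <- clusterCalls(calls[perm, ], cfg)
  expect_equal(sites2[, c("sv_type", "chrom", "start", "end", "support")],
               sites[, c("sv_type", "chrom", "start", "end", "support")])
})

test_that("representatives are lower medians of member coordinates", {
  three <- rbind(svCall("a", "t1", "DEL", "Chr01", 1000, 2000),
                 svCall("b", "t2", "DEL", "Chr01", 1010, 2030),
                 svCall("c", "t3", "DEL", "Chr01", 1040, 2010))
  s <- clusterCalls(three)
  expect_equal(s$start, 1010)
  expect_equal(s$end, 2010)
  expect_equal(s$precision, 30)
  two <- rbind(svCall("a", "t1", "DEL", "Chr01", 1000, 2000),
               svCall("b", "t2", "DEL", "Chr01", 1010, 2030))
  s2 <- clusterCalls(two)
  expect_equal(s2$start, 1000) # lower median on ties
  expect_equal(s2$end, 2000)
})

test_that("zero-noise mocks reproduce truth-set site counts per type", {
  profiles <- lapply(c("t1", "t2", "t3"), function(nm)
    list(name = nm, fn_rate = 0, fp_count = 0, breakpoint_jitter_sd = 0,
         cannot_types = character(0), dialect = "vcf"))
  spec <- syntheticSpec(seed = 41, n_samples = 20, n_snp_sites = 50,
                        n_genes = 2, chrom_length = 5e5,
                        duplication_segments = NULL,
                        caller_profiles = profiles,
                        sv_truth_counts = c(DEL = 60, INS = 20, DUP = 10,
                                            INV = 10, CNV = 8, TRA_intra = 6,
                                            TRA_inter = 4))
  ts <- generateCohort(spec, file.path(tempdir(), "zero_mocks"))
  calls <- do.call(rbind, ts$caller_calls)
  sites <- clusterCalls(calls)
  res <- unifyAndScore(sites)
  truth_counts <- table(ts$true_svs$sv_type)
  got <- table(res$catalogue$sv_type)
  expect_equal(as.integer(got[names(truth_counts)]),
               as.integer(truth_counts))
  expect_true(all(res$catalogue$support == 3L))
  expect_true(all(res$concordance$call_fraction == 1))
  expect_true(all(res$concordance$site_fraction == 1))
})

test_that("per-type concordance and the weighted mean follow the planting", {
  # sites seen by two tools with planted per-type site-level rates
  rates <- c(DEL = 0.91, INS = 0.87, INV = 0.86, DUP = 0.83)
  n_per <- c(DEL = 600, INS = 160, INV = 42, DUP = 28)
  set.seed(55)
  calls <- list()
  for (ty in names(rates)) {
    for (i in seq_len(n_per[ty])) {
      s <- i * 20000
      e <- if (ty == "INS") s + 1 else s + 1000
      two_tools <- runif(1) < rates[ty]
      calls[[length(calls) + 1L]] <- svCall(
        sprintf("%s%04d_1", ty, i), "t1", ty, "Chr01", s, e)
      if (two_tools)
        calls[[length(calls) + 1L]] <- svCall(
          sprintf("%s%04d_2", ty, i), "t2", ty, "Chr01", s, e)
    }
  }
  calls <- do.call(rbind, calls)
  res <- unifyAndScore(clusterCalls(calls))
  conc <- res$concordance
  for (ty in names(rates)) {
    site_frac <- conc$site_fraction[conc$sv_type == ty]
    se <- sqrt(rates[ty] * (1 - rates[ty]) / n_per[ty])
    expect_lt(abs(site_frac - rates[ty]), 4 * se)
    # call-level fraction follows its closed form 2r/(1+r)
    r_hat <- site_frac
    expect_equal(conc$call_fraction[conc$sv_type == ty],
                 2 * r_hat / (1 + r_hat), tolerance = 1e-9)
  }
  # weighted mean equals the hand-computed weighted average
  cw <- conc[match(names(rates), conc$sv_type), ]
  expect_equal(res$weighted_site_concordance,
               sum(cw$site_fraction * cw$n_calls) / sum(cw$n_calls),
               tolerance = 1e-12)
})

test_that("a type absent from the catalogue is omitted, not zero-divided", {
  one <- svCall("a", "t1", "DEL", "Chr01", 1000, 2000)
  res <- unifyAndScore(clusterCalls(one))
  expect_equal(nrow(res$catalogue), 0L)
  expect_false("INV" %in% res$concordance$sv_type)
  expect_null(res$summary$sv_type)
})
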