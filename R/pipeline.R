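## End-to-end orchestration on a declarative config, with a manifest
## sufficient to reproduce a run byte-identically from the same inputs and
## seed.

PIPELINE_KEYS <- c("out_dir", "seed", "stages", "synthetic", "filter",
                   "ld", "sv", "hetdup", "imputation", "log")

PIPELINE_STAGES <- c("simulate", "filter", "annotate", "concordance",
                     "impute", "ld", "sv", "svgene", "hetdup")

#' Validate a pipeline configuration
#'
#' @param config named list, or path to a YAML file.
#' @return The validated config (with defaults filled in).
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% tempfile("inbredvar_run")
  config$stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config
}

#' Run the pipeline on a synthetic cohort
#'
#' Runs the requested stages in dependency order on a cohort simulated from
#' the config's synthetic block (all stages start from the simulated files,
#' so a run is reproducible from the config and seed alone).
#'
#' @param config named list or YAML path; keys: out_dir, seed, stages
#'   (subset of simulate/filter/annotate/concordance/impute/ld/sv/svgene/
#'   hetdup), plus optional per-stage parameter blocks (synthetic, filter,
#'   ld, sv, hetdup, imputation).
#' @return Run manifest (list): parameter echo, per-stage outputs, file
#'   checksums. Also written as \code{manifest.json} in out_dir.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = config, stages = list())
  spec_args <- config$synthetic %||% list()
  spec_args$seed <- config$seed
  spec <- do.call(syntheticSpec, spec_args)
  cohort <- generateCohort(spec, file.path(config$out_dir, "cohort"))
  manifest$stages$simulate <- list(files = unname(cohort$files))

  st <- config$stages
  vcf <- readVariantVcf(cohort$files[["variants"]])

  if ("filter" %in% st) {
    flt <- applySiteFilters(vcf$variants,
                            do.call(filterConfig, config$filter %||% list()))
    f_tally <- file.path(config$out_dir, "filter_tally.tsv")
    writeFilterTally(flt$tally, f_tally)
    f_vcf <- file.path(config$out_dir, "variants_filtered.vcf")
    keep <- match(siteKey(flt$retained$chrom, flt$retained$pos,
                          flt$retained$ref, flt$retained$alt),
                  siteKeys(vcf$genotypes))
    writeVariantVcf(vcf$genotypes[keep, ], f_vcf,
                    provenance_line = "##inbredvar_filtered=six-rule site filter")
    manifest$stages$filter <- list(retained = nrow(flt$retained),
                                   tally = as.list(flt$tally),
                                   files = c(f_tally, f_vcf))
  }
  if ("annotate" %in% st) {
    ref <- Biostrings::readDNAStringSet(cohort$files[["reference"]])
    names(ref) <- sub(" .*", "", names(ref))
    genes <- readGeneModels(cohort$files[["genes"]])
    ann <- annotateVariants(vcf$variants, genes, ref)
    f_ann <- file.path(config$out_dir, "variant_annotation.tsv")
    writeTsv(ann, f_ann)
    spectra <- summarizeSpectra(ann)
    f_ctx <- file.path(config$out_dir, "context_proportions.tsv")
    writeTsv(data.frame(context = names(spectra$context_proportions),
                        proportion = as.numeric(spectra$context_proportions)),
             f_ctx)
    manifest$stages$annotate <- list(
      impact_counts = as.list(spectra$impact_counts), files = c(f_ann, f_ctx))
  }
  if ("concordance" %in% st) {
    arr <- readArrayTable(cohort$files[["array"]])
    rep_ <- computeConcordance(alignLoci(vcf$genotypes, arr),
                               indel_surrogate = TRUE)
    f_conc <- file.path(config$out_dir, "concordance.tsv")
    writeTsv(rep_$by_class, f_conc)
    manifest$stages$concordance <- list(overall = rep_$overall,
                                        shared = rep_$shared, files = f_conc)
  }
  if ("impute" %in% st) {
    imp_cfg <- config$imputation %||% list()
    arr <- readArrayTable(cohort$files[["array"]])
    ev <- evaluateUntypedImputation(
      vcf$genotypes, arr,
      n_permutations = imp_cfg$n_permutations %||% 5L,
      seed = config$seed, k = imp_cfg$k %||% 5L, w = imp_cfg$w %||% 50L)
    f_imp <- file.path(config$out_dir, "imputation_accuracy.tsv")
    if (!is.null(ev$per_permutation)) writeTsv(ev$per_permutation, f_imp)
    manifest$stages$impute <- list(mean_accuracy = ev$mean_accuracy,
                                   files = f_imp)
  }
  if ("ld" %in% st) {
    ld_cfg <- config$ld %||% list()
    pairs <- computeLdPairs(vcf$genotypes,
                            max_sites_apart = ld_cfg$max_sites_apart %||% 300L)
    dec <- ldDecay(pairs, bin_width = ld_cfg$bin_width %||% 5e4,
                   threshold = ld_cfg$threshold %||% 0.2)
    pruned <- windowPrune(vcf$genotypes, window = ld_cfg$window %||% 50L)
    f_tags <- file.path(config$out_dir, "tag_snps.tsv")
    writeTsv(data.frame(tag = pruned$tags), f_tags)
    manifest$stages$ld <- list(decay_bp = dec$decay_bp,
                               n_tags = length(pruned$tags), files = f_tags)
  }
  sv_result <- NULL
  if (any(c("sv", "svgene", "hetdup") %in% st)) {
    sv_cfg <- do.call(svFilterConfig, config$sv %||% list())
    calls <- do.call(rbind, lapply(spec$caller_profiles, function(p) {
      f <- cohort$files[[p$name]]
      ingestCallset(f, p$name,
                    if (grepl("bedpe$", f)) "bedpe" else "vcf_svtype")
    }))
    filt <- applyRawFilters(calls, sv_cfg)
    sites <- clusterCalls(filt$retained, sv_cfg)
    sv_result <- unifyAndScore(sites)
    f_cat <- file.path(config$out_dir, "sv_catalogue.vcf")
    writeCatalogueVcf(sv_result$catalogue, f_cat,
                      contigs = cohort$chrom_lengths)
    f_sum <- file.path(config$out_dir, "sv_summary.tsv")
    writeTsv(sv_result$summary, f_sum)
    manifest$stages$sv <- list(
      n_unified = nrow(sv_result$catalogue),
      weighted_call_concordance = sv_result$weighted_call_concordance,
      files = c(f_cat, f_sum))
  }
  if ("svgene" %in% st) {
    genes <- readGeneModels(cohort$files[["genes"]])
    scen <- classifySvGeneOverlap(sv_result$catalogue, genes)
    summ <- summarizeGeneImpact(scen, sv_result$catalogue)
    f_scen <- file.path(config$out_dir, "sv_gene_scenarios.tsv")
    writeTsv(scen, f_scen)
    manifest$stages$svgene <- list(
      percent_affecting = as.list(summ$percent_affecting), files = f_scen)
  }
  if ("hetdup" %in% st) {
    hd_cfg <- config$hetdup %||% list()
    prof <- hetProfile(vcf$genotypes,
                       window = hd_cfg$window %||% 1e5,
                       step = hd_cfg$step %||% 5e4,
                       min_sites = hd_cfg$min_sites %||% 5L,
                       chrom_lengths = cohort$chrom_lengths)
    thr <- hd_cfg$het_threshold %||%
      if (spec$background_het_rate > 0) NULL else 0.05
    clus <- detectHetClusters(prof, het_threshold = thr,
                              background_rate = spec$background_het_rate,
                              min_windows = hd_cfg$min_windows %||% 3L)
    dup <- sv_result$catalogue[
      sv_result$catalogue$sv_type %in% c("DUP", "CNV"), , drop = FALSE]
    ## carrier sets of the unified sites come from their member truth calls
    dup$id <- dup$site_id
    dup$carriers <- vapply(strsplit(dup$member_ids, ","), function(ids) {
      m <- calls[calls$id %in% ids, , drop = FALSE]
      paste(unique(unlist(expandIds(m$carriers[nzchar(m$carriers)]))),
            collapse = ",")
    }, character(1))
    conc <- duplicationHetConcordance(clus, dup)
    f_hd <- file.path(config$out_dir, "hetdup_concordance.tsv")
    if (!is.null(conc$per_call)) writeTsv(conc$per_call, f_hd)
    manifest$stages$hetdup <- list(fraction = conc$fraction,
                                   n_clusters = nrow(clus), files = f_hd)
  }

  all_files <- unlist(lapply(manifest$stages, function(x) x$files))
  all_files <- all_files[file.exists(all_files)]
  manifest$checksums <- as.list(tools::md5sum(all_files))
  f_manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest$path <- f_manifest
  invisible(manifest)
}

#' Render a human-readable report from a run manifest
#'
#' @param manifest manifest list from \code{\link{runPipeline}} or path to a
#'   manifest.json.
#' @param path output Markdown file (default: report.md next to the
#'   manifest).
#' @return The report path, invisibly.
#' @export
makeReport <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    mpath <- manifest
    manifest <- jsonlite::read_json(manifest)
    manifest$path <- mpath
  }
  if (is.null(path))
    path <- file.path(dirname(manifest$path %||% "."), "report.md")
  st <- manifest$stages
  lines <- c("# Pipeline run report", "")
  section <- function(name, body) {
    if (is.null(st[[name]])) {
      c(sprintf("## %s", name), "", "_stage not run_", "")
    } else c(sprintf("## %s", name), "", body, "")
  }
  fmtv <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) "NA"
    else format(x, digits = 4)
  lines <- c(lines,
    section("filter", c(
      sprintf("- retained sites: %s", fmtv(st$filter$retained)),
      sprintf("- removed (%s): %s", names(st$filter$tally),
              unlist(st$filter$tally)))),
    section("annotate", sprintf("- impact %s: %s",
                                names(st$annotate$impact_counts),
                                unlist(st$annotate$impact_counts))),
    section("concordance", c(
      sprintf("- shared genotypes: %s", fmtv(st$concordance$shared)),
      sprintf("- overall concordance: %s", fmtv(st$concordance$overall)))),
    section("impute", sprintf("- mean untyped-locus accuracy: %s",
                              fmtv(st$impute$mean_accuracy))),
    section("ld", c(sprintf("- LD decay distance (bp): %s",
                            fmtv(st$ld$decay_bp)),
                    sprintf("- tag SNPs: %s", fmtv(st$ld$n_tags)))),
    section("sv", c(sprintf("- unified SV sites: %s", fmtv(st$sv$n_unified)),
                    sprintf("- weighted call concordance: %s",
                            fmtv(st$sv$weighted_call_concordance)))),
    section("svgene", sprintf("- %% sites affecting genes (%s): %s",
                              names(st$svgene$percent_affecting),
                              unlist(st$svgene$percent_affecting))),
    section("hetdup", sprintf("- duplication-het concordance: %s",
                              fmtv(st$hetdup$fraction))))
  writeLines(lines, path)
  invisible(path)
}
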