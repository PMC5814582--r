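## Structural-variant call-set I/O.
##
## Internal coordinates are 0-based half-open. The VCF dialect uses POS
## (1-based) with INFO END (1-based inclusive), so POS = start + 1 and
## END = end; conversion happens only at these boundaries. The BEDPE dialect
## is 6+4 columns (chrom1,start1,end1,chrom2,start2,end2,name,score,
## strand1,strand2) plus a key=value tag column carrying TYPE and metadata.

SV_TYPES <- c("DEL", "INS", "DUP", "INV", "CNV", "TRA_intra", "TRA_inter")

emptyCalls <- function() {
  data.frame(id = character(0), caller = character(0), sv_type = character(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             chrom2 = character(0), length = numeric(0), gq = numeric(0),
             pe = numeric(0), rd_ratio = numeric(0),
             genotyped_ratio = numeric(0), carrier_pair_fraction = numeric(0),
             carriers = character(0), stringsAsFactors = FALSE)
}

#' Simulate mock caller outputs from an SV truth set
#'
#' Each caller profile drops true calls at its false-negative rate, jitters
#' breakpoints with Gaussian noise (type and chromosome are retained), adds
#' false positives, and suppresses SV types the tool cannot emit (as a
#' paired-end caller misses tandem duplications).
#'
#' @param truth data.frame of true SV calls (as in a TruthSet's
#'   \code{true_svs}): id, sv_type, chrom, start, end, chrom2, length, gq,
#'   pe, rd_ratio, genotyped_ratio, carrier_pair_fraction, carriers.
#' @param profiles list of caller profiles
#'   (\code{\link{defaultCallerProfiles}}).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @return Named list of per-caller call data.frames with added columns
#'   \code{caller} and \code{truth_id} (NA for false positives).
#' @export
simulateCallerOutputs <- function(truth, profiles, chrom_lengths) {
  out <- list()
  for (p in profiles) {
    if (p$fn_rate < 0 || p$fn_rate > 1) stop("fn_rate must be in [0, 1]")
    if (p$breakpoint_jitter_sd < 0) stop("breakpoint_jitter_sd must be >= 0")
    keep <- truth[!(truth$sv_type %in% (p$cannot_types %||% character(0))), ,
                  drop = FALSE]
    keep <- keep[runif(nrow(keep)) >= p$fn_rate, , drop = FALSE]
    calls <- keep
    calls$truth_id <- keep$id
    if (nrow(calls) && p$breakpoint_jitter_sd > 0) {
      sd <- p$breakpoint_jitter_sd
      calls$start <- calls$start + round(rnorm(nrow(calls), 0, sd))
      pointlike <- calls$sv_type %in% c("INS")
      calls$end <- ifelse(pointlike, calls$start + 1,
                          calls$end + round(rnorm(nrow(calls), 0, sd)))
      calls$start <- pmax(0, pmin(calls$start,
                                  chrom_lengths[calls$chrom] - 2))
      lim2 <- chrom_lengths[calls$chrom2]
      calls$end <- pmax(calls$start + 1, pmin(calls$end, lim2))
    }
    fp_n <- p$fp_count %||% 0L
    if (fp_n > 0) {
      allowed <- setdiff(SV_TYPES, p$cannot_types %||% character(0))
      allowed <- intersect(allowed, unique(truth$sv_type))
      if (length(chrom_lengths) < 2)
        allowed <- setdiff(allowed, "TRA_inter")
      fp <- lapply(seq_len(fp_n), function(i) {
        ty <- sample(allowed, 1)
        rng <- svSizeRange(ty)
        width <- round(10^runif(1, rng[1], rng[2]))
        chrom <- sample(names(chrom_lengths), 1)
        if (ty == "INS") {
          s <- sample.int(chrom_lengths[chrom] - 2, 1); e <- s + 1
          chrom2 <- chrom
        } else if (ty == "TRA_inter") {
          chrom2 <- sample(setdiff(names(chrom_lengths), chrom), 1)
          s <- sample.int(chrom_lengths[chrom] - 2, 1)
          e <- sample.int(chrom_lengths[chrom2] - 2, 1)
        } else {
          s <- sample.int(max(2, chrom_lengths[chrom] - width - 1), 1)
          e <- s + width
          chrom2 <- chrom
        }
        data.frame(id = sprintf("FP_%s_%03d", p$name, i), sv_type = ty,
                   chrom = chrom, start = s, end = e, chrom2 = chrom2,
                   length = width, gq = round(runif(1, 31, 80)),
                   pe = round(runif(1, 11, 40)),
                   rd_ratio = if (ty == "DEL") round(runif(1, 0.3, 0.6), 3)
                              else if (ty %in% c("DUP", "CNV"))
                                round(runif(1, 1.6, 2.4), 3) else NA_real_,
                   genotyped_ratio = if (ty == "INV") round(runif(1, 0.6, 3), 2)
                                     else NA_real_,
                   carrier_pair_fraction = if (ty == "INV")
                     round(runif(1, 0.4, 0.9), 2) else NA_real_,
                   carriers = "", truth_id = NA_character_,
                   stringsAsFactors = FALSE)
      })
      calls <- rbind(calls, do.call(rbind, fp))
    }
    if (nrow(calls)) {
      calls$caller <- p$name
      calls <- calls[order(calls$chrom, calls$start, calls$id), , drop = FALSE]
      rownames(calls) <- NULL
    }
    out[[p$name]] <- calls
  }
  out
}

#' Write an SV call set as VCF with symbolic alleles
#'
#' @param calls SV call data.frame (internal 0-based half-open coordinates).
#' @param path output file.
#' @param contigs optional named chromosome lengths for the header.
#' @return The path, invisibly.
#' @export
writeCallsetVcf <- function(calls, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=inbredvar")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr,
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End (1-based inclusive)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Second chromosome">',
    '##INFO=<ID=PE,Number=1,Type=Integer,Description="Spanning read pairs">',
    '##INFO=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality (phred)">',
    '##INFO=<ID=RDRATIO,Number=1,Type=Float,Description="Carrier/non-carrier depth ratio">',
    '##INFO=<ID=GTRATIO,Number=1,Type=Float,Description="Genotyped/ungenotyped sample ratio">',
    '##INFO=<ID=CARRIERF,Number=1,Type=Float,Description="Carrier supporting-pair fraction">',
    '##INFO=<ID=CARRIERS,Number=.,Type=String,Description="Carrier samples">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  fmtNum <- function(x) ifelse(is.na(x), NA,
                               format(x, trim = TRUE, scientific = FALSE))
  info <- vapply(seq_len(nrow(calls)), function(i) {
    z <- calls[i, ]
    kv <- c(SVTYPE = z$sv_type, END = fmtNum(z$end), SVLEN = fmtNum(z$length),
            CHR2 = if (!is.na(z$chrom2) && z$chrom2 != z$chrom) z$chrom2 else NA,
            PE = fmtNum(z$pe), GQ = fmtNum(z$gq), RDRATIO = fmtNum(z$rd_ratio),
            GTRATIO = fmtNum(z$genotyped_ratio),
            CARRIERF = fmtNum(z$carrier_pair_fraction),
            CARRIERS = if (nzchar(z$carriers %||% "")) z$carriers else NA)
    kv <- kv[!is.na(kv)]
    paste(paste0(names(kv), "=", kv), collapse = ";")
  }, character(1))
  alt_sym <- sub("_.*", "", calls$sv_type) # TRA_intra/TRA_inter -> <TRA>
  body <- paste(calls$chrom, format(calls$start + 1, trim = TRUE,
                                    scientific = FALSE),
                calls$id, "N", paste0("<", alt_sym, ">"), ".", ".", info,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an SV call set as BEDPE (6+4 columns plus a key=value tag column)
#'
#' @param calls SV call data.frame (internal 0-based half-open coordinates).
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeCallsetBedpe <- function(calls, path) {
  fmtNum <- function(x) ifelse(is.na(x), ".",
                               format(x, trim = TRUE, scientific = FALSE))
  tags <- vapply(seq_len(nrow(calls)), function(i) {
    z <- calls[i, ]
    kv <- c(TYPE = z$sv_type, LENGTH = fmtNum(z$length), PE = fmtNum(z$pe),
            GQ = fmtNum(z$gq), RDRATIO = fmtNum(z$rd_ratio),
            GTRATIO = fmtNum(z$genotyped_ratio),
            CARRIERF = fmtNum(z$carrier_pair_fraction),
            CARRIERS = if (nzchar(z$carriers %||% "")) z$carriers else ".")
    kv <- kv[kv != "."]
    paste(paste0(names(kv), "=", kv), collapse = ";")
  }, character(1))
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE)
  rows <- paste(calls$chrom, fmt(calls$start), fmt(calls$start + 1),
                calls$chrom2, fmt(pmax(calls$end - 1, 0)), fmt(calls$end),
                calls$id, fmt(ifelse(is.na(calls$gq), 0, calls$gq)),
                "+", "+", tags, sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

parseInfoField <- function(x) {
  kv <- strsplit(x, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", kv, fixed = TRUE)
  keys <- sub("=.*", "", kv[has_eq])
  vals <- sub("^[^=]*=", "", kv[has_eq])
  setNames(vals, keys)
}

#' Ingest an SV call set from a caller output file
#'
#' Normalizes coordinates to internal 0-based half-open convention (VCF
#' POS/END are 1-based with END inclusive) and maps type vocabulary to the
#' canonical set (DEL, INS, DUP, INV, CNV, TRA_intra, TRA_inter; a BEDPE row
#' with chrom1 != chrom2, or a TRA with a different CHR2, is TRA_inter).
#' Records with unknown SV types are skipped with a message.
#'
#' @param path caller output file.
#' @param caller caller identifier recorded on every call.
#' @param dialect "vcf_svtype" or "bedpe".
#' @return SV call data.frame.
#' @export
ingestCallset <- function(path, caller, dialect = c("vcf_svtype", "bedpe")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(emptyCalls())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (dialect == "vcf_svtype") {
      if (length(f) < 8) stop("malformed VCF line ", i, " in ", path)
      info <- parseInfoField(f[8])
      ty <- unname(info["SVTYPE"])
      chrom <- f[1]
      chrom2 <- if (!is.na(info["CHR2"])) unname(info["CHR2"]) else chrom
      if (is.na(ty)) ty <- sub("[<>]", "", f[5])
      if (identical(ty, "TRA"))
        ty <- if (chrom2 != chrom) "TRA_inter" else "TRA_intra"
      if (!(ty %in% SV_TYPES)) {
        message("skipping record with unknown SVTYPE '", ty, "' at line ", i)
        next
      }
      pos <- suppressWarnings(as.numeric(f[2]))
      if (is.na(pos)) stop("malformed VCF line ", i, " in ", path)
      start <- pos - 1
      end <- suppressWarnings(as.numeric(info["END"]))
      if (is.na(end)) end <- start + 1
      len <- suppressWarnings(as.numeric(info["SVLEN"]))
      if (is.na(len)) len <- abs(end - start)
      num <- function(k) suppressWarnings(as.numeric(info[k]))
      out[[i]] <- data.frame(
        id = f[3], caller = caller, sv_type = ty, chrom = chrom,
        start = start, end = end, chrom2 = chrom2, length = abs(len),
        gq = num("GQ"), pe = num("PE"), rd_ratio = num("RDRATIO"),
        genotyped_ratio = num("GTRATIO"),
        carrier_pair_fraction = num("CARRIERF"),
        carriers = if (!is.na(info["CARRIERS"])) unname(info["CARRIERS"]) else "",
        stringsAsFactors = FALSE)
    } else {
      if (length(f) < 11) stop("malformed BEDPE line ", i, " in ", path)
      tags <- parseInfoField(f[11])
      ty <- unname(tags["TYPE"])
      chrom <- f[1]; chrom2 <- f[4]
      if (identical(ty, "TRA") || (!is.na(ty) && chrom != chrom2 &&
                                   !startsWith(ty, "TRA")))
        ty <- if (chrom != chrom2) "TRA_inter" else "TRA_intra"
      if (is.na(ty) || !(ty %in% SV_TYPES)) {
        message("skipping BEDPE record with unknown TYPE at line ", i)
        next
      }
      start <- suppressWarnings(as.numeric(f[2]))
      end <- suppressWarnings(as.numeric(f[6]))
      if (is.na(start) || is.na(end)) stop("malformed BEDPE line ", i, " in ", path)
      num <- function(k) suppressWarnings(as.numeric(tags[k]))
      len <- num("LENGTH")
      if (is.na(len)) len <- abs(end - start)
      out[[i]] <- data.frame(
        id = f[7], caller = caller, sv_type = ty, chrom = chrom,
        start = start, end = end, chrom2 = chrom2, length = abs(len),
        gq = num("GQ"), pe = num("PE"), rd_ratio = num("RDRATIO"),
        genotyped_ratio = num("GTRATIO"),
        carrier_pair_fraction = num("CARRIERF"),
        carriers = if (!is.na(tags["CARRIERS"])) unname(tags["CARRIERS"]) else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(emptyCalls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
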