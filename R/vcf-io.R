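#' Read a multi-sample VCF of biallelic SNPs into a genotype matrix
#'
#' Imports GT calls from a VCF (v4.x, plain or bgzipped) and recodes them as
#' diploid dosages: `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` ->
#' `NA`; phased separators (`|`) are treated identically. Records that are
#' not biallelic SNPs (multi-allelic ALT, indels, missing ALT) are skipped
#' and counted. When the FORMAT field carries GQ, calls with GQ below
#' `gq_min` are masked to `NA` before anything else sees them; when the INFO
#' field carries QD, FS or MQ these are attached to the locus table for
#' [apply_screens()].
#'
#' @param path Path to the VCF file.
#' @param map Optional [sample_map()]; every mapped sample must be present
#'   in the VCF (an informative error names absentees). Samples are
#'   reordered to match the map.
#' @param gq_min Genotype-quality mask threshold; calls with GQ below it
#'   become `NA`. Set to `NULL` to disable. Default 20.
#' @return A [genotype_matrix()] with attribute `skipped` giving the number
#'   of non-biallelic-SNP records dropped.
#' @export
read_vcf <- function(path, map = NULL, gq_min = 20) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples <- colnames(vcf@gt)[-1L]

  if (!is.null(map)) {
    absent <- setdiff(map$sample, samples)
    if (length(absent)) {
      stop("sample(s) in map absent from VCF: ",
           paste(absent, collapse = ", "))
    }
  }

  keep <- if (n_rec) {
    !is.na(fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  } else logical(0)
  skipped <- sum(!keep)
  if (skipped) {
    message("read_vcf: skipped ", skipped,
            " record(s) that are not biallelic SNPs")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec,
                                     dimnames = list(NULL, samples))
  gt <- gt[keep, , drop = FALSE]

  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  dos <- matrix(code(gt), nrow = nrow(gt),
                dimnames = list(NULL, colnames(gt)))

  if (!is.null(gq_min) && any(grepl("GQ", vcf@gt[, 1L], fixed = TRUE))) {
    gq <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
    if (is.null(dim(gq))) gq <- matrix(gq, nrow = n_rec)
    gq <- gq[keep, , drop = FALSE]
    dos[!is.na(gq) & gq < gq_min] <- NA_integer_
  }

  loci <- data.frame(chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     stringsAsFactors = FALSE)
  ids <- fix$ID[keep]
  if (length(ids) && !all(is.na(ids) | ids == ".")) loci$id <- ids
  for (key in c("QD", "FS", "MQ")) {
    if (n_rec && any(grepl(paste0(key, "="), fix$INFO, fixed = TRUE))) {
      val <- suppressWarnings(
        vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
      loci[[tolower(key)]] <- val[keep]
    }
  }

  dosage <- t(dos)
  if (!is.null(map)) dosage <- dosage[map$sample, , drop = FALSE]
  out <- genotype_matrix(dosage, loci)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Emits a GT-only VCF that is the exact inverse of [read_vcf()]'s dosage
#' coding (0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`). Output is
#' deterministic: identical matrices produce byte-identical files.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkpop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(x$dosage)), collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (ncol(x$dosage)) {
    gt_code <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(ncol(x$dosage)), function(j) {
      g <- x$dosage[, j]
      gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
      paste(c(x$loci$chrom[j], x$loci$pos[j], x$loci$id[j],
              x$loci$ref[j], x$loci$alt[j], ".", ".", ".", "GT", gt),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Per-locus allele frequency and call rate
#'
#' @param x A [genotype_matrix()] with at least one sample.
#' @return Data frame with one row per locus: `id`, `alt_freq` (alternate
#'   allele frequency among non-missing calls, `NA` when every call is
#'   missing), `maf` (minor-allele frequency), and `call_rate`
#'   (non-missing / total samples; the "integrity" of the locus).
#' @export
site_stats <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!nrow(x$dosage)) stop("site_stats needs at least one sample")
  n_called <- colSums(!is.na(x$dosage))
  alt <- colSums(x$dosage, na.rm = TRUE)
  p <- ifelse(n_called > 0L, alt / (2 * n_called), NA_real_)
  data.frame(id = x$loci$id,
             alt_freq = p,
             maf = pmin(p, 1 - p),
             call_rate = n_called / nrow(x$dosage),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Site-screening configuration
#'
#' Thresholds for the locus screens: minimum minor-allele frequency,
#' minimum call rate ("integrity"), and the GATK-style hard-filter bounds
#' applied when per-locus QD/FS/MQ annotations are available. Screens keep
#' a locus when MAF >= `maf_min`, call rate >= `integrity_min`, and (if
#' annotated) QD >= `qd_min`, FS <= `fs_max`, MQ >= `mq_min`.
#'
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param integrity_min Minimum per-locus call rate (default 0.95).
#' @param qd_min,fs_max,mq_min Hard-filter bounds on the QD, FS and MQ
#'   annotations (defaults 2.0, 60.0, 40.0).
#' @param gq_min Per-call genotype-quality mask used at VCF import
#'   (default 20); recorded here for provenance.
#' @return A list of class `locus_filter_config`.
#' @export
locus_filter_config <- function(maf_min = 0.05, integrity_min = 0.95,
                                qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                                gq_min = 20) {
  stopifnot(maf_min >= 0, maf_min <= 1, integrity_min >= 0,
            integrity_min <= 1)
  structure(list(maf_min = maf_min, integrity_min = integrity_min,
                 qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
                 gq_min = gq_min),
            class = "locus_filter_config")
}

#' Apply site screens to a genotype matrix
#'
#' Retains loci passing, in order: the MAF screen, the integrity
#' (call-rate) screen, then the QD/FS/MQ hard filters (only where those
#' annotations exist). Retained loci keep their original order. Boundary
#' values are kept (MAF exactly `maf_min`, call rate exactly
#' `integrity_min` pass).
#'
#' @param x A [genotype_matrix()].
#' @param cfg A [locus_filter_config()].
#' @param info Optional data frame of per-locus annotations with columns
#'   among `qd`, `fs`, `mq` (one row per locus). Defaults to any such
#'   columns already present in `x$loci` (as populated by [read_vcf()]).
#' @return The filtered `genotype_matrix`, with attribute `filter_report`:
#'   a data frame of loci removed per rule in application order. Removing
#'   every locus warns rather than errors.
#' @export
apply_screens <- function(x, cfg = locus_filter_config(), info = NULL) {
  stopifnot(inherits(x, "genotype_matrix"),
            inherits(cfg, "locus_filter_config"))
  if (is.null(info)) {
    info <- x$loci[, intersect(c("qd", "fs", "mq"), names(x$loci)),
                   drop = FALSE]
  }
  if (nrow(info) && nrow(info) != ncol(x$dosage)) {
    stop("info table must have one row per locus")
  }
  st <- site_stats(x)
  keep <- rep(TRUE, ncol(x$dosage))
  report <- data.frame(rule = character(0), removed = integer(0))
  drop_rule <- function(keep, fail, rule) {
    fail <- keep & fail
    report <<- rbind(report, data.frame(rule = rule, removed = sum(fail)))
    keep & !fail
  }
  keep <- drop_rule(keep, is.na(st$maf) | st$maf < cfg$maf_min, "maf")
  keep <- drop_rule(keep, st$call_rate < cfg$integrity_min, "integrity")
  if (!is.null(info$qd)) {
    keep <- drop_rule(keep, !is.na(info$qd) & info$qd < cfg$qd_min, "qd")
  }
  if (!is.null(info$fs)) {
    keep <- drop_rule(keep, !is.na(info$fs) & info$fs > cfg$fs_max, "fs")
  }
  if (!is.null(info$mq)) {
    keep <- drop_rule(keep, !is.na(info$mq) & info$mq < cfg$mq_min, "mq")
  }
  if (!any(keep)) warning("all loci removed by screens")
  out <- subset_genotypes(x, loci = which(keep))
  attr(out, "filter_report") <- report
  out
}
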