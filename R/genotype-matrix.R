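#' Construct a bulk genotype matrix
#'
#' The central exchange object of the package: a samples-by-loci matrix of
#' diploid dosage calls for bulked (pooled-DNA) samples, together with locus
#' metadata. Dosage coding follows the usual VCF GT convention for biallelic
#' SNPs: 0 = homozygous reference (0/0), 1 = heterozygous (0/1), 2 =
#' homozygous alternate (1/1), `NA` = missing (./.). For a bulk of pooled
#' plants the "heterozygous" state means the pool segregates for both
#' alleles.
#'
#' @param dosage Integer matrix, samples in rows, loci in columns, values in
#'   \{0, 1, 2, NA\}. Row names are sample identifiers.
#' @param loci Data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`. Extra columns (e.g. INFO fields `qd`,
#'   `fs`, `mq`) are carried along.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `loci`.
#' @seealso [read_vcf()], [write_vcf()], [site_stats()], [apply_screens()]
#' @export
genotype_matrix <- function(dosage, loci) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    stop("dosage matrix must have sample identifiers as row names")
  }
  if (anyDuplicated(rownames(dosage))) {
    stop("duplicate sample identifiers in dosage matrix")
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(loci) != ncol(dosage)) {
    stop("loci table (", nrow(loci), " rows) does not match dosage matrix (",
         ncol(dosage), " columns)")
  }
  if (nrow(loci)) {
    if (any(loci$pos < 1L)) stop("locus positions must be >= 1")
    bad <- !(nchar(loci$ref) == 1L & nchar(loci$alt) == 1L &
               loci$ref != loci$alt)
    if (any(bad)) stop(sum(bad), " loci are not biallelic SNPs")
    key <- paste(loci$chrom, loci$pos, loci$alt)
    if (anyDuplicated(key)) stop("duplicate (chrom, pos, alt) loci")
    vals <- dosage[!is.na(dosage)]
    if (length(vals) && !all(vals %in% 0:2)) {
      stop("dosage values must be 0, 1, 2 or NA")
    }
  }
  if (is.null(loci$id)) {
    loci$id <- if (nrow(loci)) paste0(loci$chrom, "_", loci$pos) else
      character(0)
  }
  colnames(dosage) <- loci$id
  storage.mode(dosage) <- "integer"
  structure(list(dosage = dosage, loci = loci), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x",
      ncol(x$dosage), "biallelic SNP loci\n")
  nmis <- sum(is.na(x$dosage))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nmis,
              100 * nmis / max(1L, length(x$dosage))))
  cat("  samples:", paste(utils::head(rownames(x$dosage), 6L),
                          collapse = ", "),
      if (nrow(x$dosage) > 6L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x A [genotype_matrix()].
#' @param samples,loci Index vectors (integer, logical or character) into
#'   rows and columns; `NULL` keeps everything.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, loci = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  l <- x$loci
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(loci)) {
    d <- d[, loci, drop = FALSE]
    l <- l[loci, , drop = FALSE]
  }
  rownames(l) <- NULL
  genotype_matrix(d, l)
}

#' Define the sample-to-variety hierarchy
#'
#' Maps bulk sample identifiers to the variety each bulk was drawn from;
#' this grouping defines the AMOVA hierarchy and all per-variety summaries.
#'
#' @param sample Character vector of bulk sample IDs.
#' @param variety Character vector (same length) of variety names.
#' @return A data frame of class `sample_map` with columns `sample` and
#'   `variety`.
#' @export
sample_map <- function(sample, variety) {
  sample <- as.character(sample)
  variety <- as.character(variety)
  if (length(sample) != length(variety)) {
    stop("sample and variety must have the same length")
  }
  if (!length(sample)) stop("sample map is empty")
  if (anyDuplicated(sample)) {
    stop("duplicate sample IDs in map: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  structure(data.frame(sample = sample, variety = variety,
                       stringsAsFactors = FALSE),
            class = c("sample_map", "data.frame"))
}

#' Read a sample map from a two-column TSV
#'
#' @param path Path to a tab-separated file with columns `sample` and
#'   `variety` (header optional; two unnamed columns are taken in that
#'   order).
#' @return A [sample_map()].
#' @export
read_sample_map <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("sample", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          col.names = if (header) NULL else
                            c("sample", "variety"))
  names(df)[1:2] <- c("sample", "variety")
  sample_map(df$sample, df$variety)
}

## variety label per matrix row, validating the one-to-one assignment
map_groups <- function(x, map) {
  stopifnot(inherits(map, "sample_map"))
  ids <- if (inherits(x, "genotype_matrix")) rownames(x$dosage) else x
  idx <- match(ids, map$sample)
  if (anyNA(idx)) {
    stop("samples missing from sample map: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  stats::setNames(map$variety[idx], ids)
}
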