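## Per-locus index battery for one set of diploid samples.
## n: non-missing calls per locus; p: alt allele frequency.
locus_indices <- function(dosage) {
  n <- colSums(!is.na(dosage))
  alt <- colSums(dosage, na.rm = TRUE)
  p <- ifelse(n > 0L, alt / (2 * n), NA_real_)
  q <- 1 - p
  he <- 1 - p^2 - q^2
  ne <- 1 / (p^2 + q^2)
  ho <- ifelse(n > 0L, colSums(dosage == 1L, na.rm = TRUE) / n, NA_real_)
  plogp <- function(z) ifelse(z > 0, z * log(z), 0)
  shi <- -(plogp(p) + plogp(q))
  nei <- ifelse(n > 0L, (2 * n / pmax(2 * n - 1, 1)) * he, NA_real_)
  na_cnt <- ifelse(n == 0L, 0L, ifelse(p > 0 & p < 1, 2L, 1L))
  list(n = n, p = p, he = he, ne = ne, ho = ho, shi = shi, nei = nei,
       na_cnt = na_cnt)
}

#' Per-variety genetic diversity indices
#'
#' Computes, for each variety (and for all samples pooled as one
#' population, the `"all"` row), the classical locus-averaged diversity
#' battery. Within a variety, each locus with `n` non-missing diploid
#' bulks and alternate-allele frequency `p` (`q = 1 - p`) contributes:
#' expected heterozygosity `He = 1 - p^2 - q^2`, effective allele number
#' `Ne = 1 / (p^2 + q^2)`, observed heterozygosity `Ho` = heterozygote
#' fraction, Shannon information `Shi = -(p ln p + q ln q)`, Nei's
#' unbiased gene diversity `Nei = (2n / (2n - 1)) He`, and allele count
#' `Na` (distinct alleles observed: 1 or 2). Indices are averaged over
#' loci with at least one call in that variety; loci entirely missing in
#' a variety are excluded from its denominators.
#'
#' @param x A screened [genotype_matrix()].
#' @param map A [sample_map()].
#' @return A data frame of class `diversity_table` with columns
#'   `variety`, `n_bulks`, `n_loci` (callable loci), `ne`, `na`, `ho`,
#'   `he`, `nei`, `shi`; one row per variety plus an `"all"` row pooling
#'   every sample. A variety with no callable locus yields an `NA` row
#'   with a warning.
#' @seealso [summarize_means()], [nucleotide_pi()]
#' @export
variety_diversity <- function(x, map) {
  stopifnot(inherits(x, "genotype_matrix"))
  groups <- map_groups(x, map)
  vars <- unique(map$variety[map$sample %in% rownames(x$dosage)])
  one_pop <- function(dosage) {
    li <- locus_indices(dosage)
    callable <- li$n > 0L
    if (!any(callable)) {
      return(data.frame(n_loci = 0L, ne = NA_real_, na = NA_real_,
                        ho = NA_real_, he = NA_real_, nei = NA_real_,
                        shi = NA_real_))
    }
    data.frame(n_loci = sum(callable),
               ne = mean(li$ne[callable]),
               na = mean(li$na_cnt[callable]),
               ho = mean(li$ho[callable]),
               he = mean(li$he[callable]),
               nei = mean(li$nei[callable]),
               shi = mean(li$shi[callable]))
  }
  rows <- lapply(vars, function(v) {
    d <- x$dosage[names(groups)[groups == v], , drop = FALSE]
    cbind(data.frame(variety = v, n_bulks = nrow(d)), one_pop(d))
  })
  rows <- do.call(rbind, rows)
  if (any(rows$n_loci == 0L)) {
    warning("variety with no callable loci: ",
            paste(rows$variety[rows$n_loci == 0L], collapse = ", "))
  }
  all_row <- cbind(data.frame(variety = "all",
                              n_bulks = nrow(x$dosage)),
                   one_pop(x$dosage))
  out <- rbind(rows, all_row)
  rownames(out) <- NULL
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Column means of a diversity table
#'
#' Unweighted arithmetic mean of each index over the variety rows
#' (excluding the pooled `"all"` row), as printed in the "Means" row of
#' published diversity tables.
#'
#' @param table A `diversity_table` from [variety_diversity()], or any
#'   data frame with a `variety` column and numeric index columns.
#' @return A one-row data frame with `variety = "Means"`.
#' @export
summarize_means <- function(table) {
  stopifnot(is.data.frame(table), "variety" %in% names(table))
  rows <- table[!(table$variety %in% c("all", "Means")), , drop = FALSE]
  if (!nrow(rows)) stop("no variety rows to average")
  num <- vapply(rows, is.numeric, logical(1))
  out <- rows[1, , drop = FALSE]
  out$variety <- "Means"
  for (col in names(rows)[num]) out[[col]] <- mean(rows[[col]])
  rownames(out) <- NULL
  out
}

#' Per-variety nucleotide diversity over screened SNP loci
#'
#' Nucleotide diversity `pi` as the average pairwise difference among the
#' allele copies sampled in a variety: at a locus with `c = 2 * n`
#' non-missing allele copies and alternate frequency `p`,
#' `pi = (c / (c - 1)) * 2 p (1 - p)` (the unbiased per-site
#' heterozygosity). `Pi` is the mean over callable loci, i.e. on a
#' per-screened-SNP scale rather than per genomic site, so only
#' orderings — not absolute genome-wide values — are comparable with
#' whole-sequence estimates.
#'
#' @param x A [genotype_matrix()].
#' @param map A [sample_map()].
#' @return Data frame of class `pi_table`: `variety`, `n_loci`, `pi`.
#' @export
nucleotide_pi <- function(x, map) {
  stopifnot(inherits(x, "genotype_matrix"))
  groups <- map_groups(x, map)
  vars <- unique(map$variety[map$sample %in% rownames(x$dosage)])
  rows <- lapply(vars, function(v) {
    d <- x$dosage[names(groups)[groups == v], , drop = FALSE]
    n <- colSums(!is.na(d))
    cc <- 2 * n
    p <- ifelse(n > 0L, colSums(d, na.rm = TRUE) / cc, NA_real_)
    callable <- n > 0L
    pi_loc <- (cc / pmax(cc - 1, 1)) * 2 * p * (1 - p)
    data.frame(variety = v, n_loci = sum(callable),
               pi = if (any(callable)) mean(pi_loc[callable]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pi_table", "data.frame")
  out
}

#' Gene flow from pairwise differentiation
#'
#' Island-model effective migration, `Nm = (1 - Fst) / (4 Fst)`, applied
#' element-wise to a pairwise differentiation matrix. `Fst = 0` yields
#' `Inf` (unbounded gene flow).
#'
#' @param fst An `fst_matrix` from [pairwise_fst()] or a plain symmetric
#'   matrix of pairwise Fst values in \[0, 1).
#' @return A symmetric matrix of Nm values (diagonal `NA`).
#' @export
gene_flow_nm <- function(fst) {
  m <- if (inherits(fst, "fst_matrix")) fst$phi else as.matrix(fst)
  if (any(m < 0 | m >= 1, na.rm = TRUE)) {
    stop("Fst values must lie in [0, 1)")
  }
  nm <- ifelse(m == 0, Inf, (1 - m) / (4 * m))
  diag(nm) <- NA_real_
  nm
}
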