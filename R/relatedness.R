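#' VanRaden genomic relationship (kinship) matrix
#'
#' The first VanRaden genomic relationship matrix on dosage calls:
#' with per-locus alternate frequency `p` estimated from all samples,
#' centered scores `Z = dosage - 2p` (missing dosages imputed at the mean,
#' i.e. `Z = 0`), `K = Z Z' / (2 * sum p (1 - p))`, summing over
#' polymorphic loci only (monomorphic loci carry no information and are
#' excluded from numerator and denominator alike).
#'
#' @param x A [genotype_matrix()] with at least two samples and at least
#'   one polymorphic locus.
#' @return A symmetric samples x samples matrix of class `matrix`.
#' @export
vanraden_kinship <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  if (nrow(d) < 2L) stop("need at least two samples")
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0L, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci")
  z <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly])
  z[is.na(z)] <- 0
  k <- tcrossprod(z) / (2 * sum(p[poly] * (1 - p[poly])))
  (k + t(k)) / 2
}

#' Neighbor-joining tree from a squared-distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}) on the package's
#' mean squared dosage distance, with negative branch lengths clamped to
#' zero. No substitution model is assumed — appropriate for unlinked SNP
#' dosages of pooled bulks, where model-based phylogenetics has no
#' meaningful likelihood.
#'
#' @param dist A symmetric distance matrix (e.g.
#'   [pairwise_sq_distance()]) over at least three samples, or a `dist`
#'   object.
#' @return An unrooted `ape::phylo` tree over the samples.
#' @export
nj_tree <- function(dist) {
  m <- as.matrix(dist)
  if (nrow(m) < 3L) stop("neighbor joining needs at least three samples")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the neighbor-joining bulk tree
#'
#' Builds the reference NJ tree on all loci, then resamples loci with
#' replacement `n_boot` times, rebuilds the tree per replicate, and
#' reports for each internal edge of the reference tree the percentage of
#' replicates containing the same bipartition. Supports are stored as
#' internal node labels, so the tree can be written to Newick with
#' `ape::write.tree()`.
#'
#' @param x A [genotype_matrix()] with at least four samples.
#' @param n_boot Number of bootstrap replicates; `0` returns the
#'   reference tree without supports.
#' @param seed Seed for the resampling stream.
#' @return An `ape::phylo` tree with `node.label` holding support
#'   percentages (root label empty).
#' @export
bootstrap_supports <- function(x, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  if (nrow(d) < 4L) stop("need at least four samples")
  build <- function(mat) nj_tree(pairwise_sq_distance(mat))
  ref <- build(d)
  if (n_boot < 1L) return(ref)
  counts <- with_seed(if (is.null(seed)) NULL else
                        stream_seed(seed, "bootstrap"), {
    ape::boot.phylo(ref, d, build, B = n_boot, quiet = TRUE,
                    trees = FALSE)
  })
  supports <- round(100 * counts / n_boot, 1)
  sup <- supports[-1L]          # drop the root: no bipartition there
  sup[is.na(sup)] <- 0
  ref$node.label <- c("", as.character(sup))
  attr(ref, "support") <- sup
  ref
}

#' Principal component scores of bulk genotypes
#'
#' Missing dosages are imputed at the per-locus mean, columns are
#' centered, and scores are taken from the singular value decomposition
#' (scores = left singular vectors times singular values), so the first
#' components capture the dominant axes of among-bulk SNP variation.
#'
#' @param x A [genotype_matrix()] with at least two samples.
#' @param n_components Number of components to return (default 2; capped
#'   at the matrix rank).
#' @return A list of class `pca_scores`: `scores` (samples x components),
#'   `explained` (fraction of total variance per returned component), and
#'   `sdev`.
#' @export
pca_scores <- function(x, n_components = 2L) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  if (nrow(d) < 2L) stop("need at least two samples")
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  d <- sweep(d, 2L, colMeans(d))
  sv <- svd(d)
  k <- min(as.integer(n_components), sum(sv$d > 1e-8))
  k <- max(k, 1L)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x$dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  tot <- sum(sv$d^2)
  structure(list(scores = scores,
                 explained = if (tot > 0) sv$d[seq_len(k)]^2 / tot else
                   rep(0, k),
                 sdev = sv$d / sqrt(max(1, nrow(d) - 1))),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("PCA scores:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("explained variance:",
      paste0(round(100 * x$explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Evanno delta-K from clustering log-likelihood runs
#'
#' The second-order rate of change of the clustering log-likelihood,
#' used to choose the number of genetic clusters K from replicate
#' Bayesian-clustering runs: per run, `L'(K) = L(K) - L(K-1)` and
#' `L''(K) = |L'(K+1) - L'(K)|`; then
#' `deltaK(K) = mean(L''(K)) / sd(L(K))` across runs. Zero run-to-run
#' standard deviation yields `Inf` (an unambiguous kink). deltaK is
#' undefined at the first and last K.
#'
#' @param runs Matrix of log-likelihoods with one row per K (consecutive
#'   K values as row names, or supply `k_values`) and one column per
#'   replicate run; at least 3 K values and 2 runs.
#' @param k_values Optional integer vector of K values (defaults to row
#'   names, else `1:nrow`).
#' @return A data frame of class `delta_k_table`: `k`, `mean_l`, `sd_l`,
#'   `delta_k` (`NA` at the endpoints); attribute `modal_k` gives the
#'   argmax.
#' @export
evanno_delta_k <- function(runs, k_values = NULL) {
  runs <- as.matrix(runs)
  if (is.null(k_values)) {
    k_values <- if (!is.null(rownames(runs))) {
      as.integer(rownames(runs))
    } else seq_len(nrow(runs))
  }
  if (nrow(runs) < 3L) stop("need at least three consecutive K values")
  if (ncol(runs) < 2L) stop("need at least two runs per K")
  if (any(diff(k_values) != 1L)) stop("K values must be consecutive")
  nk <- nrow(runs)
  l1 <- apply(runs, 2L, diff)                    # (nk-1) x runs: L'(K2..)
  l2 <- abs(apply(l1, 2L, diff))                 # (nk-2) x runs: L''
  if (is.null(dim(l2))) l2 <- matrix(l2, nrow = 1L)
  mean_l2 <- rowMeans(l2)
  sd_l <- apply(runs, 1L, stats::sd)
  dk <- rep(NA_real_, nk)
  mid <- 2:(nk - 1L)
  dk[mid] <- ifelse(sd_l[mid] == 0,
                    ifelse(mean_l2 == 0, 0, Inf),
                    mean_l2 / sd_l[mid])
  out <- data.frame(k = k_values, mean_l = rowMeans(runs), sd_l = sd_l,
                    delta_k = dk)
  rownames(out) <- NULL
  attr(out, "modal_k") <- k_values[mid][which.max(dk[mid])]
  class(out) <- c("delta_k_table", "data.frame")
  out
}

#' @export
print.delta_k_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat("modal K:", attr(x, "modal_k"), "\n")
  invisible(x)
}
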