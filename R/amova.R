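#' Mean squared dosage distance between samples
#'
#' Squared genetic distance used throughout the package:
#' `d2(i, j)` is the mean, over loci called in *both* samples, of the
#' squared dosage difference. Averaging (rather than summing) over shared
#' loci makes distances comparable across panels of different sizes and
#' robust to missing calls.
#'
#' @param x A [genotype_matrix()] (or a plain samples x loci dosage
#'   matrix) with at least two samples.
#' @return A symmetric samples x samples matrix with zero diagonal. A pair
#'   of samples sharing no called locus is an error.
#' @export
pairwise_sq_distance <- function(x) {
  d <- if (inherits(x, "genotype_matrix")) x$dosage else as.matrix(x)
  if (nrow(d) < 2L) stop("need at least two samples")
  m <- !is.na(d)
  x0 <- d
  x0[!m] <- 0
  storage.mode(x0) <- "double"
  mode(m) <- "numeric"
  n_shared <- tcrossprod(m)
  sq <- x0^2
  ssq <- tcrossprod(sq, m) + tcrossprod(m, sq) - 2 * tcrossprod(x0)
  off <- row(n_shared) != col(n_shared)
  if (any(n_shared[off] == 0)) {
    stop("sample pair(s) share no called locus")
  }
  d2 <- ssq / pmax(n_shared, 1)
  d2[!off] <- 0
  d2 <- (d2 + t(d2)) / 2  # enforce exact symmetry against FP noise
  dimnames(d2) <- list(rownames(d), rownames(d))
  d2
}

## Within-group sum of squares from a squared-distance matrix:
## SS_w = sum over groups of (1 / n_g) * sum_{i<j in g} d2(i, j)
ss_within_groups <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      ss <- ss + sum(d2[idx, idx]) / 2 / length(idx)
    }
  }
  ss
}

## All distinct assignments of a label multiset to positions (rows).
## Used for the exact permutation null on small designs.
multiset_permutations <- function(labels) {
  n <- length(labels)
  rec <- function(counts) {
    if (sum(counts) == 0L) return(matrix(character(0), nrow = 1L))
    out <- NULL
    for (lab in names(counts)[counts > 0L]) {
      cnt <- counts
      cnt[lab] <- cnt[lab] - 1L
      sub <- rec(cnt)
      out <- rbind(out, cbind(lab, sub, deparse.level = 0))
    }
    out
  }
  counts <- table(labels)
  rec(counts[order(names(counts))])
}

n_label_assignments <- function(groups) {
  cnt <- table(groups)
  exp(lgamma(length(groups) + 1) - sum(lgamma(cnt + 1)))
}

amova_phi <- function(d2, groups, N, G, df_among, df_within, n0) {
  ss_total <- sum(d2) / 2 / N
  ss_within <- ss_within_groups(d2, groups)
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  vc_among <- (ms_among - ms_within) / n0
  vc_within <- ms_within
  denom <- vc_among + vc_within
  phi <- if (abs(denom) < 1e-300) 0 else vc_among / denom
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       ms_among = ms_among, ms_within = ms_within,
       vc_among = vc_among, vc_within = vc_within, phi = phi)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions the squared-distance variance of bulk samples into
#' among-variety and within-variety components and tests the fixation
#' index PhiST by permuting sample-to-variety labels. Sums of squares
#' follow the standard distance formulation:
#' `SS_total = (1/N) sum_{i<j} d2(i,j)` and
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d2(i,j)`; variance
#' components use `n0 = (N - sum n_g^2 / N) / (G - 1)`,
#' `VC_among = (MS_among - MS_within) / n0`, `VC_within = MS_within`, and
#' `PhiST = VC_among / (VC_among + VC_within)`.
#'
#' When the number of distinct label assignments is small (at most
#' `exhaustive_max`), the permutation null is enumerated exactly and the
#' P-value is the exact proportion of assignments with PhiST at least the
#' observed (the identity assignment makes it strictly positive).
#' Otherwise `n_perm` random permutations are drawn and
#' `P = (1 + b) / (1 + B)` where `b` counts permuted PhiST >= observed.
#'
#' A dataset with zero total variance carries no information: PhiST is
#' defined as 0 with P = 1.
#'
#' @param x A [genotype_matrix()], or a precomputed symmetric squared
#'   distance matrix as from [pairwise_sq_distance()].
#' @param map A [sample_map()] covering every sample.
#' @param n_perm Number of random permutations (default 999); ignored
#'   when the null is enumerated exhaustively.
#' @param seed Optional seed for the permutation stream.
#' @param method `"auto"` (exhaustive when feasible, else sampled),
#'   `"exhaustive"` or `"sampled"`.
#' @param exhaustive_max Largest number of label assignments enumerated
#'   under `"auto"`.
#' @return An object of class `bulkpop_amova`: degrees of freedom, sums
#'   of squares, mean squares, variance components, percentages of
#'   variation (negative `VC_among` clamped to zero for percentages),
#'   `phi_st`, `p_value`, `n_permutations` and the permutation method.
#' @examples
#' sim <- simulate_bulk_dataset(simulation_config(n_loci = 300, seed = 9))
#' amova(sim$genotypes, sim$map, n_perm = 99, seed = 1)
#' @export
amova <- function(x, map, n_perm = 999, seed = NULL,
                  method = c("auto", "exhaustive", "sampled"),
                  exhaustive_max = 500) {
  method <- match.arg(method)
  d2 <- if (inherits(x, "genotype_matrix")) pairwise_sq_distance(x) else {
    as.matrix(x)
  }
  groups <- map_groups(rownames(d2), map)
  N <- nrow(d2)
  G <- length(unique(groups))
  if (G < 2L) stop("AMOVA needs at least two varieties")
  n_g <- table(groups)
  df_among <- G - 1L
  df_within <- N - G
  if (df_within < 1L) stop("AMOVA needs replicate samples within varieties")
  n0 <- (N - sum(n_g^2) / N) / df_among
  if (n0 <= 0) stop("invalid design: n0 <= 0")

  obs <- amova_phi(d2, groups, N, G, df_among, df_within, n0)

  degenerate <- obs$ss_total < 1e-12
  n_assign <- n_label_assignments(groups)
  use_exhaustive <- !degenerate &&
    (method == "exhaustive" ||
       (method == "auto" && n_assign <= exhaustive_max))

  if (degenerate) {
    phi <- 0
    p <- 1
    n_done <- 0L
    perm_method <- "none"
  } else if (use_exhaustive) {
    perms <- multiset_permutations(groups)
    phis <- apply(perms, 1L, function(g) {
      amova_phi(d2, g, N, G, df_among, df_within, n0)$phi
    })
    phi <- obs$phi
    p <- mean(phis >= obs$phi - 1e-12)
    n_done <- nrow(perms)
    perm_method <- "exhaustive"
  } else {
    phi <- obs$phi
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        amova_phi(d2, sample(groups), N, G, df_among, df_within, n0)$phi
      }, numeric(1)) >= obs$phi - 1e-12)
    })
    p <- (1 + hits) / (1 + n_perm)
    n_done <- as.integer(n_perm)
    perm_method <- "sampled"
  }

  vc_among_c <- max(obs$vc_among, 0)
  tot_c <- vc_among_c + max(obs$vc_within, 0)
  pct_among <- if (tot_c > 0) 100 * vc_among_c / tot_c else 0
  structure(list(df_among = df_among, df_within = df_within,
                 df_total = df_among + df_within,
                 ss_among = obs$ss_among, ss_within = obs$ss_within,
                 ss_total = obs$ss_total,
                 ms_among = obs$ms_among, ms_within = obs$ms_within,
                 vc_among = obs$vc_among, vc_within = obs$vc_within,
                 pct_among = pct_among, pct_within = 100 - pct_among,
                 n0 = n0, phi_st = phi, p_value = p,
                 n_permutations = n_done, method = perm_method,
                 n_samples = N, n_varieties = G),
            class = "bulkpop_amova")
}

#' @export
print.bulkpop_amova <- function(x, digits = 4, ...) {
  cat("Two-level AMOVA:", x$n_varieties, "varieties,",
      x$n_samples, "bulk samples\n\n")
  tab <- data.frame(
    df = c(x$df_among, x$df_within, x$df_total),
    SS = signif(c(x$ss_among, x$ss_within, x$ss_total), digits + 2),
    MS = c(signif(c(x$ms_among, x$ms_within), digits + 2), NA),
    VC = c(signif(c(x$vc_among, x$vc_within), digits + 2), NA),
    pct = c(round(c(x$pct_among, x$pct_within), 2), NA),
    row.names = c("Among varieties", "Within varieties", "Total"))
  print(tab, na.print = "")
  cat(sprintf("\nPhiST = %.*f, P = %.4g (%s, %d permutations)\n",
              digits, x$phi_st, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' Summarise printed variance components into percentages and PhiST
#'
#' The bookkeeping applied to a pair of AMOVA variance components:
#' percentages of variation (negative components clamped to zero) and the
#' fixation index `PhiST = VC_among / (VC_among + VC_within)`. Useful for
#' re-deriving the derived columns of a published AMOVA table from its
#' printed components.
#'
#' @param vc_among,vc_within Variance components.
#' @return A list with `pct_among`, `pct_within` and `phi_st`.
#' @export
variance_component_summary <- function(vc_among, vc_within) {
  a <- max(vc_among, 0)
  tot <- a + max(vc_within, 0)
  pct <- if (tot > 0) 100 * a / tot else 0
  list(pct_among = pct, pct_within = 100 - pct,
       phi_st = vc_among / (vc_among + vc_within))
}

#' Pairwise PhiST between all varieties
#'
#' Computes, for every pair of varieties, the two-group AMOVA fixation
#' index on their bulks, with a permutation P-value per pair (exact
#' enumeration is used automatically for small designs, e.g. the 10
#' distinct splits of 3 + 3 bulks).
#'
#' @param x A [genotype_matrix()] or a precomputed squared distance
#'   matrix over all samples (per-pair distances are already restricted
#'   to loci shared by the two samples, so subsetting is exact).
#' @param map A [sample_map()].
#' @param n_perm Random permutations per pair when enumeration is not
#'   feasible.
#' @param seed Optional seed for the permutation stream.
#' @return An object of class `fst_matrix`: `phi` and `p_value`, both
#'   varieties x varieties symmetric matrices (diagonal 0 and 1
#'   respectively).
#' @export
pairwise_fst <- function(x, map, n_perm = 999, seed = NULL) {
  d2 <- if (inherits(x, "genotype_matrix")) pairwise_sq_distance(x) else {
    as.matrix(x)
  }
  groups <- map_groups(rownames(d2), map)
  vars <- unique(map$variety[map$sample %in% rownames(d2)])
  if (length(vars) < 2L) stop("need at least two varieties")
  G <- length(vars)
  phi <- matrix(0, G, G, dimnames = list(vars, vars))
  pval <- matrix(1, G, G, dimnames = list(vars, vars))
  diag(pval) <- 1
  with_seed(seed, {
    for (a in seq_len(G - 1L)) {
      for (b in seq((a + 1L), G)) {
        idx <- which(groups %in% vars[c(a, b)])
        res <- amova(d2[idx, idx, drop = FALSE], map, n_perm = n_perm)
        phi[a, b] <- phi[b, a] <- res$phi_st
        pval[a, b] <- pval[b, a] <- res$p_value
      }
    }
  })
  structure(list(phi = phi, p_value = pval, n_varieties = G),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise PhiST among", x$n_varieties, "varieties\n")
  print(round(x$phi, digits))
  ext <- fst_extremes(x)
  cat(sprintf("min %.4f (%s, %s); max %.4f (%s, %s)\n",
              ext$min_value, ext$min_pair[1], ext$min_pair[2],
              ext$max_value, ext$max_pair[1], ext$max_pair[2]))
  invisible(x)
}

#' Most and least differentiated variety pairs
#'
#' Scans the off-diagonal of a pairwise differentiation matrix for its
#' minimum and maximum. Ties are broken lexicographically by the sorted
#' pair of variety names, so the result is deterministic.
#'
#' @param fst An `fst_matrix` from [pairwise_fst()], or a plain symmetric
#'   matrix with variety names.
#' @return A list: `min_pair`, `min_value`, `max_pair`, `max_value` (each
#'   pair sorted alphabetically).
#' @export
fst_extremes <- function(fst) {
  m <- if (inherits(fst, "fst_matrix")) fst$phi else as.matrix(fst)
  if (nrow(m) < 2L) stop("need at least two varieties")
  vars <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- data.frame(a = vars[idx[, 1]], b = vars[idx[, 2]],
                      value = m[idx], stringsAsFactors = FALSE)
  swap <- pairs$a > pairs$b
  tmp <- pairs$a[swap]
  pairs$a[swap] <- pairs$b[swap]
  pairs$b[swap] <- tmp
  pairs <- pairs[order(pairs$a, pairs$b), ]
  i_min <- which.min(pairs$value)
  i_max <- which.max(pairs$value)
  list(min_pair = c(pairs$a[i_min], pairs$b[i_min]),
       min_value = pairs$value[i_min],
       max_pair = c(pairs$a[i_max], pairs$b[i_max]),
       max_value = pairs$value[i_max])
}
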