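#' Select the focal variety pair for panel sizing
#'
#' The hardest pair to tell apart — the off-diagonal minimum of the
#' pairwise differentiation matrix — is the natural worst case for
#' deciding how many markers a panel needs.
#'
#' @param fst An `fst_matrix` from [pairwise_fst()] or a plain symmetric
#'   matrix.
#' @return Character vector of the two variety names (sorted).
#' @export
select_focal_pair <- function(fst) {
  fst_extremes(fst)$min_pair
}

#' Marker-panel subsampling curve
#'
#' How does the ability to separate two varieties change with the number
#' of SNPs genotyped? For each panel size, `n_reps` random marker panels
#' are drawn (without replacement within a draw, fresh draw per
#' replicate) and a two-group AMOVA on the focal pair's bulks is run on
#' each, recording PhiST and its permutation P-value (enumerated exactly
#' for small designs, e.g. the 10 distinct splits of 3 + 3 bulks).
#'
#' @param x A [genotype_matrix()].
#' @param map A [sample_map()].
#' @param pair Character vector of two variety names; typically
#'   [select_focal_pair()].
#' @param sizes Strictly increasing panel sizes; each must not exceed the
#'   number of loci available.
#' @param n_reps Replicate panels per size (default 100).
#' @param n_perm Random permutations per replicate when the null cannot
#'   be enumerated (default 99).
#' @param seed Seed for the subsampling/permutation stream.
#' @return A data frame of class `subsampling_curve` with one row per
#'   size: `size`, `mean_phi`, `sd_phi`, `mean_p`; attributes
#'   `focal_pair` and `n_replicates`.
#' @seealso [recommend_panel_size()]
#' @export
subsampling_curve <- function(x, map, pair, sizes = c(10, 20, 50, 80, 100,
                                                      500, 1000, 5000,
                                                      10000),
                              n_reps = 100, n_perm = 99, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), length(pair) == 2L)
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing")
  }
  L <- ncol(x$dosage)
  if (any(sizes > L)) {
    stop("panel size(s) exceed available loci (", L, "): ",
         paste(sizes[sizes > L], collapse = ", "))
  }
  groups <- map_groups(x, map)
  keep <- which(groups %in% pair)
  if (length(unique(groups[keep])) != 2L) {
    stop("both varieties of the focal pair must be present")
  }
  d <- x$dosage[keep, , drop = FALSE]
  pmap <- sample_map(rownames(d), groups[keep])

  res <- with_seed(if (is.null(seed)) NULL else
                     stream_seed(seed, "subsampling"), {
    lapply(sizes, function(s) {
      phi <- numeric(n_reps)
      pv <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        idx <- sample.int(L, s)
        a <- amova(pairwise_sq_distance(d[, idx, drop = FALSE]),
                   pmap, n_perm = n_perm)
        phi[r] <- a$phi_st
        pv[r] <- a$p_value
      }
      data.frame(size = s, mean_phi = mean(phi), sd_phi = stats::sd(phi),
                 mean_p = mean(pv))
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "focal_pair") <- sort(pair)
  attr(out, "n_replicates") <- as.integer(n_reps)
  class(out) <- c("subsampling_curve", "data.frame")
  out
}

#' @export
print.subsampling_curve <- function(x, ...) {
  cat("Marker-panel subsampling curve for pair",
      paste(attr(x, "focal_pair"), collapse = " vs "),
      sprintf("(%d replicates per size)\n", attr(x, "n_replicates")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.subsampling_curve <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$size, x$mean_phi, log = "x", type = "b", pch = 16,
                 xlab = "Number of markers", ylab = "Mean PhiST", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$size, x$mean_p, log = "x", type = "b", pch = 1,
                 lty = 2, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("Mean AMOVA P", side = 4, line = 2.5)
  invisible(x)
}

#' Recommend a marker-panel size from a subsampling curve
#'
#' The smallest panel size whose mean permutation P-value is at most
#' `alpha` *and* whose mean PhiST strictly exceeds `stability` times the
#' curve's maximum (i.e. the differentiation estimate has reached its
#' plateau; a size sitting exactly at the stability fraction has not). If
#' no size qualifies, the largest size is returned with a warning.
#'
#' @param curve A [subsampling_curve()].
#' @param alpha Significance threshold on the mean P-value (default
#'   0.05).
#' @param stability Fraction of the maximum mean PhiST that must be
#'   reached (default 0.95).
#' @return A single panel size (integer).
#' @export
recommend_panel_size <- function(curve, alpha = 0.05, stability = 0.95) {
  stopifnot(inherits(curve, "subsampling_curve") ||
              all(c("size", "mean_phi", "mean_p") %in% names(curve)))
  if (!nrow(curve)) stop("empty curve")
  # comparisons at 12 digits so decimal thresholds behave as written
  plateau <- round(stability * max(curve$mean_phi), 12)
  ok <- curve$mean_p <= alpha & round(curve$mean_phi, 12) > plateau
  if (!any(ok)) {
    warning("no panel size meets both criteria; returning the largest")
    return(curve$size[nrow(curve)])
  }
  curve$size[which(ok)[1L]]
}
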