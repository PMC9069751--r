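# Shared builders and independent oracles. Oracles are written as plain
# loops straight from the defining formulas, independent of the package
# internals they are used to check.

# quick genotype_matrix from a samples x loci dosage matrix
gm <- function(dosage, samples = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) {
    samples <- if (!is.null(rownames(dosage))) rownames(dosage) else
      paste0("s", seq_len(nrow(dosage)))
  }
  rownames(dosage) <- samples
  L <- ncol(dosage)
  genotype_matrix(dosage, data.frame(chrom = "1", pos = seq_len(L),
                                     ref = "A", alt = "G"))
}

# brute-force mean squared dosage distance over shared loci
oracle_d2 <- function(dosage) {
  n <- nrow(dosage)
  out <- matrix(0, n, n, dimnames = list(rownames(dosage),
                                         rownames(dosage)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(dosage[i, ]) & !is.na(dosage[j, ])
    out[i, j] <- mean((dosage[i, ok] - dosage[j, ok])^2)
  }
  out
}

# AMOVA sums of squares, variance components and PhiST from first
# principles (plain loops over the distance matrix)
oracle_amova <- function(d2, groups) {
  n <- nrow(d2)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d2[i, j]
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
    }
    ssw <- ssw + s / length(idx)
  }
  G <- length(unique(groups))
  dfa <- G - 1
  dfw <- n - G
  ng <- as.vector(table(groups))
  n0 <- (n - sum(ng^2) / n) / dfa
  msa <- (sst - ssw) / dfa
  msw <- ssw / dfw
  vca <- (msa - msw) / n0
  phi <- if (vca + msw == 0) 0 else vca / (vca + msw)
  list(ss_total = sst, ss_within = ssw, ss_among = sst - ssw,
       phi = phi)
}

# exact permutation P for a two-group design by enumerating every
# distinct split with combn()
oracle_exact_p <- function(d2, groups) {
  obs <- oracle_amova(d2, groups)$phi
  n <- length(groups)
  n1 <- sum(groups == groups[1])
  sets <- utils::combn(n, n1)
  phis <- apply(sets, 2, function(idx) {
    g <- rep("B", n)
    g[idx] <- "A"
    oracle_amova(d2, g)$phi
  })
  mean(phis >= obs - 1e-12)
}

# Weir-Cockerham-style Fst from true per-variety allele frequencies:
# ratio of summed among-variety variances to summed p(1-p)
oracle_truth_fst <- function(freq) {
  s2 <- apply(freq, 1, stats::var)
  pbar <- rowMeans(freq)
  sum(s2) / sum(pbar * (1 - pbar))
}

# number of varieties whose bulks form a split (clade) of the unrooted
# tree, i.e. are each other's neighbors
count_variety_splits <- function(tree, map) {
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  n <- length(labs)
  part_keys <- vapply(parts, function(p) {
    v <- logical(n)
    v[p] <- TRUE
    if (!v[1]) v <- !v  # canonical orientation
    paste(as.integer(v), collapse = "")
  }, character(1))
  hits <- 0L
  for (v in unique(map$variety)) {
    w <- labs %in% map$sample[map$variety == v]
    if (!w[1]) w <- !w
    key <- paste(as.integer(w), collapse = "")
    if (key %in% part_keys) hits <- hits + 1L
  }
  hits
}

read_published <- function(file) {
  utils::read.delim(bulkpop_example(file), check.names = FALSE,
                    stringsAsFactors = FALSE)
}
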