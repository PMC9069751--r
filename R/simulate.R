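#' Configuration of the synthetic bulked-variety generator
#'
#' Describes one simulated multi-variety trial: a set of open-pollinated
#' varieties, each sampled as several bulks of pooled plants, genotyped at
#' independent biallelic SNPs. Divergence among varieties follows the
#' Balding-Nichols model with drift parameter `fst_target`; each bulk is
#' then genotyped by emulating pooled sequencing (plant sampling, Poisson
#' read depth, binomial allele sampling) and a three-state diploid call on
#' the pooled alternate-read fraction.
#'
#' Defaults mirror the bulked RAD-seq design the package targets: 11
#' varieties x 3 bulks x 50 plants per bulk, divergence at the centre of
#' the observed pairwise-Fst range (0.11-0.25), mean depth 30, ~5%
#' missingness, calls made only at depth >= 5 with the pool declared
#' segregating when the alternate-read fraction lies in (0.10, 0.90).
#'
#' @param n_varieties Number of varieties (>= 2).
#' @param n_bulks_per_variety Bulks per variety (>= 2).
#' @param n_plants_per_bulk Plants pooled into each bulk.
#' @param n_loci Number of independent biallelic SNP loci.
#' @param fst_target Balding-Nichols drift parameter in (0, 1); the
#'   divergence level the generator aims for.
#' @param ancestral_maf_range Range the ancestral alternate-allele
#'   frequency is drawn from (uniform).
#' @param mean_depth Mean sequencing depth per bulk and locus (Poisson).
#' @param missing_rate Extra per-call dropout probability in \[0, 1).
#' @param het_call_band Pooled alternate-read fraction band (low, high)
#'   within which a bulk is called heterozygous (dosage 1).
#' @param min_depth_call Minimum read depth for a call; shallower sites
#'   are missing.
#' @param seed Master seed; stage-specific streams are derived from it so
#'   identical configs reproduce identical datasets byte for byte.
#' @return A list of class `simulation_config`.
#' @seealso [simulate_bulk_dataset()]
#' @export
simulation_config <- function(n_varieties = 11L, n_bulks_per_variety = 3L,
                              n_plants_per_bulk = 50L, n_loci = 2000L,
                              fst_target = 0.15,
                              ancestral_maf_range = c(0.05, 0.5),
                              mean_depth = 30, missing_rate = 0.05,
                              het_call_band = c(0.10, 0.90),
                              min_depth_call = 5L, seed = 1L) {
  if (n_varieties < 2L) stop("n_varieties must be >= 2")
  if (n_bulks_per_variety < 2L) stop("n_bulks_per_variety must be >= 2")
  if (n_plants_per_bulk < 1L || n_loci < 1L) {
    stop("n_plants_per_bulk and n_loci must be positive")
  }
  if (!is.finite(fst_target) || fst_target <= 0 || fst_target >= 1) {
    stop("fst_target must lie strictly between 0 and 1")
  }
  stopifnot(length(ancestral_maf_range) == 2L,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] < 1,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            length(het_call_band) == 2L,
            het_call_band[1] < het_call_band[2],
            mean_depth > 0, missing_rate >= 0, missing_rate < 1,
            min_depth_call >= 1)
  structure(list(n_varieties = as.integer(n_varieties),
                 n_bulks_per_variety = as.integer(n_bulks_per_variety),
                 n_plants_per_bulk = as.integer(n_plants_per_bulk),
                 n_loci = as.integer(n_loci),
                 fst_target = fst_target,
                 ancestral_maf_range = ancestral_maf_range,
                 mean_depth = mean_depth,
                 missing_rate = missing_rate,
                 het_call_band = het_call_band,
                 min_depth_call = as.integer(min_depth_call),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_variety_names <- function(config) {
  sprintf("V%02d", seq_len(config$n_varieties))
}

sim_bulk_names <- function(config) {
  as.vector(t(outer(sim_variety_names(config),
                    seq_len(config$n_bulks_per_variety),
                    function(v, b) sprintf("%s_b%d", v, b))))
}

#' Simulate per-variety allele frequencies under Balding-Nichols drift
#'
#' Draws each locus's ancestral alternate-allele frequency `p` uniformly
#' within `ancestral_maf_range`, then each variety's frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_target` — the
#' Balding-Nichols model, whose among-variety variance is `F p (1-p)`.
#' Loci are independent.
#'
#' @param config A [simulation_config()].
#' @return A list of class `variety_freqs`: `freq` (loci x varieties
#'   matrix of population allele frequencies), `ancestral` (per-locus
#'   ancestral frequency), `loci` (locus metadata as in
#'   [genotype_matrix()]), and the `config`.
#' @export
simulate_variety_frequencies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$n_loci
  V <- config$n_varieties
  FF <- config$fst_target
  with_seed(stream_seed(config$seed, "frequencies"), {
    p0 <- stats::runif(L, config$ancestral_maf_range[1],
                       config$ancestral_maf_range[2])
    freq <- matrix(stats::rbeta(L * V,
                                shape1 = rep(p0 * (1 - FF) / FF, V),
                                shape2 = rep((1 - p0) * (1 - FF) / FF, V)),
                   nrow = L, ncol = V)
  })
  vn <- sim_variety_names(config)
  colnames(freq) <- vn
  bases <- c("A", "C", "G", "T")
  idx <- (seq_len(L) - 1L) %% 4L + 1L
  loci <- data.frame(chrom = "1", pos = 100L * seq_len(L),
                     ref = bases[idx], alt = bases[c(3L, 4L, 1L, 2L)][idx],
                     stringsAsFactors = FALSE)
  loci$id <- paste0("snp", seq_len(L))
  rownames(freq) <- loci$id
  structure(list(freq = freq, ancestral = p0, loci = loci,
                 config = config),
            class = "variety_freqs")
}

#' Simulate diploid bulk genotype calls from variety frequencies
#'
#' Emulates pooled genotyping of each bulk: `n_plants_per_bulk` diploid
#' plants are drawn per bulk and locus (alternate copies ~
#' `Binomial(2 * n_plants, p_variety)`), sequencing depth is
#' `Poisson(mean_depth)`, alternate reads are binomial in the realized
#' pool fraction, and the bulk is called from the alternate-read fraction
#' `f`: dosage 0 if `f < band[1]`, 2 if `f > band[2]`, else 1 (the pool
#' segregates). Calls are missing when depth falls below `min_depth_call`
#' or with probability `missing_rate`.
#'
#' @param freqs A `variety_freqs` object from
#'   [simulate_variety_frequencies()].
#' @param config The matching [simulation_config()]; defaults to the one
#'   stored in `freqs`.
#' @return A [genotype_matrix()] of the bulks, with attribute `pool_freq`:
#'   the loci x bulks matrix of realized pooled allele frequencies (the
#'   plant-sampling truth, before sequencing noise).
#' @export
simulate_bulk_genotypes <- function(freqs, config = freqs$config) {
  stopifnot(inherits(freqs, "variety_freqs"),
            inherits(config, "simulation_config"))
  if (!nrow(freqs$freq)) stop("empty frequency table")
  if (ncol(freqs$freq) != config$n_varieties ||
      nrow(freqs$freq) != config$n_loci) {
    stop("frequency table inconsistent with config")
  }
  L <- config$n_loci
  B <- config$n_bulks_per_variety
  n_bulks <- config$n_varieties * B
  n2 <- 2L * config$n_plants_per_bulk
  p_bulk <- freqs$freq[, rep(seq_len(config$n_varieties), each = B),
                       drop = FALSE]
  ncell <- L * n_bulks

  with_seed(stream_seed(config$seed, "genotypes"), {
    alt_copies <- stats::rbinom(ncell, size = n2, prob = as.vector(p_bulk))
    pool <- alt_copies / n2
    depth <- stats::rpois(ncell, config$mean_depth)
    alt_reads <- stats::rbinom(ncell, size = depth, prob = pool)
  })
  frac <- ifelse(depth > 0L, alt_reads / depth, NA_real_)
  dosage <- ifelse(frac < config$het_call_band[1], 0L,
                   ifelse(frac > config$het_call_band[2], 2L, 1L))
  dosage[depth < config$min_depth_call] <- NA_integer_
  with_seed(stream_seed(config$seed, "missingness"), {
    dosage[stats::runif(ncell) < config$missing_rate] <- NA_integer_
  })

  bulks <- sim_bulk_names(config)
  dosage <- matrix(dosage, nrow = L, ncol = n_bulks,
                   dimnames = list(freqs$loci$id, bulks))
  out <- genotype_matrix(t(dosage), freqs$loci)
  attr(out, "pool_freq") <- matrix(pool, nrow = L, ncol = n_bulks,
                                   dimnames = list(freqs$loci$id, bulks))
  out
}

#' Simulate a complete bulked-variety SNP dataset
#'
#' Runs [simulate_variety_frequencies()] and [simulate_bulk_genotypes()]
#' and assembles the sample map and the ground-truth table used by
#' parameter-recovery tests.
#'
#' @param config A [simulation_config()].
#' @return A list of class `bulk_sim`: `genotypes` (a
#'   [genotype_matrix()]), `map` (a [sample_map()]), `freqs` (the
#'   `variety_freqs`), `truth` (data frame with per-locus ancestral and
#'   per-variety frequencies plus realized per-bulk pool frequencies),
#'   and `config`.
#' @examples
#' sim <- simulate_bulk_dataset(simulation_config(n_loci = 200, seed = 42))
#' sim$genotypes
#' @export
simulate_bulk_dataset <- function(config = simulation_config()) {
  freqs <- simulate_variety_frequencies(config)
  geno <- simulate_bulk_genotypes(freqs, config)
  map <- sample_map(rownames(geno$dosage),
                    rep(sim_variety_names(config),
                        each = config$n_bulks_per_variety))
  pool <- attr(geno, "pool_freq")
  truth <- data.frame(locus_id = freqs$loci$id,
                      ancestral_freq = freqs$ancestral,
                      stringsAsFactors = FALSE)
  fcols <- as.data.frame(freqs$freq)
  names(fcols) <- paste0("freq_", colnames(freqs$freq))
  pcols <- as.data.frame(pool)
  names(pcols) <- paste0("pool_", colnames(pool))
  truth <- cbind(truth, fcols, pcols)
  rownames(truth) <- NULL
  structure(list(genotypes = geno, map = map, freqs = freqs,
                 truth = truth, config = config),
            class = "bulk_sim")
}

#' @export
print.bulk_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("bulk_sim: %d varieties x %d bulks x %d plants, ",
                     "%d loci (fst_target = %.3f, seed = %d)\n"),
              cfg$n_varieties, cfg$n_bulks_per_variety,
              cfg$n_plants_per_bulk, cfg$n_loci, cfg$fst_target, cfg$seed))
  invisible(x)
}

#' Write / read the simulation ground-truth table
#'
#' The truth table (per-locus ancestral frequency, per-variety population
#' frequencies, realized per-bulk pool frequencies) round-trips losslessly
#' through a plain tab-separated file.
#'
#' @param truth Data frame as produced in [simulate_bulk_dataset()]'s
#'   `truth` element; must be nonempty.
#' @param path File path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns
#'   the data frame.
#' @export
write_truth <- function(truth, path) {
  truth <- as.data.frame(truth)
  if (!nrow(truth)) stop("truth table is empty")
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
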