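write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

mini_header <- function(samples, fmt_gq = FALSE) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (fmt_gq)
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
}

test_that("GT codes map to dosages and phased separators are equivalent", {
  path <- write_mini_vcf(c(
    mini_header(c("b1", "b2")),
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t1/1",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT\t0|1\t1|0",
    "1\t300\t.\tG\tA\t.\t.\t.\tGT\t./.\t1/1"))
  m <- read_vcf(path)
  expect_identical(unname(m$dosage[, 1]), c(0L, 2L))
  expect_identical(unname(m$dosage[, 2]), c(1L, 1L))
  expect_identical(unname(m$dosage[, 3]), c(NA_integer_, 2L))
  expect_identical(attr(m, "skipped"), 0L)
})

test_that("multi-allelic and non-SNP records are skipped and counted", {
  path <- write_mini_vcf(c(
    mini_header(c("b1", "b2")),
    "1\t100\t.\tA\tG,T\t.\t.\t.\tGT\t0/1\t0/0",
    "1\t200\t.\tAT\tA\t.\t.\t.\tGT\t0/1\t0/0",
    "1\t300\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0"))
  m <- suppressMessages(read_vcf(path))
  expect_identical(ncol(m$dosage), 1L)
  expect_identical(attr(m, "skipped"), 2L)
})

test_that("a mapped sample absent from the VCF is reported by name", {
  path <- write_mini_vcf(c(
    mini_header(c("b1", "b2")),
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t1/1"))
  map <- sample_map(c("b1", "bX"), c("v1", "v2"))
  expect_error(read_vcf(path, map), "bX")
})

test_that("GQ below threshold masks individual calls to missing", {
  path <- write_mini_vcf(c(
    mini_header(c("b1", "b2"), fmt_gq = TRUE),
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:GQ\t0/1:19\t1/1:45",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT:GQ\t0/0:99\t0/1:20"))
  m <- read_vcf(path)
  expect_identical(unname(m$dosage[, 1]), c(NA_integer_, 2L))
  expect_identical(unname(m$dosage[, 2]), c(0L, 1L))
})

test_that("write then read is the identity on the dosage matrix", {
  sim <- simulate_bulk_dataset(simulation_config(n_loci = 500, seed = 21))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  back <- read_vcf(path, sim$map)
  expect_identical(back$dosage, sim$genotypes$dosage)
  expect_equal(back$loci[, c("chrom", "pos", "ref", "alt")],
               sim$genotypes$loci[, c("chrom", "pos", "ref", "alt")])
})

test_that("missing dosages are written as ./. and empty matrices as header-only", {
  m <- gm(matrix(c(0L, NA, 1L, 2L), nrow = 2))
  path <- tempfile(fileext = ".vcf")
  write_vcf(m, path)
  lines <- readLines(path)
  expect_match(lines[5], "\\./\\.")
  empty <- genotype_matrix(
    matrix(integer(0), nrow = 2, ncol = 0,
           dimnames = list(c("a", "b"), NULL)),
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0)))
  write_vcf(empty, path)
  expect_identical(sum(!startsWith(readLines(path), "#")), 0L)
})

test_that("site statistics match the direct copy-count definition", {
  m <- gm(matrix(c(0L, 1L, 2L, NA, NA, NA), nrow = 3))
  st <- site_stats(m)
  expect_equal(st$alt_freq, c(0.5, NA))
  expect_equal(st$call_rate, c(1, 0))
  # randomized matrix against the brute-force count
  set.seed(42)
  d <- matrix(sample(c(0:2, NA), 33 * 1000, replace = TRUE), nrow = 33)
  rownames(d) <- paste0("b", 1:33)
  st <- site_stats(gm(d))
  brute <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j][!is.na(d[, j])]
    if (!length(x)) NA_real_ else sum(x) / (2 * length(x))
  }, numeric(1))
  expect_equal(st$alt_freq, brute)
})

test_that("screens keep boundary values and drop below-threshold loci in order", {
  # 33 bulks; locus 1: MAF 0.04 (below), locus 2: MAF ~0.05 (kept),
  # locus 3: 2 missing calls -> call rate 31/33 < 0.95 (dropped)
  n <- 33
  d <- matrix(0L, nrow = n, ncol = 3)
  d[1:3, 1] <- c(1L, 1L, 1L)        # 3/66 = 0.0455 < 0.05
  d[1:4, 2] <- c(1L, 1L, 1L, 1L)    # 4/66 = 0.0606 >= 0.05
  d[1:6, 3] <- 1L
  d[7:8, 3] <- NA
  out <- apply_screens(gm(d))
  expect_identical(ncol(out$dosage), 1L)
  rep <- attr(out, "filter_report")
  expect_identical(rep$rule[1:2], c("maf", "integrity"))
  expect_identical(rep$removed[1:2], c(1L, 1L))
  # exact boundary: MAF exactly 0.05 is kept
  d2 <- matrix(0L, nrow = 10, ncol = 1)
  d2[1, 1] <- 1L  # 1/20 = 0.05
  expect_identical(ncol(apply_screens(gm(d2))$dosage), 1L)
})

test_that("screens are idempotent, order-preserving, and report sums balance", {
  sim <- simulate_bulk_dataset(simulation_config(n_loci = 1000, seed = 31))
  once <- apply_screens(sim$genotypes)
  rep1 <- attr(once, "filter_report")
  expect_identical(sum(rep1$removed),
                   ncol(sim$genotypes$dosage) - ncol(once$dosage))
  kept_ids <- once$loci$id
  orig_ids <- sim$genotypes$loci$id
  expect_identical(kept_ids, orig_ids[orig_ids %in% kept_ids])
  twice <- apply_screens(once)
  expect_identical(sum(attr(twice, "filter_report")$removed), 0L)
  expect_identical(twice$dosage, once$dosage)
})

test_that("hard filters use the QD/FS/MQ annotations when present", {
  d <- matrix(rep(c(0L, 1L, 2L), 4), nrow = 3, ncol = 4)
  info <- data.frame(qd = c(1.9, 2.0, 5, 5),
                     fs = c(0, 0, 61, 10),
                     mq = c(50, 50, 50, 39.9))
  out <- apply_screens(gm(d), info = info)
  expect_identical(ncol(out$dosage), 1L)
  rep <- attr(out, "filter_report")
  expect_identical(rep$removed[rep$rule %in% c("qd", "fs", "mq")],
                   c(1L, 1L, 1L))
})
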