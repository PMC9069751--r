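test_that("squared distances follow the shared-loci mean definition", {
  m <- gm(matrix(c(0L, 2L, 0L, 2L), nrow = 2))
  d2 <- pairwise_sq_distance(m)
  expect_equal(d2[1, 2], 4)
  expect_equal(diag(d2), c(s1 = 0, s2 = 0))
  m2 <- gm(matrix(c(1L, 1L, 2L, 2L), nrow = 2))
  expect_equal(pairwise_sq_distance(m2)[1, 2], 0)
  # 6 x 50 with missing calls vs brute-force loop
  set.seed(8)
  d <- matrix(sample(c(0:2, NA), 6 * 50, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 6)
  rownames(d) <- paste0("b", 1:6)
  expect_equal(pairwise_sq_distance(gm(d)), oracle_d2(d))
})

test_that("the two-variety fixed-difference design partitions exactly", {
  m <- gm(matrix(c(0L, 0L, 2L, 2L), nrow = 4), paste0("b", 1:4))
  map <- sample_map(paste0("b", 1:4), c("A", "A", "B", "B"))
  res <- amova(m, map)
  expect_equal(res$ss_total, 4)
  expect_equal(res$ss_among, 4)
  expect_equal(res$ss_within, 0)
  expect_equal(res$phi_st, 1)
  expect_identical(res$df_among, 1L)
  expect_identical(res$df_within, 2L)
})

test_that("an all-identical dataset is the degenerate zero-information case", {
  m <- gm(matrix(1L, nrow = 4, ncol = 5), paste0("b", 1:4))
  map <- sample_map(paste0("b", 1:4), c("A", "A", "B", "B"))
  res <- amova(m, map)
  expect_equal(res$ss_total, 0)
  expect_equal(res$phi_st, 0)
  expect_equal(res$p_value, 1)
})

test_that("printed variance components yield the published percentages and PhiST", {
  am <- read_published("ryegrass_amova.tsv")
  s <- variance_component_summary(am$vc[1], am$vc[2])
  expect_equal(s$pct_among, 37.27, tolerance = 0.01 / 37.27)
  expect_equal(s$phi_st, 0.373, tolerance = 0.001)
  expect_equal(am$ss[1] / am$df[1], am$ms[1], tolerance = 1e-4)
  expect_equal(am$ss[1] + am$ss[2], am$ss[3], tolerance = 1e-9)
})

test_that("df bookkeeping and SS additivity hold on the 11x3 design", {
  sim <- simulate_bulk_dataset(simulation_config(n_loci = 500, seed = 17))
  res <- amova(sim$genotypes, sim$map, n_perm = 19, seed = 1)
  expect_identical(c(res$df_among, res$df_within, res$df_total),
                   c(10L, 22L, 32L))
  expect_equal(res$ss_among + res$ss_within, res$ss_total)
  expect_equal(res$ms_among, res$ss_among / 10)
  expect_equal(res$ms_within, res$ss_within / 22)
  expect_equal(res$pct_among + res$pct_within, 100)
  expect_equal(res$phi_st, res$vc_among / (res$vc_among + res$vc_within))
})

test_that("exhaustive permutation P matches independent enumeration", {
  set.seed(5)
  for (rep in 1:3) {
    d <- matrix(sample(0:2, 6 * 40, replace = TRUE), nrow = 6)
    rownames(d) <- paste0("b", 1:6)
    map <- sample_map(paste0("b", 1:6), rep(c("A", "B"), each = 3))
    res <- amova(gm(d), map, method = "exhaustive")
    d2 <- oracle_d2(d)
    expect_equal(res$p_value,
                 oracle_exact_p(d2, rep(c("A", "B"), each = 3)))
    expect_equal(res$phi_st,
                 oracle_amova(d2, rep(c("A", "B"), each = 3))$phi)
  }
  # 8 samples, unequal groups
  d <- matrix(sample(0:2, 8 * 30, replace = TRUE), nrow = 8)
  rownames(d) <- paste0("b", 1:8)
  map <- sample_map(paste0("b", 1:8),
                    c("A", "A", "A", "A", "A", "B", "B", "B"))
  res <- amova(gm(d), map, method = "exhaustive")
  expect_equal(res$p_value,
               oracle_exact_p(oracle_d2(d), map$variety))
})

test_that("sampled permutation P approaches the exact value and is seed-stable", {
  set.seed(3)
  d <- matrix(sample(0:2, 6 * 60, replace = TRUE, prob = c(2, 1, 2)),
              nrow = 6)
  d[1:3, 1:20] <- 0L  # plant modest structure
  rownames(d) <- paste0("b", 1:6)
  map <- sample_map(paste0("b", 1:6), rep(c("A", "B"), each = 3))
  exact <- amova(gm(d), map, method = "exhaustive")$p_value
  sampled <- amova(gm(d), map, method = "sampled", n_perm = 4999,
                   seed = 2)$p_value
  expect_equal(sampled, exact, tolerance = 0.08 / exact)
  again <- amova(gm(d), map, method = "sampled", n_perm = 4999,
                 seed = 2)$p_value
  expect_identical(sampled, again)
})

test_that("permutation results are invariant to sample order", {
  sim <- simulate_bulk_dataset(
    simulation_config(n_varieties = 3, n_loci = 300, seed = 23))
  m <- sim$genotypes
  perm <- rev(seq_len(nrow(m$dosage)))
  shuffled <- subset_genotypes(m, samples = perm)
  a <- amova(m, sim$map, n_perm = 99, seed = 4)
  b <- amova(shuffled, sim$map, n_perm = 99, seed = 4)
  expect_equal(a$phi_st, b$phi_st)
  expect_equal(a$ss_within, b$ss_within)
})

test_that("pairwise PhiST separates fixed varieties and not identical ones", {
  # identical varieties: same frequency vector, bulks split by seed
  cfg <- simulation_config(n_varieties = 2, n_loci = 800,
                           fst_target = 1e-6, seed = 6)
  sim <- simulate_bulk_dataset(cfg)
  fst <- pairwise_fst(sim$genotypes, sim$map)
  expect_lt(abs(fst$phi[1, 2]), 0.08)
  expect_gt(fst$p_value[1, 2], 0.05)
  # opposite fixation
  m <- gm(rbind(matrix(0L, 3, 50), matrix(2L, 3, 50)), paste0("b", 1:6))
  map <- sample_map(paste0("b", 1:6), rep(c("A", "B"), each = 3))
  fst2 <- pairwise_fst(m, map)
  expect_equal(fst2$phi[1, 2], 1)
  expect_equal(fst2$phi, t(fst2$phi))
  expect_equal(diag(fst2$phi), c(A = 0, B = 0))
})

test_that("matrix extremes match an exhaustive scan and the published table", {
  fst <- read_published("ryegrass_pairwise_fst.tsv")
  m <- as.matrix(fst[, -1])
  rownames(m) <- fst$variety
  ext <- fst_extremes(m)
  expect_equal(ext$min_value, 0.1069)
  expect_identical(ext$min_pair, c("TG", "YC"))
  # the table's true maximum (the accompanying text claims 0.2480
  # between AGS and CJT, but the matrix itself prints a larger entry)
  expect_equal(ext$max_value, 0.2519)
  expect_identical(ext$max_pair, c("CJT", "JT"))
  # random symmetric matrix vs brute-force scan
  set.seed(1)
  r <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  r[upper.tri(r)] <- runif(10)
  r <- r + t(r)
  ext <- fst_extremes(r)
  off <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[upper.tri(r)]
  expect_equal(ext$min_value, min(vals))
  expect_equal(ext$max_value, max(vals))
  # 2x2: min equals max
  s <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  e2 <- fst_extremes(s)
  expect_equal(e2$min_value, e2$max_value)
})

test_that("the sums of squares agree with an independent PERMANOVA implementation", {
  sim <- simulate_bulk_dataset(simulation_config(n_loci = 400, seed = 2))
  d2 <- pairwise_sq_distance(sim$genotypes)
  res <- amova(d2, sim$map, n_perm = 19, seed = 1)
  df <- data.frame(
    variety = sim$map$variety[match(rownames(d2), sim$map$sample)])
  ad <- vegan::adonis2(stats::as.dist(sqrt(d2)) ~ variety, data = df,
                       permutations = 19)
  expect_equal(ad$SumOfSqs, c(res$ss_among, res$ss_within, res$ss_total))
})
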