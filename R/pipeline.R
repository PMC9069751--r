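#' Configuration for a full pipeline run
#'
#' Bundles the inputs and knobs of one reproducible end-to-end analysis:
#' either a VCF + sample map pair or a [simulation_config()] as the data
#' source, the site screens, permutation and bootstrap counts, panel
#' sizes, the master seed and the output directory. Paths are validated
#' here, before any stage runs.
#'
#' @param out_dir Output directory (created if absent).
#' @param vcf,map Input VCF path and sample map (a [sample_map()] or path
#'   to a two-column TSV); mutually exclusive with `sim`.
#' @param sim A [simulation_config()] used to generate the input dataset.
#' @param filter A [locus_filter_config()].
#' @param n_perm Permutations for the overall and pairwise AMOVA.
#' @param panel_sizes,panel_reps Subsampling-curve panel sizes and
#'   replicates per size.
#' @param n_boot Bootstrap replicates for tree supports.
#' @param seed Master seed recorded in every output header.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, vcf = NULL, map = NULL, sim = NULL,
                       filter = locus_filter_config(), n_perm = 999,
                       panel_sizes = c(10, 20, 50, 80, 100, 500, 1000),
                       panel_reps = 100, n_boot = 100, seed = 1L) {
  if (is.null(sim)) {
    if (is.null(vcf) || is.null(map)) {
      stop("supply either `sim` or both `vcf` and `map`")
    }
    if (!file.exists(vcf)) stop("VCF not found: ", vcf)
    if (is.character(map)) {
      if (!file.exists(map)) stop("sample map not found: ", map)
      map <- read_sample_map(map)
    }
    stopifnot(inherits(map, "sample_map"))
  } else {
    stopifnot(inherits(sim, "simulation_config"))
  }
  stopifnot(inherits(filter, "locus_filter_config"))
  structure(list(out_dir = out_dir, vcf = vcf, map = map, sim = sim,
                 filter = filter, n_perm = n_perm,
                 panel_sizes = panel_sizes, panel_reps = panel_reps,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "run_config")
}

write_stage_tsv <- function(df, path, stage, seed) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# bulkpop %s stage=%s seed=%d",
                     as.character(utils::packageVersion("bulkpop")),
                     stage, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full bulked-variety analysis pipeline
#'
#' Executes, in order: data input (simulation or VCF), site screening,
#' diversity indices, overall AMOVA and pairwise PhiST, marker-panel
#' subsampling, and relatedness summaries (kinship, bootstrapped NJ tree,
#' PCA). Each stage writes a plain-text output (TSV / Newick) with a
#' provenance header carrying the package version and seed; a failure
#' aborts with the stage name. Re-running an identical configuration
#' reproduces identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list of class `bulkpop_run` with the in-memory
#'   results (`genotypes`, `map`, `diversity`, `pi`, `amova`, `fst`,
#'   `curve`, `recommended_size`, `kinship`, `tree`, `pca`) and `files`,
#'   the named vector of paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (!quiet) message("bulkpop: ", ...)
  files <- c()
  out <- function(name) file.path(config$out_dir, name)

  say("stage input")
  inp <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_bulk_dataset(config$sim)
      write_vcf(sim$genotypes, out("input.vcf"))
      write_truth(sim$truth, out("truth.tsv"))
      utils::write.table(sim$map, out("sample_map.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files[c("vcf", "truth", "map")] <-
        c(out("input.vcf"), out("truth.tsv"), out("sample_map.tsv"))
      list(geno = sim$genotypes, map = sim$map)
    } else {
      list(geno = read_vcf(config$vcf, config$map), map = config$map)
    }
  })

  say("stage filter")
  geno <- run_stage("filter", {
    g <- apply_screens(inp$geno, config$filter)
    files["filter_report"] <- write_stage_tsv(
      attr(g, "filter_report"), out("filter_report.tsv"), "filter", seed)
    g
  })

  say("stage diversity")
  div <- run_stage("diversity", {
    d <- variety_diversity(geno, inp$map)
    d <- rbind(d, summarize_means(d))
    pi <- nucleotide_pi(geno, inp$map)
    files["diversity"] <- write_stage_tsv(d, out("diversity.tsv"),
                                           "diversity", seed)
    files["pi"] <- write_stage_tsv(pi, out("pi.tsv"), "diversity", seed)
    list(table = d, pi = pi)
  })

  say("stage amova")
  am <- run_stage("amova", {
    d2 <- pairwise_sq_distance(geno)
    ov <- amova(d2, inp$map, n_perm = config$n_perm,
                seed = stream_seed(seed, "permutations"))
    fst <- pairwise_fst(d2, inp$map, n_perm = config$n_perm,
                        seed = stream_seed(seed, "permutations"))
    tab <- data.frame(
      source = c("Among varieties", "Within varieties", "Total"),
      df = c(ov$df_among, ov$df_within, ov$df_total),
      ss = c(ov$ss_among, ov$ss_within, ov$ss_total),
      ms = c(ov$ms_among, ov$ms_within, NA),
      vc = c(ov$vc_among, ov$vc_within, NA),
      pct = c(ov$pct_among, ov$pct_within, NA))
    files["amova"] <- write_stage_tsv(tab, out("amova.tsv"), "amova",
                                       seed)
    files["fst"] <- write_stage_tsv(
      data.frame(variety = rownames(fst$phi), fst$phi,
                 check.names = FALSE),
      out("pairwise_fst.tsv"), "amova", seed)
    files["fst_p"] <- write_stage_tsv(
      data.frame(variety = rownames(fst$p_value), fst$p_value,
                 check.names = FALSE),
      out("pairwise_fst_p.tsv"), "amova", seed)
    nm <- gene_flow_nm(fst)
    files["nm"] <- write_stage_tsv(
      data.frame(variety = rownames(nm), nm, check.names = FALSE),
      out("gene_flow_nm.tsv"), "amova", seed)
    list(overall = ov, fst = fst, d2 = d2)
  })

  say("stage panel")
  panel <- run_stage("panel", {
    pair <- select_focal_pair(am$fst)
    sizes <- config$panel_sizes[config$panel_sizes <=
                                  ncol(geno$dosage)]
    if (!length(sizes)) stop("no panel size fits the ",
                             ncol(geno$dosage), " screened loci")
    if (length(sizes) < length(config$panel_sizes)) {
      say("dropping panel sizes larger than the ", ncol(geno$dosage),
          " screened loci")
    }
    curve <- subsampling_curve(geno, inp$map, pair,
                               sizes = sizes,
                               n_reps = config$panel_reps, seed = seed)
    rec <- suppressWarnings(recommend_panel_size(curve))
    files["curve"] <- write_stage_tsv(curve, out("panel_curve.tsv"),
                                       "panel", seed)
    list(pair = pair, curve = curve, recommended = rec)
  })

  say("stage relatedness")
  rel <- run_stage("relatedness", {
    k <- vanraden_kinship(geno)
    tree <- bootstrap_supports(geno, n_boot = config$n_boot, seed = seed)
    pca <- pca_scores(geno, 2L)
    files["kinship"] <- write_stage_tsv(
      data.frame(sample = rownames(k), k, check.names = FALSE),
      out("kinship.tsv"), "relatedness", seed)
    files["tree"] <- out("nj_tree.nwk")
    ape::write.tree(tree, files[["tree"]])
    files["pca"] <- write_stage_tsv(
      data.frame(sample = rownames(pca$scores), pca$scores,
                 check.names = FALSE),
      out("pca_scores.tsv"), "relatedness", seed)
    list(kinship = k, tree = tree, pca = pca)
  })

  say("done")
  invisible(structure(list(genotypes = geno, map = inp$map,
                           diversity = div$table, pi = div$pi,
                           amova = am$overall, fst = am$fst,
                           focal_pair = panel$pair, curve = panel$curve,
                           recommended_size = panel$recommended,
                           kinship = rel$kinship, tree = rel$tree,
                           pca = rel$pca, files = files,
                           config = config),
                      class = "bulkpop_run"))
}

#' @export
print.bulkpop_run <- function(x, ...) {
  cat("bulkpop pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  loci after screening:", ncol(x$genotypes$dosage), "\n")
  cat(sprintf("  overall PhiST = %.4f (P = %.4g)\n",
              x$amova$phi_st, x$amova$p_value))
  cat("  focal pair:", paste(x$focal_pair, collapse = " vs "),
      "| recommended panel size:", x$recommended_size, "\n")
  cat("  outputs in:", x$config$out_dir, "\n")
  invisible(x)
}
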