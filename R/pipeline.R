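#' Run the full simulate -> coverage -> compare -> stratify pipeline
#'
#' End-to-end driver reproducing the analysis structure of a DPC-seq study
#' on a simulated dataset: per-gene normalized coverage, metagene profiles
#' before and after recovery, transcription-dependent calls (flavopiridol vs
#' untreated at 6 h), CSB-dependent calls (CSB knockout vs WT at 6 h), paired
#' Wilcoxon group tests across occupancy groups and across dependence
#' classes, quadrant summaries against a size-matched control, and
#' feature enrichment. All stages are pure functions of (config, seed);
#' rerunning with the same seed reproduces every table byte for byte.
#'
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional output directory; when given, all tables are
#'   written as TSV together with a JSON run manifest.
#' @param alpha Significance level for dependent-gene calls.
#' @param min_coverage Minimum-coverage filter for testing.
#' @param pseudocount Pseudocount for fold changes and log t-tests.
#' @return Invisibly, a list with `samplesheet`, `matrix`, `calls_td`,
#'   `calls_csb`, `group_tests_occupancy`, `group_tests_dependence`,
#'   `quadrants`, `quadrant_summary`, `enrichment`, `metagene`, `truth`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(), seed = 1L,
                         out_dir = NULL, alpha = 0.05, min_coverage = 0.1,
                         pseudocount = 0.01) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  sim <- stage("simulate", simulate_dpcseq(config, seed))
  ss <- sim$samplesheet
  ids <- function(genotype, drug, recovery_h) {
    ss$sample_id[ss$genotype == genotype & ss$drug == drug &
                   ss$recovery_h == recovery_h]
  }

  mat <- stage("coverage", coverage_matrix(sim$fragments, sim$genes))

  calls_td <- stage("compare", compare_coverage(
    mat, ids("WT", "flavopiridol", 6), ids("WT", "none", 6),
    alpha = alpha, pseudocount = pseudocount, min_coverage = min_coverage))
  calls_csb <- stage("compare", compare_coverage(
    mat, ids("CSB_KO", "none", 6), ids("WT", "none", 6),
    alpha = alpha, pseudocount = pseudocount, min_coverage = min_coverage))

  # 6 h / 0 h per-gene recovery fold changes under the different conditions
  l2fc_wt <- log2_fold_change(mat, ids("WT", "none", 6), ids("WT", "none", 0),
                              pseudocount)
  l2fc_flavo <- log2_fold_change(mat, ids("WT", "flavopiridol", 6),
                                 ids("WT", "none", 0), pseudocount)
  l2fc_csb <- log2_fold_change(mat, ids("CSB_KO", "none", 6),
                               ids("CSB_KO", "none", 0), pseudocount)

  occ_groups <- stage("stratify", quantile_groups(
    sim$covariates$occupancy, 4L, ids = sim$covariates$gene_id))
  gt_occ <- stage("stratify", group_recovery_test(
    l2fc_flavo, l2fc_wt, occ_groups$group))

  dep_class <- factor(ifelse(calls_td$call == "dependent",
                             "transcription_dependent", "no_change"),
                      levels = c("no_change", "transcription_dependent"))
  gt_dep <- stage("stratify", group_recovery_test(l2fc_csb, l2fc_wt,
                                                  dep_class))

  quadrants <- stage("stratify", quadrant_assign(sim$covariates))
  td_genes <- calls_td$gene_id[calls_td$call == "dependent"]
  nc_genes <- calls_td$gene_id[calls_td$call == "non_changing"]
  quadrant_summary <- NULL
  if (length(td_genes) > 0L && length(nc_genes) >= length(td_genes)) {
    control <- match_size_control(td_genes, nc_genes, derive_seed(seed, 77L))
    qp_td <- quadrant_percentages(td_genes, quadrants)
    qp_ctrl <- quadrant_percentages(control, quadrants)
    qp_td$gene_set <- "transcription_dependent"
    qp_ctrl$gene_set <- "matched_control"
    quadrant_summary <- rbind(qp_td, qp_ctrl)
  }

  csb_genes <- calls_csb$gene_id[calls_csb$call == "dependent"]
  csb_nc <- calls_csb$gene_id[calls_csb$call == "non_changing"]
  enrichment <- NULL
  if (length(csb_genes) > 0L && length(csb_nc) > 0L) {
    enrichment <- stage("stratify", feature_enrichment(
      csb_genes, csb_nc, sim$genes, sim$covariates))
  }

  pool_fragments <- function(sample_ids) {
    fragment_set(do.call(rbind, lapply(sim$fragments[sample_ids],
                                       function(f) f$fragments)))
  }
  mg0 <- stage("metagene", metagene_profile(pool_fragments(ids("WT", "none", 0)),
                                            sim$genes))
  mg6 <- stage("metagene", metagene_profile(pool_fragments(ids("WT", "none", 6)),
                                            sim$genes))
  metagene <- data.frame(bin = mg0$bin_labels, rpm_0h = mg0$values,
                         rpm_6h = mg6$values, stringsAsFactors = FALSE)

  out <- list(samplesheet = ss, matrix = mat, calls_td = calls_td,
              calls_csb = calls_csb, group_tests_occupancy = gt_occ,
              group_tests_dependence = gt_dep, quadrants = quadrants,
              quadrant_summary = quadrant_summary, enrichment = enrichment,
              metagene = metagene, truth = sim$truth,
              covariates = sim$covariates, genes = sim$genes)

  if (!is.null(out_dir)) {
    out$manifest <- write_pipeline_outputs(out, config, seed, out_dir)
  }
  invisible(out)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_pipeline_outputs <- function(out, config, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- c(
    write_tsv(out$genes, p("genes.tsv")),
    write_tsv(out$covariates, p("covariates.tsv")),
    write_tsv(out$samplesheet, p("samplesheet.tsv")),
    write_tsv(out$truth, p("truth.tsv")),
    {
      write_coverage_matrix(out$matrix, p("matrix.tsv"))
      p("matrix.tsv")
    },
    write_tsv(out$calls_td, p("calls_transcription_dependent.tsv")),
    write_tsv(out$calls_csb, p("calls_csb_dependent.tsv")),
    write_tsv(out$group_tests_occupancy, p("group_tests_occupancy.tsv")),
    write_tsv(out$group_tests_dependence, p("group_tests_dependence.tsv")),
    write_tsv(out$metagene, p("metagene.tsv"))
  )
  if (!is.null(out$quadrant_summary)) {
    files <- c(files, write_tsv(out$quadrant_summary, p("quadrants.tsv")))
  }
  if (!is.null(out$enrichment)) {
    files <- c(files, write_tsv(out$enrichment, p("enrichment.tsv")))
  }
  cfg_json <- p("config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, cfg_json)
  manifest <- list(
    package = "dpcseq",
    version = as.character(packageVersion("dpcseq")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  manifest
}
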