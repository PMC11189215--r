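## End-to-end orchestration: genotype QC -> expression preparation -> cis /
## trans scans (+ permutations) -> stricter-of-two thresholds -> trio
## integration -> clumping / tiers -> mediation -> optional per-index-SNV
## differential expression + TE-family GSEA -> optional trait-category
## enrichment.

#' Analysis parameters for a pipeline run
#'
#' Defaults equal the reference analysis values: alpha 0.05, MAF >= 1\%, HWE
#' p >= 1e-6, CPM rule "more than the CPM of 10 reads in the median library
#' in >= 90\% of samples", 1 Mb cis window, 500 kb / r^2 > 0.1 clumping,
#' 5 kb L1 flank, 20 scan permutations. Mediation permutations default to
#' 1,000 here for interactive turnaround; the reference analysis used
#' 30,000.
#'
#' @param alpha significance level for every FDR gate
#' @param maf_min,hwe_p_min variant QC thresholds
#' @param cpm_reads reads in the median library defining the CPM cutoff
#' @param expr_min_fraction fraction of samples that must exceed the cutoff
#' @param cis_window_bp cis scan window
#' @param clump_window_bp,clump_r2 LD clumping parameters
#' @param prune_window,prune_step,prune_r2 LD pruning parameters
#' @param n_pcs genotype PCs used as covariates
#' @param n_perm_scan permutation rounds for the empirical FDR
#' @param n_perm_mediation permutations per mediation trio
#' @param n_hidden_factors extra PCA hidden factors to residualize (0 = off)
#' @param run_enrichment run per-index-SNV differential expression + TE
#'   family GSEA?
#' @param gsea_n_perm GSEA permutations
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(alpha = 0.05, maf_min = 0.01, hwe_p_min = 1e-6,
                            cpm_reads = 10, expr_min_fraction = 0.9,
                            cis_window_bp = 1e6, clump_window_bp = 5e5,
                            clump_r2 = 0.1, prune_window = 50,
                            prune_step = 10, prune_r2 = 0.1, n_pcs = 2,
                            n_perm_scan = 20, n_perm_mediation = 1000,
                            n_hidden_factors = 0, run_enrichment = FALSE,
                            gsea_n_perm = 500) {
  stopifnot(alpha > 0, alpha < 1, maf_min >= 0, maf_min <= 0.5,
            n_perm_scan >= 1, n_perm_mediation >= 100)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full regulator scan on a cohort
#'
#' Executes every stage of the in-silico scan for candidate TE regulators on
#' an in-memory cohort (e.g. from \code{\link{simulate_cohort}} or assembled
#' from the readers in this package) and returns all intermediate and final
#' tables plus a run report. When \code{out_dir} is given, the stage outputs
#' are written as TSV/JSON.
#'
#' @param cohort list with \code{genotypes}, \code{svs}, \code{counts},
#'   \code{covariates} (lab/population/sex), \code{genes}, \code{te};
#'   optionally \code{trait_map}
#' @param config \code{\link{pipeline_config}}
#' @param seed integer seed for every stochastic stage
#' @param out_dir optional output directory
#' @return list of class \code{teqtl_run}: \code{genotypes} (QC'd),
#'   \code{pcs}, \code{expression} (inverse normal), \code{cis},
#'   \code{trans}, \code{thresholds}, \code{trios}, \code{orphans},
#'   \code{clumps}, \code{mediation}, optional \code{enrichment} and
#'   \code{phewas}, and \code{report}
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  g <- .stage("variant_qc",
              qc_filter_variants(cohort$genotypes, config$maf_min,
                                 config$hwe_p_min))
  pruned <- .stage("ld_pruning",
                   prune_ld(g, config$prune_window, config$prune_step,
                            config$prune_r2))
  pcs <- .stage("genotype_pca", genotype_pca(pruned, config$n_pcs))
  cn <- .stage("net_copy_number", net_te_copy_number(cohort$svs))

  prep <- .stage("expression_prep", {
    cm <- cohort$counts
    is_locus <- cm$features$kind == "te_locus"
    lib <- cm$library_size
    subfam <- aggregate_te_counts(
      count_matrix(cm$counts[is_locus, , drop = FALSE], "te_locus", lib),
      cohort$te)
    genes_cm <- count_matrix(
      cm$counts[cm$features$kind == "gene", , drop = FALSE], "gene", lib)
    viral_row <- cm$counts[cm$features$kind == "viral", , drop = FALSE]
    cpm_min <- cpm_for_reads(config$cpm_reads, lib)
    genes_f <- filter_low_expression(genes_cm, cpm_min,
                                     config$expr_min_fraction)
    subfam_f <- filter_low_expression(subfam, cpm_min,
                                      config$expr_min_fraction)
    joint <- count_matrix(rbind(genes_f$counts, subfam_f$counts),
                          c(rep("gene", nrow(genes_f$counts)),
                            rep("te_subfamily", nrow(subfam_f$counts))), lib)
    cov <- data.frame(cohort$covariates, pcs,
                      net_te_cn = as.numeric(cn[samples(joint)]))
    if (nrow(viral_row) > 0)
      cov$viral_expr <- log2(as.vector(viral_row[1, ]) / (lib / 1e6) + 1)
    cov <- cov[, vapply(cov, function(x)
      length(unique(x)) > 1, logical(1)), drop = FALSE]
    e <- vst_transform(joint)
    e <- residualize_covariates(e, cov)
    if (config$n_hidden_factors > 0) {
      hf <- estimate_hidden_factors(e, config$n_hidden_factors)
      e <- residualize_covariates(e, hf)
    }
    list(e = inverse_normal_transform(e), cov = cov, cpm_min = cpm_min,
         counts_filtered = joint)
  })
  e_gene <- subset_kind(prep$e, "gene")
  e_te <- subset_kind(prep$e, "te_subfamily")

  cis <- .stage("cis_scan",
                cis_scan(g, e_gene, cohort$genes, config$cis_window_bp))
  tr <- .stage("trans_scan",
               trans_scan(g, e_te, n_perm = config$n_perm_scan,
                          seed = seed + 7L))
  thresholds <- .stage("thresholds", {
    ef <- empirical_fdr(tr$results$p, tr$perm_p)
    significance_threshold(bh_threshold_p(tr$results$p, config$alpha),
                           ef$threshold(config$alpha), config$alpha,
                           config$n_perm_scan)
  })
  integ <- .stage("trio_integration",
                  integrate_trios(cis, tr$results, prep$e,
                                  alpha = config$alpha,
                                  p_final = thresholds$p_final))
  trios <- integ$trios

  clumps <- NULL
  if (nrow(trios) > 0) {
    clumps <- .stage("clumping", {
      tr_sub <- tr$results[tr$results$snv_id %in% trios$snv_id, ]
      pmin_by_snv <- tapply(tr_sub$p, tr_sub$snv_id, min)
      clump_by_pvalue(stats::setNames(as.numeric(pmin_by_snv),
                                      names(pmin_by_snv)),
                      g, config$clump_window_bp, config$clump_r2)
    })
    trios <- .stage("tier_assignment", assign_tiers(trios, clumps))
  }
  mediation <- .stage("mediation",
                      mediate_trios(trios, g, prep$e,
                                    n_perm = config$n_perm_mediation,
                                    seed = seed + 11L,
                                    alpha = config$alpha))

  enrichment <- NULL
  if (config$run_enrichment && nrow(trios) > 0) {
    enrichment <- .stage("enrichment", {
      fam_sets <- build_te_family_sets(cohort$te)
      lapply(unique(trios$snv_id[trios$is_index_snv]), function(snv) {
        dge <- stratified_dge(prep$counts_filtered,
                              as.numeric(g$dosage[, snv]), prep$cov)
        ranked <- stats::setNames(dge$wald_stat, dge$feature_id)
        list(snv = snv, dge = dge,
             gsea = gsea_run(ranked, fam_sets, n_perm = config$gsea_n_perm,
                             seed = seed + 13L))
      })
    })
  }

  phewas <- NULL
  if (!is.null(cohort$trait_map) && nrow(trios) > 0) {
    phewas <- .stage("phewas",
                     category_enrichment(unique(trios$snv_id),
                                         cohort$trait_map,
                                         seed = seed + 17L))
  }

  report <- list(
    seed = seed,
    config = unclass(config),
    n_samples = nrow(g$dosage),
    n_variants_input = ncol(cohort$genotypes$dosage),
    n_variants_qc = ncol(g$dosage),
    n_variants_pruned = ncol(pruned$dosage),
    cpm_min = prep$cpm_min,
    n_genes_expressed = sum(prep$e$features$kind == "gene"),
    n_subfamilies_expressed = sum(prep$e$features$kind == "te_subfamily"),
    n_cis_tests = nrow(cis),
    n_cis_significant = sum(cis$fdr_bh < config$alpha),
    n_trans_tests = nrow(tr$results),
    n_trans_significant = sum(tr$results$fdr_bh < config$alpha &
                                tr$results$p <= thresholds$p_final),
    p_threshold_bh = thresholds$p_bh,
    p_threshold_empirical = thresholds$p_emp,
    p_threshold_final = thresholds$p_final,
    n_trios = nrow(trios),
    n_tier1_genes = if (nrow(trios)) length(unique(
      trios$gene_id[trios$gene_tier == 1L])) else 0L,
    n_orphan_snvs = length(unique(integ$orphans$snv_id)),
    n_mediation_significant = sum(mediation$significant),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(genotypes = g, pcs = pcs, expression = prep$e,
                        covariates = prep$cov, cis = cis, trans = tr,
                        thresholds = thresholds, trios = trios,
                        orphans = integ$orphans, clumps = clumps,
                        mediation = mediation, enrichment = enrichment,
                        phewas = phewas, report = report),
                   class = "teqtl_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.teqtl_run <- function(x, ...) {
  r <- x$report
  cat("teqtl pipeline run\n")
  cat(sprintf("  variants: %d -> %d after QC (%d pruned panel)\n",
              r$n_variants_input, r$n_variants_qc, r$n_variants_pruned))
  cat(sprintf("  cis tests: %d (%d significant) | trans tests: %d (%d significant)\n",
              r$n_cis_tests, r$n_cis_significant, r$n_trans_tests,
              r$n_trans_significant))
  cat(sprintf("  p thresholds: BH %.3g, empirical %.3g -> final %.3g\n",
              r$p_threshold_bh, r$p_threshold_empirical, r$p_threshold_final))
  cat(sprintf("  trios: %d (%d tier-1 gene(s)); orphan SNVs: %d; significant mediations: %d\n",
              r$n_trios, r$n_tier1_genes, r$n_orphan_snvs,
              r$n_mediation_significant))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the scan, trio, clump, orphan and mediation tables as TSV, the
#' permutation p-values one TSV per round, and the run report (with a config
#' hash) as JSON.
#'
#' @param run \code{teqtl_run} from \code{\link{run_pipeline}}
#' @param dir output directory
#' @return invisible vector of written paths
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "teqtl_run"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    .write_tsv(df, p)
    written <<- c(written, p)
  }
  put(run$cis, "cis_scan.tsv")
  put(run$trans$results, "trans_scan.tsv")
  for (b in seq_along(run$trans$perm_p))
    put(data.frame(p = run$trans$perm_p[[b]]),
        sprintf("trans_perm_%02d.tsv", b))
  put(run$trios, "trios.tsv")
  put(run$orphans, "orphan_snvs.tsv")
  if (!is.null(run$clumps)) put(run$clumps, "clumps.tsv")
  put(run$mediation, "mediation.tsv")
  if (!is.null(run$phewas)) put(run$phewas, "phewas.tsv")
  cfg_json <- jsonlite::toJSON(run$report$config, auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  report <- c(run$report, list(config_hash = unname(tools::md5sum(tf))))
  unlink(tf)
  rp <- file.path(dir, "report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), rp)
  invisible(c(written, rp))
}
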