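#' Pipeline configuration
#'
#' Bundles inputs and tuning for [run_pipeline()]. Each data input may be
#' given as an in-memory object (the types produced by the readers /
#' [generate_cohort()]) or as a file path in the corresponding TSV/VCF
#' dialect (genotype paths ending in `.vcf` are read as VCF).
#'
#' @param genotypes [genotype_matrix()] or path.
#' @param annotation annotation data frame or path.
#' @param gene_go gene-to-GO named list or path.
#' @param go_targets character vector of target GO accessions or path.
#' @param cohort cohort data frame or path.
#' @param event,threshold endpoint definition (default grade >= 2
#'   diarrhea).
#' @param screen a [screen_config()].
#' @param hwe_threshold,maf_threshold QC thresholds (defaults 0.2, 0.05).
#' @param model_specs list of character vectors of model terms for
#'   [compare_models()]; NULL (default) builds specs from the top SNP and
#'   the covariates with scan p < 0.1.
#' @param out_dir output directory for the report bundle.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, annotation, gene_go, go_targets,
                            cohort, event = "diarrhea", threshold = 2,
                            screen = screen_config(),
                            hwe_threshold = 0.2, maf_threshold = 0.05,
                            model_specs = NULL, out_dir = "kbscreen_out") {
  structure(list(genotypes = genotypes, annotation = annotation,
                 gene_go = gene_go, go_targets = go_targets,
                 cohort = cohort, event = event, threshold = threshold,
                 screen = screen, hwe_threshold = hwe_threshold,
                 maf_threshold = maf_threshold, model_specs = model_specs,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

.resolve_inputs <- function(pc) {
  g <- pc$genotypes
  if (is.character(g))
    g <- if (grepl("\\.vcf$", g)) read_genotypes_vcf(g)
         else read_genotypes_tsv(g)
  ann <- pc$annotation
  if (is.character(ann)) ann <- read_snp_annotation(ann)
  gg <- pc$gene_go
  if (is.character(gg)) gg <- read_gene_go_map(gg)
  tg <- pc$go_targets
  if (length(tg) == 1 && file.exists(tg)) tg <- read_go_term_list(tg)
  ch <- pc$cohort
  if (is.character(ch)) ch <- read_cohort_table(ch)
  list(genotypes = g, annotation = ann, gene_go = gg, go_targets = tg,
       cohort = ch)
}

#' Run the full screening pipeline
#'
#' Executes, in order: knowledge-based SNP selection, HWE/MAF quality
#' control, stage-1 screening on the monotherapy subset, stage-2 testing on
#' the full cohort, the min-p permutation correction, Benjamini-Hochberg
#' q-values over the full-dataset-only scan of all post-QC candidates,
#' covariate scans, and logistic model comparison around the top SNP.
#' Writes a deterministic report bundle (no timestamps) into
#' `config$out_dir` and logs the candidate-count funnel at every step.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every intermediate result (kb, qc,
#'   screen, null, association report, model comparison, covariate scans,
#'   funnel counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .stage("read_inputs", .resolve_inputs(config))
  cohort <- .stage("endpoint",
                   define_endpoint(inp$cohort, config$event,
                                   config$threshold))
  geno <- inp$genotypes
  missing_pat <- setdiff(cohort$patient_id, geno$patient_ids)
  if (length(missing_pat))
    stop("[read_inputs] cohort patients missing from genotypes: ",
         paste(utils::head(missing_pat, 5), collapse = ", "))

  funnel <- c(input = length(geno$snp_ids))
  kb <- .stage("kb_snp", select_snps_by_go(inp$annotation, inp$gene_go,
                                           inp$go_targets))
  funnel["kb_selected"] <- length(kb$selected_snp_ids)

  gsub_ <- geno$dosage[match(cohort$patient_id, geno$patient_ids),
                       intersect(geno$snp_ids, kb$selected_snp_ids),
                       drop = FALSE]
  gm <- genotype_matrix(gsub_, allele_labels = geno$allele_labels)
  qc <- .stage("qc_filters",
               qc_filter(gm, config$hwe_threshold, config$maf_threshold))
  candidates <- qc$pass
  funnel["qc_passed"] <- length(candidates)

  scr <- .stage("two_stage",
                run_two_stage(gm, cohort, candidates, config$screen))
  funnel["stage1_selected"] <- nrow(scr$stage2)
  null <- .stage("permutation",
                 permutation_null(gm, cohort, candidates, config$screen))

  # full-dataset-only scan of every candidate: p_F, then BH q and p_per
  setup <- .screen_setup(gm, cohort, candidates, config$screen)
  cache <- new.env(parent = emptyenv())
  p_full <- .stage("association",
                   .stage_p(setup, cohort$outcome, 2L, cache))
  names(p_full) <- candidates
  qv <- .stage("multiplicity", bh_qvalues(p_full))
  p_per <- .stage("permutation", adjusted_p(p_full, null))
  funnel["significant_p_per"] <- sum(p_per[candidates %in% scr$stage2$snp_id]
                                     < 0.05)

  ann <- inp$annotation
  am <- match(candidates, ann$snp_id)
  lab <- geno$allele_labels
  lm_ <- if (is.null(lab)) rep(NA_integer_, length(candidates))
         else match(candidates, lab$snp_id)
  qrec <- qc$records[match(candidates, qc$records$snp_id), ]
  s1m <- match(candidates, scr$stage1$snp_id)
  report <- data.frame(
    snp_id = candidates,
    allele = if (is.null(lab)) NA_character_
             else paste0(lab$minor[lm_], "/", lab$major[lm_]),
    maf = qrec$maf,
    location = ann$location_class[am],
    chromosome = ann$chromosome[am],
    position = ann$position[am],
    gene = vapply(ann$gene_symbols[am], paste, "", collapse = ","),
    p_stage1 = scr$stage1$p_stage1[s1m],
    p_F = as.numeric(p_full),
    q_BH = qv$q,
    p_per = p_per,
    stringsAsFactors = FALSE)
  report <- report[order(report$p_F, report$snp_id), ]

  scan1 <- .stage("covariate_scan", covariate_scan(cohort, "first"))
  scan2 <- .stage("covariate_scan", covariate_scan(cohort, "second"))

  # model comparison around the top SNP
  top <- report$snp_id[1]
  mdata <- cohort
  mdata[[top]] <- gm$dosage[, top]
  specs <- config$model_specs
  if (is.null(specs)) {
    sig_cov <- scan2$covariate[!is.na(scan2$p) & scan2$p < 0.1]
    specs <- c(list(character(0), top),
               lapply(sig_cov, identity),
               if (length(sig_cov)) list(c(top, sig_cov)))
  }
  comparison <- .stage("modeling",
                       suppressMessages(compare_models(specs, mdata)))
  best_terms <- strsplit(comparison$model[comparison$model != "NULL"][1],
                         "+", fixed = TRUE)[[1]]
  use <- stats::complete.cases(mdata[, c(best_terms, "outcome")])
  best_fit <- suppressWarnings(
    fit_logistic(mdata[use, best_terms, drop = FALSE],
                 mdata$outcome[use]))
  best_roc <- roc_auc(best_fit$fitted, mdata$outcome[use])

  # --- report bundle -------------------------------------------------
  wtsv <- function(df, f)
    utils::write.table(df, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(report, "association_report.tsv")
  s2 <- scr$stage2
  s2$p_per <- adjusted_p(s2$p_stage2, null)
  wtsv(s2, "screen_report.tsv")
  write_null_distribution(null, config$screen,
                          file.path(config$out_dir,
                                    "null_distribution.tsv"))
  write_qc_report(qc, file.path(config$out_dir, "qc_report.tsv"))
  write_kb_selection(kb, file.path(config$out_dir, "kb_selection.tsv"))
  wtsv(comparison, "model_comparison.tsv")
  wtsv(best_roc$curve, "roc_points.tsv")
  wtsv(scan1, "covariate_scan_first.tsv")
  wtsv(scan2, "covariate_scan_second.tsv")

  resolved <- list(event = config$event, threshold = config$threshold,
                   alpha1 = config$screen$alpha1,
                   model = config$screen$model,
                   n_perm = config$screen$n_perm,
                   seed = config$screen$seed,
                   stratified = config$screen$stratified,
                   hwe_threshold = config$hwe_threshold,
                   maf_threshold = config$maf_threshold)
  cfg_yaml <- yaml::as.yaml(resolved)
  tf <- tempfile(); writeLines(cfg_yaml, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  writeLines(cfg_yaml, file.path(config$out_dir, "resolved_config.yaml"))
  log_lines <- c(
    sprintf("config_md5: %s", cfg_hash),
    sprintf("seed: %d", config$screen$seed),
    sprintf("n_patients_analyzed: %d", nrow(cohort)),
    sprintf("n_monotherapy: %d", sum(cohort$monotherapy)),
    sprintf("n_events: %d", sum(cohort$outcome)),
    sprintf("funnel_%s: %d", names(funnel), funnel),
    sprintf("observed_min_p: %.17g", scr$observed_min_p),
    sprintf("top_snp: %s", top),
    sprintf("best_model: %s", comparison$model[1]))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))

  invisible(list(kb = kb, qc = qc, screen = scr, null = null,
                 association = report, qvalues = qv,
                 covariate_scan_first = scan1,
                 covariate_scan_second = scan2,
                 model_comparison = comparison, best_roc = best_roc,
                 funnel = funnel, cohort = cohort,
                 config_hash = cfg_hash))
}
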