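#' Synthetic cohort configuration
#'
#' Generative specification of a pharmacogenomic case-control cohort with
#' the structure the screening pipeline assumes: independent SNPs in
#' Hardy-Weinberg proportions, GO-annotated gene structure, a logistic
#' phenotype model with optional causal SNPs and covariate effects, and a
#' nested monotherapy subset. Defaults mirror the cohort the pipeline is
#' designed for: 168 patients of whom 53 on monotherapy, an event rate near
#' 36/168, and concomitant-drug covariates that are structurally zero in
#' the monotherapy subset.
#'
#' @param n_patients cohort size (default 168).
#' @param monotherapy_fraction fraction in the nested first dataset
#'   (default 53/168).
#' @param n_snps number of SNPs (default 350).
#' @param maf_range minor-allele-frequency range, drawn uniformly
#'   (default c(0.05, 0.5)).
#' @param n_genes number of genes; genic SNPs are assigned to contiguous
#'   gene blocks (default 60).
#' @param intergenic_fraction fraction of SNPs with no gene annotation
#'   (default 0.1).
#' @param n_go_terms size of the GO term pool (default 20).
#' @param n_target_terms leading pool terms forming the knowledge-filter
#'   target list (default 6).
#' @param go_terms_per_gene range of GO terms drawn per gene (default 1:3).
#' @param causal_snps NULL or data frame with columns `index` (SNP column
#'   index) and `beta` (log odds ratio per minor-allele copy).
#' @param event_rate target marginal event probability (default 36/168);
#'   used to tune the intercept when `baseline_logit` is NULL.
#' @param baseline_logit intercept of the phenotype model; NULL (default)
#'   sets qlogis(event_rate) minus the expected causal and covariate
#'   contributions.
#' @param covariates named list of covariate specs, each a list with
#'   `type` in "binary"/"ordinal"/"continuous" plus `prevalence` (binary),
#'   `probs` (ordinal, over 0:2), `beta` (log-OR, default 0) and
#'   `concomitant` (binary only: forced to 0 for monotherapy patients).
#'   The default emulates a chemotherapy cohort: an ordinal 0/1/2 genetic
#'   factor, a continuous standardized age, and five concomitant drugs of
#'   prevalence 34, 68, 11, 4 and 2 per 168.
#' @param missing_rate per-call genotype missingness probability
#'   (default 0.005).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_patients = 168L,
                             monotherapy_fraction = 53 / 168,
                             n_snps = 350L,
                             maf_range = c(0.05, 0.5),
                             n_genes = 60L,
                             intergenic_fraction = 0.1,
                             n_go_terms = 20L,
                             n_target_terms = 6L,
                             go_terms_per_gene = 1:3,
                             causal_snps = NULL,
                             event_rate = 36 / 168,
                             baseline_logit = NULL,
                             covariates = default_covariates(),
                             missing_rate = 0.005,
                             seed = 1L) {
  stopifnot(n_patients >= 2, monotherapy_fraction >= 0,
            monotherapy_fraction <= 1, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            intergenic_fraction >= 0, intergenic_fraction < 1,
            n_target_terms <= n_go_terms,
            event_rate > 0, event_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(causal_snps)) {
    stopifnot(is.data.frame(causal_snps),
              all(c("index", "beta") %in% names(causal_snps)),
              all(causal_snps$index >= 1),
              all(causal_snps$index <= n_snps))
  }
  structure(list(n_patients = as.integer(n_patients),
                 monotherapy_fraction = monotherapy_fraction,
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_genes = as.integer(n_genes),
                 intergenic_fraction = intergenic_fraction,
                 n_go_terms = as.integer(n_go_terms),
                 n_target_terms = as.integer(n_target_terms),
                 go_terms_per_gene = go_terms_per_gene,
                 causal_snps = causal_snps, event_rate = event_rate,
                 baseline_logit = baseline_logit, covariates = covariates,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default covariate specification
#'
#' @return named list of covariate specs (see [synthetic_config()]).
#' @export
default_covariates <- function() {
  list(
    ugt1a1 = list(type = "ordinal", probs = c(81, 73, 14) / 168, beta = 0),
    age = list(type = "continuous", beta = 0),
    drug_5fu = list(type = "binary", prevalence = 34 / 168, beta = 0,
                    concomitant = TRUE),
    drug_cddp = list(type = "binary", prevalence = 68 / 168, beta = 0,
                     concomitant = TRUE),
    drug_mmc = list(type = "binary", prevalence = 11 / 168, beta = 0,
                    concomitant = TRUE),
    drug_vp16 = list(type = "binary", prevalence = 4 / 168, beta = 0,
                     concomitant = TRUE),
    drug_amrubicin = list(type = "binary", prevalence = 2 / 168, beta = 0,
                          concomitant = TRUE))
}

.cov_mean <- function(spec) {
  switch(spec$type,
         binary = spec$prevalence,
         ordinal = sum(spec$probs * (seq_along(spec$probs) - 1)),
         continuous = 0,
         stop("unknown covariate type: ", spec$type))
}

#' Generate a synthetic cohort
#'
#' Draws genotypes per SNP under Hardy-Weinberg equilibrium (dosage ~
#' Binomial(2, MAF), SNPs independent), assigns genes and GO annotations,
#' draws covariates, and samples the binary endpoint from the logistic
#' model logit P(event) = baseline + sum(beta_snp * dosage) +
#' sum(beta_cov * covariate). Adverse-event grades are then drawn
#' consistently with the endpoint (events get grade 2-4, non-events 0-1)
#' so that [define_endpoint()] at threshold 2 recovers the simulated
#' outcome. Genotype missingness is applied after the phenotype draw.
#' Fully reproducible under `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_cohort`: list(genotypes, annotation,
#'   gene_go, go_targets, cohort, config, truth).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients; S <- config$n_snps
  patient_ids <- sprintf("P%04d", seq_len(n))
  snp_ids <- sprintf("rs%07d", seq_len(S) * 13L + 100000L)

  mafs <- stats::runif(S, config$maf_range[1], config$maf_range[2])
  dos <- vapply(mafs, function(q) stats::rbinom(n, 2L, q), integer(n))
  dimnames(dos) <- list(patient_ids, snp_ids)

  # gene / GO structure
  genic <- stats::runif(S) >= config$intergenic_fraction
  gene_names <- sprintf("GENE%03d", seq_len(config$n_genes))
  gene_of <- rep(NA_character_, S)
  if (any(genic))
    gene_of[genic] <- gene_names[
      as.integer(cut(seq_len(sum(genic)), breaks = config$n_genes,
                     labels = FALSE))]
  pool <- c("GO:0005215",
            sprintf("GO:%07d", 1900000L + seq_len(config$n_go_terms - 1L)))
  targets <- pool[seq_len(config$n_target_terms)]
  gene_go <- lapply(seq_len(config$n_genes), function(g)
    sort(sample(pool, sample(config$go_terms_per_gene, 1L))))
  names(gene_go) <- gene_names

  loc_pool <- c("intron", "coding", "5'UTR", "3'UTR", "NearGene-5")
  chrom_of_gene <- ((seq_len(config$n_genes) - 1L) %% 22L) + 1L
  gidx <- match(gene_of, gene_names)
  annotation <- data.frame(
    snp_id = snp_ids,
    chromosome = as.character(ifelse(genic, chrom_of_gene[gidx],
                                     (seq_len(S) %% 22L) + 1L)),
    position = seq_len(S) * 2497L + 10000L,
    location_class = ifelse(genic,
                            sample(loc_pool, S, replace = TRUE,
                                   prob = c(.6, .15, .08, .08, .09)),
                            "intergenic"),
    stringsAsFactors = FALSE)
  annotation$gene_symbols <- lapply(seq_len(S), function(i)
    if (genic[i]) gene_of[i] else character(0))

  # monotherapy flag: independent of genotype and outcome
  n_mono <- round(config$monotherapy_fraction * n)
  mono <- rep(FALSE, n)
  mono[sample.int(n, n_mono)] <- TRUE

  # covariates
  covs <- list()
  for (nm in names(config$covariates)) {
    sp <- config$covariates[[nm]]
    covs[[nm]] <- switch(sp$type,
      binary = {
        x <- integer(n)
        if (isTRUE(sp$concomitant)) {
          p_combo <- min(1, sp$prevalence / max(1e-12, mean(!mono)))
          x[!mono] <- stats::rbinom(sum(!mono), 1L, p_combo)
        } else x <- stats::rbinom(n, 1L, sp$prevalence)
        x
      },
      ordinal = sample(seq_along(sp$probs) - 1L, n, replace = TRUE,
                       prob = sp$probs),
      continuous = stats::rnorm(n))
  }

  # phenotype model
  beta_cov <- vapply(config$covariates,
                     function(sp) if (is.null(sp$beta)) 0 else sp$beta,
                     numeric(1))
  lp <- rep(0, n)
  exp_shift <- 0
  if (!is.null(config$causal_snps)) {
    for (i in seq_len(nrow(config$causal_snps))) {
      j <- config$causal_snps$index[i]; b <- config$causal_snps$beta[i]
      lp <- lp + b * dos[, j]
      exp_shift <- exp_shift + b * 2 * mafs[j]
    }
  }
  for (nm in names(covs)) {
    lp <- lp + beta_cov[[nm]] * covs[[nm]]
    exp_shift <- exp_shift + beta_cov[[nm]] * .cov_mean(config$covariates[[nm]])
  }
  baseline <- if (is.null(config$baseline_logit))
    stats::qlogis(config$event_rate) - exp_shift else config$baseline_logit
  outcome <- stats::rbinom(n, 1L, stats::plogis(baseline + lp))
  grade <- integer(n)
  grade[outcome == 1L] <- sample(2:4, sum(outcome), replace = TRUE,
                                 prob = c(.6, .3, .1))
  grade[outcome == 0L] <- sample(0:1, sum(!outcome), replace = TRUE,
                                 prob = c(.7, .3))

  # genotype missingness applied only to the emitted matrix
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * S) < config$missing_rate
    dos[miss] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  minor <- sample(bases, S, replace = TRUE)
  major <- vapply(minor, function(b) sample(setdiff(bases, b), 1L), "")
  geno <- genotype_matrix(dos, allele_labels = data.frame(
    snp_id = snp_ids, minor = minor, major = unname(major),
    stringsAsFactors = FALSE))

  cohort <- data.frame(patient_id = patient_ids,
                       monotherapy = mono,
                       diarrhea_grade = grade,
                       stringsAsFactors = FALSE)
  for (nm in names(covs)) cohort[[nm]] <- covs[[nm]]

  structure(list(genotypes = geno, annotation = annotation,
                 gene_go = gene_go, go_targets = targets, cohort = cohort,
                 config = config,
                 truth = list(maf = stats::setNames(mafs, snp_ids),
                              causal_snps = config$causal_snps,
                              baseline_logit = baseline)),
            class = "synthetic_cohort")
}

#' Generate a fully null synthetic cohort
#'
#' As [generate_cohort()] with every genotype effect removed (used for
#' family-wise error calibration). Covariate effects are retained as
#' configured.
#'
#' @param config a [synthetic_config()]; its `causal_snps` are ignored.
#' @return a `synthetic_cohort`.
#' @export
generate_null_cohort <- function(config) {
  config$causal_snps <- NULL
  generate_cohort(config)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients (%d monotherapy), %d SNPs, %d causal\n",
              nrow(x$cohort), sum(x$cohort$monotherapy),
              length(x$genotypes$snp_ids),
              if (is.null(x$truth$causal_snps)) 0L
              else nrow(x$truth$causal_snps)))
  invisible(x)
}

#' Write a synthetic cohort in the pipeline's input dialects
#'
#' Emits genotypes.tsv, genotypes.vcf, annotation.tsv, gene_go.tsv,
#' go_targets.txt, phenotype.tsv and manifest.yaml (full configuration and
#' seed) into `dir`.
#'
#' @param x a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(x$genotypes, file.path(dir, "genotypes.tsv"))
  write_genotypes_vcf(x$genotypes, file.path(dir, "genotypes.vcf"),
                      annotation = x$annotation)
  ann <- x$annotation
  ann$gene_symbols <- vapply(ann$gene_symbols, paste, "", collapse = ",")
  utils::write.table(ann[, c("snp_id", "chromosome", "position",
                             "gene_symbols", "location_class")],
                     file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gg <- data.frame(gene = rep(names(x$gene_go),
                              lengths(x$gene_go)),
                   go = unlist(x$gene_go, use.names = FALSE))
  utils::write.table(gg, file.path(dir, "gene_go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(x$go_targets, file.path(dir, "go_targets.txt"))
  ph <- x$cohort
  ph$monotherapy <- as.integer(ph$monotherapy)
  utils::write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- x$config
  cfg$covariates <- lapply(cfg$covariates, function(sp)
    lapply(sp, function(v) if (is.numeric(v)) as.numeric(v) else v))
  if (!is.null(cfg$causal_snps))
    cfg$causal_snps <- as.list(as.data.frame(cfg$causal_snps))
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
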