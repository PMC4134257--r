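#' Construct a genotype matrix
#'
#' Container for diploid biallelic calls coded as minor-allele dosage.
#' Rows are patients, columns are SNPs; cells count copies of the designated
#' minor allele (0, 1, 2) with `NA` for missing calls.
#'
#' @param dosage integer matrix (patients x SNPs) with values in
#'   \{0, 1, 2, NA\}; must carry patient IDs as rownames and SNP IDs as
#'   colnames, both unique.
#' @param allele_labels optional data frame with columns `snp_id`, `minor`,
#'   `major` giving the base pair per SNP; minor and major must differ.
#' @return an object of class `genotype_matrix` with fields `patient_ids`,
#'   `snp_ids`, `dosage`, `allele_labels`.
#' @export
genotype_matrix <- function(dosage, allele_labels = NULL) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix")
  if (is.null(rownames(dosage)) || (ncol(dosage) > 0 &&
                                    is.null(colnames(dosage))))
    stop("dosage must have patient rownames and SNP colnames")
  if (is.null(colnames(dosage))) colnames(dosage) <- character(0)
  if (anyDuplicated(rownames(dosage))) stop("duplicate patient IDs")
  if (anyDuplicated(colnames(dosage))) stop("duplicate SNP IDs")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("dosage values must be in {0, 1, 2, NA}")
  storage.mode(dosage) <- "integer"
  if (!is.null(allele_labels)) {
    stopifnot(all(c("snp_id", "minor", "major") %in% names(allele_labels)))
    if (any(allele_labels$minor == allele_labels$major))
      stop("minor and major allele labels must differ")
  }
  structure(
    list(patient_ids = rownames(dosage), snp_ids = colnames(dosage),
         dosage = dosage, allele_labels = allele_labels),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d patients x %d SNPs (%.2f%% missing)\n",
              length(x$patient_ids), length(x$snp_ids),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic SNP records and converts GT fields to minor-allele dosage.
#' The minor allele is decided per SNP by sample allele frequency; a tie at
#' 0.5 is broken toward the alphabetically smaller base (logged).
#' Multiallelic records are skipped with a message.
#'
#' @param path path to a VCF (v4.x) file; only the GT subfield is used.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped: ",
            paste(utils::head(fix$ID[multi], 5), collapse = ", "))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic SNP records in ", path)
  ids <- fix$ID
  if (anyDuplicated(ids)) stop("duplicate rs ID in VCF: ",
                               ids[duplicated(ids)][1])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # ALT-allele dosage per patient: count "1" alleles in the GT string
  alt_dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  alt_dos <- matrix(as.integer(alt_dos), nrow = nrow(gt),
                    dimnames = dimnames(gt))
  n_ok <- rowSums(!is.na(alt_dos))
  alt_freq <- rowSums(alt_dos, na.rm = TRUE) / (2 * pmax(n_ok, 1L))
  minor_is_alt <- alt_freq < 0.5
  tie <- abs(alt_freq - 0.5) < .Machine$double.eps^0.5 & n_ok > 0
  if (any(tie)) {
    # tie at 0.5: alphabetically smaller base is declared minor
    minor_is_alt[tie] <- fix$ALT[tie] < fix$REF[tie]
    message(sum(tie), " SNP(s) with allele frequency 0.5; ",
            "alphabetic tie-break applied")
  }
  dos <- alt_dos
  flip <- !minor_is_alt
  dos[flip, ] <- 2L - alt_dos[flip, , drop = FALSE]
  dos <- t(dos)  # patients x SNPs
  colnames(dos) <- ids
  lab <- data.frame(
    snp_id = ids,
    minor = ifelse(minor_is_alt, fix$ALT, fix$REF),
    major = ifelse(minor_is_alt, fix$REF, fix$ALT),
    stringsAsFactors = FALSE)
  genotype_matrix(dos, allele_labels = lab)
}

#' Read genotypes from the dosage TSV dialect
#'
#' Tab-separated file: header `patient_id<TAB>rs...`, one row per patient,
#' cells already oriented to minor-allele dosage in \{0, 1, 2, NA\}.
#'
#' @param path path to the TSV file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("empty genotype table: ", path)
  if (names(df)[1] != "patient_id") stop("first column must be patient_id")
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient ID: ", df$patient_id[duplicated(df$patient_id)][1])
  body <- as.matrix(df[, -1, drop = FALSE])
  bad <- !(body %in% c("0", "1", "2", "NA") | is.na(body))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage '%s' at patient %s, SNP %s",
                 body[bad][1], df$patient_id[idx[1]],
                 colnames(body)[idx[2]]))
  }
  dos <- matrix(suppressWarnings(as.integer(body)), nrow = nrow(body),
                dimnames = list(df$patient_id, colnames(body)))
  genotype_matrix(dos)
}

#' Write genotypes to the dosage TSV dialect
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(x, path) {
  df <- data.frame(patient_id = x$patient_ids,
                   x$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCF v4.2 file with GT-only genotype fields, one biallelic record
#' per SNP. Positions and chromosomes come from an annotation table when
#' given, otherwise are synthetic placeholders. REF is the major allele and
#' ALT the minor allele (so ALT dosage equals minor dosage).
#'
#' @param x a [genotype_matrix()]; must carry `allele_labels`.
#' @param path output path.
#' @param annotation optional data frame with `snp_id`, `chromosome`,
#'   `position`.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(x, path, annotation = NULL) {
  if (is.null(x$allele_labels)) stop("allele_labels required to write VCF")
  lab <- x$allele_labels[match(x$snp_ids, x$allele_labels$snp_id), ]
  if (is.null(annotation)) {
    chrom <- rep("1", length(x$snp_ids))
    pos <- seq_along(x$snp_ids) * 1000L
  } else {
    m <- match(x$snp_ids, annotation$snp_id)
    chrom <- as.character(annotation$chromosome[m])
    pos <- annotation$position[m]
  }
  gt_of <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$patient_ids), collapse = "\t")),
             con)
  for (j in seq_along(x$snp_ids)) {
    writeLines(paste(c(chrom[j], pos[j], x$snp_ids[j], lab$major[j],
                       lab$minor[j], ".", "PASS", ".", "GT",
                       gt_of(x$dosage[, j])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Dichotomize adverse-event grades
#'
#' Maps NCI-CTC grades (0-4) to a binary endpoint: 1 iff grade >= threshold
#' (e.g. grade >= 2 diarrhea, grade >= 3 neutropenia). Patients with a
#' missing grade get `NA` and are counted in a message; downstream analyses
#' drop them.
#'
#' @param grades integer vector of highest observed grades, in 0..4 or NA.
#' @param threshold integer in 1..4.
#' @return integer 0/1 vector with NA where the grade is missing.
#' @export
dichotomize_grades <- function(grades, threshold) {
  stopifnot(length(threshold) == 1L, threshold %in% 1:4)
  ok <- is.na(grades) | (grades %in% 0:4)
  if (!all(ok)) stop("grades must be in 0..4 or NA")
  if (anyNA(grades))
    message(sum(is.na(grades)), " patient(s) with missing grade excluded")
  as.integer(grades >= threshold)
}

#' Read the SNP annotation table
#'
#' TSV with columns `snp_id`, `chromosome`, `position`, `gene_symbols`
#' (comma-separated, empty for intergenic), `location_class`.
#'
#' @param path path to the TSV file.
#' @return data frame with `gene_symbols` as a list column.
#' @export
read_snp_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("snp_id", "chromosome", "position", "gene_symbols",
            "location_class")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in annotation")
  df$position <- as.integer(df$position)
  if (any(df$position < 1L)) stop("positions must be >= 1")
  df$gene_symbols <- lapply(strsplit(df$gene_symbols, ","),
                            function(g) g[nzchar(g)])
  df
}

#' Read a gene-to-GO map
#'
#' TSV dialect `gene<TAB>GO:NNNNNNN`, one association per line, no header.
#'
#' @param path path to the TSV file.
#' @return named list: gene symbol -> character vector of GO accessions.
#' @export
read_gene_go_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          col.names = c("gene", "go"))
  if (!all(grepl("^GO:[0-9]{7}$", df$go)))
    stop("malformed GO accession: ",
         df$go[!grepl("^GO:[0-9]{7}$", df$go)][1])
  split(df$go, df$gene)
}

#' Read a GO term list
#'
#' One accession per line; used as the knowledge filter.
#'
#' @param path path to the text file.
#' @return character vector of unique accessions, input order preserved.
#' @export
read_go_term_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[nzchar(trimws(x))])
  if (!length(x)) stop("empty GO term list: ", path)
  if (!all(grepl("^GO:[0-9]{7}$", x)))
    stop("malformed GO accession in term list: ",
         x[!grepl("^GO:[0-9]{7}$", x)][1])
  unique(x)
}

#' Read the phenotype / covariate table
#'
#' TSV with columns `patient_id`, `monotherapy` (0/1), one or more
#' `<event>_grade` columns (NCI-CTC 0-4), and arbitrary covariate columns
#' (binary, ordinal or continuous, read as numeric).
#'
#' @param path path to the TSV file.
#' @return data frame with logical `monotherapy`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (!all(c("patient_id", "monotherapy") %in% names(df)))
    stop("cohort table must have patient_id and monotherapy columns")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  df$monotherapy <- as.logical(as.integer(df$monotherapy))
  df
}

#' Attach a binary endpoint to a cohort table
#'
#' Dichotomizes one adverse-event grade column and drops patients whose
#' grade is missing (they cannot contribute to any analysis).
#'
#' @param cohort data frame as returned by [read_cohort_table()].
#' @param event event name; grades are read from column `<event>_grade`.
#' @param threshold grade threshold, outcome 1 iff grade >= threshold.
#' @return the cohort with an integer `outcome` column, missing-grade rows
#'   removed.
#' @export
define_endpoint <- function(cohort, event = "diarrhea", threshold = 2) {
  col <- paste0(event, "_grade")
  if (!col %in% names(cohort)) stop("no grade column ", col)
  out <- dichotomize_grades(cohort[[col]], threshold)
  keep <- !is.na(out)
  cohort <- cohort[keep, , drop = FALSE]
  cohort$outcome <- out[keep]
  cohort
}
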