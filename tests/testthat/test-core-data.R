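test_that("genotype TSV writer and reader round-trip the dosage matrix", {
  set.seed(42)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 6,
                dimnames = list(sprintf("P%02d", 1:6),
                                sprintf("rs%03d", 1:10)))
  gm <- genotype_matrix(dos)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(gm, f)
  gm2 <- read_genotypes_tsv(f)
  expect_identical(gm2$dosage, gm$dosage)
  expect_identical(gm2$patient_ids, gm$patient_ids)
})

test_that("genotype TSV reader rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\trs1\trs2", "P1\t0\t3"), f)
  expect_error(read_genotypes_tsv(f), "invalid dosage")
  writeLines(c("patient_id\trs1", "P1\t0", "P1\t1"), f)
  expect_error(read_genotypes_tsv(f), "duplicated patient ID")
  writeLines("patient_id\trs1", f)
  expect_error(read_genotypes_tsv(f), "empty")
})

test_that("genotype_matrix enforces its invariants", {
  dos <- matrix(0L, 2, 2, dimnames = list(c("P1", "P2"), c("rs1", "rs1")))
  expect_error(genotype_matrix(dos), "duplicate SNP")
  dos <- matrix(c(0L, 5L, 1L, 2L), 2,
                dimnames = list(c("P1", "P2"), c("rs1", "rs2")))
  expect_error(genotype_matrix(dos), "0, 1, 2")
  # dosage sum bounded by 2 x non-missing count per SNP
  set.seed(1)
  dos <- matrix(sample(c(0:2, NA), 200, TRUE, prob = c(.4, .3, .2, .1)),
                20, dimnames = list(sprintf("P%02d", 1:20),
                                    sprintf("rs%02d", 1:10)))
  gm <- genotype_matrix(dos)
  sums <- colSums(gm$dosage, na.rm = TRUE)
  nn <- colSums(!is.na(gm$dosage))
  expect_true(all(sums <= 2 * nn))
})

test_that("VCF reader orients dosage to the sample minor allele", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("S1", "S2", "S3"), list(
    # ALT freq 1/6: ALT is minor, dosage = ALT count
    c("1", 100, "rs1", "A", "C", ".", "PASS", ".", "GT",
      "0/0", "0/1", "0/0"),
    # ALT freq 5/6: REF is minor, dosage flipped
    c("1", 200, "rs2", "A", "C", ".", "PASS", ".", "GT",
      "1/1", "0/1", "1/1"),
    # ALT freq 0.5 tie: alphabetically smaller base (G < T) is minor
    c("1", 300, "rs3", "T", "G", ".", "PASS", ".", "GT",
      "0/0", "0/1", "1/1"),
    # missing call: allele frequency is computed over non-missing calls
    # (ALT freq 3/4 here, so REF becomes the minor allele)
    c("1", 400, "rs4", "A", "C", ".", "PASS", ".", "GT",
      "./.", "0/1", "1/1")))
  gm <- suppressMessages(read_genotypes_vcf(f))
  expect_equal(unname(gm$dosage[, "rs1"]), c(0L, 1L, 0L))
  expect_equal(unname(gm$dosage[, "rs2"]), c(0L, 1L, 0L))
  lab <- gm$allele_labels
  expect_equal(lab$minor[lab$snp_id == "rs2"], "A")
  # tie: ALT G is alphabetically smaller, stays minor -> ALT counts
  expect_equal(unname(gm$dosage[, "rs3"]), c(0L, 1L, 2L))
  expect_equal(lab$minor[lab$snp_id == "rs3"], "G")
  expect_equal(unname(gm$dosage[, "rs4"]), c(NA_integer_, 1L, 0L))
  expect_equal(lab$minor[lab$snp_id == "rs4"], "A")
})

test_that("VCF reader skips multiallelic records and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("S1", "S2"), list(
    c("1", 100, "rs1", "A", "C,G", ".", "PASS", ".", "GT", "0/1", "0/2"),
    c("1", 200, "rs2", "A", "C", ".", "PASS", ".", "GT", "0/1", "0/0")))
  expect_message(gm <- read_genotypes_vcf(f), "multiallelic")
  expect_equal(gm$snp_ids, "rs2")
  write_test_vcf(f, "S1", list(
    c("1", 100, "rs1", "A", "C", ".", "PASS", ".", "GT", "0/1"),
    c("1", 200, "rs1", "A", "G", ".", "PASS", ".", "GT", "0/1")))
  expect_error(read_genotypes_vcf(f), "duplicate rs ID")
})

test_that("VCF writer round-trips dosages for minor-oriented SNPs", {
  x <- generate_cohort(synthetic_config(n_patients = 40, n_snps = 25,
                                        missing_rate = 0.05, seed = 5))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(x$genotypes, f, annotation = x$annotation)
  gm2 <- suppressMessages(read_genotypes_vcf(f))
  # compare SNPs whose sample minor frequency is strictly below 0.5
  # (orientation of the rest is legitimately re-decided by the reader)
  freq <- colMeans(x$genotypes$dosage, na.rm = TRUE) / 2
  keep <- names(freq)[freq < 0.5 - 1e-9]
  expect_gt(length(keep), 5)
  expect_identical(gm2$dosage[, keep], x$genotypes$dosage[, keep])
})

test_that("grade dichotomization applies the >= threshold rule", {
  expect_equal(dichotomize_grades(c(0, 1, 2, 3), 2), c(0L, 0L, 1L, 1L))
  expect_equal(dichotomize_grades(4, 4), 1L)
  expect_equal(dichotomize_grades(c(2, 2), 3), c(0L, 0L))
  expect_message(out <- dichotomize_grades(c(2, NA), 2), "missing grade")
  expect_equal(out, c(1L, NA))
  expect_error(dichotomize_grades(c(0, 5), 2), "0..4")
})

test_that("endpoint definition drops missing-grade patients only", {
  ch <- data.frame(patient_id = c("P1", "P2", "P3"),
                   monotherapy = c(TRUE, FALSE, TRUE),
                   diarrhea_grade = c(3, NA, 1))
  out <- suppressMessages(define_endpoint(ch, "diarrhea", 2))
  expect_equal(out$patient_id, c("P1", "P3"))
  expect_equal(out$outcome, c(1L, 0L))
  # monotherapy subset extraction is pure row selection
  mono <- out[out$monotherapy, ]
  expect_identical(mono, out[out$patient_id %in% mono$patient_id, ])
})

test_that("annotation, GO-map and term-list readers validate their dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchromosome\tposition\tgene_symbols\tlocation_class",
               "rs1\t6\t100\tGENE1,GENE2\tintron",
               "rs2\t6\t200\t\tintergenic"), f)
  ann <- read_snp_annotation(f)
  expect_equal(ann$gene_symbols[[1]], c("GENE1", "GENE2"))
  expect_length(ann$gene_symbols[[2]], 0)
  writeLines(c("GENE1\tGO:0005215", "GENE1\tGO:1900001",
               "GENE2\tbadterm"), f)
  expect_error(read_gene_go_map(f), "malformed GO accession")
  writeLines(c("GENE1\tGO:0005215", "GENE1\tGO:1900001"), f)
  gg <- read_gene_go_map(f)
  expect_equal(gg$GENE1, c("GO:0005215", "GO:1900001"))
  writeLines(c("GO:0005215", "", "GO:1900001"), f)
  expect_equal(read_go_term_list(f), c("GO:0005215", "GO:1900001"))
})
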