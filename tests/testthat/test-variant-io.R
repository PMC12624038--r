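test_that("genotype strings normalize phase-insensitively", {
  expect_equal(normalize_gt(c("0/1", "1/0", "0|1", "1|0")),
               rep("0/1", 4))
  expect_equal(normalize_gt(c("./.", ".", "./1", "")), rep("./.", 4))
  expect_equal(normalize_gt("2/0"), "0/2")
  expect_equal(gt_to_dose(c("0/0", "0/1", "1/1", "./.", "0/2")),
               c(0L, 1L, 2L, NA, NA))
  expect_equal(gt_state(c("0/0", "1/0", "2/2", "./.")),
               c("hom-ref", "het", "hom-alt", "missing"))
})

test_that("VCF records map fields directly and keep absent metrics absent", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "A", "B", "C", sep = "\t"),
               paste("1", "101", ".", "A", "T", ".", ".", "QD=6.1", "GT",
                     "0/0", "0/1", "1/1", sep = "\t"),
               paste("1", "200", ".", "G", "C,GAT", ".", ".",
                     "QD=7;MQ=55.2", "GT:DP", "0/0:10", "1/2:12", "./.:0",
                     sep = "\t")),
             f)
  x <- read_vcf(f)
  expect_equal(x$samples, c("A", "B", "C"))
  expect_equal(x$variants$pos, c(101L, 200L))
  expect_equal(x$variants$qd, c(6.1, 7))
  expect_true(all(is.na(x$variants$mq_rank_sum)))
  expect_equal(x$variants$mq, c(NA, 55.2))
  expect_equal(unname(x$gt[1, ]), c("0/0", "0/1", "1/1"))
  expect_equal(unname(x$gt[2, ]), c("0/0", "1/2", "./."))
  expect_equal(x$variants$alt[2], "C,GAT")
})

test_that("malformed headers and missing GT are format errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), f)
  expect_error(read_vcf(f), "header")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "A", sep = "\t"),
               paste("1", "5", ".", "A", "T", ".", ".", ".", "DP", "10",
                     sep = "\t")), f)
  expect_error(read_vcf(f), "GT absent")
})

test_that("read-write-read is the identity on synthetic cohorts and byte-stable", {
  coh <- generate_cohort(cohort_spec(
    chromosomes = data.frame(chrom = c("1", "2"), length = 200000L),
    filter_fail_plan = c(QD = 1), indel_fail_plan = c(QD = 1),
    n_high_impact_genes = 2, n_high_impact = 3, seed = 42))
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(coh$variants, f1)
  back <- read_vcf(f1)
  expect_equal(back$variants, coh$variants$variants)
  expect_equal(back$gt, coh$variants$gt)
  expect_equal(back$samples, coh$variants$samples)
  write_vcf(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("parsing agrees with vcfR on a synthetic file", {
  skip_if_not_installed("vcfR")
  coh <- generate_cohort(cohort_spec(
    chromosomes = data.frame(chrom = "1", length = 150000L),
    filter_fail_plan = c(QD = 1), indel_fail_plan = c(QD = 1),
    n_high_impact_genes = 2, n_high_impact = 2, seed = 5))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(coh$variants, f)
  x <- read_vcf(f)
  ref <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(as.integer(ref@fix[, "POS"]), x$variants$pos)
  expect_equal(unname(ref@fix[, "REF"]), x$variants$ref)
  gt_ref <- vcfR::extract.gt(ref, element = "GT")
  expect_equal(unname(normalize_gt(gt_ref)), unname(as.vector(x$gt)))
  qd_ref <- as.numeric(vcfR::extract.info(ref, "QD"))
  expect_equal(qd_ref, x$variants$qd)
})

test_that("ANN fields parse per block, skip short blocks, survive emptiness", {
  ann <- parse_ann_field("T|stop_gained|HIGH|GS3")
  expect_equal(ann$effect, "stop_gained")
  expect_equal(ann$impact, "HIGH")
  expect_equal(ann$gene_id, "GS3")
  two <- parse_ann_field("G|synonymous_variant|LOW|X,G|upstream_gene_variant|MODIFIER|Y")
  expect_equal(nrow(two), 2L)
  expect_equal(two$gene_id, c("X", "Y"))
  expect_equal(nrow(parse_ann_field("")), 0L)
  expect_equal(nrow(parse_ann_field(NA_character_)), 0L)
  expect_warning(short <- parse_ann_field("T|stop_gained,A|x|HIGH|G2"),
                 "fewer than 4")
  expect_equal(short$gene_id, "G2")
})

test_that("QTL tables validate rows and normalize categories", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("qtl_id\tchrom\tstart\tend\tcategory",
               "qGL3-1\t3\t16000000\t17000000\tEA",
               "one-bp\t5\t100\t100\tsr",
               "low\t2\t10\t20\tea"), f)
  q <- read_qtl_table(f)
  expect_equal(q$category, c("EA", "SR", "EA"))
  expect_true(q$start[1] <= 16733441 && q$end[1] >= 16733441)
  expect_equal(q$start[2], q$end[2])
  writeLines(c("qtl_id\tchrom\tstart\tend\tcategory",
               "bad\t1\t200\t100\tEA"), f)
  expect_error(read_qtl_table(f), "start > end")
  writeLines(c("qtl_id\tchrom\tstart\tend\tcategory",
               "bad\t1\t100\t200\tXX"), f)
  expect_error(read_qtl_table(f), "category")
})

test_that("genotype matrix text reader applies the missing-row policy", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CHROM POS A B C",
               "1 100 0/0 0/1 1/1",
               "1 200 ./. 0/0 0/0",
               "1 300 1/0 1/1 0/0",
               "1 400 ./. ./. ./."), f)
  gm <- read_genotype_matrix_txt(f)
  expect_equal(length(gm$keys), 2L)
  expect_equal(unname(gm$dose[2, ]), c(1L, 2L, 0L)) # 1/0 same as 0/1
  # the all-missing reading keeps partial rows, which cannot form complete
  # dosage profiles — surfaced as an error rather than silent NA entries
  expect_error(read_genotype_matrix_txt(f, drop_missing = "all"),
               "partially missing")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CHROM POS A B C",
               "1 100 0/0 0/1 1/1",
               "1 400 ./. ./. ./."), f2)
  gm_all <- read_genotype_matrix_txt(f2, drop_missing = "all")
  expect_equal(length(gm_all$keys), 1L)
  writeLines(c("CHROM POS A B C", "1 100 0/0 0/1"), f)
  expect_error(read_genotype_matrix_txt(f), "columns")
})

test_that("the published panel fixture round-trips through the text reader", {
  path <- system.file("extdata", "table4_genotypes.tsv", package = "varpanel")
  gm <- read_genotype_matrix_txt(path)
  ref <- table4_genotypes()
  expect_equal(length(gm$keys), 5L)
  expect_equal(length(gm$varieties), 22L)
  expect_equal(gm$dose, ref$dose)
  expect_equal(gm$keys, ref$keys)
  # spot values from the printed matrix
  expect_equal(unname(ref$dose["6:20640731", "Basmati Type III"]), 1L)
  expect_equal(unname(ref$dose[, "Albatros"]), c(0L, 0L, 0L, 2L, 1L))
  expect_false(anyNA(ref$dose))
})
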