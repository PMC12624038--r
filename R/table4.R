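#' The published 5-SNP discriminating panel genotype matrix
#'
#' The transcribed 5-SNP x 22-variety genotype matrix of the published
#' minimal discriminating panel for Mediterranean rice varieties: SNPs at
#' chr4:22,375,729 (G>T), chr6:20,640,731 (C>T), chr10:6,918,411 (C>T),
#' chr11:19,577,767 (C>T) and chr11:28,814,241 (G>A), with each variety's
#' call coded against the Nipponbare reference. Contains no missing
#' calls. The same matrix ships as a text fixture at
#' `system.file("extdata", "table4_genotypes.tsv", package = "varpanel")`.
#'
#' @return a [genotype_matrix()], 5 SNPs x 22 varieties.
#' @export
table4_genotypes <- function() {
  snps <- data.frame(chrom = c("4", "6", "10", "11", "11"),
                     pos = c(22375729L, 20640731L, 6918411L,
                             19577767L, 28814241L),
                     stringsAsFactors = FALSE)
  gt <- c(
    "Albatros",         "0/0 0/0 0/0 1/1 0/1",
    "Arborio",          "1/1 1/1 1/1 1/1 0/1",
    "Arelate",          "0/0 0/0 0/0 1/1 0/0",
    "Ariete",           "1/1 0/0 0/0 0/0 0/1",
    "Basmati Type III", "1/1 0/1 1/1 0/0 0/1",
    "Bomba",            "0/0 1/1 0/0 1/1 0/0",
    "CL-28",            "0/0 0/0 1/1 1/1 0/0",
    "Caravela",         "1/1 0/0 1/1 0/0 0/1",
    "Carnaroli",        "1/1 1/1 0/0 1/1 0/1",
    "Elettra",          "0/0 1/1 1/1 1/1 0/0",
    "Gageron",          "1/1 0/0 0/0 0/0 0/0",
    "Giza 177",         "1/1 0/0 0/0 1/1 0/0",
    "Giza 181",         "1/1 0/0 1/1 1/1 0/0",
    "JSendra",          "0/0 1/1 0/0 0/0 0/1",
    "Lusitano",         "1/1 0/1 1/1 0/1 0/1",
    "Ma\u00e7arico", "1/1 1/1 0/1 1/1 0/0",
    "Manobi",           "0/0 1/1 0/0 0/0 0/0",
    "Puntal",           "1/1 0/0 0/1 1/1 0/1",
    "Ronaldo",          "1/1 0/0 0/1 0/1 0/1",
    "Super Basmati",    "1/1 0/0 1/1 0/0 0/0",
    "Teti",             "0/0 1/1 1/1 1/1 0/1",
    "Ulisse",           "1/1 0/1 1/1 1/1 0/1")
  varieties <- gt[seq(1, length(gt), 2)]
  calls <- strsplit(gt[seq(2, length(gt), 2)], " ", fixed = TRUE)
  dose <- vapply(calls, gt_to_dose, integer(5))
  colnames(dose) <- varieties
  genotype_matrix(snps, dose)
}

#' Reference and alternate alleles of the published panel SNPs
#' @return data.frame with `chrom`, `pos`, `ref`, `alt` for the five SNPs
#'   of [table4_genotypes()].
#' @export
table4_alleles <- function() {
  data.frame(chrom = c("4", "6", "10", "11", "11"),
             pos = c(22375729L, 20640731L, 6918411L, 19577767L, 28814241L),
             ref = c("G", "C", "C", "C", "G"),
             alt = c("T", "T", "T", "T", "A"),
             stringsAsFactors = FALSE)
}
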