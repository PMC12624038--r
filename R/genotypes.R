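#' Normalize diploid genotype strings
#'
#' Genotype calls are stored as unphased, index-sorted strings: `"1/0"`,
#' `"1|0"` and `"0/1"` all normalize to `"0/1"`, so equality is
#' phase-insensitive. Any call containing a missing allele (`.`) normalizes
#' to `"./."`.
#'
#' @param x character vector of GT strings (e.g. `"0/1"`, `"1|0"`, `"./."`).
#' @return character vector of normalized genotype strings.
#' @examples
#' normalize_gt(c("1/0", "0|1", ".", "./1"))
#' @export
normalize_gt <- function(x) {
  ux <- unique(x)
  norm1 <- function(g) {
    if (is.na(g) || g == "") return("./.")
    g <- gsub("|", "/", g, fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- c(parts, parts)
    if (length(parts) != 2L || any(parts == ".") || any(parts == "")) return("./.")
    idx <- suppressWarnings(as.integer(parts))
    if (anyNA(idx) || any(idx < 0L)) return("./.")
    paste(sort(idx), collapse = "/")
  }
  map <- vapply(ux, norm1, character(1))
  unname(map[match(x, ux)])
}

#' Convert biallelic genotype strings to alternate-allele dosage
#'
#' Dosage is the count of alternate alleles: `"0/0"` is 0, `"0/1"` is 1,
#' `"1/1"` is 2 and `"./."` is `NA`. Genotypes referring to allele indices
#' above 1 (multi-allelic calls) also map to `NA`; callers restrict to
#' biallelic sites first.
#'
#' @param x character vector or matrix of normalized genotype strings.
#' @return integer vector or matrix of dosages in `{0, 1, 2, NA}`.
#' @export
gt_to_dose <- function(x) {
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  d <- lookup[normalize_gt(as.character(x))]
  d <- unname(d)
  if (is.matrix(x)) {
    dim(d) <- dim(x)
    dimnames(d) <- dimnames(x)
  }
  d
}

#' Convert dosages back to genotype strings
#'
#' @param d integer vector/matrix with values in `{0, 1, 2, NA}`.
#' @return character vector/matrix of `"0/0"`, `"0/1"`, `"1/1"`, `"./."`.
#' @export
dose_to_gt <- function(d) {
  g <- c("0/0", "0/1", "1/1")[as.integer(d) + 1L]
  g[is.na(g)] <- "./."
  if (is.matrix(d)) {
    dim(g) <- dim(d)
    dimnames(g) <- dimnames(d)
  }
  g
}

#' Carrier state of a genotype call
#'
#' @param x character vector of genotype strings.
#' @return character vector in `{"hom-ref", "het", "hom-alt", "missing"}`;
#'   heterozygous means the two allele indices differ, hom-alt that both are
#'   the same non-reference allele.
#' @export
gt_state <- function(x) {
  g <- normalize_gt(x)
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (p[1] == ".") return("missing")
    a <- as.integer(p)
    if (a[1] == 0L && a[2] == 0L) return("hom-ref")
    if (a[1] == a[2]) return("hom-alt")
    "het"
  }, character(1))
}

# strip an optional "chr"/"Chr" prefix so IRGSP and MSU naming dialects compare
norm_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))
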