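#' Per-chromosome variant counts, rate and density
#'
#' For each chromosome: SNP and InDel record counts, the variant rate
#' (mean base pairs per variant, `length / (n_snps + n_indels)`) and the
#' variant density (mean variants per 1-kbp window,
#' `(n_snps + n_indels) / (length / 1000)`), so `rate * density = 1000`
#' whenever at least one variant is present. The `"All"` row pools counts
#' and lengths across chromosomes rather than averaging per-chromosome
#' values. Mixed-class records are tallied in `n_mixed` but do not enter
#' rate/density.
#'
#' @param x a [variant_set()].
#' @param chroms chromosome-length table (data.frame `chrom`, `length`).
#' @param density_unit window size in bp for the density definition
#'   (default 1000).
#' @return data.frame with one row per chromosome plus an `"All"` row:
#'   `chrom`, `length`, `n_snps`, `n_indels`, `n_mixed`, `n_variants`,
#'   `rate`, `density`.
#' @export
summarize_by_chromosome <- function(x, chroms, density_unit = 1000) {
  cls <- classify_variants(x)
  vchrom <- norm_chrom(x$variants$chrom)
  tchrom <- norm_chrom(chroms$chrom)
  missing <- setdiff(unique(vchrom), tchrom)
  if (length(missing)) {
    stop("chromosome(s) absent from length table: ",
         paste(missing, collapse = ", "))
  }
  per <- lapply(seq_len(nrow(chroms)), function(i) {
    on_c <- vchrom == tchrom[i]
    data.frame(chrom = chroms$chrom[i], length = chroms$length[i],
               n_snps = sum(on_c & cls == "SNP"),
               n_indels = sum(on_c & cls == "INDEL"),
               n_mixed = sum(on_c & cls == "MIXED"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- rbind(out, data.frame(chrom = "All", length = sum(out$length),
                               n_snps = sum(out$n_snps),
                               n_indels = sum(out$n_indels),
                               n_mixed = sum(out$n_mixed)))
  out$n_variants <- out$n_snps + out$n_indels
  out$rate <- ifelse(out$n_variants > 0, out$length / out$n_variants, NA_real_)
  out$density <- out$n_variants / (out$length / density_unit)
  out
}

#' Substitution spectrum of SNP records
#'
#' Counts the 12 ordered reference-to-alternate base changes over
#' \{A, C, G, T\} without strand collapsing (C>T and G>A are tallied
#' separately). Multi-allelic SNP records contribute one count per
#' alternate allele. Non-SNP records are skipped and tallied in the
#' `n_skipped` attribute.
#'
#' @param x a [variant_set()].
#' @return data.frame of all 12 ordered pairs with columns `ref`, `alt`,
#'   `count`; attribute `n_skipped` counts non-SNP records.
#' @export
substitution_spectrum <- function(x) {
  cls <- classify_variants(x)
  snp <- subset_variants(x, cls == "SNP")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(alt = bases, ref = bases,
                       stringsAsFactors = FALSE)[, c("ref", "alt")]
  pairs <- pairs[pairs$ref != pairs$alt, ]
  rownames(pairs) <- NULL
  key <- paste0(pairs$ref, ">", pairs$alt)
  alts <- strsplit(snp$variants$alt, ",", fixed = TRUE)
  obs <- paste0(rep(snp$variants$ref, lengths(alts)), ">", unlist(alts))
  tab <- table(factor(obs, levels = key))
  pairs$count <- as.integer(tab)
  attr(pairs, "n_skipped") <- sum(cls != "SNP")
  pairs
}

#' Observed transition/transversion ratio
#' @param spectrum output of [substitution_spectrum()].
#' @return numeric Ti/Tv ratio.
#' @export
ti_tv_ratio <- function(spectrum) {
  ti <- c("A>G", "G>A", "C>T", "T>C")
  is_ti <- paste0(spectrum$ref, ">", spectrum$alt) %in% ti
  sum(spectrum$count[is_ti]) / sum(spectrum$count[!is_ti])
}

#' InDel length spectrum
#'
#' Histogram of signed InDel lengths, `nchar(alt) - nchar(ref)`: negative
#' values are deletions, positive insertions. Only biallelic
#' INDEL-classified records are counted; multi-allelic ones are tallied in
#' the `n_skipped` attribute. Counts are on the raw scale (log scaling in
#' figures is presentation only).
#'
#' @param x a [variant_set()].
#' @return data.frame with columns `length` (signed, never 0) and `count`;
#'   attribute `n_skipped`.
#' @export
indel_length_spectrum <- function(x) {
  cls <- classify_variants(x)
  bial <- cls == "INDEL" & !grepl(",", x$variants$alt, fixed = TRUE)
  v <- x$variants[bial, , drop = FALSE]
  len <- nchar(v$alt) - nchar(v$ref)
  if (any(len == 0L)) stop("length-0 record classified as InDel")
  tab <- table(len)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(out$length), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(cls == "INDEL") - sum(bial)
  out
}

window_index <- function(pos, window_size) (pos - 1L) %/% window_size + 1L

#' Fixed-width window variant counts
#'
#' Windows tile each chromosome with 1-based starts and half-open spans
#' `[start, start + size)`; the final window may be short. Every variant
#' is assigned to exactly one window by position, so window counts sum to
#' the chromosome count.
#'
#' @param x a [variant_set()].
#' @param chroms chromosome-length table.
#' @param window_size window width in bp (default 100,000).
#' @return data.frame with columns `chrom`, `start`, `end` (inclusive bp),
#'   `count`.
#' @export
window_counts <- function(x, chroms, window_size = 100000) {
  if (window_size < 1) stop("window_size must be >= 1")
  vchrom <- norm_chrom(x$variants$chrom)
  tchrom <- norm_chrom(chroms$chrom)
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    n_win <- as.integer(ceiling(len / window_size))
    pos <- x$variants$pos[vchrom == tchrom[i]]
    if (any(pos > len)) {
      stop("position ", max(pos), " beyond ", chroms$chrom[i],
           " length ", len)
    }
    starts <- (seq_len(n_win) - 1L) * window_size + 1L
    data.frame(chrom = chroms$chrom[i], start = starts,
               end = pmin(starts + window_size - 1L, len),
               count = tabulate(window_index(pos, window_size), n_win),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-variety SNP density profiles
#'
#' For each chromosome, a varieties x windows matrix counting, per
#' variety, the windowed variants where that variety carries at least one
#' non-reference allele (missing genotypes never count). This is the
#' per-variety track used for density-profile clustering; each entry is
#' bounded above by the cohort window count.
#'
#' @param x a [variant_set()].
#' @param chroms chromosome-length table.
#' @param window_size window width in bp (default 100,000).
#' @return named list (by chromosome) of integer matrices, varieties in
#'   rows and windows in columns.
#' @export
density_profiles <- function(x, chroms, window_size = 100000) {
  if (window_size < 1) stop("window_size must be >= 1")
  carrier <- matrix(FALSE, n_variants(x), length(x$samples))
  g <- x$gt
  carrier[] <- g != "./." & g != "0/0"
  vchrom <- norm_chrom(x$variants$chrom)
  tchrom <- norm_chrom(chroms$chrom)
  out <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    n_win <- as.integer(ceiling(len / window_size))
    on_c <- vchrom == tchrom[i]
    widx <- window_index(x$variants$pos[on_c], window_size)
    m <- matrix(0L, length(x$samples), n_win,
                dimnames = list(x$samples, NULL))
    cc <- carrier[on_c, , drop = FALSE]
    for (v in seq_along(x$samples)) {
      m[v, ] <- tabulate(widx[cc[, v]], n_win)
    }
    m
  })
  names(out) <- chroms$chrom
  out
}
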