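#' Multi-sample variant set
#'
#' The in-memory model for a (subset of a) multi-sample VCF. A
#' `variant_set` is a list with three components:
#' \describe{
#'   \item{`variants`}{data.frame with one row per VCF record: `chrom`,
#'     `pos` (1-based), `ref`, `alt` (comma-joined alternate alleles), the
#'     hard-filter INFO metrics `qd`, `sor`, `fs`, `mq`, `mq_rank_sum`,
#'     `read_pos_rank_sum` (`NA` when the key is absent from INFO — absence
#'     is never coerced to a number), and `ann` (the raw SnpEff-style ANN
#'     string, `NA` when absent).}
#'   \item{`gt`}{character matrix, records x samples, of normalized
#'     genotype strings (see [normalize_gt()]).}
#'   \item{`samples`}{character vector of variety names in VCF column
#'     order.}
#' }
#'
#' @param variants data.frame as described above.
#' @param gt character matrix of genotypes, `nrow(variants)` x
#'   `length(samples)`.
#' @param samples character vector of unique sample names.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(variants, gt, samples) {
  stopifnot(is.data.frame(variants), is.matrix(gt),
            nrow(gt) == nrow(variants), ncol(gt) == length(samples))
  if (anyDuplicated(samples)) stop("duplicate sample names")
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1L)) stop("positions must be >= 1")
    bad <- !grepl("^[ACGT]+$", variants$ref) |
      !grepl("^[ACGT]+(,[ACGT]+)*$", variants$alt)
    if (any(bad)) {
      stop("non-ACGT ref/alt allele at ", variants$chrom[bad][1], ":",
           variants$pos[bad][1])
    }
  }
  colnames(gt) <- samples
  rownames(variants) <- NULL
  structure(list(variants = variants, gt = gt, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "records,",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Number of records in a variant set
#' @param x a `variant_set`.
#' @return integer record count.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a variant set by record index
#' @param x a `variant_set`.
#' @param i integer or logical index over records.
#' @return a `variant_set` with the selected records.
#' @export
subset_variants <- function(x, i) {
  variant_set(x$variants[i, , drop = FALSE],
              x$gt[i, , drop = FALSE], x$samples)
}

info_metric_keys <- c(qd = "QD", sor = "SOR", fs = "FS", mq = "MQ",
                      mq_rank_sum = "MQRankSum",
                      read_pos_rank_sum = "ReadPosRankSum")

#' Read a multi-sample VCF
#'
#' Parses the VCF 4.x subset this pipeline uses: CHROM/POS/REF/ALT, the
#' INFO metrics QD, SOR, FS, MQ, MQRankSum and ReadPosRankSum, the ANN
#' annotation string, and the GT field of every sample. Plain and
#' gzip-compressed files are both accepted. Absent INFO keys become `NA`,
#' never zero; multi-allelic records are kept as-is.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^##", lines)
  chrom_line <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_line) != 1L ||
      (length(hdr) > 0 && chrom_line < max(hdr))) {
    stop("malformed VCF header: expected a single #CHROM line after ",
         "## meta lines (line ", if (length(chrom_line)) chrom_line[1] else "absent", ")")
  }
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L || cols[9] != "FORMAT") {
    stop("malformed VCF header: FORMAT/sample columns missing (line ",
         chrom_line, ")")
  }
  samples <- cols[-(1:9)]
  body <- lines[seq_along(lines) > chrom_line]
  body <- body[nzchar(body)]
  n <- length(body)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qd = numeric(0), sor = numeric(0), fs = numeric(0),
                      mq = numeric(0), mq_rank_sum = numeric(0),
                      read_pos_rank_sum = numeric(0), ann = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(variant_set(empty, matrix(character(0), 0, length(samples)),
                       samples))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != length(cols))) {
    stop("VCF record with wrong column count at data line ",
         which(nf != length(cols))[1])
  }
  f <- matrix(unlist(f), nrow = n, byrow = TRUE)
  fmt <- strsplit(f[, 9], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(k) match("GT", k), integer(1))
  if (anyNA(gt_idx)) {
    stop("GT absent from FORMAT at data line ", which(is.na(gt_idx))[1])
  }
  info <- strsplit(f[, 8], ";", fixed = TRUE)
  get_key <- function(kv, key) {
    hit <- startsWith(kv, paste0(key, "="))
    if (!any(hit)) NA_character_ else sub("^[^=]*=", "", kv[hit][1])
  }
  variants <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]),
                         ref = f[, 4], alt = f[, 5],
                         stringsAsFactors = FALSE)
  for (j in seq_along(info_metric_keys)) {
    raw <- vapply(info, get_key, character(1), key = info_metric_keys[[j]])
    variants[[names(info_metric_keys)[j]]] <- as.numeric(raw)
  }
  variants$ann <- vapply(info, get_key, character(1), key = "ANN")
  gt <- f[, -(1:9), drop = FALSE]
  for (i in seq_len(n)) {
    if (gt_idx[i] > 1L || length(fmt[[i]]) > 1L) {
      gt[i, ] <- vapply(strsplit(gt[i, ], ":", fixed = TRUE),
                        `[`, character(1), gt_idx[i])
    }
  }
  gt <- matrix(normalize_gt(gt), nrow = n)
  variant_set(variants, gt, samples)
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a variant set as VCF
#'
#' Emits a VCF 4.2 file with the INFO keys this pipeline reads (QD, SOR,
#' FS, MQ, MQRankSum, ReadPosRankSum, ANN) declared in the header and GT as
#' the only FORMAT field. Records must be sorted by (chrom, pos). Output is
#' deterministic: the same variant set always yields byte-identical files.
#'
#' @param x a [variant_set()].
#' @param path output path (plain text).
#' @param contigs optional chromosome-length table (data.frame `chrom`,
#'   `length`) to declare as contig lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contigs = NULL) {
  v <- x$variants
  if (nrow(v) > 1) {
    # each chromosome one contiguous block (in the caller's contig order),
    # positions ascending within it
    blocks <- rle(v$chrom)$values
    by_pos <- tapply(v$pos, factor(v$chrom, levels = unique(v$chrom)),
                     is.unsorted)
    if (anyDuplicated(blocks) || any(unlist(by_pos))) {
      stop("records must be sorted by (chrom, pos) before writing")
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
                   unname(info_metric_keys), unname(info_metric_keys)),
           '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$chrom, as.integer(contigs$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples),
                      collapse = "\t"))
  info_str <- vapply(seq_len(nrow(v)), function(i) {
    kv <- character(0)
    for (j in seq_along(info_metric_keys)) {
      val <- v[[names(info_metric_keys)[j]]][i]
      if (!is.na(val)) kv <- c(kv, paste0(info_metric_keys[[j]], "=", fmt_num(val)))
    }
    if (!is.na(v$ann[i])) kv <- c(kv, paste0("ANN=", v$ann[i]))
    if (length(kv) == 0L) "." else paste(kv, collapse = ";")
  }, character(1))
  body <- if (nrow(v) == 0L) character(0) else {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", info_str, "GT",
          apply(x$gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(enc2utf8(c(hdr, body)), path, useBytes = TRUE)
  invisible(path)
}

#' Parse a SnpEff-style ANN field
#'
#' An ANN field is a comma-separated list of annotations, each a
#' pipe-delimited record whose first four subfields are allele, effect
#' terms (`&`-joined), putative impact (HIGH, MODERATE, LOW or MODIFIER)
#' and gene identifier. Extra subfields are ignored; blocks with fewer than
#' four subfields are skipped with a warning.
#'
#' @param raw a single ANN string (possibly `NA` or empty).
#' @return data.frame with columns `allele`, `effect`, `impact`,
#'   `gene_id`; zero rows for empty input.
#' @examples
#' parse_ann_field("T|stop_gained|HIGH|GS3")
#' @export
parse_ann_field <- function(raw) {
  out <- data.frame(allele = character(0), effect = character(0),
                    impact = character(0), gene_id = character(0),
                    stringsAsFactors = FALSE)
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) return(out)
  blocks <- strsplit(raw, ",", fixed = TRUE)[[1]]
  # sentinel keeps trailing empty subfields (strsplit would drop them)
  parts <- lapply(strsplit(paste0(blocks, "|\x01"), "|", fixed = TRUE),
                  function(p) p[-length(p)])
  short <- lengths(parts) < 4L
  if (any(short)) {
    warning("skipping ", sum(short),
            " ANN block(s) with fewer than 4 subfields")
    parts <- parts[!short]
  }
  if (length(parts) == 0L) return(out)
  ann <- data.frame(allele = vapply(parts, `[`, character(1), 1L),
                    effect = vapply(parts, `[`, character(1), 2L),
                    impact = vapply(parts, `[`, character(1), 3L),
                    gene_id = vapply(parts, `[`, character(1), 4L),
                    stringsAsFactors = FALSE)
  bad <- !ann$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (any(bad)) {
    warning("skipping ", sum(bad), " ANN block(s) with unknown impact")
    ann <- ann[!bad, , drop = FALSE]
  }
  rownames(ann) <- NULL
  ann
}

#' Read a QTL interval table
#'
#' Tab-separated table with columns `qtl_id`, `chrom`, `start`, `end`,
#' `category`. Coordinates are 1-based and end-inclusive. Categories are
#' case-folded to `EA` (eating quality) or `SR` (seed-related).
#'
#' @param path path to the TSV file.
#' @return validated data.frame of intervals.
#' @export
read_qtl_table <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qtl_id", "chrom", "start", "end", "category")
  if (!all(need %in% names(q))) {
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  }
  q$chrom <- as.character(q$chrom)
  q$start <- as.integer(q$start)
  q$end <- as.integer(q$end)
  q$category <- toupper(trimws(q$category))
  bad <- which(q$start > q$end)
  if (length(bad)) {
    stop("QTL row ", bad[1] + 1L, ": start > end (", q$qtl_id[bad[1]], ")")
  }
  bad <- which(!q$category %in% c("EA", "SR"))
  if (length(bad)) {
    stop("QTL row ", bad[1] + 1L, ": unknown category '",
         q$category[bad[1]], "'")
  }
  q[need]
}

#' Read a chromosome-length table
#'
#' Tab-separated with columns `chrom`, `length` and optionally
#' `centromere` (all bp).
#'
#' @param path path to the TSV file.
#' @return data.frame with unique chromosome names and positive lengths.
#' @export
read_chrom_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(ct))) {
    stop("chromosome table must have columns chrom, length")
  }
  ct$chrom <- as.character(ct$chrom)
  ct$length <- as.integer(ct$length)
  if (any(ct$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(ct$chrom)) stop("duplicate chromosome names")
  ct
}

#' Read a genotype matrix in CHROM/POS/varieties text format
#'
#' The input dialect is a delimited text table whose first two columns are
#' CHROM and POS and whose remaining columns are one genotype call per
#' variety (`0/0`, `0/1`, `1/1` or `./.`). Files with a tab in the header
#' are split on tabs (variety names may then contain spaces); otherwise any
#' whitespace separates columns. Rows with missing calls are excluded
#' before dosage conversion.
#'
#' @param path path to the text file.
#' @param drop_missing `"any"` (default) drops a row if any variety call is
#'   missing, guaranteeing complete panel profiles; `"all"` drops only rows
#'   where every call is missing.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix_txt <- function(path, drop_missing = c("any", "all")) {
  drop_missing <- match.arg(drop_missing)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty genotype matrix file")
  sep_split <- if (grepl("\t", lines[1], fixed = TRUE)) {
    function(l) strsplit(l, "\t", fixed = TRUE)
  } else {
    function(l) strsplit(trimws(l), "[[:space:]]+")
  }
  header <- sep_split(lines[1])[[1]]
  if (length(header) < 4L || toupper(header[1]) != "CHROM" ||
      toupper(header[2]) != "POS") {
    stop("genotype matrix header must start with CHROM POS and have >= 2 varieties")
  }
  varieties <- header[-(1:2)]
  rows <- sep_split(lines[-1])
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    stop("genotype matrix row ", which(nf != length(header))[1] + 1L,
         " has ", nf[nf != length(header)][1], " columns, expected ",
         length(header))
  }
  m <- matrix(unlist(rows), ncol = length(header), byrow = TRUE)
  gt <- matrix(normalize_gt(m[, -(1:2), drop = FALSE]),
               nrow = nrow(m), dimnames = list(NULL, varieties))
  miss <- gt == "./."
  keep <- if (drop_missing == "any") rowSums(miss) == 0L else rowSums(miss) < ncol(gt)
  if (drop_missing == "all" && any(rowSums(miss[keep, , drop = FALSE]) > 0L)) {
    stop("rows with partially missing calls remain under drop_missing = ",
         "'all'; they cannot form complete dosage profiles (use 'any')")
  }
  snps <- data.frame(chrom = m[keep, 1], pos = as.integer(m[keep, 2]),
                     stringsAsFactors = FALSE)
  genotype_matrix(snps, gt_to_dose(gt[keep, , drop = FALSE]))
}

#' Write a genotype matrix in CHROM/POS/varieties text format
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix_txt <- function(gm, path) {
  gt <- dose_to_gt(gm$dose)
  lines <- c(paste(c("CHROM", "POS", gm$varieties), collapse = "\t"),
             paste(gm$snps$chrom, gm$snps$pos,
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Build a genotype dosage matrix from a variant set
#'
#' Restricts to biallelic SNP records and converts GT calls to alternate
#' allele dosage. With `drop_missing = "any"` (the panel-selection
#' contract) rows with any missing call are excluded; `"none"` keeps `NA`
#' entries for diversity statistics that use pairwise deletion.
#'
#' @param x a [variant_set()].
#' @param drop_missing `"any"`, `"all"` or `"none"`.
#' @return a [genotype_matrix()] for `"any"`/`"all"`; for `"none"` a list
#'   with `snps` and the `NA`-containing integer `dose` matrix.
#' @export
vcf_to_genotype_matrix <- function(x, drop_missing = c("any", "all", "none")) {
  drop_missing <- match.arg(drop_missing)
  cls <- classify_variants(x)
  bial <- cls == "SNP" & !grepl(",", x$variants$alt, fixed = TRUE)
  v <- x$variants[bial, , drop = FALSE]
  dose <- gt_to_dose(x$gt[bial, , drop = FALSE])
  snps <- data.frame(chrom = v$chrom, pos = v$pos, stringsAsFactors = FALSE)
  if (drop_missing == "none") {
    return(list(snps = snps, dose = dose))
  }
  miss <- is.na(dose)
  keep <- if (drop_missing == "any") rowSums(miss) == 0L else rowSums(miss) < ncol(dose)
  genotype_matrix(snps[keep, , drop = FALSE], dose[keep, , drop = FALSE])
}
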