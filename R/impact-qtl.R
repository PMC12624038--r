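#' Extract HIGH-impact variant annotations
#'
#' Parses the ANN string of every record and emits one row per
#' (record, HIGH-impact annotation) pair: gene id, position, effect terms
#' and the per-variety carrier states taken from GT. HIGH annotations with
#' an empty gene id are kept under the sentinel id `"unassigned_gene"`
#' with a warning.
#'
#' @param x a [variant_set()] whose records carry ANN strings.
#' @return data.frame with columns `gene_id`, `chrom`, `pos`, `ref`,
#'   `allele`, `effect`; attribute `carriers` is a character matrix (rows
#'   aligned with the output) of per-variety states in
#'   \{hom-ref, het, hom-alt, missing\}.
#' @export
extract_high_impact <- function(x) {
  v <- x$variants
  rows <- list()
  carrier_rows <- list()
  states <- NULL
  for (i in seq_len(nrow(v))) {
    if (is.na(v$ann[i])) next
    ann <- parse_ann_field(v$ann[i])
    high <- ann[ann$impact == "HIGH", , drop = FALSE]
    if (nrow(high) == 0L) next
    blank <- !nzchar(high$gene_id)
    if (any(blank)) {
      warning("HIGH annotation with empty gene id at ", v$chrom[i], ":",
              v$pos[i], "; using sentinel 'unassigned_gene'")
      high$gene_id[blank] <- "unassigned_gene"
    }
    st <- gt_state(x$gt[i, ])
    for (r in seq_len(nrow(high))) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = high$gene_id[r], chrom = v$chrom[i], pos = v$pos[i],
        ref = v$ref[i], allele = high$allele[r], effect = high$effect[r],
        stringsAsFactors = FALSE)
      carrier_rows[[length(carrier_rows) + 1L]] <- st
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      allele = character(0), effect = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "carriers") <- matrix(character(0), 0, length(x$samples),
                                    dimnames = list(NULL, x$samples))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "carriers") <- matrix(unlist(carrier_rows), ncol = length(x$samples),
                                  byrow = TRUE,
                                  dimnames = list(NULL, x$samples))
  out
}

#' Screen HIGH-impact gene positions against QTL intervals
#'
#' A QTL interval matches a gene iff it lies on the same chromosome and
#' `start <= pos <= end` (1-based, end-inclusive) for at least one of the
#' gene's HIGH-impact positions. A gene's QTL list is the union over all
#' its positions; duplicate qtl ids in the source table are counted as
#' listed unless `dedup_qtls`. Genes matching no interval are reported
#' with empty lists unless `drop_unmatched`.
#'
#' @param impacts output of [extract_high_impact()].
#' @param qtls validated QTL table from [read_qtl_table()].
#' @param drop_unmatched drop genes with zero matching QTLs
#'   (default `FALSE`).
#' @param dedup_qtls collapse duplicate qtl ids per gene (default
#'   `FALSE`, matching tables that list an id once per interval).
#' @return data.frame sorted by gene: `gene_id`, `chrom`, `positions`
#'   (comma-joined), `ea_qtls`, `sr_qtls` (comma-joined, sorted),
#'   `n_ea`, `n_sr`, `total_qtls` (= `n_ea + n_sr`).
#' @export
overlap_with_qtls <- function(impacts, qtls, drop_unmatched = FALSE,
                              dedup_qtls = FALSE) {
  genes <- unique(impacts$gene_id)
  if (length(genes) == 0L || nrow(qtls) == 0L) {
    hits <- data.frame(gene = character(0), qtl = integer(0))
  } else {
    gr_pos <- GenomicRanges::GRanges(
      seqnames = norm_chrom(impacts$chrom),
      ranges = IRanges::IRanges(start = impacts$pos, width = 1L))
    gr_qtl <- GenomicRanges::GRanges(
      seqnames = norm_chrom(qtls$chrom),
      ranges = IRanges::IRanges(start = qtls$start, end = qtls$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_pos, gr_qtl))
    hits <- data.frame(gene = impacts$gene_id[S4Vectors::queryHits(ov)],
                       qtl = S4Vectors::subjectHits(ov),
                       stringsAsFactors = FALSE)
  }
  out <- lapply(sort(genes), function(g) {
    # union over the gene's positions: one count per source-table row,
    # unless deduplicating ids
    qi <- unique(hits$qtl[hits$gene == g])
    ids <- qtls$qtl_id[qi]
    cat_ <- qtls$category[qi]
    if (dedup_qtls) {
      keep <- !duplicated(ids)
      ids <- ids[keep]
      cat_ <- cat_[keep]
    }
    o <- order(ids)
    ids <- ids[o]
    cat_ <- cat_[o]
    data.frame(gene_id = g,
               chrom = paste(sort(unique(impacts$chrom[impacts$gene_id == g])),
                             collapse = ","),
               positions = paste(sort(unique(impacts$pos[impacts$gene_id == g])),
                                 collapse = ","),
               ea_qtls = paste(ids[cat_ == "EA"], collapse = ","),
               sr_qtls = paste(ids[cat_ == "SR"], collapse = ","),
               n_ea = sum(cat_ == "EA"), n_sr = sum(cat_ == "SR"),
               total_qtls = length(ids), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      positions = character(0), ea_qtls = character(0),
                      sr_qtls = character(0), n_ea = integer(0),
                      n_sr = integer(0), total_qtls = integer(0))
  }
  if (drop_unmatched) out <- out[out$total_qtls > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene, per-variety carrier report
#'
#' Long-format table of carrier states for every HIGH-impact position:
#' hom-ref, het, hom-alt or missing (never imputed).
#'
#' @param impacts output of [extract_high_impact()].
#' @return data.frame with columns `gene_id`, `chrom`, `pos`, `variety`,
#'   `state`.
#' @export
carriers_report <- function(impacts) {
  carriers <- attr(impacts, "carriers")
  if (is.null(carriers)) stop("impacts must carry the 'carriers' attribute")
  if (nrow(impacts) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), variety = character(0),
                      state = character(0)))
  }
  varieties <- colnames(carriers)
  out <- data.frame(
    gene_id = rep(impacts$gene_id, each = length(varieties)),
    chrom = rep(impacts$chrom, each = length(varieties)),
    pos = rep(impacts$pos, each = length(varieties)),
    variety = rep(varieties, times = nrow(impacts)),
    state = as.vector(t(carriers)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
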