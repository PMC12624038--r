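#' Hard-filter policies for SNPs and InDels
#'
#' GATK-style hard filtering removes a record when any quality annotation
#' violates its threshold. Comparisons are strict, exactly as the
#' conditions are conventionally written: a SNP is removed iff
#' QD < 5, SOR > 3, FS > 50, MQ < 50, MQRankSum < -2.5,
#' ReadPosRankSum < -1.0 or ReadPosRankSum > 3.5; an InDel iff QD < 2.0,
#' FS > 200.0 or ReadPosRankSum < -20.0. Values exactly equal to a
#' threshold therefore pass.
#'
#' GATK only emits the rank-sum annotations at sites with heterozygous
#' carriers, so by default an absent metric never triggers removal
#' (`missing_metric_passes = TRUE`); set it to `FALSE` to remove records
#' lacking any required metric.
#'
#' @param variant_class `"snp"` or `"indel"`.
#' @param missing_metric_passes logical; see above.
#' @param ... named threshold overrides (SNP: `qd_min`, `sor_max`,
#'   `fs_max`, `mq_min`, `mqrs_min`, `rprs_min`, `rprs_max`; InDel:
#'   `qd_min`, `fs_max`, `rprs_min`).
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(variant_class = c("snp", "indel"),
                          missing_metric_passes = TRUE, ...) {
  variant_class <- match.arg(variant_class)
  thr <- if (variant_class == "snp") {
    list(qd_min = 5, sor_max = 3, fs_max = 50, mq_min = 50,
         mqrs_min = -2.5, rprs_min = -1.0, rprs_max = 3.5)
  } else {
    list(qd_min = 2.0, fs_max = 200.0, rprs_min = -20.0)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(thr))
  if (length(unknown)) stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  thr[names(over)] <- over
  if (any(!is.finite(unlist(thr)))) stop("thresholds must be finite")
  if (variant_class == "snp" && thr$rprs_min >= thr$rprs_max) {
    stop("rprs_min must be below rprs_max")
  }
  structure(list(variant_class = variant_class, thresholds = thr,
                 missing_metric_passes = missing_metric_passes),
            class = "filter_policy")
}

#' Classify variant records as SNP, INDEL or MIXED
#'
#' A record is a SNP iff the reference and every alternate allele have
#' length 1; an INDEL iff every alternate allele differs in length from
#' the reference; MIXED otherwise (e.g. a SNP and an insertion at one
#' site).
#'
#' @param x a [variant_set()].
#' @return character vector in `{"SNP", "INDEL", "MIXED"}`, one per record.
#' @export
classify_variants <- function(x) {
  v <- x$variants
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  rl <- nchar(v$ref)
  vapply(seq_along(alts), function(i) {
    al <- nchar(alts[[i]])
    if (rl[i] == 1L && all(al == 1L)) "SNP"
    else if (all(al != rl[i])) "INDEL"
    else "MIXED"
  }, character(1))
}

#' Split a variant set into SNP, InDel and mixed subsets
#'
#' @param x a [variant_set()].
#' @return list with elements `snp`, `indel`, `mixed`, each a `variant_set`.
#' @export
split_by_class <- function(x) {
  cls <- classify_variants(x)
  list(snp = subset_variants(x, cls == "SNP"),
       indel = subset_variants(x, cls == "INDEL"),
       mixed = subset_variants(x, cls == "MIXED"))
}

# condition table: metric column, direction, threshold name, label
snp_conditions <- data.frame(
  metric = c("qd", "sor", "fs", "mq", "mq_rank_sum",
             "read_pos_rank_sum", "read_pos_rank_sum"),
  dir = c("lt", "gt", "gt", "lt", "lt", "lt", "gt"),
  thr = c("qd_min", "sor_max", "fs_max", "mq_min", "mqrs_min",
          "rprs_min", "rprs_max"),
  label = c("QD", "SOR", "FS", "MQ", "MQRankSum",
            "ReadPosRankSum_low", "ReadPosRankSum_high"),
  stringsAsFactors = FALSE)

indel_conditions <- data.frame(
  metric = c("qd", "fs", "read_pos_rank_sum"),
  dir = c("lt", "gt", "lt"),
  thr = c("qd_min", "fs_max", "rprs_min"),
  label = c("QD", "FS", "ReadPosRankSum"),
  stringsAsFactors = FALSE)

#' Apply a hard-filter policy to a variant stream
#'
#' Every record must already belong to the policy's variant class (use
#' [split_by_class()] first). A record is removed iff at least one
#' condition fails; the report attributes each removal to the first
#' failing condition in the fixed order QD, SOR, FS, MQ, MQRankSum,
#' ReadPosRankSum (low, then high).
#'
#' @param x a [variant_set()] of records of one class.
#' @param policy a [filter_policy()]; defaults to the standard policy for
#'   `class`.
#' @param class `"snp"` or `"indel"`, used when `policy` is `NULL`.
#' @return list with `retained` (a `variant_set`) and `report` (class
#'   `filter_report`: `n_input`, `n_retained`, `n_removed`, per-condition
#'   tallies `by_condition`, and per-record `verdicts` with the first
#'   failing condition).
#' @export
hard_filter <- function(x, policy = NULL, class = c("snp", "indel")) {
  class <- match.arg(class)
  if (is.null(policy)) policy <- filter_policy(class)
  cls <- classify_variants(x)
  want <- toupper(policy$variant_class)
  if (any(cls != want)) {
    stop("record ", which(cls != want)[1], " is ", cls[cls != want][1],
         ", not ", want, "; split by class before filtering")
  }
  cond <- if (policy$variant_class == "snp") snp_conditions else indel_conditions
  n <- n_variants(x)
  fail <- matrix(FALSE, n, nrow(cond))
  for (j in seq_len(nrow(cond))) {
    val <- x$variants[[cond$metric[j]]]
    thr <- policy$thresholds[[cond$thr[j]]]
    fj <- if (cond$dir[j] == "lt") val < thr else val > thr
    fj[is.na(val)] <- !policy$missing_metric_passes
    fail[, j] <- fj
  }
  removed <- rowSums(fail) > 0L
  first_fail <- apply(fail, 1, function(f) {
    i <- which(f)
    if (length(i)) cond$label[i[1]] else NA_character_
  })
  tallies <- table(factor(first_fail[removed], levels = cond$label))
  report <- structure(list(
    n_input = n, n_retained = sum(!removed), n_removed = sum(removed),
    by_condition = stats::setNames(as.integer(tallies), cond$label),
    missing_metric_passes = policy$missing_metric_passes,
    verdicts = data.frame(chrom = x$variants$chrom, pos = x$variants$pos,
                          removed = removed, reason = first_fail,
                          stringsAsFactors = FALSE)),
    class = "filter_report")
  list(retained = subset_variants(x, !removed), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("hard filter:", x$n_input, "in,", x$n_retained, "retained,",
      x$n_removed, "removed",
      if (x$missing_metric_passes) "(absent metrics pass)\n" else
        "(absent metrics fail)\n")
  for (k in names(x$by_condition)) {
    if (x$by_condition[[k]] > 0) cat("  ", k, ":", x$by_condition[[k]], "\n")
  }
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path; columns `condition`, `n_removed`.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(
    data.frame(condition = names(report$by_condition),
               n_removed = unname(report$by_condition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
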