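#' Genotype dosage matrix for panel selection
#'
#' SNPs in rows, varieties in columns, entries the alternate-allele dosage
#' 0 ("0/0"), 1 ("0/1") or 2 ("1/1"). No missing entries are allowed:
#' rows with missing calls are excluded upstream so every variety profile
#' is complete. Heterozygous calls are a distinct state from both
#' homozygotes for discrimination.
#'
#' @param snps data.frame with columns `chrom`, `pos`.
#' @param dose integer matrix, `nrow(snps)` x varieties, entries 0/1/2,
#'   with variety column names.
#' @return object of class `genotype_matrix` with components `snps`,
#'   `dose`, `varieties` and `keys` (`"chrom:pos"` strings).
#' @export
genotype_matrix <- function(snps, dose) {
  stopifnot(is.data.frame(snps), nrow(snps) == nrow(dose))
  if (is.null(colnames(dose))) stop("dose must have variety column names")
  if (anyNA(dose)) stop("genotype_matrix cannot contain missing entries")
  if (!all(dose %in% 0:2)) stop("dosages must be 0, 1 or 2")
  keys <- paste0(snps$chrom, ":", snps$pos)
  if (anyDuplicated(keys)) stop("duplicate SNP keys")
  rownames(snps) <- NULL
  dose <- matrix(as.integer(dose), nrow = nrow(snps),
                 dimnames = list(keys, colnames(dose)))
  structure(list(snps = snps, dose = dose, varieties = colnames(dose),
                 keys = keys),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$keys), "SNPs x",
      length(x$varieties), "varieties\n")
  invisible(x)
}

panel_profiles <- function(gm, panel) {
  idx <- match(panel, gm$keys)
  if (anyNA(idx)) stop("unknown SNP key(s): ",
                       paste(panel[is.na(idx)], collapse = ", "))
  sub <- gm$dose[idx, , drop = FALSE]
  apply(sub, 2, paste, collapse = ",")
}

all_pairs <- function(varieties) {
  idx <- utils::combn(length(varieties), 2)
  data.frame(a = varieties[idx[1, ]], b = varieties[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Validate a candidate SNP panel
#'
#' Restricts each variety's genotype vector to the panel and checks
#' whether all profiles are pairwise distinct. `discriminating` is `TRUE`
#' iff the number of distinct profiles equals the number of varieties,
#' equivalently iff `unresolved_pairs` is empty.
#'
#' @param gm a [genotype_matrix()].
#' @param panel character vector of `"chrom:pos"` keys, non-empty subset
#'   of `gm$keys`.
#' @return object of class `panel_result`: list with `panel`, `profiles`
#'   (named character vector of comma-joined dosage tuples),
#'   `discriminating`, `unresolved_pairs` (data.frame `a`, `b`),
#'   `method = "VALIDATE"`.
#' @export
validate_panel <- function(gm, panel) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  prof <- panel_profiles(gm, panel)
  pr <- all_pairs(gm$varieties)
  same <- prof[pr$a] == prof[pr$b]
  structure(list(panel = panel, profiles = prof,
                 discriminating = !any(same),
                 unresolved_pairs = pr[same, , drop = FALSE],
                 method = "VALIDATE"),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("panel_result [", x$method, "]: ", length(x$panel), " SNP(s), ",
      if (x$discriminating) "discriminating"
      else paste0(nrow(x$unresolved_pairs), " unresolved pair(s)"),
      "\n", sep = "")
  invisible(x)
}

# logical SNPs x pairs matrix: does SNP s resolve pair p?
resolution_matrix <- function(gm) {
  idx <- utils::combn(length(gm$varieties), 2)
  res <- gm$dose[, idx[1, ], drop = FALSE] != gm$dose[, idx[2, ], drop = FALSE]
  dimnames(res) <- list(gm$keys,
                        paste(gm$varieties[idx[1, ]], gm$varieties[idx[2, ]],
                              sep = "|"))
  res
}

#' Per-SNP pair-resolution table
#'
#' For each SNP, the variety pairs whose dosages differ at it. The union
#' of resolved pairs over all SNPs covers every pair iff the full matrix
#' is discriminating.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `snp_key`, `n_pairs_resolved`, and a
#'   list-column `pairs` of character vectors `"a|b"`.
#' @export
pair_resolution_table <- function(gm) {
  res <- resolution_matrix(gm)
  out <- data.frame(snp_key = gm$keys,
                    n_pairs_resolved = rowSums(res),
                    stringsAsFactors = FALSE)
  out$pairs <- lapply(seq_len(nrow(res)), function(i) colnames(res)[res[i, ]])
  out
}

#' Exact minimum discriminating panel by exhaustive search
#'
#' Enumerates subsets of the SNP set in increasing size (lexicographic
#' order within a size, so ties break toward the earliest keys) and
#' returns the first discriminating subset — a certified minimum-
#' cardinality panel. A pair resolvable by no SNP proves impossibility
#' immediately. Search is capped at `max_exact_snps` SNPs; larger
#' matrices should use [crs_min_panel()].
#'
#' @param gm a [genotype_matrix()].
#' @param max_exact_snps cap on the number of SNP rows (default 25).
#' @return a `panel_result` with `method = "EXACT"`; when even the full
#'   matrix fails, `discriminating = FALSE` with the full-matrix
#'   unresolved pairs.
#' @export
exact_min_panel <- function(gm, max_exact_snps = 25) {
  s <- length(gm$keys)
  if (s > max_exact_snps) {
    stop("matrix has ", s, " SNPs, above the exact-search cap of ",
         max_exact_snps, "; use crs_min_panel()")
  }
  res <- resolution_matrix(gm)
  if (any(colSums(res) == 0L)) {
    full <- validate_panel(gm, gm$keys)
    full$method <- "EXACT"
    return(full)
  }
  storage.mode(res) <- "double"
  n_pairs <- ncol(res)
  for (k in seq_len(s)) {
    subs <- utils::combn(s, k)
    for (ci in seq_len(ncol(subs))) {
      pick <- subs[, ci]
      covered <- if (k == 1L) res[pick, ] > 0 else colSums(res[pick, , drop = FALSE]) > 0
      if (all(covered)) {
        out <- validate_panel(gm, gm$keys[pick])
        out$method <- "EXACT"
        return(out)
      }
    }
  }
  full <- validate_panel(gm, gm$keys) # unreachable when pairs coverable
  full$method <- "EXACT"
  full
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Minimal discriminating panel by conditional random selection
#'
#' Seeded greedy random-restart heuristic for small discriminating SNP
#' panels. Each trial shuffles the SNP order with a seed derived from
#' `seed + trial`, greedily adds the SNP resolving the most still-
#' unresolved variety pairs (ties go to the earlier SNP in the shuffled
#' order), then backward-prunes members whose removal keeps the panel
#' discriminating. The smallest panel over all trials is returned (ties:
#' first found). The result always satisfies [validate_panel()] and can
#' never beat the certified optimum of [exact_min_panel()].
#'
#' @param gm a [genotype_matrix()] with pairwise-distinct variety columns
#'   (otherwise a non-discriminating result is returned immediately).
#' @param n_trials number of random restarts (default 1000).
#' @param seed integer seed; identical (matrix, seed, n_trials) give
#'   identical results.
#' @param prune backward-prune redundant panel members (default `TRUE`).
#' @return a `panel_result` with `method = "CRS"`, plus `trials_used` and
#'   `seed`.
#' @export
crs_min_panel <- function(gm, n_trials = 1000, seed = 1, prune = TRUE) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  res <- resolution_matrix(gm)
  if (any(colSums(res) == 0L)) {
    full <- validate_panel(gm, gm$keys)
    full$method <- "CRS"
    full$trials_used <- 0L
    full$seed <- seed
    return(full)
  }
  storage.mode(res) <- "double"
  s <- nrow(res)
  n_pairs <- ncol(res)
  best <- NULL
  for (trial in seq_len(n_trials)) {
    ord <- with_local_seed(seed + trial, sample.int(s))
    rs <- res[ord, , drop = FALSE]
    unresolved <- rep(1, n_pairs)
    picked <- integer(0)
    while (sum(unresolved) > 0) {
      gain <- as.vector(rs %*% unresolved)
      gain[picked] <- -1
      j <- which.max(gain) # ties: earliest in shuffled order
      picked <- c(picked, j)
      unresolved <- unresolved * (1 - rs[j, ])
    }
    if (prune && length(picked) > 1L) {
      for (j in picked) {
        rest <- setdiff(picked, j)
        if (all(colSums(rs[rest, , drop = FALSE]) > 0)) picked <- rest
      }
    }
    if (is.null(best) || length(picked) < length(best)) {
      best <- ord[picked]
    }
  }
  out <- validate_panel(gm, gm$keys[sort(best)])
  out$method <- "CRS"
  out$trials_used <- as.integer(n_trials)
  out$seed <- as.integer(seed)
  out
}

#' Write a panel result as TSV
#'
#' One row per variety with its `"0/0|0/1|1/1"` profile over the panel.
#'
#' @param result a `panel_result`.
#' @param gm the [genotype_matrix()] it was computed from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(result, gm, path) {
  idx <- match(result$panel, gm$keys)
  gt <- dose_to_gt(gm$dose[idx, , drop = FALSE])
  prof <- apply(gt, 2, paste, collapse = "|")
  utils::write.table(
    data.frame(variety = gm$varieties,
               profile = prof[gm$varieties],
               panel = paste(result$panel, collapse = ","),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
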