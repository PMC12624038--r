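#' Specification for a synthetic joint-genotyped cohort
#'
#' Describes the statistical structure of a synthetic multi-sample cohort
#' with fully known ground truth: two relatedness clusters whose allele
#' frequencies diverge under a Balding-Nichols model, a high-SNP-density
#' subgroup inside the first cluster (emulating a Basmati-like quartet
#' whose extra diversity concentrates in "signature" windows), records
#' planted to fail exactly one hard-filter condition each, a planted
#' minimal discriminating SNP panel of known size (certified by the exact
#' solver at generation time), missing genotypes at a stated rate, and
#' HIGH-impact annotations at positions inside and outside QTL intervals.
#'
#' Defaults are desk-scale: 12 chromosomes of 1 Mb keep a full pipeline
#' run in seconds while preserving every structural feature the analysis
#' exercises.
#'
#' @param n_varieties number of varieties (default 22).
#' @param chromosomes data.frame `chrom`, `length` (default 12 x 1 Mb).
#' @param n_cluster1 size of the first relatedness cluster (default 6).
#' @param subgroup_size high-density subgroup inside cluster 1 (default 4).
#' @param fst_between,fst_within Balding-Nichols divergence between the
#'   two clusters and of the subgroup within cluster 1 (defaults 0.3,
#'   0.05).
#' @param snp_rate,indel_rate variants per bp (defaults 5e-4, 1e-4).
#' @param ti_tv transition/transversion ratio of simulated SNPs
#'   (default 2.5).
#' @param missing_rate per-genotype missingness probability
#'   (default 0.02).
#' @param signature_frac fraction of windows per chromosome in which
#'   subgroup allele frequencies are enriched (default 0.3).
#' @param window_size window width used to lay out signature windows
#'   (default 100,000).
#' @param filter_fail_plan named counts of SNP records planted to fail
#'   exactly one condition: QD, SOR, FS, MQ, MQRankSum,
#'   ReadPosRankSum_low, ReadPosRankSum_high.
#' @param indel_fail_plan named counts for InDels: QD, FS, ReadPosRankSum.
#' @param planted_panel_size size of the planted minimal discriminating
#'   panel (default 5).
#' @param n_high_impact_genes,n_high_impact number of genes and of
#'   HIGH-impact annotations planted (defaults 10 and 12).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_varieties = 22,
                        chromosomes = data.frame(
                          chrom = as.character(1:12), length = 1000000L,
                          stringsAsFactors = FALSE),
                        n_cluster1 = 6, subgroup_size = 4,
                        fst_between = 0.3, fst_within = 0.05,
                        snp_rate = 5e-4, indel_rate = 1e-4,
                        ti_tv = 2.5, missing_rate = 0.02,
                        signature_frac = 0.3, window_size = 100000,
                        filter_fail_plan = c(QD = 3, SOR = 2, FS = 1,
                                             MQ = 1, MQRankSum = 1,
                                             ReadPosRankSum_low = 1,
                                             ReadPosRankSum_high = 1),
                        indel_fail_plan = c(QD = 2, FS = 1,
                                            ReadPosRankSum = 1),
                        planted_panel_size = 5,
                        n_high_impact_genes = 10, n_high_impact = 12,
                        seed = 1) {
  stopifnot(subgroup_size <= n_cluster1, n_cluster1 < n_varieties,
            snp_rate >= 0, indel_rate >= 0, missing_rate >= 0,
            missing_rate < 1, planted_panel_size >= 1,
            n_high_impact >= n_high_impact_genes)
  stopifnot(all(names(filter_fail_plan) %in% snp_conditions$label),
            all(names(indel_fail_plan) %in% indel_conditions$label))
  structure(as.list(environment()), class = "cohort_spec")
}

# Balding-Nichols draw of a derived population frequency around p
bn_freq <- function(p, fst) {
  shape <- (1 - fst) / fst
  stats::rbeta(length(p), p * shape, (1 - p) * shape)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

draw_alleles <- function(n, ti_tv) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is_ti <- stats::runif(n) < ti_tv / (ti_tv + 1)
  alt <- ifelse(is_ti, transition_of[ref], NA)
  for (i in which(!is_ti)) {
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"),
                             c(ref[i], transition_of[ref[i]])), 1)
  }
  list(ref = ref, alt = unname(alt))
}

# passing-range INFO metric draws, rounded to 3 decimals for exact text
# round-trips
draw_passing_metrics <- function(n) {
  data.frame(
    qd = round(stats::runif(n, 6, 35), 3),
    sor = round(stats::runif(n, 0.2, 2.5), 3),
    fs = round(stats::runif(n, 0, 40), 3),
    mq = round(stats::runif(n, 52, 60), 3),
    mq_rank_sum = round(stats::runif(n, -2, 2), 3),
    read_pos_rank_sum = round(stats::runif(n, -0.8, 3.2), 3))
}

failing_metric_value <- function(condition) {
  switch(condition,
         QD = round(stats::runif(1, 0.2, 4.5), 3),
         SOR = round(stats::runif(1, 3.5, 6), 3),
         FS = round(stats::runif(1, 60, 120), 3),
         MQ = round(stats::runif(1, 20, 45), 3),
         MQRankSum = round(stats::runif(1, -8, -3), 3),
         ReadPosRankSum_low = round(stats::runif(1, -6, -1.5), 3),
         ReadPosRankSum_high = round(stats::runif(1, 4, 8), 3),
         stop("unknown condition ", condition))
}

condition_metric <- c(QD = "qd", SOR = "sor", FS = "fs", MQ = "mq",
                      MQRankSum = "mq_rank_sum",
                      ReadPosRankSum_low = "read_pos_rank_sum",
                      ReadPosRankSum_high = "read_pos_rank_sum",
                      ReadPosRankSum = "read_pos_rank_sum")

# indel failing values reuse the indel thresholds
failing_indel_value <- function(condition) {
  switch(condition,
         QD = round(stats::runif(1, 0.1, 1.8), 3),
         FS = round(stats::runif(1, 220, 400), 3),
         ReadPosRankSum = round(stats::runif(1, -40, -22), 3),
         stop("unknown condition ", condition))
}

#' Plant a discriminating dosage panel of certified minimal size
#'
#' Constructs a `size` x `n_varieties` dosage matrix whose full SNP set
#' discriminates every variety while no proper subset does: for each SNP
#' a "twin" pair of varieties differs only at that SNP, so dropping any
#' SNP collapses its twins, and the remaining profiles are drawn
#' distinct. The construction is verified with [exact_min_panel()] and
#' redrawn (up to `max_attempts`) until certified.
#'
#' @param n_varieties number of varieties (needs `>= 2 * size + 1`).
#' @param size panel size to plant.
#' @param varieties optional variety names.
#' @param max_attempts redraw budget (default 1000).
#' @return integer dosage matrix, `size` x `n_varieties`, entries 0/1/2.
#' @export
plant_panel_profiles <- function(n_varieties, size,
                                 varieties = sprintf("VAR%02d", seq_len(n_varieties)),
                                 max_attempts = 1000) {
  if (n_varieties < 2 * size + 1) {
    stop("need at least 2*size+1 varieties to plant twins for every SNP")
  }
  if (3^size < n_varieties) {
    stop("3^size distinct profiles cannot cover ", n_varieties, " varieties")
  }
  # full profile space, one column per candidate profile
  space <- t(as.matrix(expand.grid(rep(list(0:2), size))))
  for (attempt in seq_len(max_attempts)) {
    base <- space[, sample(ncol(space), size), drop = FALSE]
    prof <- matrix(0L, size, n_varieties)
    # twin pair for SNP j: varieties 2j-1 and 2j differ only at row j
    for (j in seq_len(size)) {
      prof[, 2L * j - 1L] <- base[, j]
      twin <- base[, j]
      twin[j] <- (twin[j] + sample(1:2, 1)) %% 3L
      prof[, 2L * j] <- twin
    }
    key <- function(m) apply(m, 2, paste, collapse = ",")
    if (anyDuplicated(key(prof[, seq_len(2L * size), drop = FALSE]))) next
    # fill the rest without replacement from the unused profile space
    unused <- setdiff(key(space), key(prof[, seq_len(2L * size), drop = FALSE]))
    extra <- sample(unused, n_varieties - 2L * size)
    prof[, (2L * size + 1L):n_varieties] <-
      vapply(strsplit(extra, ",", fixed = TRUE),
             function(p) as.integer(p), integer(size))
    colnames(prof) <- varieties
    gm <- genotype_matrix(data.frame(chrom = "0",
                                     pos = seq_len(size)), prof)
    sol <- exact_min_panel(gm)
    if (sol$discriminating && length(sol$panel) == size) {
      return(prof)
    }
  }
  stop("could not plant a certified minimal panel in ", max_attempts,
       " attempts")
}

#' Generate a synthetic joint-genotyped cohort with ground truth
#'
#' Emits (optionally to disk) a multi-sample VCF, a QTL interval table
#' and a chromosome-length table realizing a [cohort_spec()], together
#' with the ground truth every pipeline stage is tested against:
#' per-record filter verdicts, per-chromosome true counts, cluster and
#' subgroup labels, the planted panel keys with certified minimal size,
#' and the planted gene-QTL overlap table. Runs are deterministic: the
#' same spec always produces byte-identical files.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, writes `cohort.vcf`,
#'   `qtls.tsv`, `chroms.tsv` and `table4.txt` (the planted-panel
#'   genotype matrix in CHROM/POS text dialect).
#' @return list with `variants` (a [variant_set()]), `qtls`, `chroms`,
#'   `truth` (list described above) and, if written, `paths`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    V <- spec$n_varieties
    varieties <- sprintf("VAR%02d", seq_len(V))
    subgroup <- varieties[seq_len(spec$subgroup_size)]
    cluster1 <- varieties[seq_len(spec$n_cluster1)]
    cluster_of <- ifelse(varieties %in% cluster1, 1L, 2L)

    per_chrom <- lapply(seq_len(nrow(spec$chromosomes)), function(ci) {
      chrom <- spec$chromosomes$chrom[ci]
      len <- spec$chromosomes$length[ci]
      n_snp <- round(len * spec$snp_rate)
      n_indel <- round(len * spec$indel_rate)
      n_win <- ceiling(len / spec$window_size)
      sig_windows <- sort(sample.int(n_win, max(1, round(spec$signature_frac * n_win))))
      pos_all <- sort(sample.int(len, n_snp + n_indel))
      snp_sel <- sort(sample.int(length(pos_all), n_snp))
      pos_snp <- pos_all[snp_sel]
      pos_indel <- pos_all[-snp_sel]
      list(chrom = chrom, len = len, pos_snp = pos_snp,
           pos_indel = pos_indel, sig_windows = sig_windows,
           n_win = n_win)
    })

    gen_snp_doses <- function(n, in_sig) {
      p_anc <- stats::rbeta(n, 0.4, 1.2)
      p_c1 <- bn_freq(p_anc, spec$fst_between)
      p_c2 <- bn_freq(p_anc, spec$fst_between)
      p_sub <- bn_freq(pmin(pmax(p_c1, 1e-4), 1 - 1e-4), spec$fst_within)
      # subgroup enrichment inside signature windows raises its
      # non-reference density (the Basmati-like pattern)
      enrich <- in_sig
      p_sub[enrich] <- pmax(p_sub[enrich], stats::runif(sum(enrich), 0.3, 0.8))
      dose <- matrix(0L, n, V)
      for (v in seq_len(V)) {
        p <- if (varieties[v] %in% subgroup) p_sub
        else if (cluster_of[v] == 1L) p_c1 else p_c2
        dose[, v] <- stats::rbinom(n, 2, p)
      }
      dose
    }

    records <- list()
    truth_counts <- list()
    for (pc in per_chrom) {
      n_snp <- length(pc$pos_snp)
      n_indel <- length(pc$pos_indel)
      widx <- window_index(pc$pos_snp, spec$window_size)
      in_sig <- widx %in% pc$sig_windows
      al <- draw_alleles(n_snp, spec$ti_tv)
      dose <- gen_snp_doses(n_snp, in_sig)
      # keep every site polymorphic in the cohort so S bookkeeping is
      # non-trivial but planted counts stay exact
      mono <- rowSums(dose) == 0L
      if (any(mono)) {
        fix_var <- sample.int(V, sum(mono), replace = TRUE)
        dose[cbind(which(mono), fix_var)] <- 1L
      }
      gt <- dose_to_gt(dose)
      miss <- matrix(stats::runif(n_snp * V) < spec$missing_rate, n_snp, V)
      gt[miss] <- "./."
      met <- draw_passing_metrics(n_snp)
      snp_df <- data.frame(chrom = pc$chrom, pos = pc$pos_snp,
                           ref = al$ref, alt = al$alt, met,
                           ann = NA_character_, class = "SNP",
                           stringsAsFactors = FALSE)
      # indels: geometric signed lengths, mode |1|
      if (n_indel > 0) {
        ins <- stats::runif(n_indel) < 0.5
        ilen <- stats::rgeom(n_indel, 0.5) + 1L
        bases <- c("A", "C", "G", "T")
        anchor <- sample(bases, n_indel, replace = TRUE)
        extra <- vapply(ilen, function(k) {
          paste(sample(bases, k, replace = TRUE), collapse = "")
        }, character(1))
        iref <- ifelse(ins, anchor, paste0(anchor, extra))
        ialt <- ifelse(ins, paste0(anchor, extra), anchor)
        ip <- stats::rbeta(n_indel, 0.4, 1.2)
        idose <- matrix(stats::rbinom(n_indel * V, 2, rep(ip, V)), n_indel, V)
        imono <- rowSums(idose) == 0L
        idose[cbind(which(imono), sample.int(V, sum(imono), replace = TRUE))] <- 1L
        igt <- dose_to_gt(idose)
        imiss <- matrix(stats::runif(n_indel * V) < spec$missing_rate,
                        n_indel, V)
        igt[imiss] <- "./."
        imet <- draw_passing_metrics(n_indel)
        indel_df <- data.frame(chrom = pc$chrom, pos = pc$pos_indel,
                               ref = iref, alt = ialt, imet,
                               ann = NA_character_, class = "INDEL",
                               stringsAsFactors = FALSE)
      } else {
        indel_df <- snp_df[0, , drop = FALSE]
        indel_df$class <- character(0)
        igt <- gt[0, , drop = FALSE]
      }
      df <- rbind(snp_df, indel_df)
      g <- rbind(gt, igt)
      o <- order(df$pos)
      df <- df[o, , drop = FALSE]
      g <- g[o, , drop = FALSE]
      records[[pc$chrom]] <- list(df = df, gt = g)
      truth_counts[[pc$chrom]] <- data.frame(
        chrom = pc$chrom, n_snps = n_snp, n_indels = n_indel,
        stringsAsFactors = FALSE)
    }

    df <- do.call(rbind, lapply(records, `[[`, "df"))
    gt <- do.call(rbind, lapply(records, `[[`, "gt"))
    rownames(df) <- NULL

    # --- plant single-fault filter failures -------------------------------
    df$fail_condition <- NA_character_
    is_snp <- df$class == "SNP"
    snp_plan <- rep(names(spec$filter_fail_plan), spec$filter_fail_plan)
    pick_snp <- sample(which(is_snp), length(snp_plan))
    for (i in seq_along(snp_plan)) {
      r <- pick_snp[i]
      df[[condition_metric[[snp_plan[i]]]]][r] <- failing_metric_value(snp_plan[i])
      df$fail_condition[r] <- snp_plan[i]
    }
    indel_plan <- rep(names(spec$indel_fail_plan), spec$indel_fail_plan)
    pick_indel <- sample(which(!is_snp), length(indel_plan))
    for (i in seq_along(indel_plan)) {
      r <- pick_indel[i]
      df[[condition_metric[[indel_plan[i]]]]][r] <- failing_indel_value(indel_plan[i])
      df$fail_condition[r] <- indel_plan[i]
    }

    # --- plant the minimal discriminating panel ---------------------------
    prof <- plant_panel_profiles(V, spec$planted_panel_size, varieties)
    # spread panel SNPs across chromosomes, on fresh passing SNP records
    panel_rows <- integer(0)
    candidates <- which(is_snp & is.na(df$fail_condition))
    panel_rows <- sample(candidates, spec$planted_panel_size)
    for (j in seq_len(spec$planted_panel_size)) {
      gt[panel_rows[j], ] <- dose_to_gt(prof[j, ]) # complete, no missing
    }
    panel_keys <- paste0(df$chrom[panel_rows], ":", df$pos[panel_rows])

    # --- plant HIGH-impact annotations and QTLs ---------------------------
    hi_candidates <- setdiff(which(is_snp & is.na(df$fail_condition)),
                             panel_rows)
    hi_rows <- sort(sample(hi_candidates, spec$n_high_impact))
    genes <- sprintf("SYNGENE%02d", seq_len(spec$n_high_impact_genes))
    gene_of <- genes[c(seq_len(spec$n_high_impact_genes),
                       sample.int(spec$n_high_impact_genes,
                                  spec$n_high_impact - spec$n_high_impact_genes))]
    effects <- sample(c("stop_gained", "start_lost", "splice_donor_variant&intron_variant"),
                      spec$n_high_impact, replace = TRUE)
    df$ann[hi_rows] <- paste0(df$alt[hi_rows], "|", effects, "|HIGH|", gene_of)
    # known carrier states at HIGH sites: 2 het + 2 hom-alt, rest hom-ref
    for (idx in seq_along(hi_rows)) {
      r <- hi_rows[idx]
      st <- rep("0/0", V)
      who <- sample.int(V, 4)
      st[who[1:2]] <- "0/1"
      st[who[3:4]] <- "1/1"
      gt[r, ] <- st
    }
    # QTL intervals: half the genes covered by an EA interval, a subset
    # also by SR, plus decoy intervals that cover no HIGH site
    qtl <- list()
    covered <- logical(spec$n_high_impact)
    for (gi in seq_along(genes)) {
      rows_g <- hi_rows[gene_of == genes[gi]]
      if (gi %% 2 == 1) {
        for (r in rows_g) {
          qtl[[length(qtl) + 1L]] <- data.frame(
            qtl_id = sprintf("synEA-%02d", length(qtl) + 1L),
            chrom = df$chrom[r],
            start = max(1L, df$pos[r] - 5000L), end = df$pos[r] + 5000L,
            category = "EA", stringsAsFactors = FALSE)
          covered[match(r, hi_rows)] <- TRUE
        }
      }
      if (gi %% 4 == 1) {
        r <- rows_g[1]
        qtl[[length(qtl) + 1L]] <- data.frame(
          qtl_id = sprintf("synSR-%02d", length(qtl) + 1L),
          chrom = df$chrom[r], start = df$pos[r], # boundary: start == pos
          end = df$pos[r] + 20000L,
          category = "SR", stringsAsFactors = FALSE)
      }
    }
    for (k in 1:5) {
      ch <- sample(spec$chromosomes$chrom, 1)
      len <- spec$chromosomes$length[spec$chromosomes$chrom == ch]
      s <- sample.int(max(1L, len - 30000L), 1)
      qtl[[length(qtl) + 1L]] <- data.frame(
        qtl_id = sprintf("synDECOY-%02d", k), chrom = ch,
        start = s, end = s + 100L, category = sample(c("EA", "SR"), 1),
        stringsAsFactors = FALSE)
    }
    qtls <- do.call(rbind, qtl)
    # drop decoys that accidentally cover a HIGH site
    decoy <- startsWith(qtls$qtl_id, "synDECOY")
    hit_high <- vapply(seq_len(nrow(qtls)), function(i) {
      any(df$chrom[hi_rows] == qtls$chrom[i] &
            df$pos[hi_rows] >= qtls$start[i] &
            df$pos[hi_rows] <= qtls$end[i])
    }, logical(1))
    qtls <- qtls[!(decoy & hit_high), , drop = FALSE]
    rownames(qtls) <- NULL

    # --- assemble ---------------------------------------------------------
    o <- order(match(df$chrom, spec$chromosomes$chrom), df$pos)
    df <- df[o, , drop = FALSE]
    gt <- gt[o, , drop = FALSE]
    fail_condition <- df$fail_condition
    class_true <- df$class
    df$fail_condition <- NULL
    df$class <- NULL
    vs <- variant_set(df, gt, varieties)

    truth <- list(
      varieties = varieties, subgroup = subgroup,
      cluster = stats::setNames(cluster_of, varieties),
      class = class_true,
      fail_condition = fail_condition,
      counts = do.call(rbind, truth_counts),
      panel_keys = panel_keys, panel_size = spec$planted_panel_size,
      panel_dose = prof,
      high_impact = data.frame(gene_id = gene_of, chrom = df$chrom[match(hi_rows, o)],
                               pos = df$pos[match(hi_rows, o)],
                               effect = effects, stringsAsFactors = FALSE),
      signature_windows = lapply(per_chrom, `[[`, "sig_windows"))
    names(truth$signature_windows) <- spec$chromosomes$chrom

    out <- list(variants = vs, qtls = qtls, chroms = spec$chromosomes,
                truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                    qtls = file.path(out_dir, "qtls.tsv"),
                    chroms = file.path(out_dir, "chroms.tsv"))
      write_vcf(vs, paths$vcf, contigs = spec$chromosomes)
      utils::write.table(qtls, paths$qtls, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(spec$chromosomes, paths$chroms, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

#' Generate one dosage window of a prescribed frequency regime
#'
#' Test harness for diversity statistics: `"balanced"` draws site
#' frequencies near 0.5 (the balancing-selection signature that pushes
#' Tajima's D up), `"rare"` makes every site a singleton (one
#' heterozygous variety), `"monomorphic"` has no variation at all, and
#' `"neutral"` draws each site's alternate-allele count from the neutral
#' sample frequency spectrum (probability proportional to 1/k for k of
#' n-1 copies) with uniform assignment to haploid slots, so the expected
#' per-site diversity equals Watterson's theta and Tajima's D centers on
#' zero by construction.
#'
#' @param kind `"balanced"`, `"rare"`, `"monomorphic"` or `"neutral"`.
#' @param n_varieties number of varieties (columns).
#' @param n_sites number of sites (rows).
#' @param seed integer seed.
#' @return integer dosage matrix, sites x varieties.
#' @export
generate_popgen_window <- function(kind = c("balanced", "rare",
                                            "monomorphic", "neutral"),
                                   n_varieties, n_sites, seed = 1) {
  kind <- match.arg(kind)
  with_local_seed(seed, {
    dose <- matrix(0L, n_sites, n_varieties,
                   dimnames = list(NULL, sprintf("VAR%02d", seq_len(n_varieties))))
    if (kind == "neutral" && n_sites > 0) {
      n <- 2L * n_varieties
      k_levels <- seq_len(n - 1L)
      for (i in seq_len(n_sites)) {
        k <- sample(k_levels, 1, prob = 1 / k_levels)
        hap <- integer(n)
        hap[sample.int(n, k)] <- 1L
        dose[i, ] <- hap[seq(1, n, by = 2)] + hap[seq(2, n, by = 2)]
      }
    } else if (kind == "balanced" && n_sites > 0) {
      for (i in seq_len(n_sites)) {
        p <- stats::runif(1, 0.4, 0.6)
        d <- stats::rbinom(n_varieties, 2, p)
        # re-draw fixed sites so S equals n_sites by construction
        while (sum(d) == 0 || sum(d) == 2 * n_varieties) {
          d <- stats::rbinom(n_varieties, 2, p)
        }
        dose[i, ] <- d
      }
    } else if (kind == "rare" && n_sites > 0) {
      carrier <- sample.int(n_varieties, n_sites, replace = TRUE)
      dose[cbind(seq_len(n_sites), carrier)] <- 1L
    }
    dose
  })
}
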