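# Independent brute-force oracles and tiny in-code fixtures shared across
# test files. Oracles deliberately use naive loops / enumeration, never the
# package's vectorized code paths.

# build a small variant_set from a compact spec; metrics default to absent
make_vs <- function(chrom, pos, ref, alt, gt, samples = NULL, ...) {
  n <- length(pos)
  gt <- matrix(gt, nrow = n)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = ref, alt = alt,
                  qd = NA_real_, sor = NA_real_, fs = NA_real_,
                  mq = NA_real_, mq_rank_sum = NA_real_,
                  read_pos_rank_sum = NA_real_, ann = NA_character_,
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (k in names(extra)) v[[k]] <- extra[[k]]
  variant_set(v, gt, samples)
}

# explicit haplotype expansion: dose 0 -> (0,0), 1 -> (0,1), 2 -> (1,1),
# NA -> (NA,NA)
dose_to_haplotypes <- function(dose) {
  V <- ncol(dose)
  hap <- matrix(NA_integer_, nrow(dose), 2L * V)
  for (v in seq_len(V)) {
    d <- dose[, v]
    hap[, 2L * v - 1L] <- ifelse(is.na(d), NA_integer_, as.integer(d >= 1L))
    hap[, 2L * v] <- ifelse(is.na(d), NA_integer_, as.integer(d == 2L))
  }
  hap
}

# textbook Tajima's D by explicit pair enumeration over haploid alleles
oracle_tajima <- function(dose, max_missing = 1) {
  V <- ncol(dose)
  n <- 2L * V
  hap <- dose_to_haplotypes(dose)
  keep <- apply(hap, 1, function(h) mean(is.na(h)) <= max_missing &&
                  sum(!is.na(h)) >= 1)
  hap <- hap[keep, , drop = FALSE]
  S <- 0L
  pi <- 0
  for (i in seq_len(nrow(hap))) {
    h <- hap[i, !is.na(hap[i, ])]
    m <- length(h)
    if (m < 2) next
    diffs <- 0L
    for (a in 1:(m - 1)) for (b in (a + 1):m) diffs <- diffs + (h[a] != h[b])
    pi_site <- diffs / choose(m, 2)
    if (length(unique(h)) > 1) {
      S <- S + 1L
      pi <- pi + pi_site
    }
  }
  i <- 1:(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- if (S == 0) NA_real_ else (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, pi = pi, theta_w = S / a1, d = d)
}

# per-pair per-site allele-sharing distance loop
oracle_distance <- function(dose) {
  V <- ncol(dose)
  d <- matrix(0, V, V, dimnames = list(colnames(dose), colnames(dose)))
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      num <- 0
      den <- 0L
      for (s in seq_len(nrow(dose))) {
        if (!is.na(dose[s, i]) && !is.na(dose[s, j])) {
          num <- num + abs(dose[s, i] - dose[s, j])
          den <- den + 1L
        }
      }
      d[i, j] <- d[j, i] <- num / (2 * den)
    }
  }
  d
}

# all-pairs gene x interval screen by double loop
oracle_overlap <- function(impacts, qtls) {
  out <- list()
  for (g in sort(unique(impacts$gene_id))) {
    pos_g <- impacts[impacts$gene_id == g, , drop = FALSE]
    hit <- logical(nrow(qtls))
    for (q in seq_len(nrow(qtls))) {
      for (r in seq_len(nrow(pos_g))) {
        if (sub("^[Cc]hr", "", pos_g$chrom[r]) == sub("^[Cc]hr", "", qtls$chrom[q]) &&
            pos_g$pos[r] >= qtls$start[q] && pos_g$pos[r] <= qtls$end[q]) {
          hit[q] <- TRUE
        }
      }
    }
    ids <- sort(qtls$qtl_id[hit])
    out[[g]] <- list(n_ea = sum(qtls$category[hit] == "EA"),
                     n_sr = sum(qtls$category[hit] == "SR"),
                     ids = ids)
  }
  out
}

# random dosage matrix with controlled missingness
random_dose <- function(n_sites, n_varieties, missing = 0, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(sample(0:2, n_sites * n_varieties, replace = TRUE),
                n_sites, n_varieties,
                dimnames = list(NULL, sprintf("V%02d", seq_len(n_varieties))))
    if (missing > 0) d[runif(length(d)) < missing] <- NA
    d
  })
}
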