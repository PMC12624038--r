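#' Constants for Tajima's D
#'
#' The variance normalization of Tajima's D for `n` sampled sequences:
#' a1 = sum(1/i), a2 = sum(1/i^2) for i in 1..n-1, b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2+a2).
#'
#' @param n number of sequences (haploid sample size), >= 2.
#' @return named list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from its components; exported pieces keep the formula testable at the
# numerator-zero point without constructing dosages.
tajima_d_from <- function(pi, S, n) {
  k <- tajima_constants(n)
  if (S == 0) return(NA_real_)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Per-site mean pairwise difference
#'
#' Treats each diploid variety as two haploid alleles. With `m` non-missing
#' alleles and alternate frequency `p` among them, the unbiased per-site
#' contribution to nucleotide diversity is `2 p (1-p) m / (m-1)` — the
#' probability that two alleles drawn without replacement differ.
#'
#' @param doses integer vector of variety dosages (0, 1, 2 or `NA`) at one
#'   site.
#' @return the site's contribution to pi; `NA` when fewer than 2 alleles
#'   are non-missing.
#' @examples
#' site_pairwise_diff(c(0L, 2L)) # 4 differing pairs of 6 = 2/3
#' @export
site_pairwise_diff <- function(doses) {
  ok <- !is.na(doses)
  m <- 2 * sum(ok)
  if (m < 2) return(NA_real_)
  p <- sum(doses[ok]) / m
  2 * p * (1 - p) * m / (m - 1)
}

# vectorized site statistics over a sites x varieties dosage matrix
site_stats <- function(dose) {
  ok <- !is.na(dose)
  m <- 2 * rowSums(ok)
  alt <- rowSums(dose, na.rm = TRUE)
  p <- ifelse(m > 0, alt / m, NA_real_)
  pi <- ifelse(m >= 2, 2 * p * (1 - p) * m / pmax(m - 1, 1), NA_real_)
  segregating <- m >= 2 & alt > 0 & alt < m
  list(m = m, p = p, pi = pi, segregating = segregating)
}

#' Tajima's D for one window of biallelic SNP dosages
#'
#' Computes the number of segregating sites S, nucleotide diversity pi
#' (sum of unbiased per-site mean pairwise differences), Watterson's
#' theta = S/a1, and Tajima's D
#' `(pi - S/a1) / sqrt(e1 S + e2 S (S-1))` on `n = 2 x varieties` haploid
#' alleles. Missing genotypes are handled by per-site deletion; sites with
#' a missing-allele fraction above `max_missing` are excluded and tallied.
#' D is undefined (reported `NA` with `defined = FALSE`) when S = 0.
#'
#' @param dose integer matrix, sites x varieties, entries 0/1/2/`NA`.
#' @param max_missing maximum tolerated fraction of missing alleles per
#'   site (default 0.2); above it the site is dropped.
#' @return object of class `tajima_components`: list with `n`, `S`, `pi`,
#'   `theta_w`, `d`, `defined`, `n_sites_used`, `n_sites_excluded` and the
#'   normalization `constants`.
#' @export
tajima_d <- function(dose, max_missing = 0.2) {
  if (!is.matrix(dose)) dose <- matrix(dose, nrow = 1)
  n <- 2L * ncol(dose)
  if (n < 4) stop("need at least 2 varieties (4 haploid alleles)")
  if (nrow(dose) == 0) {
    st <- NULL
    used <- logical(0)
  } else {
    miss_frac <- rowMeans(is.na(dose))
    used <- miss_frac <= max_missing & rowSums(!is.na(dose)) >= 1
    st <- site_stats(dose[used, , drop = FALSE])
  }
  S <- if (is.null(st)) 0L else sum(st$segregating)
  pi <- if (is.null(st)) 0 else sum(st$pi[st$segregating])
  k <- tajima_constants(n)
  d <- tajima_d_from(pi, S, n)
  structure(list(n = n, S = as.integer(S), pi = pi, theta_w = S / k$a1,
                 d = d, defined = S > 0,
                 n_sites_used = sum(used),
                 n_sites_excluded = length(used) - sum(used),
                 constants = k),
            class = "tajima_components")
}

#' @export
print.tajima_components <- function(x, ...) {
  cat(sprintf("n=%d S=%d pi=%.4f theta_w=%.4f D=%s\n", x$n, x$S, x$pi,
              x$theta_w, if (x$defined) sprintf("%.4f", x$d) else "undefined"))
  invisible(x)
}

#' Windowed diversity statistics along a chromosome
#'
#' Tiles a chromosome with fixed-width windows (1-based starts, half-open
#' `[start, start + size)`) and computes S, pi, Watterson's theta and
#' Tajima's D per window from biallelic SNP dosages. Windows with S = 0
#' carry `defined = FALSE` and `NA` for D — never a fabricated 0.
#'
#' @param dose integer matrix, sites x varieties (0/1/2/`NA`).
#' @param pos integer vector of 1-based site positions, sorted ascending.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param window_size window width in bp (default 100,000).
#' @param max_missing per-site missingness cap passed to [tajima_d()].
#' @return data.frame with columns `chrom`, `start`, `end`, `S`, `pi`,
#'   `theta_w`, `tajima_d`, `defined`.
#' @export
windowed_popgen <- function(dose, pos, chrom, chrom_length,
                            window_size = 100000, max_missing = 0.2) {
  if (!is.matrix(dose)) stop("dose must be a sites x varieties matrix")
  if (length(pos) != nrow(dose)) stop("pos length must match dose rows")
  if (is.unsorted(pos)) stop("sites must be sorted by position")
  if (length(pos) && max(pos) > chrom_length) {
    stop("position beyond chromosome length")
  }
  n_win <- as.integer(ceiling(chrom_length / window_size))
  widx <- window_index(pos, window_size)
  starts <- (seq_len(n_win) - 1L) * window_size + 1L
  rows <- lapply(seq_len(n_win), function(w) {
    tc <- tajima_d(dose[widx == w, , drop = FALSE], max_missing = max_missing)
    data.frame(chrom = chrom, start = starts[w],
               end = min(starts[w] + window_size - 1L, chrom_length),
               S = tc$S, pi = tc$pi, theta_w = tc$theta_w,
               tajima_d = tc$d, defined = tc$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
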