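# independent subset check used as the oracle against exact_min_panel:
# restrict profiles by hand and look for duplicates
brute_discriminates <- function(gm, cols) {
  prof <- apply(gm$dose[cols, , drop = FALSE], 2, paste, collapse = ",")
  !any(duplicated(prof))
}

brute_min_size <- function(gm) {
  s <- length(gm$keys)
  for (k in seq_len(s)) {
    subs <- utils::combn(s, k)
    for (ci in seq_len(ncol(subs))) {
      if (brute_discriminates(gm, subs[, ci])) return(k)
    }
  }
  Inf
}

test_that("the published 5-SNP panel discriminates all 22 varieties", {
  gm <- table4_genotypes()
  res <- validate_panel(gm, gm$keys)
  expect_true(res$discriminating)
  expect_equal(length(unique(res$profiles)), 22L)
  expect_equal(nrow(res$unresolved_pairs), 0L)
})

test_that("dropping the last panel SNP collides Ariete with Gageron", {
  gm <- table4_genotypes()
  res <- validate_panel(gm, setdiff(gm$keys, "11:28814241"))
  expect_false(res$discriminating)
  pairs <- paste(res$unresolved_pairs$a, res$unresolved_pairs$b)
  expect_true("Ariete Gageron" %in% pairs)
})

test_that("panel validation basics hold on tiny matrices", {
  gm <- genotype_matrix(data.frame(chrom = "1", pos = 10L),
                        matrix(c(0L, 2L), 1, dimnames = list(NULL, c("a", "b"))))
  expect_true(validate_panel(gm, gm$keys)$discriminating)
  expect_error(validate_panel(gm, "1:999"), "unknown")
  expect_error(validate_panel(gm, character(0)), "non-empty")
})

test_that("exhaustive search certifies the published minimum of 5", {
  gm <- table4_genotypes()
  expect_equal(brute_min_size(gm), 5)
  res <- exact_min_panel(gm)
  expect_true(res$discriminating)
  expect_equal(length(res$panel), 5L)
  # every leave-one-out subset collides
  for (k in gm$keys) {
    expect_false(validate_panel(gm, setdiff(gm$keys, k))$discriminating)
  }
})

test_that("exact search agrees with the brute-force oracle on random matrices", {
  for (s in 1:15) {
    dose <- random_dose(sample(4:8, 1), sample(4:8, 1), seed = 300 + s)
    gm <- genotype_matrix(data.frame(chrom = "1",
                                     pos = seq_len(nrow(dose))), dose)
    res <- exact_min_panel(gm)
    want <- brute_min_size(gm)
    if (is.infinite(want)) {
      expect_false(res$discriminating)
    } else {
      expect_true(res$discriminating)
      expect_equal(length(res$panel), want)
      expect_true(brute_discriminates(gm, match(res$panel, gm$keys)))
    }
  }
})

test_that("exact search finds single-SNP solutions and impossibilities", {
  dose <- matrix(0L, 10, 2, dimnames = list(NULL, c("a", "b")))
  dose[4, 2] <- 2L
  gm <- genotype_matrix(data.frame(chrom = "1", pos = 1:10), dose)
  res <- exact_min_panel(gm)
  expect_equal(res$panel, "1:4")
  dup <- genotype_matrix(data.frame(chrom = "1", pos = 1:3),
                         matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 3,
                                dimnames = list(NULL, c("a", "b"))))
  r2 <- exact_min_panel(dup)
  expect_false(r2$discriminating)
  expect_error(exact_min_panel(table4_genotypes(), max_exact_snps = 3),
               "crs_min_panel")
})

test_that("pair resolution counts follow the dose splits", {
  gm <- table4_genotypes()
  tab <- pair_resolution_table(gm)
  # first column splits varieties 8 vs 14
  expect_equal(tab$n_pairs_resolved[tab$snp_key == "4:22375729"], 112)
  mono <- genotype_matrix(data.frame(chrom = "1", pos = 1L),
                          matrix(c(1L, 1L, 1L), 1,
                                 dimnames = list(NULL, c("a", "b", "c"))))
  expect_equal(pair_resolution_table(mono)$n_pairs_resolved, 0)
  # 11/11 split resolves 121 pairs
  dose <- matrix(rep(c(0L, 2L), each = 11), 1,
                 dimnames = list(NULL, sprintf("v%02d", 1:22)))
  gm2 <- genotype_matrix(data.frame(chrom = "1", pos = 1L), dose)
  expect_equal(pair_resolution_table(gm2)$n_pairs_resolved, 121)
  # union covers all pairs iff the full matrix discriminates
  full <- table4_genotypes()
  union_pairs <- unique(unlist(pair_resolution_table(full)$pairs))
  expect_equal(length(union_pairs), choose(22, 2))
})

test_that("CRS finds the optimum on the published matrix and is reproducible", {
  gm <- table4_genotypes()
  res <- crs_min_panel(gm, n_trials = 200, seed = 1)
  expect_true(res$discriminating)
  expect_equal(length(res$panel), 5L)
  rerun <- crs_min_panel(gm, n_trials = 200, seed = 1)
  expect_identical(res$panel, rerun$panel)
  expect_identical(res$profiles, rerun$profiles)
  other <- crs_min_panel(gm, n_trials = 50, seed = 999)
  expect_true(other$discriminating)
  expect_gte(length(other$panel), 5L)
})

test_that("CRS always returns valid panels bounded below by the exact optimum", {
  for (s in 1:8) {
    dose <- random_dose(12, 6, seed = 700 + s)
    gm <- genotype_matrix(data.frame(chrom = "1", pos = 1:12), dose)
    exact <- exact_min_panel(gm)
    crs <- crs_min_panel(gm, n_trials = 30, seed = s)
    expect_equal(crs$discriminating, exact$discriminating)
    if (exact$discriminating) {
      expect_gte(length(crs$panel), length(exact$panel))
      check <- validate_panel(gm, crs$panel)
      expect_true(check$discriminating)
    }
  }
})

test_that("CRS finds a planted signature among decoys", {
  planted <- withr::with_seed(12, {
    sig <- plant_panel_profiles(8, 3, varieties = sprintf("v%d", 1:8))
    decoys <- matrix(sample(0:1, 50 * 8, replace = TRUE, prob = c(0.9, 0.1)),
                     50, 8, dimnames = list(NULL, sprintf("v%d", 1:8)))
    rbind(sig, decoys)
  })
  gm <- genotype_matrix(data.frame(chrom = "1", pos = seq_len(nrow(planted))),
                        planted)
  res <- crs_min_panel(gm, n_trials = 100, seed = 4)
  expect_true(res$discriminating)
  expect_lte(length(res$panel), 5L)
  expect_gte(length(res$panel), 3L)
})

test_that("trivial two-variety matrices prune to one SNP", {
  dose <- matrix(c(0L, 2L, 0L, 1L, 1L, 2L), 3, 2, byrow = FALSE,
                 dimnames = list(NULL, c("a", "b")))
  dose <- matrix(c(0L, 2L, 1L, 2L, 0L, 1L), 3, 2,
                 dimnames = list(NULL, c("a", "b")))
  gm <- genotype_matrix(data.frame(chrom = "1", pos = 1:3), dose)
  res <- crs_min_panel(gm, n_trials = 5, seed = 1)
  expect_equal(length(res$panel), 1L)
})

test_that("adding SNP rows never increases the exact minimum", {
  for (s in 1:5) {
    dose <- random_dose(10, 5, seed = 800 + s)
    gm_small <- genotype_matrix(data.frame(chrom = "1", pos = 1:6),
                                dose[1:6, , drop = FALSE])
    gm_big <- genotype_matrix(data.frame(chrom = "1", pos = 1:10), dose)
    small <- exact_min_panel(gm_small)
    big <- exact_min_panel(gm_big)
    if (small$discriminating) {
      expect_true(big$discriminating)
      expect_lte(length(big$panel), length(small$panel))
    }
  }
})

test_that("genotype matrices reject missing and malformed input", {
  expect_error(genotype_matrix(data.frame(chrom = "1", pos = 1L),
                               matrix(NA_integer_, 1, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "missing")
  expect_error(genotype_matrix(data.frame(chrom = "1", pos = c(1L, 1L)),
                               matrix(0L, 2, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "duplicate")
  expect_error(genotype_matrix(data.frame(chrom = "1", pos = 1L),
                               matrix(3L, 1, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "0, 1 or 2")
})
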