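high_vs <- function() {
  make_vs("1", c(100, 200, 300),
          ref = c("A", "C", "G"), alt = c("T", "T", "A"),
          gt = matrix(c("0/0", "0/1", "1/1",
                        "0/0", "0/0", "./.",
                        "0/1", "0/0", "0/0"), 3, byrow = TRUE),
          samples = c("va", "vb", "vc"),
          ann = c("T|stop_gained|HIGH|G1,T|upstream_gene_variant|MODIFIER|G9",
                  NA, "A|start_lost|HIGH|G2"))
}

test_that("HIGH annotations are extracted with carrier states", {
  imp <- extract_high_impact(high_vs())
  expect_equal(nrow(imp), 2L)
  expect_equal(imp$gene_id, c("G1", "G2"))
  expect_equal(imp$effect, c("stop_gained", "start_lost"))
  carriers <- attr(imp, "carriers")
  expect_equal(unname(carriers[1, ]), c("hom-ref", "het", "hom-alt"))
  expect_equal(unname(carriers[2, ]), c("het", "hom-ref", "hom-ref"))
  # no HIGH annotations -> empty
  none <- extract_high_impact(make_vs("1", 5, "A", "T", matrix("0/0", 1),
                                      samples = "x"))
  expect_equal(nrow(none), 0L)
  # empty gene id falls back to a sentinel with a warning
  anon <- make_vs("1", 7, "A", "T", matrix("0/1", 1), samples = "x",
                  ann = "T|stop_gained|HIGH|")
  expect_warning(got <- extract_high_impact(anon), "sentinel")
  expect_equal(got$gene_id, "unassigned_gene")
})

test_that("planted HIGH annotations are recovered from synthetic cohorts", {
  coh <- generate_cohort(cohort_spec(seed = 77))
  imp <- extract_high_impact(coh$variants)
  expect_equal(nrow(imp), 12L)
  expect_equal(length(unique(imp$gene_id)), 10L)
  tr <- coh$truth$high_impact
  expect_equal(imp[order(imp$chrom, imp$pos), c("chrom", "pos")],
               tr[order(tr$chrom, tr$pos), c("chrom", "pos")],
               ignore_attr = TRUE)
  # planted carrier design: 2 het + 2 hom-alt per site, rest hom-ref
  carriers <- attr(imp, "carriers")
  expect_equal(unname(rowSums(carriers == "het")), rep(2L, 12))
  expect_equal(unname(rowSums(carriers == "hom-alt")), rep(2L, 12))
  expect_false(any(carriers == "missing"))
})

test_that("QTL matching is end-inclusive on both boundaries", {
  imp <- data.frame(gene_id = c("WX1", "GZ"), chrom = c("6", "6"),
                    pos = c(1765761L, 999L), stringsAsFactors = FALSE)
  qtls <- data.frame(qtl_id = c("qAC-6", "edge_lo", "edge_hi", "off"),
                     chrom = "6",
                     start = c(1700000L, 999L, 900L, 1000L),
                     end = c(1800000L, 1200L, 999L, 1100L),
                     category = c("EA", "SR", "SR", "EA"),
                     stringsAsFactors = FALSE)
  ov <- overlap_with_qtls(imp, qtls)
  wx <- ov[ov$gene_id == "WX1", ]
  expect_equal(wx$ea_qtls, "qAC-6")
  expect_equal(wx$total_qtls, 1L)
  gz <- ov[ov$gene_id == "GZ", ]
  # pos == start and pos == end both match; [1000,1100] does not
  expect_equal(gz$sr_qtls, "edge_hi,edge_lo")
  expect_equal(gz$n_ea, 0L)
  expect_equal(gz$total_qtls, gz$n_ea + gz$n_sr)
})

test_that("interval screening equals the brute-force double loop", {
  for (s in 1:20) {
    dat <- withr::with_seed(s, {
      g <- data.frame(
        gene_id = sprintf("g%02d", sample(50, 60, replace = TRUE)),
        chrom = as.character(sample(1:5, 60, replace = TRUE)),
        pos = sample.int(100000, 60), stringsAsFactors = FALSE)
      starts <- sample.int(95000, 200)
      q <- data.frame(qtl_id = sprintf("q%03d", 1:200),
                      chrom = as.character(sample(1:5, 200, replace = TRUE)),
                      start = starts,
                      end = starts + sample.int(8000, 200),
                      category = sample(c("EA", "SR"), 200, replace = TRUE),
                      stringsAsFactors = FALSE)
      list(g = g, q = q)
    })
    got <- overlap_with_qtls(dat$g, dat$q)
    want <- oracle_overlap(dat$g, dat$q)
    expect_equal(got$gene_id, names(want))
    expect_equal(got$n_ea, vapply(want, `[[`, numeric(1), "n_ea"),
                 ignore_attr = TRUE)
    expect_equal(got$n_sr, vapply(want, `[[`, numeric(1), "n_sr"),
                 ignore_attr = TRUE)
    ids_got <- ifelse(nzchar(got$ea_qtls) & nzchar(got$sr_qtls),
                      paste(got$ea_qtls, got$sr_qtls, sep = ","),
                      paste0(got$ea_qtls, got$sr_qtls))
    for (i in seq_len(nrow(got))) {
      expect_setequal(strsplit(ids_got[i], ",")[[1]],
                      want[[got$gene_id[i]]]$ids)
    }
    expect_false(anyDuplicated(got$gene_id) > 0)
    expect_equal(got$total_qtls, got$n_ea + got$n_sr)
  }
})

test_that("unmatched genes are kept by default and droppable by flag", {
  imp <- data.frame(gene_id = c("in", "out"), chrom = c("1", "2"),
                    pos = c(50L, 50L), stringsAsFactors = FALSE)
  qtls <- data.frame(qtl_id = "q1", chrom = "1", start = 1L, end = 100L,
                     category = "EA", stringsAsFactors = FALSE)
  ov <- overlap_with_qtls(imp, qtls)
  expect_equal(nrow(ov), 2L)
  expect_equal(ov$total_qtls[ov$gene_id == "out"], 0L)
  expect_equal(nrow(overlap_with_qtls(imp, qtls, drop_unmatched = TRUE)), 1L)
  # duplicate interval ids count as listed unless deduplicated
  qtls2 <- rbind(qtls, data.frame(qtl_id = "q1", chrom = "1", start = 10L,
                                  end = 90L, category = "EA"))
  expect_equal(overlap_with_qtls(imp, qtls2)$total_qtls[1], 2L)
  expect_equal(overlap_with_qtls(imp, qtls2,
                                 dedup_qtls = TRUE)$total_qtls[1], 1L)
})

test_that("carrier reports are long-format and never imputed", {
  imp <- extract_high_impact(high_vs())
  rep_ <- carriers_report(imp)
  expect_equal(nrow(rep_), 6L)
  expect_equal(rep_$state[rep_$gene_id == "G1"],
               c("hom-ref", "het", "hom-alt"))
  all_ref <- make_vs("1", 5, "A", "T", matrix(c("0/0", "0/0"), 1),
                     samples = c("x", "y"), ann = "T|stop_gained|HIGH|GZ")
  r2 <- carriers_report(extract_high_impact(all_ref))
  expect_true(all(r2$state == "hom-ref"))
  with_miss <- make_vs("1", 5, "A", "T", matrix(c("./.", "1/1"), 1),
                       samples = c("x", "y"), ann = "T|stop_gained|HIGH|GZ")
  r3 <- carriers_report(extract_high_impact(with_miss))
  expect_equal(sort(r3$state), c("hom-alt", "missing"))
})
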