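#' Run the full post-variant-calling analysis
#'
#' Orchestrates every stage on a cohort VCF: class splitting and hard
#' filtering (SNPs and InDels), per-chromosome summaries and spectra,
#' windowed diversity statistics (pi, Watterson's theta, Tajima's D),
#' allele-sharing distances and a relatedness tree, per-chromosome
#' density-profile clustering, the HIGH-impact x QTL screen, and minimal
#' discriminating-panel selection. All outputs are written under
#' `out_dir` and listed (with md5 hashes) in `manifest.json`; a rerun
#' with the same inputs and seed reproduces identical hashes.
#'
#' @param vcf path to the multi-sample VCF.
#' @param qtl_file path to the QTL interval TSV.
#' @param chrom_file path to the chromosome-length TSV.
#' @param out_dir output directory (created if needed).
#' @param window_size window width in bp (default 100,000); must be at
#'   least `density_unit`.
#' @param density_unit denominator of the density definition in bp
#'   (default 1000).
#' @param tree_method `"nj"` (default) or `"upgma"`.
#' @param k clusters for density-profile clustering (default 4).
#' @param crs_trials random restarts for panel selection (default 200).
#' @param seed integer seed for panel selection.
#' @param max_missing per-site missingness cap for diversity windows.
#' @return the manifest, invisibly: list of parameters, input paths and
#'   output files with md5 hashes.
#' @export
run_pipeline <- function(vcf, qtl_file, chrom_file, out_dir,
                         window_size = 100000, density_unit = 1000,
                         tree_method = c("nj", "upgma"), k = 4,
                         crs_trials = 200, seed = 1, max_missing = 0.2) {
  tree_method <- match.arg(tree_method)
  if (window_size < density_unit) {
    stop("window_size must be at least density_unit")
  }
  for (p in c(vcf, qtl_file, chrom_file)) {
    if (!file.exists(p)) stop("input does not exist: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    outputs <<- c(outputs, path)
    path
  }
  tsv <- function(d, name) {
    utils::write.table(d, emit(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  x <- stage("read", read_vcf(vcf))
  qtls <- stage("read", read_qtl_table(qtl_file))
  chroms <- stage("read", read_chrom_table(chrom_file))

  parts <- stage("filter", split_by_class(x))
  fs <- stage("filter", hard_filter(parts$snp, class = "snp"))
  fi <- stage("filter", hard_filter(parts$indel, class = "indel"))
  stage("filter", {
    write_vcf(fs$retained, emit("kept_snps.vcf"), contigs = chroms)
    write_vcf(fi$retained, emit("kept_indels.vcf"), contigs = chroms)
    tsv(rbind(data.frame(class = "SNP",
                         condition = names(fs$report$by_condition),
                         n_removed = unname(fs$report$by_condition)),
              data.frame(class = "INDEL",
                         condition = names(fi$report$by_condition),
                         n_removed = unname(fi$report$by_condition))),
        "filter_report.tsv")
  })
  kept <- variant_set(rbind(fs$retained$variants, fi$retained$variants),
                      rbind(fs$retained$gt, fi$retained$gt), x$samples)
  o <- order(match(kept$variants$chrom, chroms$chrom), kept$variants$pos)
  kept <- subset_variants(kept, o)

  stage("summarize", {
    tsv(summarize_by_chromosome(kept, chroms, density_unit),
        "chrom_summary.tsv")
    tsv(substitution_spectrum(fs$retained), "spectrum.tsv")
    tsv(indel_length_spectrum(fi$retained), "indel_lengths.tsv")
    tsv(window_counts(fs$retained, chroms, window_size), "windows.tsv")
  })

  dose_all <- stage("popgen", vcf_to_genotype_matrix(fs$retained, "none"))
  stage("popgen", {
    pg <- lapply(seq_len(nrow(chroms)), function(i) {
      on_c <- norm_chrom(dose_all$snps$chrom) == norm_chrom(chroms$chrom[i])
      windowed_popgen(dose_all$dose[on_c, , drop = FALSE],
                      dose_all$snps$pos[on_c], chroms$chrom[i],
                      chroms$length[i], window_size, max_missing)
    })
    tsv(do.call(rbind, pg), "popgen.tsv")
  })

  dm <- stage("tree", pairwise_distance(dose_all$dose))
  stage("tree", {
    write_distance_tsv(dm, emit("distance.tsv"))
    tree <- if (tree_method == "nj") nj_tree(dm) else upgma_tree(dm)
    write_newick(tree, emit("tree.nwk"))
  })

  stage("cluster", {
    prof <- density_profiles(fs$retained, chroms, window_size)
    cl <- cluster_density_profiles(prof, k = k)
    tsv(do.call(rbind, lapply(names(cl), function(ch) {
      data.frame(chrom = ch, variety = names(cl[[ch]]),
                 cluster = unname(cl[[ch]]), stringsAsFactors = FALSE)
    })), "clusters.tsv")
  })

  stage("qtl-screen", {
    impacts <- extract_high_impact(fs$retained)
    tsv(impacts, "gene_impacts.tsv")
    tsv(overlap_with_qtls(impacts, qtls), "gene_qtl_overlap.tsv")
    tsv(carriers_report(impacts), "carriers.tsv")
  })

  stage("discriminate", {
    gm <- vcf_to_genotype_matrix(fs$retained, "any")
    panel <- crs_min_panel(gm, n_trials = crs_trials, seed = seed)
    write_panel_tsv(panel, gm, emit("panel.tsv"))
    jsonlite::write_json(
      list(method = panel$method, seed = panel$seed,
           trials = panel$trials_used,
           discriminating = panel$discriminating,
           panel = panel$panel,
           n_unresolved_pairs = nrow(panel$unresolved_pairs)),
      emit("panel.json"), auto_unbox = TRUE, pretty = TRUE)
  })

  manifest <- list(
    inputs = list(vcf = vcf, qtls = qtl_file, chroms = chrom_file),
    parameters = list(window_size = window_size,
                      density_unit = density_unit,
                      tree_method = tree_method, k = k,
                      crs_trials = crs_trials, seed = seed,
                      max_missing = max_missing),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) {
                       list(path = p, md5 = unname(tools::md5sum(p)))
                     }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
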