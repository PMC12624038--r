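#' Allele-sharing distance between varieties
#'
#' For each pair of varieties, `d = sum |dose_i - dose_j| / (2 * n)` over
#' the `n` sites where both are non-missing (pairwise deletion). The
#' distance lies in [0, 1]: 0 for identical dosage vectors, 1 when one
#' variety is homozygous reference and the other homozygous alternate at
#' every shared site. Allele-sharing distance need not satisfy the
#' triangle inequality; violations are detected and reported as an
#' attribute, not treated as errors.
#'
#' @param x a [genotype_matrix()], or an integer dosage matrix
#'   (sites x varieties, 0/1/2/`NA`) with variety column names.
#' @return object of class `allele_sharing`: list with the symmetric
#'   zero-diagonal matrix `d`, the matrix `n_compared` of sites used per
#'   pair, and `labels`. Attribute `triangle_violations` counts triples
#'   violating the triangle inequality (tolerance 1e-12).
#' @export
pairwise_distance <- function(x) {
  dose <- if (inherits(x, "genotype_matrix")) x$dose else x
  if (is.null(colnames(dose))) {
    colnames(dose) <- paste0("V", seq_len(ncol(dose)))
  }
  v <- ncol(dose)
  if (v < 2) stop("need at least 2 varieties")
  labels <- colnames(dose)
  d <- matrix(0, v, v, dimnames = list(labels, labels))
  nc <- matrix(0L, v, v, dimnames = list(labels, labels))
  ok <- !is.na(dose)
  nc_full <- crossprod(ok + 0)
  for (i in seq_len(v - 1)) {
    for (j in (i + 1):v) {
      shared <- ok[, i] & ok[, j]
      n <- sum(shared)
      if (n == 0) {
        stop("no comparable sites between ", labels[i], " and ", labels[j])
      }
      d[i, j] <- d[j, i] <- sum(abs(dose[shared, i] - dose[shared, j])) / (2 * n)
    }
  }
  nc[] <- as.integer(nc_full)
  diag(nc) <- as.integer(colSums(ok))
  viol <- 0L
  if (v >= 3) {
    for (i in seq_len(v - 1)) {
      for (j in (i + 1):v) {
        k <- setdiff(seq_len(v), c(i, j))
        viol <- viol + sum(d[i, j] > d[i, k] + d[k, j] + 1e-12)
      }
    }
  }
  structure(list(d = d, n_compared = nc, labels = labels),
            class = "allele_sharing", triangle_violations = as.integer(viol))
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "allele_sharing")) return(dm$d)
  if (is.matrix(dm)) return(dm)
  as.matrix(dm)
}

check_symmetric <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. On a tree-additive matrix NJ
#' recovers the generating topology and branch lengths exactly. Negative
#' branch lengths (possible on non-additive input) are clamped to zero;
#' the total clamped length is stored in the `clamped` attribute.
#'
#' @param dm an `allele_sharing` object, symmetric matrix or `dist`.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  d <- check_symmetric(as_dist_matrix(dm))
  if (nrow(d) < 3) stop("need at least 3 labels for neighbor joining")
  tree <- ape::nj(d)
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  if (deficit > 0) {
    message("clamped ", format(deficit), " of negative branch length to 0")
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- deficit
  attr(tree, "method") <- "nj"
  tree
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree; on
#' ultrametric input the generating dendrogram is recovered exactly. Merge
#' ties are resolved deterministically by the agglomeration order of
#' `hclust` (lowest-index pair first).
#'
#' @param dm an `allele_sharing` object, symmetric matrix or `dist`.
#' @return a rooted `phylo` tree (ape).
#' @export
upgma_tree <- function(dm) {
  d <- check_symmetric(as_dist_matrix(dm))
  if (nrow(d) < 2) stop("need at least 2 labels")
  tree <- phangorn::upgma(stats::as.dist(d))
  attr(tree, "method") <- "upgma"
  tree
}

quote_label <- function(x) {
  ifelse(grepl("[[:space:](),:;]", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

#' Serialize a tree as Newick
#'
#' Writes a `phylo` tree with branch lengths; labels containing
#' whitespace or Newick metacharacters are single-quoted, so variety names
#' like "Basmati Type III" round-trip unchanged through
#' [ape::read.tree()].
#'
#' @param tree a `phylo` object.
#' @param path output file path, or `NULL` to return the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_node <- function(node, edge_idx) {
    len <- if (is.null(edge_idx) || is.null(tree$edge.length)) "" else
      paste0(":", sprintf("%.10g", tree$edge.length[edge_idx]))
    if (node <= n_tip) {
      return(paste0(quote_label(tree$tip.label[node]), len))
    }
    kids <- children[[as.character(node)]]
    inner <- paste(vapply(kids, function(e) {
      fmt_node(tree$edge[e, 2], e)
    }, character(1)), collapse = ",")
    paste0("(", inner, ")", len)
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  s <- paste0(fmt_node(root, NULL), ";")
  if (is.null(path)) return(s)
  writeLines(enc2utf8(s), path, useBytes = TRUE)
  invisible(s)
}

#' Read a Newick tree written by [write_newick()]
#'
#' Parses with [ape::read.tree()] and removes the single-quote escaping
#' that [write_newick()] applies to labels containing whitespace or
#' Newick metacharacters, so labels round-trip unchanged.
#'
#' @param path path to a Newick file.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}

#' Cluster per-variety SNP-density profiles
#'
#' Each variety's windowed SNP counts are scaled to unit row sum (so
#' clusters reflect distribution patterns, not sequencing depth),
#' Euclidean distances are computed and the average-linkage tree is cut
#' into `k` clusters. Deterministic: no random steps.
#'
#' @param profiles a varieties x windows count matrix (one chromosome), or
#'   a named list of such matrices as returned by [density_profiles()].
#' @param k number of clusters (default 4); must not exceed the number of
#'   varieties.
#' @return for a single matrix, a named integer vector of cluster ids
#'   (attribute `hclust` retains the linkage tree); for a list, a list of
#'   such vectors.
#' @export
cluster_density_profiles <- function(profiles, k = 4) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    return(lapply(profiles, cluster_density_profiles, k = k))
  }
  m <- as.matrix(profiles)
  if (k > nrow(m)) stop("k exceeds the number of varieties")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero density profile for: ",
         paste(rownames(m)[zero], collapse = ", "))
  }
  normed <- m / rowSums(m)
  hc <- stats::hclust(stats::dist(normed), method = "average")
  cl <- stats::cutree(hc, k = k)
  attr(cl, "hclust") <- hc
  cl
}

#' Write a distance matrix as TSV
#' @param dm an `allele_sharing` object or matrix.
#' @param path output path; header row and first column carry labels.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  d <- as_dist_matrix(dm)
  utils::write.table(data.frame(variety = rownames(d), d,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
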