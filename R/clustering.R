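#' Pairwise distances between copy-number profiles
#'
#' Computes the sample-by-sample distance matrix over a binned copy-number
#' matrix, with the LOH-fraction layer appended at a configurable weight.
#' A plain numeric matrix (samples in rows) is also accepted.
#'
#' @param x A `cnv_matrix` from [build_cnv_matrix()], or a numeric matrix
#'   with one profile per row (rownames used as sample ids).
#' @param metric One of `"euclidean"`, `"manhattan"`, `"correlation"`
#'   (1 minus the Pearson correlation between profiles).
#' @param loh_weight Multiplier on the LOH layer before it is appended to
#'   the copy-number layer (ignored for plain matrices). Default 1.
#' @return Symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
pairwise_distance <- function(x, metric = c("euclidean", "manhattan",
                                            "correlation"),
                              loh_weight = 1) {
  metric <- match.arg(metric)
  if (inherits(x, "cnv_matrix")) {
    m <- cbind(x$cn, loh_weight * x$loh)
    rownames(m) <- x$sample_ids
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    m <- x
  }
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(m, method = "euclidean")),
    manhattan = as.matrix(stats::dist(m, method = "manhattan")),
    correlation = 1 - stats::cor(t(m))
  )
  if (metric == "correlation") diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' Standard agglomerative clustering over a precomputed distance matrix:
#' starting from singletons, the two clusters at minimal inter-cluster
#' distance are merged repeatedly, with inter-cluster distance the maximum
#' (`complete`), mean (`average`), or minimum (`single`) over cross-pairs
#' of leaves. Distances are maintained by the Lance–Williams update. When
#' two candidate merges share the minimal distance exactly, the pair whose
#' (creation-index, creation-index) label pair is lexicographically smallest
#' is merged — singletons are numbered by input order, later clusters by
#' merge order — so results are reproducible bit for bit regardless of
#' platform or input permutation (up to that documented rule).
#'
#' @param d Symmetric distance matrix (e.g. from [pairwise_distance()]),
#'   or a `stats::dist` object.
#' @param linkage `"complete"` (default), `"average"`, or `"single"`.
#' @return An object of class `hclust` (see [stats::hclust()]) with
#'   `merge`, `height`, `order`, `labels`, and `method` components, usable
#'   with [stats::cophenetic()], [stats::cutree()] and [ape::as.phylo()].
#' @examples
#' d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' h <- hierarchical_cluster(d, "complete")
#' h$height  # 1 then 10
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2) stop("need at least 2 leaves", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters carry: id (hclust convention: -leaf or +merge index),
  # creation index (leaves 1..n, then n+1, ...), and size
  work <- d
  id <- -seq_len(n)
  created <- seq_len(n)
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(id)
    # minimal off-diagonal distance, then lexicographic creation-index
    # tie-break over all attaining pairs
    upper <- upper.tri(work)
    dmin <- min(work[upper])
    cand <- which(work == dmin & upper, arr.ind = TRUE)
    key_i <- pmin(created[cand[, 1]], created[cand[, 2]])
    key_j <- pmax(created[cand[, 1]], created[cand[, 2]])
    pick <- order(key_i, key_j)[1]
    i <- min(cand[pick, ]); j <- max(cand[pick, ])
    # record merge (hclust convention: singletons negative, ordered)
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- dmin
    # Lance-Williams update of distances to the merged cluster
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- switch(linkage,
      complete = pmax(work[i, others], work[j, others]),
      single = pmin(work[i, others], work[j, others]),
      average = (size[i] * work[i, others] + size[j] * work[j, others]) /
        (size[i] + size[j])
    )
    work <- work[-c(i, j), -c(i, j), drop = FALSE]
    work <- rbind(cbind(work, dnew), c(dnew, 0))
    id <- c(id[others], step)
    created <- c(created[others], n + step)
    size <- c(size[others], size[i] + size[j])
  }
  out <- list(merge = merge, height = height,
              order = .leaf_order(merge, n), labels = labels,
              method = linkage, call = match.call(),
              dist.method = "precomputed")
  class(out) <- "hclust"
  out
}

# left-to-right leaf order for plotting / hclust validity
.leaf_order <- function(merge, n) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(n - 1L)
}

#' Are two leaves dendrogram siblings?
#'
#' The pair-adjacency criterion for clonal relatedness: two samples are
#' "most closely related" in the tree iff the first merge involving either
#' of them joins exactly the two singletons, i.e. they are siblings at a
#' leaf-level merge.
#'
#' @param tree An `hclust` object (see [hierarchical_cluster()]).
#' @param a,b Leaf labels.
#' @return `TRUE` iff `{a, b}` form a leaf-level merge.
#' @export
leaf_pair_adjacent <- function(tree, a, b) {
  stopifnot(inherits(tree, "hclust"))
  ia <- match(a, tree$labels)
  ib <- match(b, tree$labels)
  if (is.na(ia) || is.na(ib)) {
    stop(sprintf("unknown leaf label(s): %s",
                 paste(c(a, b)[is.na(c(ia, ib))], collapse = ", ")),
         call. = FALSE)
  }
  any(tree$merge[, 1] == -ia & tree$merge[, 2] == -ib |
        tree$merge[, 1] == -ib & tree$merge[, 2] == -ia)
}

#' Cohort-level dendrogram adjacency of primary/metastasis pairs
#'
#' Applies [leaf_pair_adjacent()] to every patient of a cohort manifest and
#' reports the fraction of pairs grouped in the tree (e.g. 8 of 15 pairs
#' adjacent gives 0.533).
#'
#' @param tree An `hclust` over the cohort's tumor samples.
#' @param manifest Cohort manifest (see [read_manifest()]).
#' @return List with `pairs` (data frame `patient`, `primary`,
#'   `metastasis`, `adjacent`, `merge_height` — the height of the sibling
#'   merge, `NA` when not adjacent) and `fraction_grouped`.
#' @export
cohort_adjacency <- function(tree, manifest) {
  stopifnot(inherits(tree, "hclust"))
  missing <- setdiff(c(manifest$primary, manifest$metastasis), tree$labels)
  if (length(missing) > 0) {
    stop(sprintf("manifest sample(s) absent from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  adj <- mapply(leaf_pair_adjacent, manifest$primary, manifest$metastasis,
                MoreArgs = list(tree = tree))
  hgt <- mapply(function(a, b) {
    ia <- match(a, tree$labels); ib <- match(b, tree$labels)
    row <- which(tree$merge[, 1] == -ia & tree$merge[, 2] == -ib |
                   tree$merge[, 1] == -ib & tree$merge[, 2] == -ia)
    if (length(row) == 1) tree$height[row] else NA_real_
  }, manifest$primary, manifest$metastasis)
  pairs <- data.frame(patient = manifest$patient,
                      primary = manifest$primary,
                      metastasis = manifest$metastasis,
                      adjacent = unname(adj),
                      merge_height = unname(hgt),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, fraction_grouped = mean(pairs$adjacent))
}

#' Export a dendrogram in Newick format
#'
#' Writes the clustering tree as a Newick file with merge heights converted
#' to branch lengths (via [ape::as.phylo()]).
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
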