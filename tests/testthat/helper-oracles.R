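# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances by explicit double loops, clustering by
# recomputing inter-cluster distances from scratch at every step, t-tests by
# the textbook formulas.

# random symmetric distance matrix with zero diagonal and distinct entries
random_distance_matrix <- function(n, labels = paste0("S", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2)
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# brute-force pairwise distances by double loop
oracle_distance <- function(m, metric) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- switch(metric,
      euclidean = sqrt(sum((m[i, ] - m[j, ])^2)),
      manhattan = sum(abs(m[i, ] - m[j, ])),
      correlation = 1 - stats::cor(m[i, ], m[j, ]))
  }
  if (metric == "correlation") diag(d) <- 0
  d
}

# Naive agglomerator: keeps explicit leaf-membership lists and recomputes
# every inter-cluster distance from the original matrix at each step, with
# the same lexicographic creation-index tie-break the implementation
# documents. Returns the merged leaf partitions and heights.
oracle_agglomerate <- function(d, linkage) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)  # leaf index sets
  created <- seq_len(n)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      dij <- switch(linkage, complete = max(cross), single = min(cross),
                    average = mean(cross))
      key <- c(min(created[i], created[j]), max(created[i], created[j]))
      if (is.null(best) || dij < best$d ||
          (dij == best$d && (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$d)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    keep <- setdiff(seq_len(m), c(best$i, best$j))
    clusters <- c(clusters[keep], list(merged))
    created <- c(created[keep], n + length(merges))
  }
  list(merges = merges, heights = heights)
}

# leaf partitions of an hclust merge matrix, in merge order
hclust_partitions <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    leaves <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(leaves(tree$merge[k, 1]),
                        leaves(tree$merge[k, 2])))
  }
  sets
}

# textbook two-sample / paired t-tests
oracle_t <- function(a, b, variant) {
  if (variant == "paired") {
    d <- a - b
    t <- mean(d) / sqrt(stats::var(d) / length(d))
    df <- length(d) - 1
  } else if (variant == "welch") {
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  } else {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) *
              stats::var(b)) / (length(a) + length(b) - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    df <- length(a) + length(b) - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# per-base copy-number averaging oracle on a small genome
oracle_cnv_bin <- function(segments, sample_id, chrom, bin_start, bin_end) {
  dev <- 0; loh_cov <- 0
  for (base in bin_start:bin_end) {
    segs <- segments[segments$sample == sample_id &
                       segments$chrom == chrom &
                       segments$start <= base & segments$end >= base, ,
                     drop = FALSE]
    if (nrow(segs) > 0) {
      dev <- dev + sum(segs$copy_number - 2)
      loh_cov <- loh_cov + sum(segs$loh)
    }
  }
  len <- bin_end - bin_start + 1
  c(cn = dev / len, loh = loh_cov / len)
}

# small valid mutation / segment tables for round-trip tests
random_mutation_table <- function(n, samples = c("S1", "S2")) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  indel <- stats::runif(n) < 0.15
  ins <- indel & stats::runif(n) < 0.5
  ref[ins] <- "-"; alt[indel & !ins] <- "-"
  data.frame(
    sample = sample(samples, n, replace = TRUE),
    chrom = paste0("chr", sample(1:5, n, replace = TRUE)),
    pos = sample.int(1e6, n),
    ref = ref, alt = unname(alt),
    gene = paste0("G", sample.int(50, n, replace = TRUE)),
    effect = sample(clonalpair::mutation_effects, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

random_segment_table <- function(n, samples = c("S1", "S2")) {
  start <- sample.int(9e5, n)
  data.frame(
    sample = sample(samples, n, replace = TRUE),
    chrom = paste0("chr", sample(1:5, n, replace = TRUE)),
    start = start,
    end = start + sample.int(1e4, n),
    copy_number = sample(0:6, n, replace = TRUE),
    loh = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# reference-cohort helpers shared by tests and examples
reference_clm_counts <- function() {
  b <- clonalpair::reference_scna_burden()
  clm <- b[b$role == "CLM", ]
  stats::setNames(clm$somatic_mutations, paste0(clm$patient_id, "-CLM"))
}

reference_clm_loh <- function() {
  b <- clonalpair::reference_scna_burden()
  clm <- b[b$role == "CLM", ]
  data.frame(sample_id = paste0(clm$patient_id, "-CLM"), n_loh = clm$loh,
             stringsAsFactors = FALSE)
}
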