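#' Categorize copy-number segments into the five SCNA event classes
#'
#' Maps an integer total copy number and an LOH flag to one of the five
#' somatic copy-number alteration categories used throughout the package,
#' under the standard diploid interpretation: copy number 3 is a one-copy
#' gain, 4 or more a high copy gain, 1 a one-copy loss, 0 a homozygous loss;
#' copy-neutral LOH is called only at copy number 2 with the LOH flag set,
#' and copy number 2 without LOH is neutral. The copy-number class takes
#' precedence over the LOH flag (e.g. a deleted segment flagged LOH is a
#' homozygous loss, not an LOH event).
#'
#' @param copy_number Integer vector of non-negative total copy numbers.
#' @param loh Logical vector (recycled) of loss-of-heterozygosity flags.
#' @return Factor vector with levels `one_copy_gain`, `one_copy_loss`,
#'   `high_copy_gain`, `homozygous_loss`, `loh`, `neutral`.
#' @examples
#' categorize_segment(c(2, 0, 5, 2), c(FALSE, TRUE, FALSE, TRUE))
#' @export
categorize_segment <- function(copy_number, loh) {
  stopifnot(is.numeric(copy_number), all(copy_number >= 0),
            all(copy_number == floor(copy_number)))
  loh <- rep_len(as.logical(loh), length(copy_number))
  out <- ifelse(copy_number == 0, "homozygous_loss",
         ifelse(copy_number == 1, "one_copy_loss",
         ifelse(copy_number == 3, "one_copy_gain",
         ifelse(copy_number >= 4, "high_copy_gain",
         ifelse(loh, "loh", "neutral")))))
  factor(out, levels = scna_categories())
}

#' @rdname categorize_segment
#' @export
scna_categories <- function() {
  c("one_copy_gain", "one_copy_loss", "high_copy_gain",
    "homozygous_loss", "loh", "neutral")
}

#' Per-sample SCNA burden summary
#'
#' Counts a sample's segments in each of the five SCNA categories and the
#' total SCNA number. Following the cohort reporting convention this package
#' reproduces, `total_scna` is the sum of the four copy-number categories
#' (gains and losses); copy-neutral LOH segments are tallied separately and
#' are *not* part of the total.
#'
#' @param segments Segment data frame (see [read_segment_table()]).
#' @param sample_id Sample whose burden to summarize. All rows of `segments`
#'   must belong to it (pre-filter with `summarize_scna_cohort()` for a
#'   multi-sample table).
#' @return One-row data frame: `sample_id`, `n_one_copy_gain`,
#'   `n_one_copy_loss`, `n_high_copy_gain`, `n_homozygous_loss`, `n_loh`,
#'   `total_scna`.
#' @seealso [summarize_scna_cohort()] for all samples of a table at once.
#' @export
summarize_scna <- function(segments, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  foreign <- setdiff(unique(segments$sample), sample_id)
  if (length(foreign) > 0) {
    stop(sprintf("segments contain foreign sample id(s): %s",
                 paste(foreign, collapse = ", ")), call. = FALSE)
  }
  cat_counts <- table(categorize_segment(segments$copy_number, segments$loh))
  n <- function(k) as.integer(cat_counts[[k]])
  data.frame(
    sample_id = sample_id,
    n_one_copy_gain = n("one_copy_gain"),
    n_one_copy_loss = n("one_copy_loss"),
    n_high_copy_gain = n("high_copy_gain"),
    n_homozygous_loss = n("homozygous_loss"),
    n_loh = n("loh"),
    total_scna = n("one_copy_gain") + n("one_copy_loss") +
      n("high_copy_gain") + n("homozygous_loss"),
    stringsAsFactors = FALSE
  )
}

#' @rdname summarize_scna
#' @param sample_ids Samples to summarize; defaults to all samples present,
#'   in order of first appearance.
#' @export
summarize_scna_cohort <- function(segments, sample_ids = unique(segments$sample)) {
  out <- lapply(sample_ids, function(s) {
    summarize_scna(segments[segments$sample == s, , drop = FALSE], s)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand per-category event counts into synthetic segment records
#'
#' Builds a segment table in which each counted SCNA event of a burden row
#' becomes one synthetic unit segment of the corresponding copy-number state
#' (3, 1, >=4, 0, or 2 with LOH), laid end to end on a dummy chromosome.
#' Summarizing such a table with [summarize_scna()] recovers the category
#' counts exactly, which is how the bundled reference burden table (see
#' [reference_scna_burden()]) is replayed through the SCNA summary path.
#'
#' @param sample_id Sample identifier for the emitted segments.
#' @param one_copy_gain,one_copy_loss,high_copy_gain,homozygous_loss,loh
#'   Non-negative event counts.
#' @param chrom Chromosome label for the synthetic segments.
#' @return Segment data frame in the [read_segment_table()] layout.
#' @export
expand_burden_segments <- function(sample_id, one_copy_gain, one_copy_loss,
                                   high_copy_gain, homozygous_loss, loh,
                                   chrom = "chr1") {
  counts <- c(one_copy_gain, one_copy_loss, high_copy_gain, homozygous_loss, loh)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  cn <- rep(c(3L, 1L, 4L, 0L, 2L), counts)
  is_loh <- rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), counts)
  n <- length(cn)
  width <- 1000L
  start <- seq_len(n) * width - (width - 1L)
  data.frame(
    sample = rep(sample_id, n), chrom = rep(chrom, n),
    start = start, end = start + width - 1L,
    copy_number = cn, loh = is_loh, stringsAsFactors = FALSE
  )
}

#' Build a binned copy-number matrix for clustering
#'
#' Tiles each chromosome into fixed-size bins and computes, per sample and
#' bin, the per-base mean deviation of total copy number from the diploid
#' baseline: each base contributes `copy_number - 2` summed over the
#' segments covering it (0 where uncovered), and the bin value is that sum
#' averaged over the bin length. A parallel LOH layer holds the fraction of
#' each bin covered by LOH-flagged segments. Segments of one sample are
#' assumed non-overlapping (the SEG convention); overlapping segments add.
#'
#' @param segments Segment data frame (see [read_segment_table()]).
#' @param sample_ids Samples to include as matrix rows (default: all in
#'   `segments`, in order of first appearance).
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#'   Every segment chromosome must be present.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return An object of class `cnv_matrix`: a list with `sample_ids`,
#'   `bins` (data frame `chrom`, `start`, `end`), `cn` and `loh`
#'   (sample-by-bin numeric matrices).
#' @seealso [pairwise_distance()], [hierarchical_cluster()]
#' @export
build_cnv_matrix <- function(segments, chrom_lengths,
                             sample_ids = unique(segments$sample),
                             bin_size = 1e6) {
  stopifnot(bin_size > 0, length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)))
  unknown <- setdiff(unique(segments$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    stop(sprintf("segment chromosome(s) not in chrom_lengths: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(segments$end > chrom_lengths[segments$chrom])) {
    stop("segment(s) extend beyond their chromosome length", call. = FALSE)
  }
  # bin grid, chromosome by chromosome; the last bin may be short
  grids <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    start <- seq(1L, len, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size - 1, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, grids)
  nbin <- nrow(bins)
  bin_len <- bins$end - bins$start + 1
  # precompute each chromosome's first-bin offset for index arithmetic
  offset <- c(0, cumsum(vapply(grids, nrow, 1L)))
  names(offset) <- c(names(chrom_lengths), "..end")

  cn <- matrix(0, length(sample_ids), nbin,
               dimnames = list(sample_ids, NULL))
  loh <- matrix(0, length(sample_ids), nbin,
                dimnames = list(sample_ids, NULL))
  keep <- segments$sample %in% sample_ids
  s_row <- match(segments$sample, sample_ids)[keep]
  s_start <- segments$start[keep]; s_end <- segments$end[keep]
  s_dev <- segments$copy_number[keep] - 2
  s_loh <- segments$loh[keep]
  s_off <- offset[segments$chrom[keep]]
  s_first <- (s_start - 1) %/% bin_size + 1
  s_last <- (s_end - 1) %/% bin_size + 1
  for (r in seq_along(s_row)) {
    idx <- s_off[r] + s_first[r]:s_last[r]
    ov_start <- pmax(s_start[r], bins$start[idx])
    ov_end <- pmin(s_end[r], bins$end[idx])
    w <- (ov_end - ov_start + 1) / bin_len[idx]
    i <- s_row[r]
    cn[i, idx] <- cn[i, idx] + w * s_dev[r]
    if (s_loh[r]) loh[i, idx] <- loh[i, idx] + w
  }
  structure(list(sample_ids = sample_ids, bins = bins, cn = cn, loh = loh),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("cnv_matrix: %d samples x %d bins (%d chromosome(s))\n",
              length(x$sample_ids), nrow(x$bins),
              length(unique(x$bins$chrom))))
  invisible(x)
}

#' Write a binned copy-number matrix as TSV
#'
#' One row per sample; columns are `chrom:start-end` bin coordinates for the
#' copy-number layer followed by the same coordinates prefixed `loh:` for
#' the LOH-fraction layer.
#'
#' @param x A `cnv_matrix` (see [build_cnv_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_matrix <- function(x, path) {
  stopifnot(inherits(x, "cnv_matrix"))
  coord <- sprintf("%s:%d-%d", x$bins$chrom, x$bins$start, x$bins$end)
  out <- data.frame(sample = x$sample_ids, x$cn, x$loh, check.names = FALSE)
  names(out) <- c("sample", coord, paste0("loh:", coord))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
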