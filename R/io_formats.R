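#' Somatic mutation effect classes
#'
#' The seven effect classes retained by the exome filtering convention this
#' package expects upstream annotation to use: non-synonymous, synonymous,
#' gain or loss of the stop codon, frameshift and non-frameshift indels, and
#' splice-site mutations.
#'
#' @format Character vector of length 7.
#' @export
mutation_effects <- c(
  "nonsynonymous", "synonymous", "stopgain", "stoploss",
  "frameshift_indel", "nonframeshift_indel", "splicing"
)

# Canonical column sets for the three tabular dialects.
.mutation_cols <- c("sample", "chrom", "pos", "ref", "alt", "gene", "effect")
.segment_cols  <- c("sample", "chrom", "start", "end", "copy_number", "loh")
.manifest_cols <- c("patient", "primary", "metastasis", "normal")

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

.check_columns <- function(df, required, path, mapping = NULL) {
  if (!is.null(mapping)) {
    idx <- match(names(df), names(mapping))
    names(df)[!is.na(idx)] <- unname(mapping[idx[!is.na(idx)]])
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

# Shared strict/lenient row rejection. `bad` is a logical vector over data
# rows, `reason` a parallel character vector (NA where valid). Returns df with
# a "rejected" attribute in lenient mode; stops in strict mode.
.reject_rows <- function(df, bad, reason, path, strict) {
  rejected <- data.frame(line = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (any(bad)) {
    # +1 for the header: `line` is the physical line number in the file
    rejected <- data.frame(line = which(bad) + 1L, reason = reason[bad],
                           stringsAsFactors = FALSE)
    msg <- paste(sprintf("line %d: %s", rejected$line, rejected$reason),
                 collapse = "\n  ")
    if (strict) {
      stop(sprintf("'%s': %d invalid record(s):\n  %s",
                   path, nrow(rejected), msg), call. = FALSE)
    }
    warning(sprintf("'%s': dropped %d invalid record(s):\n  %s",
                    path, nrow(rejected), msg), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "rejected") <- rejected
  df
}

#' Read a MAF-like somatic mutation table
#'
#' Parses a strict tab-separated mutation table with header columns
#' `sample`, `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`. Positions are
#' 1-based single loci; indels carry `"-"` in `ref` or `alt`. The `effect`
#' column must be one of [mutation_effects].
#'
#' Row ordering is preserved. No row is silently dropped: in strict mode
#' (default) any invalid record aborts with line-numbered messages; with
#' `strict = FALSE` invalid records are dropped with a warning and returned
#' in the `"rejected"` attribute (a data frame of `line`, `reason`), so that
#' rows parsed plus rows rejected always equals the data lines in the file.
#'
#' @param path Path to a tab-separated file with the seven-column header.
#' @param strict Abort on invalid records (default) instead of dropping them.
#' @param column_mapping Optional named character vector renaming input
#'   columns to the canonical names, e.g.
#'   `c(Tumor_Sample_Barcode = "sample")`.
#' @return A data frame with character columns `sample`, `chrom`, `ref`,
#'   `alt`, `gene`, `effect` and integer `pos`, one row per mutation call.
#' @seealso [write_mutation_table()], [read_segment_table()]
#' @export
read_mutation_table <- function(path, strict = TRUE, column_mapping = NULL) {
  stopifnot(file.exists(path))
  df <- .check_columns(.read_tsv(path), .mutation_cols, path, column_mapping)
  if (nrow(df) == 0) {
    warning(sprintf("'%s': no data rows (header only)", path), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(df$pos))
  reason <- rep(NA_character_, nrow(df))
  bad_pos <- is.na(pos) | pos < 1L
  reason[bad_pos] <- sprintf("position '%s' is not a positive integer",
                             df$pos[bad_pos])
  bad_eff <- !(df$effect %in% mutation_effects) & is.na(reason)
  reason[bad_eff] <- sprintf("unknown effect '%s' (allowed: %s)",
                             df$effect[bad_eff],
                             paste(mutation_effects, collapse = ", "))
  allele_ok <- function(x) grepl("^([ACGT]+|-)$", x)
  bad_allele <- (!allele_ok(df$ref) | !allele_ok(df$alt) |
                   df$ref == df$alt) & is.na(reason)
  reason[bad_allele] <- sprintf(
    "invalid allele pair ref='%s' alt='%s'", df$ref[bad_allele],
    df$alt[bad_allele])
  df$pos <- pos
  df <- .reject_rows(df, !is.na(reason), reason, path, strict)
  df$pos <- as.integer(df$pos)
  df
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]: writes the canonical seven-column TSV.
#'
#' @param mutations Data frame as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  stopifnot(all(.mutation_cols %in% names(mutations)))
  utils::write.table(mutations[.mutation_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-like copy-number segment table
#'
#' Parses a tab-separated segment table with header columns `sample`,
#' `chrom`, `start`, `end`, `copy_number`, `loh`. Coordinates are 1-based
#' closed intervals. `copy_number` is the non-negative integer total copy
#' number of the segment; `loh` (loss of heterozygosity) is parsed from
#' `{0, 1, true, false}` (case-insensitive).
#'
#' @inheritParams read_mutation_table
#' @return A data frame with columns `sample`, `chrom` (character),
#'   `start`, `end`, `copy_number` (integer) and `loh` (logical).
#' @seealso [write_segment_table()], [categorize_segment()]
#' @export
read_segment_table <- function(path, strict = TRUE, column_mapping = NULL) {
  stopifnot(file.exists(path))
  df <- .check_columns(.read_tsv(path), .segment_cols, path, column_mapping)
  if (nrow(df) == 0) {
    warning(sprintf("'%s': no data rows (header only)", path), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  cn <- suppressWarnings(as.integer(df$copy_number))
  loh_map <- c("0" = FALSE, "1" = TRUE, "true" = TRUE, "false" = FALSE)
  loh <- loh_map[tolower(df$loh)]
  reason <- rep(NA_character_, nrow(df))
  bad_coord <- is.na(start) | is.na(end) | start < 1L | start > end
  reason[bad_coord] <- sprintf("invalid interval [%s, %s] (need 1 <= start <= end)",
                               df$start[bad_coord], df$end[bad_coord])
  bad_cn <- (is.na(cn) | cn < 0L) & is.na(reason)
  reason[bad_cn] <- sprintf("copy_number '%s' is not a non-negative integer",
                            df$copy_number[bad_cn])
  bad_loh <- is.na(loh) & is.na(reason)
  reason[bad_loh] <- sprintf("loh '%s' not one of 0/1/true/false",
                             df$loh[bad_loh])
  df$start <- start; df$end <- end
  df$copy_number <- cn; df$loh <- unname(loh)
  df <- .reject_rows(df, !is.na(reason), reason, path, strict)
  df$loh <- as.logical(df$loh)
  df
}

#' Write a segment table
#'
#' Inverse of [read_segment_table()]; `loh` is written as 0/1.
#'
#' @param segments Data frame as returned by [read_segment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  stopifnot(all(.segment_cols %in% names(segments)))
  out <- segments[.segment_cols]
  out$loh <- as.integer(out$loh)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Parses the tab-separated cohort manifest pairing each patient's primary
#' tumor sample with its metastasis sample (columns `patient`, `primary`,
#' `metastasis`, and optional `normal`; an absent or empty `normal` entry is
#' stored as `NA`). Sample identifiers must be unique across all roles and
#' patients.
#'
#' @param path Path to the manifest TSV.
#' @return A data frame with one row per patient and character columns
#'   `patient`, `primary`, `metastasis`, `normal`.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  df <- .read_tsv(path)
  required <- setdiff(.manifest_cols, "normal")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$normal)) df$normal <- NA_character_
  df$normal[!is.na(df$normal) & df$normal == ""] <- NA_character_
  df <- df[.manifest_cols]
  if (anyDuplicated(df$patient)) {
    stop(sprintf("'%s': duplicated patient id(s): %s", path,
                 paste(unique(df$patient[duplicated(df$patient)]),
                       collapse = ", ")), call. = FALSE)
  }
  ids <- c(df$primary, df$metastasis, df$normal[!is.na(df$normal)])
  if (anyDuplicated(ids)) {
    stop(sprintf("'%s': sample id(s) used more than once: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Write a cohort manifest
#'
#' @param manifest Data frame as returned by [read_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("patient", "primary", "metastasis") %in% names(manifest)))
  if (is.null(manifest$normal)) manifest$normal <- NA_character_
  utils::write.table(manifest[.manifest_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Reference cohort tables
#'
#' Bundled per-sample summaries for a published cohort of 15 paired primary
#' colorectal carcinomas (CRC) and matched colorectal liver metastases (CLM):
#' `reference_scna_burden()` returns the per-sample counts of somatic
#' copy-number alteration events in five categories (one copy gain, one copy
#' loss, high copy gain, homozygous loss, copy-neutral LOH), the total SCNA
#' number and the somatic mutation count; `reference_shared_mutations()`
#' returns the per-pair mutation counts, the SCNA-clustering group and the
#' printed shared point-mutation percentage.
#'
#' These tables drive the package's validation suite: the burden table fixes
#' the total-SCNA counting convention and the hypermutation / LOH analyses,
#' and the shared-mutation table validates the Jaccard shared-percentage
#' formula.
#'
#' @return A data frame (see Details).
#' @export
reference_scna_burden <- function() {
  path <- system.file("extdata", "reference_scna_burden.tsv",
                      package = "clonalpair", mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = c(patient_id = "character"))
  df
}

#' @rdname reference_scna_burden
#' @export
reference_shared_mutations <- function() {
  path <- system.file("extdata", "reference_shared_mutations.tsv",
                      package = "clonalpair", mustWork = TRUE)
  utils::read.delim(path, colClasses = c(patient_id = "character"))
}
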