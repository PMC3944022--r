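#' Pipeline configuration
#'
#' Resolves the options controlling [run_full_pipeline()]. Unknown option
#' names are rejected.
#'
#' @param mutation_table,segment_table,manifest Input file paths (may be
#'   `NULL` when the corresponding in-memory tables are passed to
#'   [run_full_pipeline()] directly).
#' @param out_dir Output directory for the report bundle.
#' @param bin_size Copy-number bin width in bp (default 1 Mb).
#' @param chrom_lengths Named chromosome lengths; by default inferred from
#'   the segment table (per-chromosome maximum segment end).
#' @param metric,linkage Clustering options (defaults `euclidean`,
#'   `complete`).
#' @param loh_weight Weight of the LOH layer in the distance (default 1).
#' @param hypermutation_strategy,hypermutation_param See
#'   [call_hypermutated()].
#' @param ttest_variant `"welch"` (default) or `"pooled"` for the
#'   LOH-association test.
#' @param driver_panel Driver gene panel (default [crc_driver_genes]).
#' @param ... Unknown options are an error.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mutation_table = NULL, segment_table = NULL,
                            manifest = NULL, out_dir = "clonalpair_out",
                            bin_size = 1e6, chrom_lengths = NULL,
                            metric = "euclidean", linkage = "complete",
                            loh_weight = 1,
                            hypermutation_strategy = "absolute",
                            hypermutation_param = NULL,
                            ttest_variant = "welch",
                            driver_panel = crc_driver_genes, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop(sprintf("unknown option(s): %s",
                 paste(names(extra), collapse = ", ")), call. = FALSE)
  }
  structure(as.list(environment())[setdiff(names(formals()), "...")],
            class = "pipeline_config")
}

#' Run the full concordance pipeline
#'
#' End-to-end orchestration: per-sample SCNA burden summary, binned
#' copy-number matrix, hierarchical clustering with pair adjacency,
#' per-pair mutation concordance, hypermutation calls with the
#' repair/polymerase screen, the LOH-association t-test, and the final
#' clonality classification. Writes `scna_summary.tsv`, `adjacency.tsv`,
#' `concordance.tsv`, `hypermutation.tsv`, `association.tsv`,
#' `clonality.tsv`, `dendrogram.nwk` and `run_log.txt` into
#' `config$out_dir`, and returns the tables invisibly.
#'
#' @param config A `pipeline_config`.
#' @param mutations,segments,manifest Optional in-memory tables overriding
#'   the configured paths.
#' @return Invisibly, a list with all report tables, the tree, and the
#'   cohort summary.
#' @export
run_full_pipeline <- function(config = pipeline_config(),
                              mutations = NULL, segments = NULL,
                              manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("clonalpair %s",
                         as.character(utils::packageVersion("clonalpair"))),
                 sprintf("R %s", getRversion()),
                 "resolved config:",
                 vapply(setdiff(names(config), "driver_panel"),
                        function(k) sprintf("  %s = %s", k,
                          paste(format(config[[k]]), collapse = " ")), ""),
                 sprintf("  driver_panel = %s",
                         paste(config$driver_panel, collapse = ",")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(mutations)) {
    mutations <- stage("read_mutations",
                       read_mutation_table(config$mutation_table))
  }
  if (is.null(segments)) {
    segments <- stage("read_segments",
                      read_segment_table(config$segment_table))
  }
  if (is.null(manifest)) {
    manifest <- stage("read_manifest", read_manifest(config$manifest))
  }
  if (nrow(manifest) == 0) stop("empty manifest: no pairs to analyze",
                                call. = FALSE)
  tumor_samples <- c(rbind(manifest$primary, manifest$metastasis))

  scna <- stage("scna_summary", summarize_scna_cohort(
    segments[segments$sample %in% tumor_samples, , drop = FALSE]))

  chrom_lengths <- config$chrom_lengths
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(segments$end, segments$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  cnv <- stage("cnv_matrix", build_cnv_matrix(
    segments, chrom_lengths, sample_ids = tumor_samples,
    bin_size = config$bin_size))
  d <- stage("distance", pairwise_distance(cnv, config$metric,
                                           config$loh_weight))
  tree <- stage("clustering", hierarchical_cluster(d, config$linkage))
  adj <- stage("adjacency", cohort_adjacency(tree, manifest))

  conc <- stage("concordance", pair_concordance(mutations, manifest,
                                                config$driver_panel))

  counts <- table(factor(mutations$sample, levels = tumor_samples))
  hm <- stage("hypermutation", call_hypermutated(
    stats::setNames(as.numeric(counts), names(counts)),
    config$hypermutation_strategy, config$hypermutation_param))
  panel_hits <- vapply(hm$sample_id, function(s) {
    hits <- repair_gene_hits(
      mutations[mutations$sample == s, , drop = FALSE])
    paste(c(hits$repair, hits$polymerase), collapse = ",")
  }, "")
  hm$panel_genes_hit <- unname(panel_hits)

  assoc <- NULL
  met_ids <- manifest$metastasis
  hm_met <- hm[hm$sample_id %in% met_ids, , drop = FALSE]
  if (sum(hm_met$flagged) >= 2 && sum(!hm_met$flagged) >= 2) {
    assoc <- stage("loh_association", loh_association(
      scna[scna$sample_id %in% met_ids, , drop = FALSE], hm_met,
      config$ttest_variant))
  }
  calls <- stage("clonality", classify_cohort(adj, conc))
  summary <- summarize_cohort(calls)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(scna, "scna_summary.tsv")
  wt(adj$pairs, "adjacency.tsv")
  wt(conc, "concordance.tsv")
  wt(hm, "hypermutation.tsv")
  assoc_df <- if (is.null(assoc)) {
    data.frame(variant = config$ttest_variant, t_statistic = NA,
               degrees_of_freedom = NA, p_value = NA,
               note = "skipped: fewer than 2 samples in a group")
  } else {
    data.frame(variant = assoc$variant, t_statistic = assoc$t_statistic,
               degrees_of_freedom = assoc$degrees_of_freedom,
               p_value = assoc$p_value, note = "")
  }
  wt(assoc_df, "association.tsv")
  wt(calls, "clonality.tsv")
  write_newick(tree, file.path(config$out_dir, "dendrogram.nwk"))
  log_lines <- c(log_lines, sprintf(
    "cohort: %d pairs, %d related, %d distinct, %d discordant (fraction related %.3f)",
    summary$n_pairs, summary$n_related, summary$n_distinct,
    summary$n_discordant, summary$fraction_related))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(scna_summary = scna, adjacency = adj, concordance = conc,
                 hypermutation = hm, association = assoc, clonality = calls,
                 tree = tree, summary = summary))
}
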