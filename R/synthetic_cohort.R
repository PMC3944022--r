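#' Simulation configuration for synthetic paired-tumor cohorts
#'
#' Builds the parameter list driving [simulate_cohort()]. Defaults emulate
#' the reference cohort's structure: 15 primary/metastasis pairs of which
#' 8/15 are clonally related; related pairs share a trunk of ~40 mutations
#' over ~65 per sample (shared percentages in the 30–55% range); about a
#' quarter of metastases are hypermutators carrying ~35-fold the baseline
#' private burden (~875 vs <= ~110 mutations) together with missense hits
#' in mismatch-repair and polymerase genes and strongly elevated
#' copy-neutral LOH (negative-binomial around 150 vs an overdispersed
#' baseline around 15); copy-number backbones of related pairs agree up to
#' a small per-bin discordance rate while unrelated profiles are drawn
#' independently.
#'
#' @param n_pairs Number of patients (primary/metastasis pairs).
#' @param fraction_related Fraction of pairs planted as clonally related;
#'   exactly `round(n_pairs * fraction_related)` pairs are related.
#' @param trunk_mutations_mean Poisson mean of shared (trunk) mutations in
#'   related pairs; at least one trunk mutation (the planted driver) is
#'   always present.
#' @param private_mutations_mean Poisson mean of private mutations per
#'   sample.
#' @param hypermutator_probability Per-metastasis probability of the
#'   hypermutator phenotype.
#' @param hypermutator_multiplier Multiplier on the private-mutation mean
#'   for hypermutators.
#' @param loh_baseline_mean,loh_hypermutator_mean Mean copy-neutral LOH
#'   segment counts for normal and hypermutated samples.
#' @param loh_dispersion_baseline,loh_dispersion_hypermutator
#'   Negative-binomial `size` parameters for the two LOH regimes (small =
#'   overdispersed).
#' @param scna_bins Total number of copy-number bins across the toy genome.
#' @param scna_event_rate Per-bin probability that a bin is altered.
#' @param scna_noise_rate Per-bin probability that a related metastasis
#'   redraws a bin independently of its primary.
#' @param driver_panel,repair_panel,polymerase_panel Gene panels for
#'   planted trunk drivers and hypermutator lesions.
#' @param chrom_lengths Named vector of toy-genome chromosome lengths.
#' @param seed Integer seed; the same configuration (seed included) yields
#'   byte-identical outputs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 15,
                              fraction_related = 8 / 15,
                              trunk_mutations_mean = 40,
                              private_mutations_mean = 25,
                              hypermutator_probability = 4 / 15,
                              hypermutator_multiplier = 35,
                              loh_baseline_mean = 15,
                              loh_hypermutator_mean = 150,
                              loh_dispersion_baseline = 0.3,
                              loh_dispersion_hypermutator = 30,
                              scna_bins = 200,
                              scna_event_rate = 0.2,
                              scna_noise_rate = 0.05,
                              driver_panel = crc_driver_genes,
                              repair_panel = mismatch_repair_genes,
                              polymerase_panel = polymerase_genes,
                              chrom_lengths = stats::setNames(
                                rep(10e6, 5), paste0("chr", 1:5)),
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_pairs >= 1,
            fraction_related >= 0, fraction_related <= 1,
            trunk_mutations_mean >= 0, private_mutations_mean >= 0,
            hypermutator_probability >= 0, hypermutator_probability <= 1,
            hypermutator_multiplier > 1,
            loh_baseline_mean >= 0, loh_hypermutator_mean >= 0,
            scna_bins >= length(chrom_lengths),
            scna_event_rate >= 0, scna_event_rate <= 1,
            scna_noise_rate >= 0, scna_noise_rate <= 1,
            length(driver_panel) > 0, !is.null(names(chrom_lengths)))
  # feasibility: expected keys must fit the genome with room to spare
  expected_keys <- n_pairs * (trunk_mutations_mean +
    2 * private_mutations_mean * hypermutator_multiplier + 10)
  if (expected_keys > 0.1 * sum(chrom_lengths)) {
    stop("toy genome too small for the requested mutation load",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# per-bin copy-number states for altered bins
.draw_states <- function(n) {
  sample(c(3L, 1L, 4L, 0L), n, replace = TRUE,
         prob = c(0.45, 0.40, 0.10, 0.05))
}

# one copy-number backbone: NA = unaltered, else integer state
.draw_backbone <- function(nbin, event_rate) {
  st <- rep(NA_integer_, nbin)
  hit <- stats::runif(nbin) < event_rate
  st[hit] <- .draw_states(sum(hit))
  st
}

.effect_probs <- c(nonsynonymous = 0.50, synonymous = 0.25, stopgain = 0.05,
                   stoploss = 0.01, frameshift_indel = 0.06,
                   nonframeshift_indel = 0.04, splicing = 0.09)

# mutation rows for a vector of global genome indices
.keys_to_mutations <- function(sample_id, idx, chrom_lengths,
                               gene = NULL, effect = NULL) {
  n <- length(idx)
  if (n == 0) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      effect = character(0), stringsAsFactors = FALSE))
  }
  bounds <- c(0, cumsum(as.numeric(chrom_lengths)))
  ci <- findInterval(idx - 0.5, bounds)
  chrom <- names(chrom_lengths)[ci]
  pos <- as.integer(idx - bounds[ci])
  if (is.null(effect)) {
    effect <- sample(names(.effect_probs), n, replace = TRUE,
                     prob = .effect_probs)
  } else {
    effect <- rep_len(effect, n)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  indel <- effect %in% c("frameshift_indel", "nonframeshift_indel")
  ins <- indel & stats::runif(n) < 0.5
  ref[ins] <- "-"
  alt[indel & !ins] <- "-"
  if (is.null(gene)) {
    gene <- sprintf("G%s_%d", chrom, pos %/% 50000L)
  } else {
    gene <- rep_len(gene, n)
  }
  data.frame(sample = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = unname(alt), gene = gene, effect = effect,
             stringsAsFactors = FALSE)
}

#' Simulate a paired primary/metastasis cohort with known truth
#'
#' Generates mutation, segment and manifest tables in the package's tabular
#' dialects, together with truth labels, under one global seed and a fixed
#' draw order (relatedness, hypermutator flags, mutation counts, mutation
#' keys, copy-number backbones, LOH counts). Mutation keys are drawn
#' without replacement from a single genome-wide pool, so unrelated samples
#' share zero mutation keys by construction; related pairs share exactly
#' their trunk, which always carries at least one driver-panel mutation.
#' Hypermutated metastases additionally carry one missense mismatch-repair
#' hit and one missense polymerase hit, and their SCNA elevation is
#' confined to the LOH layer so that copy-number relatedness and
#' hypermutation remain independent axes of truth.
#'
#' @param config A `simulation_config`.
#' @return List with `mutations`, `segments`, `manifest` (data frames in
#'   the [read_mutation_table()] / [read_segment_table()] /
#'   [read_manifest()] layouts), `truth` (list of `patients` and `samples`
#'   data frames), `bin_size` (bp, for downstream matrix building), and
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_pairs
  patients <- sprintf("P%02d", seq_len(n))
  manifest <- data.frame(
    patient = patients,
    primary = paste0(patients, "-CRC"),
    metastasis = paste0(patients, "-CLM"),
    normal = paste0(patients, "-N"),
    stringsAsFactors = FALSE
  )

  # --- truth draws (fixed order) ---
  n_related <- round(n * cfg$fraction_related)
  related <- rep(FALSE, n)
  related[sample.int(n, n_related)] <- TRUE
  hyper <- stats::runif(n) < cfg$hypermutator_probability  # metastases only

  trunk_n <- ifelse(related,
                    pmax(1L, stats::rpois(n, cfg$trunk_mutations_mean)), 0L)
  priv_crc <- stats::rpois(n, cfg$private_mutations_mean)
  priv_clm <- stats::rpois(n, ifelse(hyper,
    cfg$private_mutations_mean * cfg$hypermutator_multiplier,
    cfg$private_mutations_mean))
  # extra planted mutations: 1 trunk driver for related pairs; 1 driver per
  # sample for unrelated pairs; repair + polymerase hit for hypermutators
  n_extra_crc <- ifelse(related, 0L, 1L)
  n_extra_clm <- ifelse(related, 0L, 1L) + ifelse(hyper, 2L, 0L)

  genome_len <- sum(as.numeric(cfg$chrom_lengths))
  total_keys <- sum(trunk_n) + sum(priv_crc) + sum(priv_clm) +
    sum(n_extra_crc) + sum(n_extra_clm)
  pool <- sample(genome_len, total_keys, replace = FALSE)
  used <- 0L
  take <- function(k) {
    out <- pool[seq_len(k) + used]
    used <<- used + k
    out
  }

  mut_list <- list()
  truth_samples <- list()
  for (i in seq_len(n)) {
    crc <- manifest$primary[i]; clm <- manifest$metastasis[i]
    trunk_idx <- take(trunk_n[i])
    trunk <- .keys_to_mutations(crc, trunk_idx, cfg$chrom_lengths)
    drivers_crc <- character(0); drivers_clm <- character(0)
    if (related[i]) {
      # first trunk key becomes the shared driver mutation
      g <- sample(cfg$driver_panel, 1)
      trunk$gene[1] <- g
      trunk$effect[1] <- "nonsynonymous"
      trunk$ref[1] <- "A"; trunk$alt[1] <- "G"
      drivers_crc <- g; drivers_clm <- g
    }
    trunk_clm <- trunk
    if (nrow(trunk_clm) > 0) trunk_clm$sample <- clm
    crc_rows <- rbind(trunk,
                      .keys_to_mutations(crc, take(priv_crc[i]),
                                         cfg$chrom_lengths))
    clm_rows <- rbind(trunk_clm,
                      .keys_to_mutations(clm, take(priv_clm[i]),
                                         cfg$chrom_lengths))
    if (!related[i]) {
      gc_ <- sample(cfg$driver_panel, 1)
      gm_ <- sample(cfg$driver_panel, 1)
      crc_rows <- rbind(crc_rows, .keys_to_mutations(
        crc, take(1L), cfg$chrom_lengths, gene = gc_,
        effect = "nonsynonymous"))
      clm_rows <- rbind(clm_rows, .keys_to_mutations(
        clm, take(1L), cfg$chrom_lengths, gene = gm_,
        effect = "nonsynonymous"))
      drivers_crc <- gc_; drivers_clm <- gm_
    }
    repair_hit <- NA_character_; pol_hit <- NA_character_
    if (hyper[i]) {
      repair_hit <- sample(cfg$repair_panel, 1)
      pol_hit <- sample(cfg$polymerase_panel, 1)
      clm_rows <- rbind(clm_rows,
        .keys_to_mutations(clm, take(1L), cfg$chrom_lengths,
                           gene = repair_hit, effect = "nonsynonymous"),
        .keys_to_mutations(clm, take(1L), cfg$chrom_lengths,
                           gene = pol_hit, effect = "nonsynonymous"))
    }
    mut_list[[i]] <- rbind(crc_rows, clm_rows)
    truth_samples[[i]] <- data.frame(
      sample = c(crc, clm), patient = patients[i],
      role = c("primary", "metastasis"),
      hypermutator = c(FALSE, hyper[i]),
      n_mutations = c(nrow(crc_rows), nrow(clm_rows)),
      n_trunk = trunk_n[i],
      planted_driver = c(paste(drivers_crc, collapse = ","),
                         paste(drivers_clm, collapse = ",")),
      planted_repair_hit = c(NA_character_, repair_hit),
      planted_polymerase_hit = c(NA_character_, pol_hit),
      stringsAsFactors = FALSE
    )
  }
  mutations <- do.call(rbind, mut_list)
  rownames(mutations) <- NULL

  # --- copy-number backbones and segment tables ---
  n_chrom <- length(cfg$chrom_lengths)
  bins_per_chrom <- max(1L, round(cfg$scna_bins / n_chrom))
  if (length(unique(cfg$chrom_lengths)) != 1 ||
      cfg$chrom_lengths[1] %% bins_per_chrom != 0) {
    stop("toy-genome chromosomes must have equal lengths divisible by ",
         "the per-chromosome bin count", call. = FALSE)
  }
  bin_size <- as.integer(cfg$chrom_lengths[1] %/% bins_per_chrom)
  nbin <- bins_per_chrom * n_chrom
  bin_chrom <- rep(names(cfg$chrom_lengths), each = bins_per_chrom)
  bin_start <- rep((seq_len(bins_per_chrom) - 1L) * bin_size + 1L, n_chrom)

  seg_list <- list()
  loh_truth <- integer(2 * n)
  for (i in seq_len(n)) {
    base <- .draw_backbone(nbin, cfg$scna_event_rate)
    if (related[i]) {
      met <- base
      redraw <- stats::runif(nbin) < cfg$scna_noise_rate
      if (any(redraw)) {
        fresh <- .draw_backbone(sum(redraw), cfg$scna_event_rate)
        met[redraw] <- fresh
      }
    } else {
      met <- .draw_backbone(nbin, cfg$scna_event_rate)
    }
    for (side in 1:2) {
      sid <- if (side == 1) manifest$primary[i] else manifest$metastasis[i]
      st <- if (side == 1) base else met
      alt <- which(!is.na(st))
      segs <- data.frame(
        sample = rep(sid, length(alt)),
        chrom = bin_chrom[alt],
        start = bin_start[alt],
        end = bin_start[alt] + bin_size - 1L,
        copy_number = st[alt], loh = rep(FALSE, length(alt)),
        stringsAsFactors = FALSE
      )
      is_hyper <- side == 2 && hyper[i]
      k <- stats::rnbinom(1,
        size = if (is_hyper) cfg$loh_dispersion_hypermutator
               else cfg$loh_dispersion_baseline,
        mu = if (is_hyper) cfg$loh_hypermutator_mean
             else cfg$loh_baseline_mean)
      loh_truth[2 * (i - 1) + side] <- k
      if (k > 0) {
        ci <- sample(n_chrom, k, replace = TRUE)
        pos <- as.integer(stats::runif(k,
          max = cfg$chrom_lengths[ci] - 10000)) + 1L
        segs <- rbind(segs, data.frame(
          sample = rep(sid, k), chrom = names(cfg$chrom_lengths)[ci],
          start = pos, end = pos + 9999L,
          copy_number = rep(2L, k), loh = rep(TRUE, k),
          stringsAsFactors = FALSE
        ))
      }
      seg_list[[length(seg_list) + 1]] <- segs
    }
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  truth_s <- do.call(rbind, truth_samples)
  truth_s$n_loh <- loh_truth
  rownames(truth_s) <- NULL
  truth <- list(
    patients = data.frame(patient = patients, related = related,
                          stringsAsFactors = FALSE),
    samples = truth_s
  )
  list(mutations = mutations, segments = segments, manifest = manifest,
       truth = truth, bin_size = bin_size, config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits the three pipeline input tables plus per-patient and per-sample
#' truth tables into a directory. Identical configurations produce
#' byte-identical files.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mutation_table(sim$mutations, file.path(dir, "mutations.tsv"))
  write_segment_table(sim$segments, file.path(dir, "segments.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  utils::write.table(sim$truth$patients,
                     file.path(dir, "truth_patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples,
                     file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' Pipeline recovery experiment on simulated cohorts
#'
#' Simulates `replicates` cohorts (seeds `config$seed + 1, ...,
#' config$seed + replicates`), runs the full pipeline on each — SCNA matrix,
#' clustering, pair adjacency, mutation concordance, hypermutation calls,
#' clonality classification — and scores every stage against the planted
#' truth.
#'
#' @param config Base `simulation_config`.
#' @param replicates Number of simulated cohorts (>= 1).
#' @param linkage,metric Clustering options (defaults `complete`,
#'   `euclidean`).
#' @return List with `per_replicate` (data frame of per-replicate
#'   classification accuracy, adjacency sensitivity/specificity, and
#'   hypermutator-call accuracy) and `overall` (pooled across replicates,
#'   weighting every pair equally).
#' @export
recovery_experiment <- function(config = simulation_config(),
                                replicates = 20,
                                linkage = "complete",
                                metric = "euclidean") {
  stopifnot(replicates >= 1)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_cohort(cfg)
    res <- tryCatch(
      .score_replicate(sim, linkage, metric),
      error = function(e) stop(sprintf("replicate %d: %s", r,
                                       conditionMessage(e)), call. = FALSE))
    rows[[r]] <- cbind(data.frame(replicate = r), res)
  }
  per_rep <- do.call(rbind, rows)
  overall <- data.frame(
    classification_accuracy =
      sum(per_rep$n_correct) / sum(per_rep$n_pairs),
    adjacency_sensitivity =
      sum(per_rep$n_adj_tp) / sum(per_rep$n_related),
    adjacency_specificity =
      sum(per_rep$n_adj_tn) / sum(per_rep$n_unrelated),
    hypermutator_accuracy =
      sum(per_rep$n_hyper_correct) / sum(per_rep$n_samples)
  )
  list(per_replicate = per_rep, overall = overall)
}

.score_replicate <- function(sim, linkage, metric) {
  cfg <- sim$config
  cnv <- build_cnv_matrix(sim$segments, cfg$chrom_lengths,
                          sample_ids = c(rbind(sim$manifest$primary,
                                               sim$manifest$metastasis)),
                          bin_size = sim$bin_size)
  d <- pairwise_distance(cnv, metric)
  tree <- hierarchical_cluster(d, linkage)
  adj <- cohort_adjacency(tree, sim$manifest)
  conc <- pair_concordance(sim$mutations, sim$manifest, cfg$driver_panel)
  calls <- classify_cohort(adj, conc)

  counts <- table(sim$mutations$sample)
  hm <- call_hypermutated(
    stats::setNames(as.numeric(counts), names(counts)), "absolute")
  truth_p <- sim$truth$patients
  truth_s <- sim$truth$samples
  related_hat <- calls$label[match(truth_p$patient, calls$patient)] ==
    "related"
  adj_hat <- adj$pairs$adjacent[match(truth_p$patient, adj$pairs$patient)]
  hyper_hat <- hm$flagged[match(truth_s$sample, hm$sample_id)]
  data.frame(
    n_pairs = nrow(truth_p),
    n_correct = sum(related_hat == truth_p$related),
    n_related = sum(truth_p$related),
    n_adj_tp = sum(adj_hat & truth_p$related),
    n_unrelated = sum(!truth_p$related),
    n_adj_tn = sum(!adj_hat & !truth_p$related),
    n_samples = nrow(truth_s),
    n_hyper_correct = sum(hyper_hat == truth_s$hypermutator)
  )
}
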