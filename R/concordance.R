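#' Gene panels
#'
#' Built-in gene panels used by the concordance and hypermutation analyses:
#' the colorectal-cancer driver panel (`crc_driver_genes`), the VEGF-pathway
#' receptor panel (`vegf_pathway_genes`), the DNA mismatch-repair pathway
#' panel (`mismatch_repair_genes`) and the DNA polymerase panel
#' (`polymerase_genes`). All functions taking a panel accept any character
#' vector of gene symbols, so custom panels drop in directly.
#'
#' @format Character vectors of HGNC gene symbols.
#' @name gene_panels
NULL

#' @rdname gene_panels
#' @export
crc_driver_genes <- c("APC", "KRAS", "TP53", "SMAD4", "BRAF", "FAT4")

#' @rdname gene_panels
#' @export
vegf_pathway_genes <- c("KDR", "FLT1", "FLT4")

#' @rdname gene_panels
#' @export
mismatch_repair_genes <- c("MLH1", "MLH3", "MSH2", "MSH6", "PMS2", "PMS6",
                           "ERCC2", "ERCC5", "ERCC6", "MUTYH", "RAD9A",
                           "EXO1", "SLX4", "ATR", "BLM")

#' @rdname gene_panels
#' @export
polymerase_genes <- c("POLN", "POLL", "POLQ", "POLH", "POLE", "POLD1", "POLG")

# Non-silent effect classes: everything but synonymous.
.nonsilent_effects <- function() setdiff(mutation_effects, "synonymous")

#' Mutation identity keys
#'
#' Two mutation calls are "the same mutation" iff chromosome, position,
#' reference allele and alternate allele all agree; `mutation_key()` encodes
#' that identity as `"chrom:pos:ref:alt"` strings. Duplicate calls within a
#' sample collapse to one key.
#'
#' @param mutations Mutation data frame (see [read_mutation_table()]).
#' @return Character vector of keys, one per row of `mutations`.
#' @export
mutation_key <- function(mutations) {
  sprintf("%s:%d:%s:%s", mutations$chrom, mutations$pos,
          mutations$ref, mutations$alt)
}

#' Shared mutations between two samples
#'
#' The set of mutation keys present in both mutation lists (set
#' intersection after collapsing within-sample duplicates).
#'
#' @param muts_a,muts_b Mutation data frames for the two samples.
#' @return Character vector of shared keys (possibly empty).
#' @export
shared_mutations <- function(muts_a, muts_b) {
  intersect(unique(mutation_key(muts_a)), unique(mutation_key(muts_b)))
}

#' Shared point-mutation percentage (Jaccard form)
#'
#' The percentage of the union of two samples' mutation sets that is shared:
#' `100 * S / (n_a + n_b - S)` for `S` shared mutations among `n_a` and
#' `n_b` total. Defined as 0 when both sets are empty. This Jaccard
#' denominator is the convention the bundled reference cohort's printed
#' shared percentages follow (an integer `S` reproduces every printed value
#' to within 0.05; see the package validation suite).
#'
#' @param n_a,n_b Mutation counts of the two samples.
#' @param n_shared Number of shared mutations; at most `min(n_a, n_b)`.
#' @return Percentage in `[0, 100]` (full precision; round to one decimal
#'   for reporting).
#' @examples
#' shared_percentage(72, 65, 48)  # 53.93
#' @export
shared_percentage <- function(n_a, n_b, n_shared) {
  stopifnot(n_a >= 0, n_b >= 0, n_shared >= 0,
            n_shared <= pmin(n_a, n_b))
  denom <- n_a + n_b - n_shared
  ifelse(denom == 0, 0, 100 * n_shared / denom)
}

#' Driver-gene concordance between paired samples
#'
#' For each gene of a panel: the gene is *shared* iff both samples carry at
#' least one non-silent mutation at an identical mutation key in that gene,
#' and *discordant* iff the gene carries a non-silent mutation in at least
#' one sample but no key is shared (e.g. the same driver mutated at
#' different positions in primary and metastasis).
#'
#' @param muts_a,muts_b Mutation data frames for the paired samples.
#' @param panel Character vector of gene symbols (default the colorectal
#'   driver panel [crc_driver_genes]).
#' @return List with character vectors `shared` and `discordant` (disjoint).
#' @export
driver_concordance <- function(muts_a, muts_b, panel = crc_driver_genes) {
  stopifnot(length(panel) > 0)
  keys_in <- function(m, g) {
    sel <- m$gene == g & m$effect %in% .nonsilent_effects()
    unique(mutation_key(m[sel, , drop = FALSE]))
  }
  shared <- character(0); discordant <- character(0)
  for (g in panel) {
    ka <- keys_in(muts_a, g); kb <- keys_in(muts_b, g)
    if (length(intersect(ka, kb)) > 0) {
      shared <- c(shared, g)
    } else if (length(ka) + length(kb) > 0) {
      discordant <- c(discordant, g)
    }
  }
  list(shared = shared, discordant = discordant)
}

#' Per-pair mutation concordance over a cohort
#'
#' Computes, for every patient of the manifest, the primary and metastasis
#' mutation counts (unique keys, all seven effect classes), the shared
#' count, the Jaccard shared percentage, and the shared / discordant driver
#' genes under `panel`.
#'
#' @param mutations Cohort mutation data frame.
#' @param manifest Cohort manifest (see [read_manifest()]).
#' @param panel Driver panel (default [crc_driver_genes]).
#' @return Data frame with one row per patient: `patient`, `n_primary`,
#'   `n_metastasis`, `n_shared`, `shared_pct`, `n_shared_drivers`,
#'   `shared_drivers`, `discordant_drivers` (gene lists comma-joined).
#' @export
pair_concordance <- function(mutations, manifest, panel = crc_driver_genes) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    ma <- mutations[mutations$sample == manifest$primary[i], , drop = FALSE]
    mb <- mutations[mutations$sample == manifest$metastasis[i], , drop = FALSE]
    sh <- shared_mutations(ma, mb)
    dc <- driver_concordance(ma, mb, panel)
    na <- length(unique(mutation_key(ma)))
    nb <- length(unique(mutation_key(mb)))
    data.frame(
      patient = manifest$patient[i],
      n_primary = na, n_metastasis = nb, n_shared = length(sh),
      shared_pct = shared_percentage(na, nb, length(sh)),
      n_shared_drivers = length(dc$shared),
      shared_drivers = paste(dc$shared, collapse = ","),
      discordant_drivers = paste(dc$discordant, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-gene discordance rate across a cohort
#'
#' A pair is *informative* for a gene when at least one member carries a
#' non-silent mutation in it, and *discordant* when informative with no
#' shared mutation key in that gene. The rate is discordant / informative
#' (e.g. KRAS discordant in 3 of 6 informative pairs gives 0.5).
#'
#' @param mutations Cohort mutation data frame.
#' @param manifest Cohort manifest.
#' @param gene Gene symbol.
#' @return List with `n_discordant`, `n_informative`, `rate` (`NA` with a
#'   warning when no pair is informative).
#' @export
gene_discordance_rate <- function(mutations, manifest, gene) {
  stopifnot(is.character(gene), length(gene) == 1, nzchar(gene))
  status <- vapply(seq_len(nrow(manifest)), function(i) {
    ma <- mutations[mutations$sample == manifest$primary[i], , drop = FALSE]
    mb <- mutations[mutations$sample == manifest$metastasis[i], , drop = FALSE]
    dc <- driver_concordance(ma, mb, panel = gene)
    if (length(dc$shared) > 0) "concordant"
    else if (length(dc$discordant) > 0) "discordant"
    else "uninformative"
  }, character(1))
  n_inf <- sum(status != "uninformative")
  n_dis <- sum(status == "discordant")
  if (n_inf == 0) {
    warning(sprintf("no pair informative for gene '%s'; rate undefined",
                    gene), call. = FALSE)
    return(list(n_discordant = 0L, n_informative = 0L, rate = NA_real_))
  }
  list(n_discordant = n_dis, n_informative = n_inf, rate = n_dis / n_inf)
}

#' Gene mutation frequency by tissue role
#'
#' Percentage of a cohort's samples of one role (primary or metastasis)
#' carrying at least one non-silent mutation in a gene, e.g. a driver
#' mutated in 11 of 15 primaries gives 73 (integer percent on report;
#' returned at full precision).
#'
#' @param mutations Cohort mutation data frame.
#' @param manifest Cohort manifest.
#' @param gene Gene symbol.
#' @param role `"primary"` or `"metastasis"`.
#' @return Percentage in `[0, 100]`.
#' @export
gene_mutation_frequency <- function(mutations, manifest, gene,
                                    role = c("primary", "metastasis")) {
  role <- match.arg(role)
  samples <- manifest[[role]]
  if (length(samples) == 0) stop("no samples of the requested role",
                                 call. = FALSE)
  hit <- mutations$gene == gene & mutations$effect %in% .nonsilent_effects()
  mutated <- unique(mutations$sample[hit])
  100 * sum(samples %in% mutated) / length(samples)
}

#' Single-base substitution spectrum
#'
#' Classifies each single-nucleotide substitution into the six
#' pyrimidine-context classes `C>A, C>G, C>T, T>A, T>C, T>G` — purine
#' references are strand-collapsed to their complement (so `G>T` counts as
#' `C>A`) — and returns class proportions. Indels and multi-base variants
#' are excluded from the tally.
#'
#' @param mutations Mutation data frame.
#' @return Named numeric vector of 6 proportions summing to 1; all zeros
#'   (with attribute `n_substitutions = 0` and a warning) when no
#'   substitution is present.
#' @export
mutation_spectrum <- function(mutations) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  snv <- mutations$ref %in% bases & mutations$alt %in% bases
  ref <- mutations$ref[snv]; alt <- mutations$alt[snv]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  tab <- table(factor(paste0(ref, ">", alt), levels = classes))
  n <- sum(tab)
  out <- if (n == 0) {
    warning("no single-base substitutions; spectrum undefined",
            call. = FALSE)
    stats::setNames(numeric(6), classes)
  } else {
    as.numeric(tab) / n
  }
  names(out) <- classes
  attr(out, "n_substitutions") <- as.integer(n)
  out
}
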