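make_muts <- function(sample, pos, gene = "G1", effect = "nonsynonymous",
                      chrom = "chr1", ref = "A", alt = "G") {
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene, effect = effect,
             stringsAsFactors = FALSE)
}

test_that("shared mutations are the key-set intersection", {
  a <- make_muts("A", 1:5)
  b <- make_muts("B", 6:10)
  expect_length(shared_mutations(a, b), 0)
  expect_length(shared_mutations(a, transform(a, sample = "B")), 5)

  # planted overlap of size k, with within-sample duplicates collapsing
  set.seed(41)
  for (k in c(0, 3, 7)) {
    a <- make_muts("A", 1:20)
    b <- make_muts("B", c(seq_len(k), 101:120))
    a_dup <- rbind(a, a[1, ])
    got <- shared_mutations(a_dup, b)
    # exhaustive double-loop oracle
    want <- unique(unlist(lapply(mutation_key(a), function(ka) {
      ka[ka %in% mutation_key(b)]
    })))
    expect_setequal(got, want)
    expect_length(got, k)
  }
})

test_that("shared percentage uses the Jaccard denominator", {
  expect_equal(round(shared_percentage(72, 65, 48), 1), 53.9)
  expect_equal(round(shared_percentage(55, 63, 36), 1), 43.9)
  expect_equal(shared_percentage(10, 12, 0), 0)
  expect_equal(shared_percentage(0, 0, 0), 0)
  expect_equal(shared_percentage(5, 5, 5), 100)
  # symmetry and bounds
  set.seed(42)
  for (i in 1:50) {
    na <- sample(0:200, 1); nb <- sample(0:200, 1)
    s <- sample(0:min(na, nb), 1)
    p <- shared_percentage(na, nb, s)
    expect_equal(p, shared_percentage(nb, na, s))
    expect_gte(p, 0); expect_lte(p, 100)
  }
  expect_error(shared_percentage(5, 5, 6))
  expect_error(shared_percentage(-1, 5, 0))
})

test_that("an integer shared count reproduces every reference percentage", {
  # validates the Jaccard formula choice against the published table
  ref <- reference_shared_mutations()
  expect_equal(nrow(ref), 15)
  for (i in seq_len(nrow(ref))) {
    s_grid <- 0:min(ref$crc_mutations[i], ref$clm_mutations[i])
    pct <- shared_percentage(ref$crc_mutations[i], ref$clm_mutations[i],
                             s_grid)
    expect_lte(min(abs(pct - ref$shared_pct[i])), 0.05,
               label = sprintf("pair %s", ref$patient_id[i]))
  }
})

test_that("driver concordance distinguishes shared keys from same-gene hits", {
  a <- make_muts("A", 100, gene = "KRAS")
  b <- make_muts("B", 100, gene = "KRAS")
  res <- driver_concordance(a, b)
  expect_equal(res$shared, "KRAS")
  expect_length(res$discordant, 0)

  b2 <- make_muts("B", 200, gene = "KRAS")  # same gene, different key
  res2 <- driver_concordance(a, b2)
  expect_length(res2$shared, 0)
  expect_equal(res2$discordant, "KRAS")

  # synonymous hits never count
  syn <- make_muts("B", 100, gene = "KRAS", effect = "synonymous")
  res3 <- driver_concordance(a, syn)
  expect_equal(res3$discordant, "KRAS")

  # random planted panels vs exhaustive oracle over genes x keys
  set.seed(43)
  panel <- c("APC", "KRAS", "TP53")
  for (rep in 1:20) {
    a <- make_muts("A", sample.int(50, 12),
                   gene = sample(c(panel, "GX"), 12, replace = TRUE),
                   effect = sample(mutation_effects, 12, replace = TRUE))
    b <- make_muts("B", sample.int(50, 12),
                   gene = sample(c(panel, "GX"), 12, replace = TRUE),
                   effect = sample(mutation_effects, 12, replace = TRUE))
    got <- driver_concordance(a, b, panel)
    nonsil <- function(m, g) {
      keep <- m$gene == g & m$effect != "synonymous"
      unique(mutation_key(m[keep, , drop = FALSE]))
    }
    want_shared <- panel[vapply(panel, function(g)
      length(intersect(nonsil(a, g), nonsil(b, g))) > 0, TRUE)]
    want_disc <- setdiff(panel[vapply(panel, function(g)
      length(union(nonsil(a, g), nonsil(b, g))) > 0, TRUE)], want_shared)
    expect_setequal(got$shared, want_shared)
    expect_setequal(got$discordant, want_disc)
    expect_length(intersect(got$shared, got$discordant), 0)
  }
})

test_that("gene discordance rate counts informative pairs", {
  man <- data.frame(patient = c("P1", "P2", "P3", "P4", "P5", "P6", "P7"),
                    primary = paste0("C", 1:7), metastasis = paste0("M", 1:7),
                    normal = NA_character_)
  # P1-P3 concordant KRAS, P4-P6 discordant, P7 uninformative
  muts <- rbind(
    do.call(rbind, lapply(1:3, function(i) rbind(
      make_muts(paste0("C", i), 100, gene = "KRAS"),
      make_muts(paste0("M", i), 100, gene = "KRAS")))),
    do.call(rbind, lapply(4:6, function(i)
      make_muts(paste0("C", i), 100 + i, gene = "KRAS"))),
    make_muts("C7", 500, gene = "APC"), make_muts("M7", 500, gene = "APC"))
  res <- gene_discordance_rate(muts, man, "KRAS")
  expect_equal(res$n_informative, 6)
  expect_equal(res$n_discordant, 3)
  expect_equal(res$rate, 0.5)

  res_apc <- gene_discordance_rate(muts, man, "APC")
  expect_equal(res_apc$rate, 0)

  expect_warning(res_na <- gene_discordance_rate(muts, man, "BRAF"),
                 "no pair informative")
  expect_true(is.na(res_na$rate))
})

test_that("gene mutation frequency is the fraction of samples of a role", {
  n <- 15
  man <- data.frame(patient = sprintf("P%02d", 1:n),
                    primary = sprintf("C%02d", 1:n),
                    metastasis = sprintf("M%02d", 1:n),
                    normal = NA_character_)
  muts <- do.call(rbind, lapply(1:11, function(i)
    make_muts(sprintf("C%02d", i), i, gene = "APC")))
  expect_equal(round(gene_mutation_frequency(muts, man, "APC", "primary")),
               73)
  expect_equal(gene_mutation_frequency(muts, man, "APC", "metastasis"), 0)
  expect_equal(gene_mutation_frequency(muts, man, "TP53", "primary"), 0)
})

test_that("pair concordance table ties counts, sharing, and drivers together", {
  man <- data.frame(patient = "P1", primary = "C1", metastasis = "M1",
                    normal = NA_character_)
  a <- rbind(make_muts("C1", 1:10, gene = "GX"),
             make_muts("C1", 99, gene = "APC"))
  b <- rbind(make_muts("M1", c(1:4, 21:26), gene = "GX"),
             make_muts("M1", 99, gene = "APC"))
  pc <- pair_concordance(rbind(a, b), man)
  expect_equal(pc$n_primary, 11)
  expect_equal(pc$n_metastasis, 11)
  expect_equal(pc$n_shared, 5)  # keys 1:4 plus the shared APC key
  expect_equal(pc$shared_pct, shared_percentage(11, 11, 5))
  expect_equal(pc$n_shared_drivers, 1)
  expect_equal(pc$shared_drivers, "APC")
  expect_gte(pc$n_primary, pc$n_shared)
})

test_that("mutation spectrum collapses purine references to pyrimidine classes", {
  g_t <- make_muts("S", 1, ref = "G", alt = "T")
  sp <- mutation_spectrum(g_t)
  expect_equal(unname(sp["C>A"]), 1)
  expect_equal(sum(sp), 1)

  # all 12 raw substitutions equally often -> uniform 1/6
  bases <- c("A", "C", "G", "T")
  raw <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  raw <- raw[raw$ref != raw$alt, ]
  all12 <- make_muts("S", seq_len(nrow(raw)), ref = raw$ref, alt = raw$alt)
  expect_equal(as.numeric(mutation_spectrum(all12)), rep(1 / 6, 6))

  # indels are excluded; empty tally flagged
  indel <- make_muts("S", 1:3, ref = "-", alt = "G",
                     effect = "frameshift_indel")
  expect_warning(sp0 <- mutation_spectrum(indel), "no single-base")
  expect_equal(as.numeric(sp0), rep(0, 6))
  expect_equal(attr(sp0, "n_substitutions"), 0L)

  # 1000 random substitutions vs direct tally
  set.seed(44)
  ref <- sample(bases, 1000, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  muts <- make_muts("S", 1:1000, ref = ref, alt = unname(alt))
  got <- mutation_spectrum(muts)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r2 <- ifelse(ref %in% c("A", "G"), comp[ref], ref)
  a2 <- ifelse(ref %in% c("A", "G"), comp[alt], alt)
  want <- table(factor(paste0(r2, ">", a2),
                       levels = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")))
  expect_equal(as.numeric(got), as.numeric(want) / 1000)
})
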