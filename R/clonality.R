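#' Classify one primary/metastasis pair as clonally related or distinct
#'
#' Integrates the two evidence streams into the final call: a pair is
#' `related` when its samples are dendrogram siblings in the SCNA clustering
#' *and* share at least one driver-gene mutation key; `distinct` when
#' neither holds; and `discordant_evidence` when the two streams disagree
#' (in the reference cohort they never did, but a total rule needs the third
#' label). The shared-mutation percentage is carried as evidence only — a
#' non-adjacent pair sharing many mutations is still called `distinct`, with
#' a high-shared-fraction note in the evidence trail.
#'
#' @param adjacent Logical: are the pair's samples dendrogram siblings?
#' @param concordance One row of [pair_concordance()] output (data frame or
#'   list with `n_shared_drivers`, `shared_pct`, and optionally `patient`,
#'   `shared_drivers`).
#' @param high_shared_warn Shared percentage above which a distinct call is
#'   annotated as tension between evidence streams (default 20).
#' @return One-row data frame: `patient`, `adjacent`, `n_shared_drivers`,
#'   `shared_pct`, `label`, `evidence`.
#' @export
classify_pair <- function(adjacent, concordance, high_shared_warn = 20) {
  stopifnot(is.logical(adjacent), length(adjacent) == 1)
  nsd <- concordance$n_shared_drivers
  pct <- concordance$shared_pct
  label <- if (adjacent && nsd >= 1) "related"
    else if (!adjacent && nsd == 0) "distinct"
    else "discordant_evidence"
  evidence <- sprintf(
    "adjacent=%s; shared_drivers=%d%s; shared_pct=%.1f",
    adjacent, nsd,
    if (nsd > 0 && !is.null(concordance$shared_drivers))
      sprintf(" (%s)", concordance$shared_drivers) else "",
    pct)
  if (label == "distinct" && pct > high_shared_warn) {
    evidence <- paste0(evidence,
      "; WARNING: high shared fraction despite distinct call")
  }
  if (label == "discordant_evidence") {
    evidence <- paste0(evidence, "; evidence streams disagree")
  }
  data.frame(
    patient = if (!is.null(concordance$patient)) concordance$patient
      else NA_character_,
    adjacent = adjacent, n_shared_drivers = nsd, shared_pct = pct,
    label = label, evidence = evidence, stringsAsFactors = FALSE
  )
}

#' Classify every pair of a cohort
#'
#' Runs [classify_pair()] over the rows of an adjacency result and a
#' concordance table (matched by patient).
#'
#' @param adjacency Result of [cohort_adjacency()].
#' @param concordance Result of [pair_concordance()].
#' @param high_shared_warn Passed to [classify_pair()].
#' @return Data frame of clonality calls, one row per patient.
#' @export
classify_cohort <- function(adjacency, concordance, high_shared_warn = 20) {
  pairs <- adjacency$pairs
  idx <- match(pairs$patient, concordance$patient)
  if (anyNA(idx)) {
    stop("concordance table missing patient(s) present in adjacency",
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    classify_pair(pairs$adjacent[i], concordance[idx[i], , drop = FALSE],
                  high_shared_warn)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Summarize clonality calls over a cohort
#'
#' @param calls Data frame of clonality calls (see [classify_cohort()]).
#' @return List with `n_pairs`, `n_related`, `n_distinct`, `n_discordant`,
#'   `fraction_related`.
#' @export
summarize_cohort <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  n <- nrow(calls)
  nr <- sum(calls$label == "related")
  nd <- sum(calls$label == "distinct")
  nq <- sum(calls$label == "discordant_evidence")
  list(n_pairs = n, n_related = nr, n_distinct = nd, n_discordant = nq,
       fraction_related = nr / n)
}
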