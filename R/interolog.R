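## Interolog transfer: predict target-organism interactions by mapping
## experimentally determined reference interactions across filtered
## best-hit orthologs.

#' Filter homology hits by E-value, identity and coverage
#'
#' Retains the hits satisfying all three interolog-method thresholds:
#' E-value at most `max_evalue`, percent identity at least `min_identity`,
#' and alignment coverage at least `min_coverage`. Coverage is computed from
#' the alignment length relative to both the query and the subject sequence
#' length; by default the smaller of the two must clear the threshold (the
#' stricter symmetric reading), `coverage_mode = "query"` uses the query-side
#' coverage only.
#'
#' @param hits A homology hit tibble from [read_homology_table()].
#' @param max_evalue Maximum E-value (default `1e-5`).
#' @param min_identity Minimum percent identity (default `30`).
#' @param min_coverage Minimum percent alignment coverage (default `60`).
#' @param coverage_mode `"both"` (default) or `"query"`.
#' @return The retained hits, in input order, with added columns
#'   `query_coverage` and `subject_coverage` (percent).
#' @export
filter_homology_hits <- function(hits, max_evalue = 1e-5, min_identity = 30,
                                 min_coverage = 60,
                                 coverage_mode = c("both", "query")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(max_evalue > 0, min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100)
  hits <- as_tibble(hits)
  if (nrow(hits) && any(hits$query_length <= 0 | hits$subject_length <= 0)) {
    abort("invalid hit: query_length and subject_length must be positive")
  }
  hits <- dplyr::mutate(
    hits,
    query_coverage = 100 * .data$alignment_length / .data$query_length,
    subject_coverage = 100 * .data$alignment_length / .data$subject_length
  )
  cov <- switch(coverage_mode,
    both = pmin(hits$query_coverage, hits$subject_coverage),
    query = hits$query_coverage
  )
  dplyr::filter(
    hits,
    .data$evalue <= max_evalue,
    .data$percent_identity >= min_identity,
    cov >= min_coverage
  )
}

#' Keep the best hit per query and reference organism
#'
#' Among threshold-filtered hits, keeps for every (query, organism) pair the
#' single subject with the highest bit score — the interolog method's rule
#' for queries with multiple homologs in one organism. Ties are broken by
#' smaller E-value, then by lexicographically smaller subject id, so the map
#' is deterministic.
#'
#' @param hits A filtered homology hit tibble.
#' @return An ortholog map tibble: `query_id`, `subject_organism`,
#'   `subject_id`, `bit_score`, one row per (query, organism).
#' @export
best_hit_per_organism <- function(hits) {
  as_tibble(hits) |>
    dplyr::arrange(
      .data$query_id, .data$subject_organism,
      dplyr::desc(.data$bit_score), .data$evalue, .data$subject_id
    ) |>
    dplyr::distinct(.data$query_id, .data$subject_organism,
                    .keep_all = TRUE) |>
    dplyr::select("query_id", "subject_organism", "subject_id", "bit_score")
}

#' Transfer reference interactions across the ortholog map
#'
#' Emits the canonical edge (A, B) for target proteins A and B whenever the
#' ortholog map sends A and B to reference proteins a and b in the *same*
#' reference organism and (a, b) is an experimentally determined interaction
#' of that organism. Homomeric transfers (A = B) are produced but flagged as
#' self-loops so downstream analysis can drop them.
#'
#' @param ortholog_map An ortholog map from [best_hit_per_organism()].
#' @param reference_ppis A data frame of reference interactions with columns
#'   `protein_a`, `protein_b`, `organism`.
#' @return A canonical edge tibble with evidence tag `"interolog"` and the
#'   supporting organism(s) in `sources`.
#' @export
transfer_interactions <- function(ortholog_map, reference_ppis) {
  ref <- as_tibble(reference_ppis)
  if (!all(c("protein_a", "protein_b", "organism") %in% names(ref))) {
    abort("reference_ppis needs columns protein_a, protein_b, organism")
  }
  map <- as_tibble(ortholog_map)
  ## reverse map: (organism, subject) -> target queries
  rev_a <- dplyr::select(map, organism = "subject_organism",
                         protein_a = "subject_id", target_a = "query_id")
  rev_b <- dplyr::select(map, organism = "subject_organism",
                         protein_b = "subject_id", target_b = "query_id")
  hits <- ref |>
    dplyr::inner_join(rev_a, by = c("organism", "protein_a"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(rev_b, by = c("organism", "protein_b"),
                      relationship = "many-to-many")
  if (!nrow(hits)) {
    return(ppi_network()$edges)
  }
  canonical_edges(tibble(
    protein_a = hits$target_a,
    protein_b = hits$target_b,
    evidence = "interolog",
    sources = hits$organism
  ))
}

#' Predict interactions by the interolog method
#'
#' Convenience wrapper chaining [filter_homology_hits()],
#' [best_hit_per_organism()] and [transfer_interactions()].
#'
#' @inheritParams filter_homology_hits
#' @inheritParams transfer_interactions
#' @return A canonical edge tibble of interolog predictions.
#' @export
predict_interolog <- function(hits, reference_ppis, max_evalue = 1e-5,
                              min_identity = 30, min_coverage = 60,
                              coverage_mode = c("both", "query")) {
  hits |>
    filter_homology_hits(max_evalue, min_identity, min_coverage,
                         coverage_mode) |>
    best_hit_per_organism() |>
    transfer_interactions(reference_ppis)
}
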