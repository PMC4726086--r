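## Domain-domain interaction (DDI) channel: predict protein interactions
## from experimentally determined interacting domain pairs.

#' Assign Pfam domains to proteins from filtered domain hits
#'
#' Keeps domain hits with full-sequence E-value at most `max_evalue` and
#' bias at most `max_bias`, then collapses them to one domain set per
#' protein (multiple hits of one domain on one protein count once).
#'
#' @param hits A domain hit tibble from [read_domain_table()].
#' @param max_evalue Maximum E-value (default `1e-5`).
#' @param max_bias Maximum bias (default `1`).
#' @return A tibble `protein_id`, `domain`, one row per assigned
#'   protein-domain pair.
#' @export
assign_domains <- function(hits, max_evalue = 1e-5, max_bias = 1) {
  as_tibble(hits) |>
    dplyr::filter(.data$evalue <= max_evalue, .data$bias <= max_bias) |>
    dplyr::distinct(.data$protein_id, domain = .data$domain_accession) |>
    dplyr::arrange(.data$protein_id, .data$domain)
}

#' Canonicalize a DDI table
#'
#' @param ddis A data frame with two columns of domain accessions (named
#'   `domain_a`, `domain_b`, or the first two columns are used).
#' @return A tibble of canonical unordered domain pairs (`domain_a` <=
#'   `domain_b`), deduplicated; self-pairs are allowed.
#' @export
canonical_ddis <- function(ddis) {
  ddis <- as_tibble(ddis)
  if (!all(c("domain_a", "domain_b") %in% names(ddis))) {
    names(ddis)[1:2] <- c("domain_a", "domain_b")
  }
  a <- strip_accession_version(as.character(ddis$domain_a))
  b <- strip_accession_version(as.character(ddis$domain_b))
  tibble(domain_a = pmin(a, b), domain_b = pmax(a, b)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$domain_a, .data$domain_b)
}

#' Predict interactions from domain-domain interactions
#'
#' Emits the canonical edge (X, Y) whenever some domain m of X and some
#' domain n of Y form an experimentally determined interacting domain pair.
#' A single supporting DDI suffices; all supporting domain pairs are
#' recorded in `sources` as evidence weight. When the two interacting domain
#' instances sit on one protein (including a self-DDI d-d), the homomeric
#' edge (X, X) is emitted and flagged as a self-loop.
#'
#' @param assignment A protein-domain tibble from [assign_domains()].
#' @param ddis A DDI table, canonicalized via [canonical_ddis()].
#' @return A canonical edge tibble with evidence tag `"ddi"` and supporting
#'   domain pairs (`"PF00001-PF00002"`) in `sources`.
#' @export
predict_from_ddi <- function(assignment, ddis) {
  assignment <- as_tibble(assignment)
  ddis <- canonical_ddis(ddis)
  if (!nrow(assignment) || !nrow(ddis)) return(ppi_network()$edges)
  carriers <- function(col) {
    dplyr::inner_join(ddis, assignment,
                      by = setNames("domain", col),
                      relationship = "many-to-many")
  }
  ## proteins carrying the first / second domain of each DDI
  left <- carriers("domain_a") |> dplyr::rename(p_a = "protein_id")
  both <- dplyr::inner_join(
    left, assignment,
    by = c(domain_b = "domain"), relationship = "many-to-many"
  ) |>
    dplyr::rename(p_b = "protein_id")
  if (!nrow(both)) return(ppi_network()$edges)
  canonical_edges(tibble(
    protein_a = both$p_a,
    protein_b = both$p_b,
    evidence = "ddi",
    sources = paste0(both$domain_a, "-", both$domain_b)
  ))
}

#' Predict interactions by the DDI method
#'
#' Convenience wrapper chaining [assign_domains()] and [predict_from_ddi()].
#'
#' @inheritParams assign_domains
#' @inheritParams predict_from_ddi
#' @return A canonical edge tibble of DDI predictions.
#' @export
predict_ddi <- function(hits, ddis, max_evalue = 1e-5, max_bias = 1) {
  hits |>
    assign_domains(max_evalue, max_bias) |>
    predict_from_ddi(ddis)
}
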