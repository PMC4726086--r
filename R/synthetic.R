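## Seeded synthetic worlds with planted ground truth: a target proteome,
## reference organisms with curated interactomes and a planted ortholog
## map, homology and domain hit tables (decoys fail exactly one filter
## each), interacting-domain pairs, COG and GO annotations on a generated
## DAG, and 3-time-point RPKM profiles with correlated interacting pairs.
## The planted truth network is re-derived by brute force and asserted to
## equal the prediction pipeline's output at generation time.

#' Configuration of a synthetic world
#'
#' Desk-scale defaults: 300 target proteins, 2 reference organisms with
#' roughly 800 curated reference interactions, ~150 Pfam-style domains and
#' 200 interacting domain pairs, 4 planted dense complexes, and RPKM
#' profiles over 3 time points with pair-correlation noise sigma 0.2 —
#' sized so the full pipeline (including the exact MDS) runs in well under
#' two minutes.
#'
#' @param n_proteins Target proteome size.
#' @param n_ref_organisms Number of reference organisms.
#' @param ortholog_rate Per-organism probability that a target protein has
#'   a planted ortholog (recycled across organisms).
#' @param n_background_pairs Planted interolog-transferable target pairs
#'   outside the complexes.
#' @param n_reference_noise Reference interactions among unmapped reference
#'   proteins (never transferable).
#' @param n_decoy_hits Homology decoys, each failing exactly one of the
#'   E-value / identity / coverage filters.
#' @param n_secondary_hits Passing homology hits to alternative subjects
#'   with lower bit scores (exercise the best-hit rule).
#' @param n_domains Size of the domain pool.
#' @param n_ddis Interacting domain pairs.
#' @param n_domain_decoys Domain hits failing the E-value or bias filter.
#' @param n_complexes,complex_size_range,complex_intra_density Planted
#'   dense function-coherent modules.
#' @param cog_rate Fraction of proteins with COG annotation.
#' @param go_terms_per_namespace Approximate DAG size per namespace.
#' @param go_annotation_rate Fraction of proteins with GO terms.
#' @param go_signal Plant functional coherence on interacting pairs.
#' @param expression_signal Plant expression correlation on interacting
#'   pairs.
#' @param pair_sigma Pair-noise standard deviation (log scale) around the
#'   shared latent profile of interacting modules.
#' @param inactive_rate Probability that a non-complex gene falls below
#'   RPKM 1 at a given time point.
#' @param time_labels Ordered time point labels.
#' @return A `world_config` list.
#' @export
world_config <- function(n_proteins = 300,
                         n_ref_organisms = 2,
                         ortholog_rate = c(0.7, 0.5),
                         n_background_pairs = 150,
                         n_reference_noise = 300,
                         n_decoy_hits = 120,
                         n_secondary_hits = 60,
                         n_domains = 150,
                         n_ddis = 200,
                         n_domain_decoys = 60,
                         n_complexes = 4,
                         complex_size_range = c(5, 10),
                         complex_intra_density = 0.9,
                         cog_rate = 0.85,
                         go_terms_per_namespace = 40,
                         go_annotation_rate = 0.85,
                         go_signal = TRUE,
                         expression_signal = TRUE,
                         pair_sigma = 0.2,
                         inactive_rate = 0.1,
                         time_labels = c("11h", "22h", "33h")) {
  cfg <- as.list(environment())
  if (cfg$n_complexes * max(cfg$complex_size_range) > cfg$n_proteins) {
    abort("config error: planted complexes larger than the proteome")
  }
  if (cfg$n_ref_organisms < 1 || cfg$n_ref_organisms > 26) {
    abort("config error: n_ref_organisms must be in 1..26")
  }
  structure(cfg, class = "world_config")
}

#' Generate a synthetic world
#'
#' Deterministic for a fixed `(seed, config)`. See [world_config()] for the
#' planted structure. The returned world's `truth_network` is derived by
#' brute force from the planted ortholog map, reference interactome, domain
#' assignments and DDI set, and is asserted at generation time to equal the
#' output of the prediction pipeline run on the world's own hit tables.
#'
#' @param seed Integer seed.
#' @param config A [world_config()].
#' @return A `synthetic_world` object (a list of tibbles plus the truth
#'   network and planted structures).
#' @export
generate_world <- function(seed, config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  world <- with_seed(seed, function() build_world(seed, config))
  assert_world_consistency(world)
  world
}

build_world <- function(seed, cfg) {
  proteins <- sprintf("BL%04d", seq_len(cfg$n_proteins))
  organisms <- paste0("org", LETTERS[seq_len(cfg$n_ref_organisms)])
  rate <- rep_len(cfg$ortholog_rate, cfg$n_ref_organisms)

  ## ---- planted ortholog map -------------------------------------------
  map <- purrr::map2_dfr(organisms, rate, function(org, r) {
    has <- stats::runif(length(proteins)) < r
    tibble(query_id = proteins[has], subject_organism = org,
           subject_id = paste0(org, "_", proteins[has]))
  })

  ## ---- planted complexes (forced into the first organism's map) ------
  sizes <- sample(seq(cfg$complex_size_range[1], cfg$complex_size_range[2]),
                  cfg$n_complexes, replace = TRUE)
  pool <- sample(proteins)
  complexes <- list()
  taken <- 0
  for (k in seq_len(cfg$n_complexes)) {
    complexes[[k]] <- sort(pool[(taken + 1):(taken + sizes[k])])
    taken <- taken + sizes[k]
  }
  org1 <- organisms[1]
  missing <- setdiff(unlist(complexes),
                     map$query_id[map$subject_organism == org1])
  if (length(missing)) {
    map <- dplyr::bind_rows(map, tibble(
      query_id = missing, subject_organism = org1,
      subject_id = paste0(org1, "_", missing)
    ))
  }
  map <- dplyr::arrange(map, .data$query_id, .data$subject_organism)

  ## ---- planted transferable target pairs ------------------------------
  intra <- purrr::map_dfr(complexes, function(members) {
    prs <- t(combn(members, 2))
    keep <- stats::runif(nrow(prs)) < cfg$complex_intra_density
    tibble(protein_a = prs[keep, 1], protein_b = prs[keep, 2],
           organism = org1)
  })
  background <- background_pairs(proteins, map, organisms,
                                 cfg$n_background_pairs)
  planted_pairs <- dplyr::distinct(
    dplyr::bind_rows(intra, background),
    pmin(.data$protein_a, .data$protein_b),
    pmax(.data$protein_a, .data$protein_b),
    .keep_all = TRUE
  )[, c("protein_a", "protein_b", "organism")]

  ## ---- reference interactome ------------------------------------------
  key <- function(q, org) paste(q, org)
  subj <- setNames(map$subject_id, key(map$query_id, map$subject_organism))
  reference_edges <- tibble(
    protein_a = unname(subj[key(planted_pairs$protein_a,
                                planted_pairs$organism)]),
    protein_b = unname(subj[key(planted_pairs$protein_b,
                                planted_pairs$organism)]),
    organism = planted_pairs$organism
  )
  ## noise interactions among unmapped reference proteins
  noise_subjects <- paste0(sample(organisms, cfg$n_reference_noise,
                                  replace = TRUE),
                           "_X", seq_len(cfg$n_reference_noise))
  noise_org <- sub("_.*$", "", noise_subjects)
  shuffled <- sample(noise_subjects)
  same_org <- noise_org == sub("_.*$", "", shuffled) &
    noise_subjects != shuffled
  reference_edges <- dplyr::bind_rows(reference_edges, tibble(
    protein_a = noise_subjects[same_org],
    protein_b = shuffled[same_org],
    organism = noise_org[same_org]
  ))

  ## ---- homology hit table ---------------------------------------------
  passing <- passing_hits(map)
  secondary <- secondary_hits(map, cfg$n_secondary_hits)
  decoys <- decoy_hits(proteins, organisms, cfg$n_decoy_hits)
  homology_hits <- dplyr::bind_rows(passing, secondary, decoys) |>
    dplyr::arrange(.data$query_id, .data$subject_id)

  ## ---- domains and DDIs -----------------------------------------------
  domain_pool <- sprintf("PF%05d", seq_len(cfg$n_domains))
  n_dom <- sample(0:3, length(proteins), replace = TRUE,
                  prob = c(0.2, 0.4, 0.3, 0.1))
  assignment <- purrr::map_dfr(seq_along(proteins), function(i) {
    if (n_dom[i] == 0) return(NULL)
    tibble(protein_id = proteins[i],
           domain = sample(domain_pool, n_dom[i]))
  })
  ddis <- canonical_ddis(tibble(
    domain_a = sample(domain_pool, cfg$n_ddis, replace = TRUE),
    domain_b = sample(domain_pool, cfg$n_ddis, replace = TRUE)
  ))
  domain_hits <- dplyr::bind_rows(
    tibble(
      protein_id = assignment$protein_id,
      domain_accession = assignment$domain,
      evalue = 10^-stats::runif(nrow(assignment), 6, 30),
      bias = stats::runif(nrow(assignment), 0, 0.9),
      score = stats::runif(nrow(assignment), 20, 200)
    ),
    domain_decoy_hits(proteins, domain_pool, cfg$n_domain_decoys)
  ) |>
    dplyr::arrange(.data$protein_id, .data$domain_accession)

  ## ---- brute-force truth ----------------------------------------------
  truth_interolog <- brute_force_interolog(map, reference_edges)
  truth_ddi <- brute_force_ddi(assignment, ddis)
  truth_network <- merge_networks(truth_interolog, truth_ddi)

  ## ---- COG annotations -------------------------------------------------
  cog <- cog_annotations(proteins, complexes, cfg)

  ## ---- functional/expression modules = truth-network communities -------
  ## Interacting proteins share function and transcription behaviour; the
  ## planted signal therefore follows the truth network's community
  ## structure, which degree-preserving rewiring destroys.
  modules <- truth_communities(truth_network, complexes)

  ## ---- GO DAG and annotations ------------------------------------------
  dag <- generate_go_dag(cfg$go_terms_per_namespace)
  go <- go_annotations(proteins, modules, dag, cfg)

  ## ---- expression -------------------------------------------------------
  expression <- expression_profiles(proteins, modules, complexes, cfg)

  structure(
    list(
      seed = seed, config = cfg,
      target_proteins = proteins,
      organisms = organisms,
      organism_map = setNames(organisms, paste0(organisms, "_")),
      planted_orthologs = map,
      planted_complexes = complexes,
      reference_edges = reference_edges,
      homology_hits = homology_hits,
      domain_assignment = assignment,
      domain_hits = domain_hits,
      ddis = ddis,
      cog = cog,
      go = go,
      go_dag = dag,
      expression = expression,
      truth_interolog = truth_interolog,
      truth_ddi = truth_ddi,
      truth_network = truth_network
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> seed %d: %d proteins, %d reference edges, truth network %d edges / %d nodes\n",
    x$seed, length(x$target_proteins), nrow(x$reference_edges),
    nrow(x$truth_network$edges), length(x$truth_network$nodes)
  ))
  invisible(x)
}

background_pairs <- function(proteins, map, organisms, n_pairs) {
  if (n_pairs == 0) {
    return(tibble(protein_a = character(), protein_b = character(),
                  organism = character()))
  }
  orgs_of <- split(map$subject_organism, map$query_id)
  mapped <- names(orgs_of)
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    pr <- sample(mapped, 2)
    shared <- intersect(orgs_of[[pr[1]]], orgs_of[[pr[2]]])
    if (!length(shared)) next
    out[[k]] <- tibble(protein_a = pr[1], protein_b = pr[2],
                       organism = shared[1])
  }
  dplyr::bind_rows(out)
}

## Hits for the planted ortholog map: all three filters pass, bit scores
## high enough to beat any secondary hit.
passing_hits <- function(map) {
  n <- nrow(map)
  qlen <- sample(150:800, n, replace = TRUE)
  alen <- pmax(1L, as.integer(round(qlen * stats::runif(n, 0.65, 0.98))))
  slen <- pmax(alen, as.integer(round(alen / stats::runif(n, 0.65, 0.98))))
  tibble(
    query_id = map$query_id,
    subject_id = map$subject_id,
    subject_organism = map$subject_organism,
    percent_identity = stats::runif(n, 35, 90),
    alignment_length = alen,
    evalue = 10^-stats::runif(n, 6, 40),
    bit_score = stats::runif(n, 300, 500),
    query_length = as.integer(qlen),
    subject_length = slen
  )
}

## Passing hits to alternative subjects with strictly lower bit scores.
secondary_hits <- function(map, n_secondary) {
  if (n_secondary == 0 || !nrow(map)) return(NULL)
  rows <- map[sample(nrow(map), min(n_secondary, nrow(map))), ]
  n <- nrow(rows)
  qlen <- sample(150:800, n, replace = TRUE)
  alen <- pmax(1L, as.integer(round(qlen * stats::runif(n, 0.65, 0.98))))
  tibble(
    query_id = rows$query_id,
    subject_id = paste0(rows$subject_organism, "_ALT", seq_len(n)),
    subject_organism = rows$subject_organism,
    percent_identity = stats::runif(n, 32, 80),
    alignment_length = alen,
    evalue = 10^-stats::runif(n, 6, 20),
    bit_score = stats::runif(n, 50, 250),
    query_length = as.integer(qlen),
    subject_length = pmax(alen, as.integer(round(
      alen / stats::runif(n, 0.65, 0.98)))),
  )
}

## Decoys fail exactly one of {identity, E-value, coverage}.
decoy_hits <- function(proteins, organisms, n_decoys) {
  if (n_decoys == 0) return(NULL)
  fail <- rep_len(c("identity", "evalue", "coverage"), n_decoys)
  qlen <- sample(150:800, n_decoys, replace = TRUE)
  good_alen <- pmax(1L, as.integer(round(qlen * stats::runif(n_decoys,
                                                             0.65, 0.98))))
  bad_alen <- pmax(1L, as.integer(round(qlen * stats::runif(n_decoys,
                                                            0.15, 0.55))))
  alen <- ifelse(fail == "coverage", bad_alen, good_alen)
  org <- sample(organisms, n_decoys, replace = TRUE)
  tibble(
    query_id = sample(proteins, n_decoys, replace = TRUE),
    subject_id = paste0(org, "_DEC", seq_len(n_decoys)),
    subject_organism = org,
    percent_identity = ifelse(fail == "identity",
                              stats::runif(n_decoys, 5, 25),
                              stats::runif(n_decoys, 35, 90)),
    alignment_length = alen,
    evalue = ifelse(fail == "evalue",
                    10^-stats::runif(n_decoys, 0, 4.5),
                    10^-stats::runif(n_decoys, 6, 40)),
    bit_score = stats::runif(n_decoys, 50, 400),
    query_length = as.integer(qlen),
    ## subject coverage kept high so only the query side fails
    subject_length = alen
  )
}

domain_decoy_hits <- function(proteins, domain_pool, n_decoys) {
  if (n_decoys == 0) return(NULL)
  fail_bias <- rep_len(c(TRUE, FALSE), n_decoys)
  tibble(
    protein_id = sample(proteins, n_decoys, replace = TRUE),
    domain_accession = sample(domain_pool, n_decoys, replace = TRUE),
    evalue = ifelse(fail_bias, 10^-stats::runif(n_decoys, 6, 30),
                    10^-stats::runif(n_decoys, 0, 4.5)),
    bias = ifelse(fail_bias, stats::runif(n_decoys, 1.1, 3),
                  stats::runif(n_decoys, 0, 0.9)),
    score = stats::runif(n_decoys, 5, 100)
  )
}

## Independent re-derivation of the interolog channel from the planted map.
brute_force_interolog <- function(map, reference_edges) {
  targets_of <- split(map$query_id,
                      paste(map$subject_organism, map$subject_id))
  out <- list()
  for (e in seq_len(nrow(reference_edges))) {
    ta <- targets_of[[paste(reference_edges$organism[e],
                            reference_edges$protein_a[e])]]
    tb <- targets_of[[paste(reference_edges$organism[e],
                            reference_edges$protein_b[e])]]
    if (is.null(ta) || is.null(tb)) next
    out[[length(out) + 1]] <- tibble(
      protein_a = rep(ta, each = length(tb)),
      protein_b = rep(tb, times = length(ta)),
      evidence = "interolog",
      sources = reference_edges$organism[e]
    )
  }
  if (!length(out)) return(ppi_network()$edges)
  canonical_edges(dplyr::bind_rows(out))
}

## Independent re-derivation of the DDI channel (loop over DDIs).
brute_force_ddi <- function(assignment, ddis) {
  out <- list()
  for (k in seq_len(nrow(ddis))) {
    pa <- assignment$protein_id[assignment$domain == ddis$domain_a[k]]
    pb <- assignment$protein_id[assignment$domain == ddis$domain_b[k]]
    if (!length(pa) || !length(pb)) next
    out[[length(out) + 1]] <- tibble(
      protein_a = rep(pa, each = length(pb)),
      protein_b = rep(pb, times = length(pa)),
      evidence = "ddi",
      sources = paste0(ddis$domain_a[k], "-", ddis$domain_b[k])
    )
  }
  if (!length(out)) return(ppi_network()$edges)
  canonical_edges(dplyr::bind_rows(out))
}

cog_annotations <- function(proteins, complexes, cfg) {
  ## realistic-ish skew: transcription-heavy, few W/Z/Y
  weights <- setNames(rep(1, length(.cog_letters)), .cog_letters)
  weights[c("K", "E", "G", "J", "P")] <- 3
  weights[c("W", "Z", "Y", "B", "A")] <- 0.2
  weights["S"] <- 1.5
  annotated <- proteins[stats::runif(length(proteins)) < cfg$cog_rate]
  primary <- sample(.cog_letters, length(annotated), replace = TRUE,
                    prob = weights)
  names(primary) <- annotated
  ## planted complexes are function-coherent: shared primary category
  informative <- setdiff(.cog_letters, c("S", "R"))
  for (members in complexes) {
    cat_k <- sample(informative, 1)
    primary[members] <- cat_k
  }
  annotated <- names(primary)
  secondary_on <- stats::runif(length(annotated)) < 0.3
  rows <- tibble(protein_id = annotated, category = unname(primary),
                 priority = 1L)
  if (any(secondary_on)) {
    sec <- vapply(primary[secondary_on], function(cc) {
      sample(setdiff(.cog_letters, cc), 1)
    }, character(1))
    rows <- dplyr::bind_rows(rows, tibble(
      protein_id = annotated[secondary_on], category = unname(sec),
      priority = 2L
    ))
  }
  dplyr::arrange(rows, .data$protein_id, .data$priority)
}

## Random rooted DAG per namespace (depth 4-5), is_a-dominated.
generate_go_dag <- function(n_per_namespace) {
  make_ns <- function(ns, offset) {
    widths <- pmax(1, round(n_per_namespace * c(0.025, 0.1, 0.25, 0.625)))
    ids <- sprintf("GO:%07d", offset + seq_len(sum(widths)))
    levels <- rep(seq_along(widths), widths)
    parents <- list()
    for (lv in 2:length(widths)) {
      children <- ids[levels == lv]
      prev <- ids[levels == lv - 1]
      for (ch in children) {
        n_par <- sample(1:2, 1, prob = c(0.8, 0.2))
        par <- sample(prev, min(n_par, length(prev)))
        rel <- sample(c("is_a", "part_of"), length(par), replace = TRUE,
                      prob = c(0.85, 0.15))
        parents[[length(parents) + 1]] <-
          tibble(term = ch, parent = par, relation = rel)
      }
    }
    list(ids = ids, parents = dplyr::bind_rows(parents),
         namespace = setNames(rep(ns, length(ids)), ids),
         leaves = ids[levels == length(widths)],
         mid = ids[levels == length(widths) - 1])
  }
  bp <- make_ns("BP", 1000000)
  mf <- make_ns("MF", 2000000)
  dag <- new_go_dag(
    c(bp$ids, mf$ids),
    dplyr::bind_rows(bp$parents, mf$parents),
    c(bp$namespace, mf$namespace)
  )
  assert_acyclic(dag)
  attr(dag, "bp_leaves") <- bp$leaves
  attr(dag, "bp_mid") <- bp$mid
  dag
}

## Functional modules of the truth network: fast-greedy communities
## (deterministic) on the homomer-free graph, with every planted complex
## kept intact as its own module and singletons dropped.
truth_communities <- function(truth_network, complexes) {
  clean <- dplyr::filter(truth_network$edges, !.data$self_loop)
  if (!nrow(clean)) return(complexes)
  g <- to_igraph(ppi_network(clean))
  comm <- igraph::cluster_fast_greedy(g)
  groups <- split(igraph::V(g)$name, igraph::membership(comm))
  groups <- groups[lengths(groups) >= 2]
  in_complex <- unlist(complexes)
  groups <- lapply(groups, function(m) setdiff(m, in_complex))
  c(complexes, groups[lengths(groups) >= 2])
}

## GO annotations; with signal, each module shares a mid-level term's
## children so edge similarities are high inside modules and low across.
go_annotations <- function(proteins, modules, dag, cfg) {
  leaves <- attr(dag, "bp_leaves")
  mid <- attr(dag, "bp_mid")
  children_of_mid <- split(dag$parents$term, dag$parents$parent)
  assigned <- new.env(parent = emptyenv())
  rows <- list()
  annotate <- function(p, terms) {
    if (!is.null(assigned[[p]])) return(invisible(NULL))
    assigned[[p]] <- TRUE
    rows[[length(rows) + 1]] <<- tibble(protein_id = p, term = unique(terms))
  }
  coherent_terms <- function() {
    m <- sample(mid, 1)
    kids <- children_of_mid[[m]]
    if (is.null(kids) || length(kids) < 2) c(m) else kids
  }
  if (cfg$go_signal) {
    for (members in modules) {
      terms <- coherent_terms()
      for (p in members) {
        if (stats::runif(1) < cfg$go_annotation_rate) {
          annotate(p, sample(terms, min(2, length(terms))))
        }
      }
    }
  }
  rest <- proteins[vapply(proteins,
                          function(p) is.null(assigned[[p]]), logical(1))]
  rest <- rest[stats::runif(length(rest)) < cfg$go_annotation_rate]
  for (p in rest) {
    annotate(p, sample(leaves, sample(1:3, 1)))
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || !nrow(out)) {
    return(tibble(protein_id = character(), term = character()))
  }
  dplyr::arrange(out, .data$protein_id, .data$term)
}

## RPKM profiles: each module shares a latent profile plus pair noise;
## non-module genes are independent. Background genes occasionally fall
## below the activity threshold; planted-complex members stay active so
## the complexes persist across time points.
expression_profiles <- function(proteins, modules, complexes, cfg) {
  t_n <- length(cfg$time_labels)
  rpkm <- matrix(NA_real_, nrow = length(proteins), ncol = t_n,
                 dimnames = list(proteins, cfg$time_labels))
  latent <- function() exp(stats::rnorm(1, log(25), 0.8) +
                             stats::rnorm(t_n, 0, 0.7))
  member_noise <- function(base) {
    pmax(base * exp(stats::rnorm(t_n, 0, cfg$pair_sigma)), 1.01)
  }
  if (cfg$expression_signal) {
    for (members in modules) {
      base <- latent()
      for (p in members) {
        if (anyNA(rpkm[p, ])) rpkm[p, ] <- member_noise(base)
      }
    }
  }
  rest <- proteins[apply(rpkm, 1, anyNA)]
  for (p in rest) {
    rpkm[p, ] <- exp(stats::rnorm(1, log(15), 1) +
                       stats::rnorm(t_n, 0, 0.8))
  }
  ## sub-threshold activity outside the planted complexes
  protected <- unlist(complexes)
  for (p in setdiff(proteins, protected)) {
    off <- stats::runif(t_n) < cfg$inactive_rate
    if (any(off)) rpkm[p, off] <- stats::runif(sum(off), 0, 0.9)
  }
  out <- tibble(protein_id = proteins)
  for (j in seq_len(t_n)) out[[cfg$time_labels[j]]] <- unname(rpkm[, j])
  out
}

## Self-consistency: the prediction pipeline on the world's own tables must
## reproduce the brute-force truth network exactly.
assert_world_consistency <- function(world) {
  pred_i <- predict_interolog(world$homology_hits, world$reference_edges)
  pred_d <- predict_ddi(world$domain_hits, world$ddis)
  pred <- merge_networks(pred_i, pred_d)
  same_edges <- identical(
    pred$edges[, c("protein_a", "protein_b")],
    world$truth_network$edges[, c("protein_a", "protein_b")]
  )
  if (!same_edges) {
    abort("synthetic world failed self-consistency: pipeline output differs from planted truth")   # nocov
  }
  invisible(world)
}

#' Write a synthetic world's fixture files
#'
#' Emits every pipeline input format — homology and domain hit tables,
#' reference interactions, DDI pairs, COG and GO annotation tables, the GO
#' DAG as OBO, the RPKM matrix — plus the truth network edge list and a
#' JSON manifest of ground-truth counts. Re-reading the files with the
#' package readers reproduces the world's in-memory tables exactly.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly (tibble `file`, `n_rows`).
#' @export
write_fixtures <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(name) file.path(dir, name)
  num <- function(x) formatC(x, digits = 17, format = "g")

  h <- world$homology_hits
  writeLines(sprintf(
    "%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%d\t%d",
    h$query_id, h$subject_id, num(h$percent_identity), h$alignment_length,
    as.integer(round(h$alignment_length * (1 - h$percent_identity / 100))),
    0L, 1L, h$alignment_length, 1L, h$alignment_length,
    num(h$evalue), num(h$bit_score), h$query_length, h$subject_length
  ), fp("homology_hits.tsv"))

  d <- world$domain_hits
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s",
                     d$protein_id, d$domain_accession, num(d$evalue),
                     num(d$bias), num(d$score)),
             fp("domain_hits.tsv"))

  r <- world$reference_edges
  writeLines(c("protein_a\tprotein_b\torganism",
               sprintf("%s\t%s\t%s", r$protein_a, r$protein_b, r$organism)),
             fp("reference_edges.tsv"))

  writeLines(c("domain_a\tdomain_b",
               sprintf("%s\t%s", world$ddis$domain_a, world$ddis$domain_b)),
             fp("ddi_pairs.tsv"))

  cog_wide <- world$cog |>
    dplyr::arrange(.data$protein_id, .data$priority) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(categories = paste(.data$category, collapse = ","),
                     .groups = "drop")
  writeLines(c("protein_id\tcog",
               sprintf("%s\t%s", cog_wide$protein_id, cog_wide$categories)),
             fp("cog.tsv"))

  go_wide <- world$go |>
    dplyr::arrange(.data$protein_id, .data$term) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(terms = paste(.data$term, collapse = ";"),
                     .groups = "drop")
  writeLines(c("protein_id\tgo",
               sprintf("%s\t%s", go_wide$protein_id, go_wide$terms)),
             fp("go.tsv"))

  write_obo(world$go_dag, fp("go.obo"))

  e <- world$expression
  labels <- expression_labels(e)
  body <- do.call(paste, c(list(e$protein_id),
                           lapply(labels, function(lb) num(e[[lb]])),
                           sep = "\t"))
  writeLines(c(paste(c("protein_id", labels), collapse = "\t"), body),
             fp("expression.tsv"))

  write_edge_list(world$truth_network$edges, fp("truth_network.tsv"))

  files <- c("homology_hits.tsv", "domain_hits.tsv", "reference_edges.tsv",
             "ddi_pairs.tsv", "cog.tsv", "go.tsv", "go.obo",
             "expression.tsv", "truth_network.tsv")
  manifest <- tibble(
    file = files,
    n_rows = vapply(files, function(f) length(readLines(fp(f))),
                    integer(1))
  )
  jsonlite::write_json(
    list(
      seed = world$seed,
      organism_map = as.list(world$organism_map),
      time_labels = world$config$time_labels,
      n_truth_edges = nrow(world$truth_network$edges),
      n_truth_nodes = length(world$truth_network$nodes),
      files = manifest
    ),
    fp("manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

## Subset OBO writer for generated DAGs.
write_obo <- function(dag, path) {
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  parents_of <- split(dag$parents, dag$parents$term)
  stanzas <- vapply(dag$terms, function(t) {
    up <- parents_of[[t]]
    lines <- c("[Term]",
               paste0("id: ", t),
               paste0("namespace: ", ns_long[[dag$namespace[[t]]]]))
    if (!is.null(up)) {
      is_a <- up[up$relation == "is_a", ]
      po <- up[up$relation == "part_of", ]
      if (nrow(is_a)) lines <- c(lines, paste0("is_a: ", is_a$parent))
      if (nrow(po)) {
        lines <- c(lines, paste0("relationship: part_of ", po$parent))
      }
    }
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", paste(stanzas, collapse = "\n\n")),
             path)
  invisible(path)
}

#' Read a reference interaction table
#'
#' TSV with columns `protein_a`, `protein_b`, `organism` (header required),
#' as written by [write_fixtures()]: the experimentally determined
#' interactome of each reference organism.
#'
#' @param path Path of the TSV file.
#' @return A tibble `protein_a`, `protein_b`, `organism`.
#' @export
read_reference_edges <- function(path) {
  tab <- scan_table(path)
  if (!length(tab$fields) ||
      !identical(tab$fields[[1]], c("protein_a", "protein_b", "organism"))) {
    abort(sprintf("%s: expected header 'protein_a\tprotein_b\torganism'",
                  basename(path)))
  }
  body <- tab$fields[-1]
  ln <- tab$lineno[-1]
  row_check(lengths(body) == 3L, "expected 3 tab-separated columns", ln,
            path)
  tibble(
    protein_a = vapply(body, `[[`, character(1), 1),
    protein_b = vapply(body, `[[`, character(1), 2),
    organism = vapply(body, `[[`, character(1), 3)
  )
}

#' Read a DDI pair table
#'
#' TSV of two domain accessions per row (header `domain_a`/`domain_b`
#' recognized); pairs are canonicalized via [canonical_ddis()].
#'
#' @param path Path of the TSV file.
#' @return A canonical DDI tibble.
#' @export
read_ddi_table <- function(path) {
  tab <- scan_table(path)
  if (length(tab$fields) &&
      identical(tab$fields[[1]][1:2], c("domain_a", "domain_b"))) {
    tab$fields <- tab$fields[-1]
    tab$lineno <- tab$lineno[-1]
  }
  if (!length(tab$fields)) {
    return(canonical_ddis(tibble(domain_a = character(),
                                 domain_b = character())))
  }
  row_check(lengths(tab$fields) >= 2L, "expected 2 tab-separated columns",
            tab$lineno, path)
  canonical_ddis(tibble(
    domain_a = vapply(tab$fields, `[[`, character(1), 1),
    domain_b = vapply(tab$fields, `[[`, character(1), 2)
  ))
}
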