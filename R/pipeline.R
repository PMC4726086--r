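## End-to-end orchestration: predict -> merge -> characterize -> validate ->
## dynamics -> complexes -> annotate, with a machine-readable run report.

#' Pipeline configuration
#'
#' Collects the input paths, thresholds and seeds of a full pipeline run.
#' All referenced files must exist at validation time. The defaults mirror
#' the fixture layout written by [write_fixtures()], so
#' `pipeline_config(input_dir = dir)` is enough for a synthetic world.
#'
#' @param input_dir Directory holding the input files (used to resolve any
#'   path argument left `NULL`).
#' @param homology_hits,domain_hits,reference_edges,ddi_pairs,cog,go,obo,expression
#'   Individual file paths (override the `input_dir` defaults).
#' @param organism_map Named character vector mapping subject-id prefixes to
#'   organism names; when `NULL` and a `manifest.json` exists in
#'   `input_dir`, it is taken from there.
#' @param max_evalue,min_identity,min_coverage Interolog filters.
#' @param domain_max_evalue,domain_max_bias Domain-assignment filters.
#' @param rpkm_threshold Activity threshold for condition networks.
#' @param lambda,min_size Complex-detection parameters.
#' @param n_random Random networks per validation comparison.
#' @param alpha Enrichment significance level.
#' @param mds_time_limit Seconds allowed for the exact MDS proof.
#' @param seed Seed for every stochastic stage (validation rewirings).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            homology_hits = NULL, domain_hits = NULL,
                            reference_edges = NULL, ddi_pairs = NULL,
                            cog = NULL, go = NULL, obo = NULL,
                            expression = NULL, organism_map = NULL,
                            max_evalue = 1e-5, min_identity = 30,
                            min_coverage = 60,
                            domain_max_evalue = 1e-5, domain_max_bias = 1,
                            rpkm_threshold = 1, lambda = 1, min_size = 3,
                            n_random = 100, alpha = 0.05,
                            mds_time_limit = 60, seed = 1) {
  resolve <- function(value, default) {
    value %||% if (!is.null(input_dir)) file.path(input_dir, default)
               else NULL
  }
  cfg <- list(
    homology_hits = resolve(homology_hits, "homology_hits.tsv"),
    domain_hits = resolve(domain_hits, "domain_hits.tsv"),
    reference_edges = resolve(reference_edges, "reference_edges.tsv"),
    ddi_pairs = resolve(ddi_pairs, "ddi_pairs.tsv"),
    cog = resolve(cog, "cog.tsv"),
    go = resolve(go, "go.tsv"),
    obo = resolve(obo, "go.obo"),
    expression = resolve(expression, "expression.tsv"),
    organism_map = organism_map,
    max_evalue = max_evalue, min_identity = min_identity,
    min_coverage = min_coverage,
    domain_max_evalue = domain_max_evalue,
    domain_max_bias = domain_max_bias,
    rpkm_threshold = rpkm_threshold, lambda = lambda, min_size = min_size,
    n_random = n_random, alpha = alpha,
    mds_time_limit = mds_time_limit, seed = as.integer(seed)
  )
  required <- c("homology_hits", "domain_hits", "reference_edges",
                "ddi_pairs", "cog", "go", "obo", "expression")
  for (f in required) {
    if (is.null(cfg[[f]])) {
      abort(sprintf("config error: no path for input '%s'", f))
    }
    if (!file.exists(cfg[[f]])) {
      abort(sprintf("config error: input '%s' not found at %s", f,
                    cfg[[f]]))
    }
  }
  if (is.null(cfg$organism_map) && !is.null(input_dir)) {
    mf <- file.path(input_dir, "manifest.json")
    if (file.exists(mf)) {
      om <- jsonlite::read_json(mf)$organism_map
      cfg$organism_map <- unlist(om)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order — interolog and DDI prediction, channel
#' merging, self-loop removal, topology and power-law characterization,
#' minimum dominating set, COG heat map and MDS enrichment, GO-similarity
#' and transcription-correlation validation, condition-specific dynamics,
#' complex detection, entropy scoring and annotation of uncharacterized
#' proteins — and logs each stage's key counts into a nested run report.
#' Any stage failure aborts with the stage name; runs are deterministic for
#' a fixed config (the config seed drives every stochastic step).
#'
#' @param config A `pipeline_config` (or a path to a YAML file of
#'   `pipeline_config()` arguments).
#' @param stages `"all"` or `"predict"` (stop after channel merging — used
#'   for fast truth-network comparisons).
#' @param report_path Optional path; when given, the report is written there
#'   as JSON.
#' @return A `pipeline_result`: list with `report` (nested list of counts
#'   and statistics) and the main computed objects (`network`,
#'   `network_noself`, `topology`, `powerlaw`, `mds`, `heatmap`,
#'   `validation`, `dynamics`, `complexes`, `annotations`).
#' @export
run_pipeline <- function(config, stages = c("all", "predict"),
                         report_path = NULL) {
  stages <- match.arg(stages)
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    args <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, args)
  }
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  report <- list(seed = config$seed)
  res <- list()

  inputs <- stage("read_inputs", {
    list(
      hits = read_homology_table(config$homology_hits, config$organism_map),
      domains = read_domain_table(config$domain_hits),
      reference = read_reference_edges(config$reference_edges),
      ddis = read_ddi_table(config$ddi_pairs),
      cog = read_cog_annotations(config$cog),
      dag = read_obo_subset(config$obo),
      expression = read_expression_matrix(config$expression)
    )
  })
  inputs$go <- stage("read_inputs", {
    read_go_annotations(config$go, dag = inputs$dag)
  })

  interolog <- stage("interolog", {
    predict_interolog(inputs$hits, inputs$reference,
                      max_evalue = config$max_evalue,
                      min_identity = config$min_identity,
                      min_coverage = config$min_coverage)
  })
  ddi <- stage("ddi", {
    predict_ddi(inputs$domains, inputs$ddis,
                max_evalue = config$domain_max_evalue,
                max_bias = config$domain_max_bias)
  })
  net <- stage("merge", merge_networks(interolog, ddi))
  ms <- attr(net, "merge_stats")
  report$channels <- list(
    n_interolog = ms$n_a, n_ddi = ms$n_b, n_shared = ms$n_shared,
    n_merged_edges = ms$n_union, n_merged_nodes = length(net$nodes)
  )
  res$network <- net
  if (stages == "predict") {
    res$report <- report
    return(finish_pipeline(res, report_path))
  }

  noself <- stage("remove_self_loops", remove_self_loops(net))
  rs <- attr(noself, "removal_stats")
  report$self_loops <- list(
    n_removed = rs$n_self_loops_removed,
    n_nodes_dropped = rs$n_nodes_dropped,
    n_edges = nrow(noself$edges), n_nodes = length(noself$nodes)
  )
  res$network_noself <- noself

  topo <- stage("topology", topology_summary(noself))
  report$topology <- as.list(topo$summary)
  res$topology <- topo

  pl <- stage("powerlaw", fit_powerlaw(topo$nodes$degree, k_min = 1))
  report$powerlaw <- list(gamma = pl$gamma,
                          gamma_discrete = pl$gamma_discrete,
                          n_tail = pl$n_tail)
  res$powerlaw <- pl

  mds <- stage("mds", solve_mds_ilp(noself,
                                    time_limit = config$mds_time_limit))
  report$mds <- list(size = mds$size, optimal = mds$optimal,
                     fraction_of_nodes = mds$size / length(noself$nodes))
  res$mds <- mds

  heatmap <- stage("cog_heatmap", cog_heatmap(noself, inputs$cog))
  report$cog_heatmap <- list(
    n_annotated = heatmap$n, n_interactions = heatmap$n_interactions,
    n_categories = length(heatmap$categories),
    max_z = max(heatmap$z, na.rm = TRUE)
  )
  res$heatmap <- heatmap

  mds_enrichment <- stage("mds_enrichment", {
    fisher_enrichment(mds$members, noself$nodes, inputs$cog,
                      alpha = config$alpha)
  })
  report$mds_enrichment <- list(
    enriched_categories = mds_enrichment$category[mds_enrichment$enriched]
  )
  res$mds_enrichment <- mds_enrichment

  go_val <- stage("go_validation", {
    compare_with_random(noself, inputs$go, inputs$dag,
                        n_random = config$n_random, seed = config$seed)
  })
  pcc_val <- stage("pcc_validation", {
    transcription_pcc_validation(noself, inputs$expression,
                                 n_random = config$n_random,
                                 seed = config$seed + 1L)
  })
  report$validation <- list(
    go_similarity_p = go_val$p_value, pcc_p = pcc_val$p_value,
    n_random = config$n_random
  )
  res$validation <- list(go = go_val, pcc = pcc_val)

  labels <- expression_labels(inputs$expression)
  conditions <- stage("dynamics", {
    build_time_series_networks(noself, inputs$expression,
                               threshold = config$rpkm_threshold)
  })
  topo_cmp <- stage("dynamics", compare_local_topology(conditions))
  diffs <- stage("dynamics", {
    purrr::map_dfr(conditions, function(cn) {
      difference_distributions(cn, inputs$expression, inputs$cog,
                               groups = c("control", "all_ppi"))
    })
  })
  med <- diffs |>
    dplyr::group_by(.data$time_label, .data$group) |>
    dplyr::summarise(median = median(.data$value), .groups = "drop")
  report$dynamics <- list(
    active_nodes = setNames(
      lapply(conditions, function(cn) length(cn$nodes)), labels),
    min_topology_p = min(topo_cmp$p_value),
    median_d = med
  )
  res$dynamics <- list(conditions = conditions, topology = topo_cmp,
                       differences = diffs)

  cx <- stage("complexes", {
    detect_complexes(conditions, lambda = config$lambda,
                     min_size = config$min_size)
  })
  scores <- stage("complexes", score_complexes(cx, inputs$cog))
  report$complexes <- list(
    n_complexes = nrow(cx$complexes),
    median_entropy = if (nrow(scores)) median(scores$entropy) else NA_real_,
    low_entropy_fraction = attr(scores, "low_entropy_fraction")
  )
  res$complexes <- list(set = cx, scores = scores)

  annotations <- stage("annotate", {
    annotate_uncharacterized(cx, inputs$cog, noself$nodes,
                             alpha = config$alpha)
  })
  report$annotation <- list(n_annotated = nrow(annotations))
  res$annotations <- annotations

  res$report <- report
  finish_pipeline(res, report_path)
}

finish_pipeline <- function(res, report_path) {
  class(res) <- "pipeline_result"
  if (!is.null(report_path)) {
    jsonlite::write_json(res$report, report_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat(sprintf("  channels: interolog %d, ddi %d, shared %d -> merged %d edges / %d nodes\n",
              r$channels$n_interolog, r$channels$n_ddi, r$channels$n_shared,
              r$channels$n_merged_edges, r$channels$n_merged_nodes))
  if (!is.null(r$topology)) {
    cat(sprintf("  topology: <k> = %.2f, L = %.2f, C = %.2f, %d components\n",
                r$topology$average_degree, r$topology$average_path_length,
                r$topology$clustering_coefficient, r$topology$n_components))
    cat(sprintf("  gamma = %.2f; MDS size %d; complexes %d; annotated %d\n",
                r$powerlaw$gamma, r$mds$size, r$complexes$n_complexes,
                r$annotation$n_annotated))
  }
  invisible(x)
}
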