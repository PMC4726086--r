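## Readers and writers for the external formats the pipeline touches.
## All parsers are strict: malformed rows raise errors naming the offending
## line rather than being silently coerced.

## Returns list(fields = list of character vectors, lineno = integer vector)
## with '#' comments and blank lines dropped. split = regex for field split.
scan_table <- function(path, split = "\t") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  list(
    fields = strsplit(trimws(lines[keep], which = "right"), split),
    lineno = keep
  )
}

## Strict numeric conversion for one parsed field.
num_field <- function(x, name, lineno, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    abort(sprintf(
      "%s: line %d: field '%s' is not numeric (got '%s')",
      basename(path), lineno[bad[1]], name, x[bad[1]]
    ))
  }
  v
}

row_check <- function(ok, msg, lineno, path) {
  bad <- which(!ok)
  if (length(bad)) {
    abort(sprintf("%s: line %d: %s", basename(path), lineno[bad[1]], msg))
  }
  invisible(TRUE)
}

#' Read a homology hit table (tabular BLAST dialect)
#'
#' Parses a tab-separated homology search table in the standard 12-column
#' tabular layout (`qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`) with two appended columns `qlen` and `slen`.
#' The appended lengths are required because alignment coverage — a filter of
#' the interolog method — cannot be computed from the 12-column core.
#'
#' @param path Path to the hit table. Lines starting with `#` and blank lines
#'   are ignored.
#' @param organism_map Optional named character vector mapping subject-id
#'   prefixes to reference organism names (longest matching prefix wins).
#'   Subjects with no matching prefix are assigned organism `"unknown"`.
#' @return A tibble with one row per hit: `query_id`, `subject_id`,
#'   `subject_organism`, `percent_identity`, `alignment_length`, `evalue`,
#'   `bit_score`, `query_length`, `subject_length`.
#' @export
read_homology_table <- function(path, organism_map = NULL) {
  tab <- scan_table(path)
  if (length(tab$fields) == 0L) {
    return(tibble(
      query_id = character(), subject_id = character(),
      subject_organism = character(), percent_identity = numeric(),
      alignment_length = integer(), evalue = numeric(), bit_score = numeric(),
      query_length = integer(), subject_length = integer()
    ))
  }
  nf <- lengths(tab$fields)
  row_check(nf == 14L, sprintf("expected 14 tab-separated columns, got %d",
                               nf[which(nf != 14L)[1]]),
            tab$lineno, path)
  m <- do.call(rbind, tab$fields)
  ln <- tab$lineno
  pident <- num_field(m[, 3], "pident", ln, path)
  alen <- num_field(m[, 4], "length", ln, path)
  evalue <- num_field(m[, 11], "evalue", ln, path)
  bits <- num_field(m[, 12], "bitscore", ln, path)
  qlen <- num_field(m[, 13], "qlen", ln, path)
  slen <- num_field(m[, 14], "slen", ln, path)
  row_check(pident >= 0 & pident <= 100, "pident outside [0, 100]", ln, path)
  row_check(alen > 0, "alignment length must be positive", ln, path)
  row_check(evalue >= 0, "negative E-value", ln, path)
  row_check(bits > 0, "bit score must be positive", ln, path)
  row_check(qlen > 0 & slen > 0, "sequence lengths must be positive", ln, path)
  tibble(
    query_id = m[, 1],
    subject_id = m[, 2],
    subject_organism = resolve_organism(m[, 2], organism_map),
    percent_identity = pident,
    alignment_length = as.integer(alen),
    evalue = evalue,
    bit_score = bits,
    query_length = as.integer(qlen),
    subject_length = as.integer(slen)
  )
}

## Longest-prefix organism resolution.
resolve_organism <- function(subject_id, organism_map) {
  if (is.null(organism_map) || !length(organism_map)) {
    return(rep("unknown", length(subject_id)))
  }
  prefixes <- names(organism_map)[order(nchar(names(organism_map)),
                                        decreasing = TRUE)]
  out <- rep("unknown", length(subject_id))
  for (p in prefixes) {
    hit <- out == "unknown" & startsWith(subject_id, p)
    out[hit] <- organism_map[[p]]
  }
  out
}

#' Read a domain hit table (HMMER-style)
#'
#' Accepts either the reduced 5-column layout `protein_id domain_accession
#' evalue bias score` (tab- or whitespace-separated) or the full-width
#' per-domain tabular layout written by `hmmscan --domtblout` (>= 22
#' whitespace-separated fields; the protein is the query, columns 4/2/7/8/9
#' carry protein, accession, full-sequence E-value, score and bias).
#' Domain accessions are normalized by stripping version suffixes
#' (`PF00001.21` becomes `PF00001`).
#'
#' @param path Path to the table; `#` comment lines are ignored.
#' @return A tibble with columns `protein_id`, `domain_accession`, `evalue`,
#'   `bias`, `score`.
#' @export
read_domain_table <- function(path) {
  tab <- scan_table(path, split = "[ \t]+")
  empty <- tibble(
    protein_id = character(), domain_accession = character(),
    evalue = numeric(), bias = numeric(), score = numeric()
  )
  if (length(tab$fields) == 0L) return(empty)
  nf <- lengths(tab$fields)
  ln <- tab$lineno
  if (all(nf == 5L)) {
    m <- do.call(rbind, tab$fields)
    out <- tibble(
      protein_id = m[, 1],
      domain_accession = m[, 2],
      evalue = num_field(m[, 3], "evalue", ln, path),
      bias = num_field(m[, 4], "bias", ln, path),
      score = num_field(m[, 5], "score", ln, path)
    )
  } else if (all(nf >= 22L)) {
    get <- function(i) vapply(tab$fields, `[[`, character(1), i)
    acc <- get(2)
    acc[acc == "-"] <- get(1)[acc == "-"]
    out <- tibble(
      protein_id = get(4),
      domain_accession = acc,
      evalue = num_field(get(7), "full-sequence evalue", ln, path),
      bias = num_field(get(9), "full-sequence bias", ln, path),
      score = num_field(get(8), "full-sequence score", ln, path)
    )
  } else {
    bad <- which(nf != 5L & nf < 22L)[1]
    abort(sprintf(
      "%s: line %d: expected 5 columns (reduced layout) or >= 22 (per-domain layout), got %d",
      basename(path), ln[bad], nf[bad]
    ))
  }
  row_check(nzchar(out$domain_accession), "empty domain accession", ln, path)
  row_check(out$evalue >= 0, "negative E-value", ln, path)
  row_check(out$bias >= 0, "negative bias", ln, path)
  out$domain_accession <- strip_accession_version(out$domain_accession)
  out
}

strip_accession_version <- function(x) sub("\\.\\d+$", "", x)

#' Read and write interaction edge lists
#'
#' Edge lists are TSV files with at least two columns (`protein_a`,
#' `protein_b`) and optional `evidence` and `sources` columns. On reading,
#' unordered duplicate pairs are merged with evidence union and every pair is
#' canonicalized ([canonical_edges()]); a header row matching the column
#' names is recognized and skipped. `write_edge_list()` always writes the
#' four-column headered form, so write-then-read is the identity on
#' canonical records.
#'
#' @param path Path of the TSV file.
#' @return `read_edge_list()` returns a canonical edge tibble.
#' @export
read_edge_list <- function(path) {
  tab <- scan_table(path)
  if (length(tab$fields) &&
      identical(tab$fields[[1]][1:2], c("protein_a", "protein_b"))) {
    tab$fields <- tab$fields[-1]
    tab$lineno <- tab$lineno[-1]
  }
  if (length(tab$fields) == 0L) {
    return(ppi_network()$edges)
  }
  nf <- lengths(tab$fields)
  row_check(nf >= 2L, "expected at least 2 tab-separated columns",
            tab$lineno, path)
  get <- function(i) {
    vapply(tab$fields, function(f) if (length(f) >= i) f[[i]] else "",
           character(1))
  }
  canonical_edges(tibble(
    protein_a = get(1), protein_b = get(2),
    evidence = get(3), sources = get(4)
  ))
}

#' @param edges An edge data frame (canonicalized before writing).
#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) {
  edges <- canonical_edges(edges)
  lines <- c(
    "protein_a\tprotein_b\tevidence\tsources",
    sprintf("%s\t%s\t%s\t%s",
            edges$protein_a, edges$protein_b, edges$evidence, edges$sources)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a GO DAG from a subset OBO file
#'
#' Parses `[Term]` stanzas (fields `id`, `namespace`, `is_a`,
#' `relationship: part_of`, `is_obsolete`) into a directed acyclic graph over
#' GO terms. Obsolete terms are skipped; a parent reference to an undefined
#' term, a parent in a different namespace, or a cycle is a format error.
#'
#' @param path Path to the OBO file.
#' @return A `go_dag` object: `terms` (character), `parents` (tibble with
#'   columns `term`, `parent`, `relation` where relation is `is_a` or
#'   `part_of`) and `namespace` (named character with values `"BP"`, `"MF"`,
#'   `"CC"`).
#' @export
read_obo_subset <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  ns_map <- c(
    biological_process = "BP",
    molecular_function = "MF",
    cellular_component = "CC"
  )
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) terms[[cur$id]] <- cur
    terms
  }
  for (line in lines) {
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NA_character_, namespace = NA_character_,
                  parents = character(), relations = character(),
                  obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", line)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(line)) {
      if (startsWith(line, "id:")) {
        cur$id <- trimws(sub("^id:", "", line))
      } else if (startsWith(line, "namespace:")) {
        ns <- trimws(sub("^namespace:", "", line))
        if (!ns %in% names(ns_map)) {
          abort(sprintf("unknown namespace '%s' for term %s", ns, cur$id))
        }
        cur$namespace <- ns_map[[ns]]
      } else if (startsWith(line, "is_a:")) {
        p <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
        cur$parents <- c(cur$parents, p)
        cur$relations <- c(cur$relations, "is_a")
      } else if (startsWith(line, "relationship:")) {
        rel <- strsplit(trimws(sub("!.*$", "", sub("^relationship:", "", line))),
                        "\\s+")[[1]]
        if (length(rel) >= 2 && rel[1] == "part_of") {
          cur$parents <- c(cur$parents, rel[2])
          cur$relations <- c(cur$relations, "part_of")
        }
      } else if (startsWith(line, "is_obsolete:")) {
        cur$obsolete <- grepl("true", line, fixed = TRUE)
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) {
    return(new_go_dag(character(),
                      tibble(term = character(), parent = character(),
                             relation = character()),
                      character()))
  }
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyNA(ids)) abort("OBO format error: [Term] stanza without an id")
  namespace <- vapply(terms, `[[`, character(1), "namespace")
  parents <- purrr::map_dfr(terms, function(t) {
    if (!length(t$parents)) return(NULL)
    tibble(term = t$id, parent = t$parents, relation = t$relations)
  })
  if (!nrow(parents)) {
    parents <- tibble(term = character(), parent = character(),
                      relation = character())
  }
  if (nrow(parents)) {
    dangling <- setdiff(parents$parent, ids)
    if (length(dangling)) {
      abort(sprintf(
        "OBO format error: undefined parent term(s): %s (referenced by %s)",
        paste(dangling, collapse = ", "),
        paste(unique(parents$term[parents$parent %in% dangling]),
              collapse = ", ")
      ))
    }
    cross <- namespace[parents$term] != namespace[parents$parent]
    if (any(cross)) {
      abort(sprintf(
        "OBO format error: term %s has a parent in a different namespace",
        parents$term[which(cross)[1]]
      ))
    }
  }
  dag <- new_go_dag(unname(ids), parents, setNames(unname(namespace), ids))
  assert_acyclic(dag)
  dag
}

new_go_dag <- function(terms, parents, namespace) {
  structure(list(terms = terms, parents = parents, namespace = namespace),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d parent links (%s)\n",
              length(x$terms), nrow(x$parents),
              paste(sprintf("%s: %d", names(table(x$namespace)),
                            table(x$namespace)), collapse = ", ")))
  invisible(x)
}

## Kahn topological sort; errors on cycles.
assert_acyclic <- function(dag) {
  if (!nrow(dag$parents)) return(invisible(TRUE))
  indeg <- setNames(integer(length(dag$terms)), dag$terms)
  tab <- table(dag$parents$term)
  indeg[names(tab)] <- as.integer(tab)
  children_of <- split(dag$parents$term, dag$parents$parent)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children_of[[v]] %||% character()) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(dag$terms)) {
    abort("OBO format error: cycle detected in the term graph")
  }
  invisible(TRUE)
}

#' Read annotation tables
#'
#' `read_cog_annotations()` parses a TSV of `protein_id` and a comma-joined
#' list of single-letter COG categories (the list order is meaningful: the
#' first letter is the protein's primary category). `read_go_annotations()`
#' parses a TSV of `protein_id` and a semicolon-joined list of GO term
#' identifiers, optionally validated against a loaded DAG.
#'
#' @param path Path of the TSV file (optional header rows `protein_id ...`
#'   are recognized; `#` comments ignored).
#' @param dag Optional `go_dag`; when supplied, unknown GO terms are a
#'   format error.
#' @return `read_cog_annotations()`: tibble `protein_id`, `category`,
#'   `priority` (1 = primary). `read_go_annotations()`: tibble `protein_id`,
#'   `term`.
#' @export
read_cog_annotations <- function(path) {
  tab <- scan_table(path)
  if (length(tab$fields) && tab$fields[[1]][1] == "protein_id") {
    tab$fields <- tab$fields[-1]
    tab$lineno <- tab$lineno[-1]
  }
  out <- tibble(protein_id = character(), category = character(),
                priority = integer())
  if (!length(tab$fields)) return(out)
  rows <- purrr::map2_dfr(tab$fields, tab$lineno, function(f, ln) {
    if (!length(f) || !nzchar(f[[1]])) {
      abort(sprintf("%s: line %d: missing protein_id", basename(path), ln))
    }
    cats <- if (length(f) >= 2 && nzchar(f[[2]])) {
      strsplit(f[[2]], ",", fixed = TRUE)[[1]]
    } else {
      character()
    }
    bad <- setdiff(cats, .cog_letters)
    if (length(bad)) {
      abort(sprintf("%s: line %d: unknown COG category '%s'",
                    basename(path), ln, bad[1]))
    }
    if (!length(cats)) return(NULL)
    tibble(protein_id = f[[1]], category = cats,
           priority = seq_along(cats))
  })
  if (!nrow(rows)) out else rows
}

#' @rdname read_cog_annotations
#' @export
read_go_annotations <- function(path, dag = NULL) {
  tab <- scan_table(path)
  if (length(tab$fields) && tab$fields[[1]][1] == "protein_id") {
    tab$fields <- tab$fields[-1]
    tab$lineno <- tab$lineno[-1]
  }
  out <- tibble(protein_id = character(), term = character())
  if (!length(tab$fields)) return(out)
  rows <- purrr::map2_dfr(tab$fields, tab$lineno, function(f, ln) {
    if (!length(f) || !nzchar(f[[1]])) {
      abort(sprintf("%s: line %d: missing protein_id", basename(path), ln))
    }
    terms <- if (length(f) >= 2 && nzchar(f[[2]])) {
      strsplit(f[[2]], ";", fixed = TRUE)[[1]]
    } else {
      character()
    }
    if (!is.null(dag)) {
      bad <- setdiff(terms, dag$terms)
      if (length(bad)) {
        abort(sprintf("%s: line %d: GO term %s not in the supplied DAG",
                      basename(path), ln, bad[1]))
      }
    }
    if (!length(terms)) return(NULL)
    tibble(protein_id = f[[1]], term = unique(terms))
  })
  if (!nrow(rows)) out else rows
}

#' Read an RPKM expression matrix
#'
#' Parses a TSV whose header is `protein_id` followed by the ordered time
#' labels (e.g. `11h 22h 33h`); each data row carries one protein's
#' non-negative RPKM value per time point.
#'
#' @param path Path of the TSV file.
#' @return A tibble with a `protein_id` column and one numeric column per
#'   time label.
#' @export
read_expression_matrix <- function(path) {
  tab <- scan_table(path)
  if (!length(tab$fields)) abort(sprintf("%s: empty expression matrix", path))
  header <- tab$fields[[1]]
  if (header[1] != "protein_id" || length(header) < 2) {
    abort(sprintf(
      "%s: line %d: expected header 'protein_id<TAB>label...'",
      basename(path), tab$lineno[1]
    ))
  }
  labels <- header[-1]
  body <- tab$fields[-1]
  ln <- tab$lineno[-1]
  row_check(lengths(body) == length(header),
            sprintf("expected %d columns", length(header)), ln, path)
  if (!length(body)) {
    m <- matrix(numeric(), ncol = length(labels))
  } else {
    m <- do.call(rbind, lapply(body, `[`, -1))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(labels))
  for (j in seq_along(labels)) {
    vals[, j] <- num_field(m[, j], labels[j], ln, path)
  }
  row_check(apply(vals >= 0, 1, all) | !length(body),
            "negative RPKM value", ln, path)
  out <- tibble(protein_id = vapply(body, `[[`, character(1), 1))
  for (j in seq_along(labels)) out[[labels[j]]] <- vals[, j]
  out
}

## Long view of an expression matrix: protein_id, time_label, rpkm.
expression_long <- function(expression) {
  tidyr::pivot_longer(expression, -"protein_id",
                      names_to = "time_label", values_to = "rpkm")
}

expression_labels <- function(expression) {
  setdiff(names(expression), "protein_id")
}
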