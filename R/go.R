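#' Parse an OBO ontology file
#'
#' Reads the `[Term]` stanzas of an OBO file, keeping `id`, `name`,
#' `namespace` and `is_a` edges (child -> parent). Obsolete terms are
#' skipped. Non-BP namespaces are retained and can be filtered downstream.
#' The is_a graph must be acyclic.
#'
#' @param path Path to the OBO file.
#' @return An object of class `ontology`: a terms tibble (`id`, `name`,
#'   `namespace`), an edges tibble (`child`, `parent`) and an igraph DAG.
#' @export
parse_obo <- function(path) {
  lines <- readr::read_lines(path)
  term_starts <- which(trimws(lines) == "[Term]")
  if (length(term_starts) == 0) abort(sprintf("no [Term] stanzas in '%s'", path))
  stanza_ends <- c(term_starts[-1] - 1, length(lines))
  # other stanza types ([Typedef], ...) end a [Term] block too
  other <- which(grepl("^\\[", trimws(lines)) & trimws(lines) != "[Term]")
  terms <- list(); edges <- list()
  for (s in seq_along(term_starts)) {
    lo <- term_starts[s] + 1
    hi <- stanza_ends[s]
    cut <- other[other >= lo & other <= hi]
    if (length(cut) > 0) hi <- min(cut) - 1
    if (hi < lo) next
    block <- lines[lo:hi]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               block[startsWith(block, paste0(key, ":"))])
      if (length(v) == 0) NA_character_ else trimws(v[1])
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    terms[[length(terms) + 1]] <- tibble::tibble(
      id = id, name = get1("name") %||% NA_character_,
      namespace = get1("namespace"))
    isa <- block[startsWith(block, "is_a:")]
    for (e in isa) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", e)))
      edges[[length(edges) + 1]] <- tibble::tibble(child = id, parent = parent)
    }
  }
  terms <- dplyr::distinct(dplyr::bind_rows(terms), .data$id, .keep_all = TRUE)
  edges <- if (length(edges) > 0) {
    dplyr::distinct(dplyr::bind_rows(edges))
  } else tibble::tibble(child = character(), parent = character())
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown) > 0) {
    abort(sprintf("is_a edge references unknown term(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    abort(sprintf("is_a graph is cyclic (e.g. term %s)", cyc[1]))
  }
  structure(list(terms = terms, edges = edges, graph = g), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d terms, %d is_a edges>\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

# term -> all is_a ancestors (term included), as a named list
ontology_ancestors <- function(ont, terms = ont$terms$id) {
  setNames(lapply(terms, function(t) {
    igraph::subcomponent(ont$graph, t, mode = "out")$name
  }), terms)
}

#' Parse a GAF/GPAD annotation file
#'
#' Tab-separated gene-association files; comment lines start with `!`. The
#' dialect is auto-detected from the column count: GAF (15-17 columns; object
#' id in column 2, qualifier in 4, term in 5, aspect in 9) or GPAD (12
#' columns; object id in 2, qualifier in 3, term in 4, no aspect column).
#' Rows whose qualifier contains `NOT` are dropped; malformed rows are
#' skipped and counted (attribute `n_skipped`).
#'
#' @param path Path to the annotation file.
#' @param aspect Aspect filter for GAF files ("P", "F", "C" or NULL for all);
#'   ignored for GPAD (filter by ontology namespace downstream instead).
#' @return A tibble with columns `id`, `term` (direct annotations only).
#' @export
parse_annotations <- function(path, aspect = "P") {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_mode <- if (length(fields) > 0) {
    as.integer(names(sort(table(lengths(fields)), decreasing = TRUE))[1])
  } else 0L
  is_gaf <- ncol_mode >= 15
  id_col <- 2L
  qual_col <- if (is_gaf) 4L else 3L
  term_col <- if (is_gaf) 5L else 4L
  aspect_col <- if (is_gaf) 9L else NA_integer_
  min_cols <- if (is_gaf) 9L else 4L
  n_skipped <- 0L
  rows <- purrr::map(fields, function(f) {
    if (length(f) < min_cols || !nzchar(f[id_col]) || !nzchar(f[term_col])) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    if (grepl("NOT", f[qual_col], fixed = TRUE)) return(NULL)
    if (is_gaf && !is.null(aspect) && f[aspect_col] != aspect) return(NULL)
    tibble::tibble(id = f[id_col], term = f[term_col])
  })
  out <- dplyr::distinct(dplyr::bind_rows(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(id = character(), term = character())
  }
  if (n_skipped > 0) {
    inform(sprintf("parse_annotations: skipped %d malformed row(s)", n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Propagate annotations to ancestor terms
#'
#' Closes a direct annotation table upward along is_a edges: each id becomes
#' annotated to every ancestor of each of its direct terms (the term itself
#' included). Idempotent.
#'
#' @param ann A data frame with columns `id`, `term` (direct annotations).
#' @param ont An [parse_obo()] ontology.
#' @return A tibble with columns `id`, `term` (closed annotations).
#' @export
propagate <- function(ann, ont) {
  ann <- tibble::as_tibble(ann)
  stopifnot(all(c("id", "term") %in% names(ann)),
            inherits(ont, "ontology"))
  missing <- setdiff(unique(ann$term), ont$terms$id)
  if (length(missing) > 0) {
    abort(sprintf("annotation to unknown term(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  anc <- ontology_ancestors(ont, unique(ann$term))
  out <- ann |>
    dplyr::mutate(term = unname(anc[.data$term])) |>
    tidyr::unnest("term") |>
    dplyr::distinct(.data$id, .data$term)
  out
}

#' GO term enrichment of a study set against a background
#'
#' Upper-tail hypergeometric enrichment of each ontology term among the study
#' ids, against the annotated background, with Benjamini-Hochberg adjustment
#' (shared kernel with [enrich_targets()]; see [hyper_enrichment()]). By
#' default only background ids carrying at least one (propagated) annotation
#' count toward the universe.
#'
#' @param study Character vector of study ids (subset of `background`).
#' @param background Character vector of background ids.
#' @param ann A closed annotation table from [propagate()] (columns `id`,
#'   `term`).
#' @param fdr FDR threshold (default 0.10).
#' @param namespace Optional namespace filter; requires `ont`.
#' @param ont Optional ontology, used to attach term names and to filter by
#'   namespace.
#' @param include_unannotated Count background ids without annotations in the
#'   universe (default FALSE).
#' @param min_count Minimum background count `K` for a term to be tested
#'   (default 1).
#' @return An `enrichment_table` with a `name` column when `ont` is given.
#' @export
go_enrich <- function(study, background, ann, fdr = 0.10, namespace = NULL,
                      ont = NULL, include_unannotated = FALSE,
                      min_count = 1L) {
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (length(study) == 0) abort("study set is empty")
  if (!all(study %in% background)) {
    abort("study ids must be a subset of the background")
  }
  ann <- tibble::as_tibble(ann)
  if (!is.null(namespace)) {
    if (is.null(ont)) abort("`namespace` filtering requires `ont`")
    keep_terms <- ont$terms$id[ont$terms$namespace %in% namespace]
    ann <- ann[ann$term %in% keep_terms, ]
  }
  ann <- ann[ann$id %in% background, ]
  universe <- if (include_unannotated) background else {
    intersect(background, unique(ann$id))
  }
  study_u <- intersect(study, universe)
  if (length(study_u) == 0) abort("no annotated study id in the universe")
  res <- hyper_enrichment(
    tibble::tibble(entity = ann$term, id = ann$id),
    study = study_u, universe = universe, fdr = fdr
  )
  res <- res[res$K >= min_count, ]
  if (!is.null(ont)) {
    res$name <- ont$terms$name[match(res$entity, ont$terms$id)]
    res <- res[, c("entity", "name", setdiff(names(res),
                                             c("entity", "name")))]
    class(res) <- c("enrichment_table", class(tibble::tibble()))
  }
  res
}
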