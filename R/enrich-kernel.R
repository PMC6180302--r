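#' Hypergeometric enrichment with Benjamini-Hochberg FDR control
#'
#' The shared enrichment kernel used both for target deconvolution
#' ([enrich_targets()]) and for GO term enrichment ([go_enrich()]). For each
#' entity with `K` annotated members in a universe of size `N`, and `k`
#' annotated members among the `n` study ids, the upper-tail hypergeometric
#' p-value `P(X >= k)` is computed, adjusted across all tested entities by
#' the Benjamini-Hochberg step-up rule, and flagged significant when the
#' adjusted value falls below `fdr`. Entities with `k = 0` are retained with
#' `p = 1` so the adjustment family is stable.
#'
#' @param members A data frame with columns `entity` and `id`: one row per
#'   (entity, member) annotation within the universe.
#' @param study Character vector of study ids (must be a subset of the
#'   universe).
#' @param universe Character vector of all ids in the background.
#' @param fdr FDR threshold for the `significant` flag (default 0.10).
#' @return A tibble of class `enrichment_table` with columns `entity`, `k`,
#'   `K`, `n`, `N`, `p`, `q`, `significant`, sorted by `q` then `p`.
#' @examples
#' members <- tibble::tibble(entity = "t1", id = c("a", "b", "c"))
#' hyper_enrichment(members, study = c("a", "b", "c", "d"),
#'                  universe = c(letters[1:10]))
#' @export
hyper_enrichment <- function(members, study, universe, fdr = 0.10) {
  members <- tibble::as_tibble(members)
  stopifnot(all(c("entity", "id") %in% names(members)))
  universe <- unique(as.character(universe))
  study <- unique(as.character(study))
  if (length(study) == 0) abort("study set is empty")
  if (!all(study %in% universe)) abort("study ids must be a subset of the universe")
  members <- members[members$id %in% universe, ]
  members <- dplyr::distinct(members, .data$entity, .data$id)
  N <- length(universe)
  n <- length(study)
  counts <- members |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(K = dplyr::n(), k = sum(.data$id %in% study),
                     .groups = "drop")
  if (nrow(counts) == 0) abort("no annotated entities in the universe")
  counts$n <- n
  counts$N <- N
  counts$p <- phyper(counts$k - 1, counts$K, N - counts$K, n,
                     lower.tail = FALSE)
  counts$q <- p.adjust(counts$p, method = "BH")
  counts$significant <- counts$q < fdr
  out <- counts[order(counts$q, counts$p, counts$entity, method = "radix"),
                c("entity", "k", "K", "n", "N", "p", "q", "significant")]
  attr(out, "fdr") <- fdr
  class(out) <- c("enrichment_table", class(out))
  out
}

#' @rdname hyper_enrichment
#' @param x An `enrichment_table`.
#' @param ... Unused.
#' @export
glance.enrichment_table <- function(x, ...) {
  tibble::tibble(n_entities = nrow(x), n_significant = sum(x$significant),
                 universe_size = x$N[1] %||% NA_integer_,
                 study_size = x$n[1] %||% NA_integer_,
                 fdr = attr(x, "fdr") %||% NA_real_)
}

#' Volcano-style plot of an enrichment table
#'
#' Plots each tested entity's fold enrichment (`(k/n)/(K/N)`) against
#' `-log10(q)`, highlighting entities significant at the table's FDR
#' threshold.
#'
#' @param object An `enrichment_table`.
#' @param top_labels Number of smallest-q entities to label (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_table <- function(object, top_labels = 5, ...) {
  df <- tibble::as_tibble(object)
  df$fold <- (df$k / df$n) / (df$K / df$N)
  df$label <- ifelse(seq_len(nrow(df)) <= top_labels, df$entity, "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = -log10(.data$q),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "fold enrichment (k/n)/(K/N)",
                  y = expression(-log[10](q)),
                  colour = sprintf("q < %.2g", attr(object, "fdr") %||% 0.1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write an enrichment table to TSV
#'
#' @param x An `enrichment_table`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
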