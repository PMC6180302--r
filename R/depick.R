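#' Assemble per-compound target sets for target deconvolution
#'
#' For every screened compound, the target set is the union of its known
#' annotations in the association database (passed through with precision
#' 1.0) and its ligand-based predictions with calibrated precision strictly
#' above `precision_min`. Highly promiscuous compounds — those exceeding
#' `promiscuity_max` known-or-predicted targets — are removed entirely, and
#' compounds with no remaining targets drop out of the analysis universe.
#'
#' @param screen A data frame with columns `compound_id` and `active`
#'   (logical or 0/1), and optionally a `fingerprint` list column. Compounds
#'   found in `db` by id contribute their known annotations; compounds with a
#'   fingerprint are additionally (or alternatively) run through
#'   [predict_targets()] when `calib` is supplied.
#' @param db An [association_db()].
#' @param calib A [calibrate_precision()] table, or NULL to use known
#'   annotations only (no predictions).
#' @param precision_min Predictions must exceed this precision (strictly) to
#'   be retained; default 0.5.
#' @param promiscuity_max Compounds with more targets than this are discarded
#'   as promiscuous; default 100.
#' @return A tibble of class `compound_target_map` with columns
#'   `compound_id`, `target`, `provenance` ("known" or "predicted") and
#'   `precision`.
#' @export
collect_targets <- function(screen, db, calib = NULL, precision_min = 0.5,
                            promiscuity_max = 100L) {
  screen <- tibble::as_tibble(screen)
  stopifnot(all(c("compound_id", "active") %in% names(screen)),
            inherits(db, "association_db"))
  screen$compound_id <- as.character(screen$compound_id)
  has_fp <- "fingerprint" %in% names(screen)
  if (has_fp && db$n_compounds > 0) {
    db_fp <- db$compounds$fingerprint[[1]]
    ok <- vapply(screen$fingerprint, function(f) {
      is.null(f) || (inherits(f, "fingerprint") &&
                       tryCatch({ check_fp_compatible(f, db_fp); TRUE },
                                error = function(e) FALSE))
    }, logical(1))
    if (!all(ok)) abort("screen fingerprints incompatible with the database's")
  }
  # known annotations, vectorised over the screen
  j <- match(screen$compound_id, db$compounds$id)
  known_list <- db$compounds$targets[j]
  known_list[is.na(j)] <- list(character())
  map <- tibble::tibble(
    compound_id = rep(screen$compound_id, lengths(known_list)),
    target = unlist(known_list) %||% character(),
    provenance = "known", precision = 1.0
  )
  # ligand-based predictions, per compound with a fingerprint
  if (!is.null(calib) && has_fp) {
    preds <- purrr::map(seq_len(nrow(screen)), function(i) {
      fp <- screen$fingerprint[[i]]
      if (is.null(fp) || length(fp$features) == 0) return(NULL)
      cid <- screen$compound_id[i]
      pred <- predict_targets(fp, db, calib, query_id = cid)
      pred <- pred[pred$precision > precision_min &
                     !(pred$target %in% known_list[[i]]), ]
      if (nrow(pred) == 0) return(NULL)
      tibble::tibble(compound_id = cid, target = pred$target,
                     provenance = "predicted", precision = pred$precision)
    })
    map <- dplyr::bind_rows(map, dplyr::bind_rows(preds))
  }
  if (nrow(map) > 0) {
    keep <- map |>
      dplyr::count(.data$compound_id) |>
      dplyr::filter(.data$n <= promiscuity_max)
    map <- map[map$compound_id %in% keep$compound_id, ]
  }
  class(map) <- c("compound_target_map", class(map))
  map
}

#' Test targets for enrichment among screen actives
#'
#' DePick-style deconvolution: with the analysis universe defined as all
#' screened, non-promiscuous compounds carrying at least one
#' known-or-predicted target (actives and inactives alike), each target is
#' tested for over-representation among the active compounds with the
#' upper-tail hypergeometric test, followed by Benjamini-Hochberg adjustment
#' across the screen's target family (significant at adjusted q < `fdr`,
#' default 10%).
#'
#' @param map A [collect_targets()] output (compound -> target map).
#' @param actives Character vector of active compound ids (subset of the
#'   map's compounds).
#' @param fdr FDR threshold (default 0.10).
#' @return An `enrichment_table` (see [hyper_enrichment()]) with targets as
#'   entities.
#' @export
enrich_targets <- function(map, actives, fdr = 0.10) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("compound_id", "target") %in% names(map)))
  actives <- unique(as.character(actives))
  if (length(actives) == 0) abort("active set is empty")
  universe <- unique(map$compound_id)
  actives <- actives[actives %in% universe]
  if (length(actives) == 0) {
    abort("no active compound remains in the analysis universe")
  }
  hyper_enrichment(
    tibble::tibble(entity = map$target, id = map$compound_id),
    study = actives, universe = universe, fdr = fdr
  )
}

#' Run target deconvolution on one screen
#'
#' Convenience wrapper: [collect_targets()] then [enrich_targets()] using the
#' screen's `active` column.
#'
#' @inheritParams collect_targets
#' @inheritParams enrich_targets
#' @return An `enrichment_table` of targets.
#' @export
depick <- function(screen, db, calib = NULL, precision_min = 0.5,
                   promiscuity_max = 100L, fdr = 0.10) {
  map <- collect_targets(screen, db, calib, precision_min, promiscuity_max)
  actives <- screen$compound_id[as.logical(screen$active)]
  enrich_targets(map, actives, fdr = fdr)
}
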