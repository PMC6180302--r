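#' Build a compound-target association database
#'
#' The reference chemical-protein interaction space used for ligand-based
#' target prediction: annotated compounds with fingerprints, plus the count
#' caches needed for Laplacian-corrected naive Bayes scoring (per-feature
#' compound counts, per-(feature, target) counts, and per-target priors).
#'
#' @param compounds A data frame with columns `id` (character),
#'   `fingerprint` (list of [fingerprint()] objects) and `targets` (list of
#'   character vectors of target ids).
#' @param targets Optional declared target universe. Targets observed in the
#'   annotations are always included; declared targets with zero annotated
#'   compounds are legal and score 0 for every query.
#' @return An object of class `association_db`.
#' @examples
#' db <- association_db(tibble::tibble(
#'   id = c("c1", "c2", "c3", "c4"),
#'   fingerprint = list(fingerprint(c(1, 2)), fingerprint(2),
#'                      fingerprint(3), fingerprint(c(1, 3))),
#'   targets = list("t1", "t1", "t2", "t2")
#' ))
#' db$n_associations # 4
#' @export
association_db <- function(compounds, targets = NULL) {
  compounds <- tibble::as_tibble(compounds)
  stopifnot(all(c("id", "fingerprint", "targets") %in% names(compounds)))
  compounds$id <- as.character(compounds$id)
  if (anyDuplicated(compounds$id)) abort("compound ids must be unique")
  if (!all(vapply(compounds$fingerprint, inherits, logical(1), "fingerprint"))) {
    abort("`fingerprint` must be a list of fingerprint objects")
  }
  compounds$targets <- purrr::map(compounds$targets, as.character)
  db <- structure(list(compounds = compounds), class = "association_db")
  db <- db_build_caches(db)
  extra <- setdiff(as.character(targets %||% character()), db$target_universe)
  db$target_universe <- sort_cstr(c(db$target_universe, extra))
  db
}

db_build_caches <- function(db) {
  cp <- db$compounds
  n <- nrow(cp)
  feat_by_cpd <- purrr::map(cp$fingerprint, "features")
  all_f <- unlist(feat_by_cpd)
  fc <- table(all_f)
  feature_counts <- setNames(as.integer(fc), names(fc))
  tgt_universe <- sort_cstr(unique(unlist(cp$targets)))
  ftc <- list()
  tgt_n <- setNames(integer(length(tgt_universe)), tgt_universe)
  for (i in seq_len(n)) {
    for (t in cp$targets[[i]]) {
      tgt_n[[t]] <- tgt_n[[t]] + 1L
      v <- ftc[[t]] %||% integer()
      f <- as.character(feat_by_cpd[[i]])
      present <- f %in% names(v)
      if (any(present)) v[f[present]] <- v[f[present]] + 1L
      if (any(!present)) v[f[!present]] <- 1L
      ftc[[t]] <- v
    }
  }
  db$feature_counts <- feature_counts
  db$feature_target_counts <- ftc
  db$target_n <- tgt_n
  db$n_compounds <- n
  db$n_associations <- sum(lengths(cp$targets))
  db$target_universe <- tgt_universe
  db
}

#' @export
print.association_db <- function(x, ...) {
  cat(sprintf("<association_db: %d compounds, %d targets, %d associations>\n",
              x$n_compounds, length(x$target_universe), x$n_associations))
  invisible(x)
}

# remove a set of compounds from the database, decrementing all count caches
db_drop <- function(db, ids) {
  keep <- !(db$compounds$id %in% ids)
  dropped <- db$compounds[!keep, ]
  db$compounds <- db$compounds[keep, ]
  for (i in seq_len(nrow(dropped))) {
    f <- as.character(dropped$fingerprint[[i]]$features)
    db$feature_counts[f] <- db$feature_counts[f] - 1L
    for (t in dropped$targets[[i]]) {
      db$target_n[[t]] <- db$target_n[[t]] - 1L
      v <- db$feature_target_counts[[t]]
      v[f] <- v[f] - 1L
      db$feature_target_counts[[t]] <- v
    }
  }
  db$n_compounds <- nrow(db$compounds)
  db$n_associations <- sum(lengths(db$compounds$targets))
  db
}

#' Laplacian-corrected naive Bayes target score
#'
#' Log-scale additive score of a query fingerprint against one target:
#' `sum over query features f of ln((A_ft + 1) / (A_f * P(t) + 1))`, where
#' `A_ft` is the number of database compounds annotated to the target that
#' contain feature `f`, `A_f` the number of database compounds containing
#' `f`, and `P(t)` the fraction of database compounds annotated to the
#' target. Features absent from the database contribute `ln(1/1) = 0`, as
#' does every feature when the target has no annotated compounds.
#'
#' @param query A [fingerprint()].
#' @param db An [association_db()].
#' @param target A target id present in the database's target universe.
#' @return A single numeric score (natural-log scale).
#' @examples
#' db <- association_db(tibble::tibble(
#'   id = paste0("c", 1:4),
#'   fingerprint = list(fingerprint(c(1, 2)), fingerprint(2),
#'                      fingerprint(3), fingerprint(c(1, 3))),
#'   targets = list("t1", "t1", "t2", "t2")
#' ))
#' nb_score(fingerprint(c(1, 2)), db, "t1") # log(3/2) = 0.4055
#' @export
nb_score <- function(query, db, target) {
  stopifnot(inherits(query, "fingerprint"), inherits(db, "association_db"))
  if (!target %in% db$target_universe) {
    abort(sprintf("unknown target id '%s'", target))
  }
  f <- as.character(query$features)
  if (length(f) == 0) return(0)
  a_f <- db$feature_counts[f]
  a_f[is.na(a_f)] <- 0L
  v <- db$feature_target_counts[[target]] %||% integer()
  a_ft <- v[f]
  a_ft[is.na(a_ft)] <- 0L
  p_t <- (db$target_n[target] %||% 0L)
  p_t <- if (is.na(p_t)) 0 else as.numeric(p_t) / db$n_compounds
  sum(log((as.numeric(a_ft) + 1) / (as.numeric(a_f) * p_t + 1)))
}

#' k-NN neighbour space covering a fixed number of distinct targets
#'
#' Sorts the database compounds by descending Tanimoto similarity to the
#' query (ties broken by ascending compound id) and returns the shortest
#' prefix whose union of target annotations covers `n_targets` distinct
#' targets — or all of them if fewer exist. Compounds with zero similarity to
#' the query are not neighbours: they share no substructure and are excluded
#' from the space, so a query with no structural overlap to the database
#' yields an empty space (and no predictions).
#'
#' @param query A non-empty [fingerprint()].
#' @param db An [association_db()].
#' @param n_targets Number of distinct targets the space must cover
#'   (default 10).
#' @return A tibble with columns `id`, `tanimoto`, `targets` (list column),
#'   ordered by decreasing similarity.
#' @export
knn_target_space <- function(query, db, n_targets = 10L) {
  stopifnot(inherits(query, "fingerprint"), inherits(db, "association_db"))
  if (db$n_compounds == 0) abort("association database is empty")
  if (length(query$features) == 0) abort("query fingerprint is empty")
  sims <- vapply(db$compounds$fingerprint, function(f) tanimoto(query, f),
                 numeric(1))
  pos <- which(sims > 0)
  if (length(pos) == 0) {
    return(tibble::tibble(id = character(), tanimoto = numeric(),
                          targets = list()))
  }
  sims <- sims[pos]
  db_ids <- db$compounds$id[pos]
  db_targets <- db$compounds$targets[pos]
  ord <- order(-sims, db_ids, method = "radix")
  ids <- db_ids[ord]
  tgts <- db_targets[ord]
  seen <- character()
  cut <- length(ord)
  for (i in seq_along(ord)) {
    seen <- unique(c(seen, tgts[[i]]))
    if (length(seen) >= n_targets) { cut <- i; break }
  }
  tibble::tibble(id = ids[seq_len(cut)], tanimoto = sims[ord][seq_len(cut)],
                 targets = tgts[seq_len(cut)])
}

#' Predict protein targets for a query compound
#'
#' Ligand-based prediction over the k-NN space covering up to 10 distinct
#' targets: each candidate target receives its naive Bayes score
#' ([nb_score()]), its occurrence (number of space compounds annotated to
#' it), the Tanimoto similarity to the most similar annotated space compound,
#' a rank by descending score (ties by descending occurrence, then ascending
#' target id; at most 10 ranks are kept), and a cross-validated precision
#' looked up from the calibration table.
#'
#' @param query A non-empty [fingerprint()].
#' @param db An [association_db()].
#' @param calib A [calibrate_precision()] table, or NULL to skip precision
#'   assignment (precision column is then NA).
#' @param query_id Identifier recorded in the output.
#' @param n_targets Size of the distinct-target space (default 10).
#' @return A tibble with columns `query_id`, `target`, `nb_score`,
#'   `occurrence`, `rank`, `max_tanimoto`, `precision`, sorted by rank.
#' @export
predict_targets <- function(query, db, calib = NULL, query_id = "query",
                            n_targets = 10L) {
  space <- knn_target_space(query, db, n_targets)
  cand <- unique(as.character(unlist(space$targets)))
  cand <- if (length(cand) > 0) sort_cstr(cand) else cand
  if (length(cand) == 0) {
    return(tibble::tibble(query_id = character(), target = character(),
                          nb_score = numeric(), occurrence = integer(),
                          rank = integer(), max_tanimoto = numeric(),
                          precision = numeric()))
  }
  rows <- purrr::map(cand, function(t) {
    has_t <- vapply(space$targets, function(v) t %in% v, logical(1))
    tibble::tibble(target = t,
                   nb_score = nb_score(query, db, t),
                   occurrence = sum(has_t),
                   max_tanimoto = max(space$tanimoto[has_t]))
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$nb_score, -out$occurrence, out$target, method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out <- out[out$rank <= n_targets, ]
  out$precision <- if (is.null(calib)) {
    NA_real_
  } else {
    lookup_precision(calib, out$occurrence, out$rank, out$max_tanimoto)
  }
  out$query_id <- query_id
  out[, c("query_id", "target", "nb_score", "occurrence", "rank",
          "max_tanimoto", "precision")]
}

occ_bin <- function(x) {
  cut(x, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
      labels = c("1", "2", "3", ">=4"))
}
rank_bin <- function(x) {
  cut(x, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
      labels = c("1", "2", "3", "4-10"))
}
tan_bin <- function(x) {
  cut(x, breaks = c(-Inf, 0.4, 0.7, Inf),
      labels = c("[0,0.4)", "[0.4,0.7)", "[0.7,1]"))
}

#' Cross-validated precision calibration
#'
#' Each database compound (leave-one-out, the default) or fold is held out:
#' its records are removed from all counts and from the neighbour search, it
#' is re-predicted, and each prediction is marked correct iff the predicted
#' target belongs to the held-out compound's true annotation. Predictions are
#' accumulated into bins over occurrence (1/2/3/>=4), rank (1/2/3/4-10) and
#' maximum Tanimoto ([0,0.4), [0.4,0.7), [0.7,1]); per-bin precision is
#' correct/total. Bins with fewer than `min_cell` predictions fall back to
#' the marginal rank-bin precision, then to the overall precision.
#'
#' @param db An [association_db()] with at least 2 compounds.
#' @param folds NULL for leave-one-out (default) or an integer >= 2 for
#'   seeded k-fold cross-validation.
#' @param seed Seed for the fold assignment (irrelevant for leave-one-out but
#'   recorded).
#' @param min_cell Minimum predictions per bin before the fallback rule
#'   applies (default 20).
#' @return An object of class `calibration_table`.
#' @export
calibrate_precision <- function(db, folds = NULL, seed = 1L, min_cell = 20L) {
  stopifnot(inherits(db, "association_db"))
  if (db$n_compounds < 2) abort("calibration needs at least 2 compounds")
  n <- db$n_compounds
  if (is.null(folds)) {
    fold_of <- seq_len(n)   # leave-one-out
  } else {
    folds <- as.integer(folds)
    if (folds < 2) abort("`folds` must be >= 2 (or NULL for leave-one-out)")
    set.seed(seed)
    fold_of <- sample(rep_len(seq_len(folds), n))
  }
  preds <- purrr::map(unique(fold_of), function(fd) {
    held <- db$compounds[fold_of == fd, ]
    db2 <- db_drop(db, held$id)
    if (db2$n_compounds == 0) return(NULL)
    purrr::map(seq_len(nrow(held)), function(i) {
      p <- predict_targets(held$fingerprint[[i]], db2, calib = NULL,
                           query_id = held$id[i])
      if (nrow(p) == 0) return(NULL)
      p$correct <- p$target %in% held$targets[[i]]
      p
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(preds) == 0) {
    warn("cross-validation produced no predictions (no query had a structural neighbour)")
    preds <- tibble::tibble(query_id = character(), target = character(),
                            nb_score = numeric(), occurrence = integer(),
                            rank = integer(), max_tanimoto = numeric(),
                            precision = numeric(), correct = logical())
  }
  preds$occ_bin <- occ_bin(preds$occurrence)
  preds$rank_bin <- rank_bin(preds$rank)
  preds$tan_bin <- tan_bin(preds$max_tanimoto)
  bins <- preds |>
    dplyr::group_by(.data$occ_bin, .data$rank_bin, .data$tan_bin,
                    .drop = FALSE) |>
    dplyr::summarise(n_predictions = dplyr::n(),
                     n_correct = sum(.data$correct), .groups = "drop") |>
    dplyr::mutate(precision = ifelse(.data$n_predictions > 0,
                                     .data$n_correct / .data$n_predictions,
                                     NA_real_))
  rank_marginal <- preds |>
    dplyr::group_by(.data$rank_bin, .drop = FALSE) |>
    dplyr::summarise(n_predictions = dplyr::n(),
                     n_correct = sum(.data$correct), .groups = "drop") |>
    dplyr::mutate(precision = ifelse(.data$n_predictions > 0,
                                     .data$n_correct / .data$n_predictions,
                                     NA_real_))
  structure(list(
    bins = bins,
    rank_marginal = rank_marginal,
    overall = list(n_predictions = nrow(preds),
                   n_correct = sum(preds$correct),
                   precision = mean(preds$correct)),
    scheme = list(folds = if (is.null(folds)) "loo" else folds,
                  seed = seed, min_cell = as.integer(min_cell))
  ), class = "calibration_table")
}

#' Look up calibrated precision for predictions
#'
#' @param calib A [calibrate_precision()] table.
#' @param occurrence,rank,max_tanimoto Vectors describing predictions.
#' @return Numeric vector of precisions in `[0, 1]`.
#' @export
lookup_precision <- function(calib, occurrence, rank, max_tanimoto) {
  stopifnot(inherits(calib, "calibration_table"))
  key <- paste(occ_bin(occurrence), rank_bin(rank), tan_bin(max_tanimoto))
  bins <- calib$bins
  bkey <- paste(bins$occ_bin, bins$rank_bin, bins$tan_bin)
  idx <- match(key, bkey)
  prec <- bins$precision[idx]
  nb <- bins$n_predictions[idx]
  use_fallback <- is.na(prec) | nb < calib$scheme$min_cell
  if (any(use_fallback)) {
    rm_ <- calib$rank_marginal
    ridx <- match(as.character(rank_bin(rank)), as.character(rm_$rank_bin))
    rprec <- rm_$precision[ridx]
    rn <- rm_$n_predictions[ridx]
    rprec[is.na(rprec) | rn == 0] <- calib$overall$precision
    prec[use_fallback] <- rprec[use_fallback]
  }
  unname(prec)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table: %d CV predictions, overall precision %.3f (%s)>\n",
              x$overall$n_predictions, x$overall$precision,
              if (identical(x$scheme$folds, "loo")) "leave-one-out"
              else sprintf("%d-fold", x$scheme$folds)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname calibrate_precision
#' @param x A `calibration_table`.
#' @param ... Unused.
#' @export
tidy.calibration_table <- function(x, ...) x$bins

#' @rdname calibrate_precision
#' @export
glance.calibration_table <- function(x, ...) {
  tibble::tibble(n_predictions = x$overall$n_predictions,
                 n_correct = x$overall$n_correct,
                 precision = x$overall$precision,
                 scheme = as.character(x$scheme$folds)[1],
                 seed = x$scheme$seed)
}

#' Read an association database from TSV
#'
#' Three tab-separated columns (no header): compound id, either a
#' comma-separated integer feature list or a SMILES string, and a
#' semicolon-separated list of target ids.
#'
#' @param path Path to the TSV file.
#' @param radius,nbits Fingerprint parameters.
#' @return An [association_db()].
#' @export
read_association_db <- function(path, radius = 2L, nbits = NULL) {
  tbl <- readr::read_tsv(path, col_names = c("id", "structure", "targets"),
                         col_types = "ccc", progress = FALSE)
  fps <- purrr::map2(tbl$structure, tbl$id, function(s, id) {
    if (grepl("^[0-9, ]+$", s)) {
      fingerprint(as.integer(strsplit(s, ",")[[1]]), radius, nbits)
    } else {
      circular_fingerprint(desalt(parse_smiles(s, id)), radius, nbits)
    }
  })
  association_db(tibble::tibble(
    id = as.character(tbl$id), fingerprint = fps,
    targets = strsplit(tbl$targets, ";")
  ))
}

#' Write target predictions to TSV
#'
#' @param predictions Output of [predict_targets()] (possibly row-bound over
#'   queries).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path, progress = FALSE)
  invisible(path)
}

#' Serialise a calibration table to JSON
#'
#' @param calib A [calibrate_precision()] table.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  obj <- list(bins = calib$bins, rank_marginal = calib$rank_marginal,
              overall = calib$overall, scheme = calib$scheme)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", factor = "string")
  invisible(path)
}

#' Read a calibration table from JSON
#'
#' @param path Path written by [write_calibration()].
#' @return A `calibration_table`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lvl <- list(occ = c("1", "2", "3", ">=4"), rank = c("1", "2", "3", "4-10"),
              tan = c("[0,0.4)", "[0.4,0.7)", "[0.7,1]"))
  bins <- tibble::as_tibble(obj$bins)
  bins$occ_bin <- factor(bins$occ_bin, levels = lvl$occ)
  bins$rank_bin <- factor(bins$rank_bin, levels = lvl$rank)
  bins$tan_bin <- factor(bins$tan_bin, levels = lvl$tan)
  rm_ <- tibble::as_tibble(obj$rank_marginal)
  rm_$rank_bin <- factor(rm_$rank_bin, levels = lvl$rank)
  structure(list(bins = bins, rank_marginal = rm_,
                 overall = as.list(obj$overall),
                 scheme = as.list(obj$scheme)),
            class = "calibration_table")
}
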