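#' Configure an end-to-end pipeline run
#'
#' Bundles input paths, thresholds and the seed for [run_pipeline()].
#' Thresholds default to the published analysis settings: exact-duplicate
#' Tanimoto threshold 1.0, prediction precision cutoff 0.5 (strict),
#' promiscuity cap 100 targets, FDR 10%, and 1,000,000 label permutations for
#' the overlap test.
#'
#' @param inputs Named list of input paths: `library` (fingerprint TSV),
#'   `association_db` (TSV), `screen_a`, `screen_b` (screen TSVs),
#'   `ontology` (OBO), `annotations` (GAF/GPAD), `study`, `background`
#'   (id lists, one per line). Only the inputs needed by the enabled stages
#'   are required.
#' @param outdir Output directory.
#' @param stages Character vector of stages to run, a subset of
#'   `c("dedup", "calibrate", "depick", "overlap", "goenrich")`.
#' @param dedup_threshold,precision_min,promiscuity_max,fdr,n_perm Analysis
#'   thresholds.
#' @param seed Integer seed; each stage forks a deterministic sub-seed from
#'   it and its stage name, so toggling one stage never perturbs another's
#'   randomness.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, outdir,
                       stages = c("dedup", "calibrate", "depick", "overlap",
                                  "goenrich"),
                       dedup_threshold = 1.0, precision_min = 0.5,
                       promiscuity_max = 100L, fdr = 0.10, n_perm = 1e6,
                       seed = 1L) {
  stopifnot(is.list(inputs), precision_min >= 0, precision_min <= 1,
            promiscuity_max >= 1, fdr > 0, fdr < 1, n_perm >= 1)
  bad <- setdiff(stages, c("dedup", "calibrate", "depick", "overlap",
                           "goenrich"))
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s",
                                     paste(bad, collapse = ", ")))
  structure(list(inputs = inputs, outdir = outdir, stages = stages,
                 dedup_threshold = dedup_threshold,
                 precision_min = precision_min,
                 promiscuity_max = as.integer(promiscuity_max),
                 fdr = fdr, n_perm = n_perm, seed = as.integer(seed)),
            class = "run_config")
}

stage_seed <- function(cfg, stage) {
  (cfg$seed + hash31(stage)) %% 2147483647L
}

config_hash <- function(cfg) {
  hash31(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

need_input <- function(cfg, key, stage) {
  path <- cfg$inputs[[key]]
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("stage '%s': missing input '%s' (%s)", stage, key,
                  path %||% "not configured"))
  }
  path
}

#' Run the end-to-end deconvolution pipeline
#'
#' Executes the enabled stages in order — duplicate collapsing, precision
#' calibration, per-screen target deconvolution, cross-screen overlap
#' significance, and GO enrichment — writing per-stage TSV/JSON artifacts
#' into the output directory plus a run manifest (config hash, seed,
#' per-stage row counts) that enables exact reruns. Any stage failure aborts
#' with the stage name.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return()
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    manifest$stages[[stage]] <<- res
  }
  lib <- NULL
  db <- NULL
  calib <- NULL

  run_stage("dedup", function() {
    lib <<- read_fingerprints(need_input(cfg, "library", "dedup"))
    dd <- deduplicate(lib, threshold = cfg$dedup_threshold)
    write_dedup_map(dd, file.path(cfg$outdir, "dedup_map.tsv"))
    list(n_compounds = nrow(dd), n_groups = length(unique(dd$canonical_id)))
  })
  run_stage("calibrate", function() {
    db <<- read_association_db(need_input(cfg, "association_db", "calibrate"))
    calib <<- calibrate_precision(db, seed = stage_seed(cfg, "calibrate"))
    write_calibration(calib, file.path(cfg$outdir, "calibration.json"))
    list(n_cv_predictions = calib$overall$n_predictions,
         overall_precision = calib$overall$precision)
  })
  run_stage("depick", function() {
    if (is.null(db)) {
      db <<- read_association_db(need_input(cfg, "association_db", "depick"))
    }
    counts <- list()
    for (sc in c("screen_a", "screen_b")) {
      screen <- read_screen(need_input(cfg, sc, "depick"))
      if (!is.null(lib)) {
        screen$fingerprint <- lib$fingerprint[match(screen$compound_id,
                                                    lib$id)]
      }
      res <- depick(screen, db, calib, precision_min = cfg$precision_min,
                    promiscuity_max = cfg$promiscuity_max, fdr = cfg$fdr)
      write_enrichment(res, file.path(cfg$outdir,
                                      paste0("depick_", sc, ".tsv")))
      jsonlite::write_json(
        as.list(glance(res)),
        file.path(cfg$outdir, paste0("depick_", sc, "_summary.json")),
        auto_unbox = TRUE, digits = NA)
      counts[[sc]] <- list(n_targets_tested = nrow(res),
                           n_significant = sum(res$significant))
    }
    counts
  })
  run_stage("overlap", function() {
    a <- read_screen(need_input(cfg, "screen_a", "overlap"))
    b <- read_screen(need_input(cfg, "screen_b", "overlap"))
    ds <- dual_screen(a$compound_id, a$compound_id[a$active],
                      b$compound_id, b$compound_id[b$active])
    ot <- overlap_permutation_test(ds, n_perm = cfg$n_perm,
                                   seed = stage_seed(cfg, "overlap"))
    write_overlap(ot, file.path(cfg$outdir, "overlap.json"))
    list(observed = ot$observed, p_empirical = ot$p_empirical,
         p_analytic = ot$p_analytic)
  })
  run_stage("goenrich", function() {
    ont <- parse_obo(need_input(cfg, "ontology", "goenrich"))
    ann <- parse_annotations(need_input(cfg, "annotations", "goenrich"),
                             aspect = "P")
    closed <- propagate(ann, ont)
    study <- readr::read_lines(need_input(cfg, "study", "goenrich"))
    background <- readr::read_lines(need_input(cfg, "background", "goenrich"))
    res <- go_enrich(study, background, closed, fdr = cfg$fdr, ont = ont)
    write_enrichment(res, file.path(cfg$outdir, "go_enrichment.tsv"))
    list(n_terms_tested = nrow(res), n_significant = sum(res$significant))
  })
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
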