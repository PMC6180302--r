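#' Simulation configuration for the synthetic screen pipeline
#'
#' Defines the study conditions every generator draws from. The defaults
#' emulate the structure of a two-organism phenotypic suppression study at
#' roughly one tenth of its printed dimensions: screens of 160 and 475
#' compounds sharing 108, hit rates 8.4% and 7.4%, a reference
#' compound-target database with planted feature blocks per target, and a
#' five-fold activity excess for carriers of the designated disease targets
#' (which simultaneously plants target enrichment within each screen and an
#' excess of shared actives across screens).
#'
#' @param seed RNG seed; every generator is a pure function of the config.
#' @param n_compounds Reference database size.
#' @param n_features Structural feature universe size (fingerprints are
#'   folded to this length).
#' @param feature_rate Per-feature inclusion probability for unannotated
#'   library compounds.
#' @param n_targets Number of protein targets in the database.
#' @param targets_per_compound Annotated targets per database compound.
#' @param block_size Planted feature-block size per target.
#' @param association_strength Probability that an annotated compound carries
#'   each feature of its target's block.
#' @param baseline_feature_rate Probability of carrying any non-block
#'   feature.
#' @param n_duplicate_pairs Exact duplicate pairs injected into generated
#'   libraries (for deduplication tests).
#' @param n_a,n_b,n_shared Screen sizes and shared-compound count.
#' @param hit_rate_a,hit_rate_b Expected overall active fractions.
#' @param active_excess Activity-probability multiplier for disease-target
#'   carriers (1 = null configuration).
#' @param n_disease_targets Number of planted disease targets.
#' @param ontology_depth,ontology_branching Generated DAG shape.
#' @param diamond_rate Probability that a term gets a second parent.
#' @param n_genes Annotated genes in the generated background.
#' @param terms_per_gene Direct leaf annotations per gene.
#' @param planted_excess Sampling-weight multiplier pulling study genes from
#'   the planted branch.
#' @param study_fraction Fraction of the background drawn into the study set.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 560L, n_features = 512L,
                       feature_rate = 0.05,
                       n_targets = 16L, targets_per_compound = 2L,
                       block_size = 8L, association_strength = 0.9,
                       baseline_feature_rate = 0.02,
                       n_duplicate_pairs = 0L,
                       n_a = 160L, n_b = 475L, n_shared = 108L,
                       hit_rate_a = 0.084, hit_rate_b = 0.074,
                       active_excess = 5, n_disease_targets = 1L,
                       ontology_depth = 3L, ontology_branching = 2L,
                       diamond_rate = 0.15, n_genes = 80L,
                       terms_per_gene = 2L, planted_excess = 3,
                       study_fraction = 0.25) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_compounds > 0, n_features > 0, n_targets > 0,
              block_size > 0, n_a > 0, n_b > 0,
              targets_per_compound >= 1, targets_per_compound <= n_targets,
              ontology_depth >= 1, ontology_branching >= 1, n_genes > 0)
    if (n_shared > min(n_a, n_b)) abort("overlap exceeds the smaller screen")
    if (hit_rate_a <= 0 || hit_rate_a >= 1 || hit_rate_b <= 0 || hit_rate_b >= 1) {
      abort("hit rates must lie in (0, 1)")
    }
    if (n_targets * block_size > n_features) {
      abort("planted feature blocks exceed the feature universe")
    }
  })
  structure(cfg, class = "sim_config")
}

target_ids <- function(cfg) sprintf("T%02d", seq_len(cfg$n_targets))

random_fingerprint <- function(cfg, rate) {
  f <- which(runif(cfg$n_features) < rate) - 1L
  if (length(f) == 0) f <- sample.int(cfg$n_features, 1) - 1L
  fingerprint(f, radius = 2L, nbits = cfg$n_features)
}

#' Generate a random compound library
#'
#' Compounds as random structural feature sets (each feature included
#' independently at `feature_rate`), with optional injected exact duplicates.
#' Deterministic per seed.
#'
#' @param cfg A [sim_config()].
#' @return A [compound_library()] tibble.
#' @export
gen_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fps <- purrr::map(seq_len(cfg$n_compounds), function(i) {
    random_fingerprint(cfg, cfg$feature_rate)
  })
  lib <- tibble::tibble(id = sprintf("CPD%04d", seq_len(cfg$n_compounds)),
                        fingerprint = fps, source = "sim")
  if (cfg$n_duplicate_pairs > 0) {
    if (cfg$n_duplicate_pairs > cfg$n_compounds) {
      abort("more duplicate pairs than compounds")
    }
    dup <- lib[seq_len(cfg$n_duplicate_pairs), ]
    dup$id <- sprintf("DUP%04d", seq_len(cfg$n_duplicate_pairs))
    lib <- dplyr::bind_rows(lib, dup)
  }
  compound_library(lib)
}

#' Generate an association database with planted feature-target signal
#'
#' Each target owns a disjoint block of `block_size` features; each compound
#' is annotated to `targets_per_compound` targets and carries its targets'
#' block features with probability `association_strength` and every other
#' feature with probability `baseline_feature_rate`. With strength 1 and
#' baseline 0 the annotated compounds are the unique carriers of their
#' target's block.
#'
#' @param cfg A [sim_config()].
#' @return An [association_db()].
#' @export
gen_association_db <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  tgts <- target_ids(cfg)
  blocks <- lapply(seq_len(cfg$n_targets), function(j) {
    seq.int((j - 1) * cfg$block_size, j * cfg$block_size - 1)
  })
  rows <- purrr::map(seq_len(cfg$n_compounds), function(i) {
    mine <- sort(sample.int(cfg$n_targets, cfg$targets_per_compound))
    block_f <- unlist(blocks[mine])
    keep_block <- block_f[runif(length(block_f)) < cfg$association_strength]
    other_f <- setdiff(seq.int(0, cfg$n_features - 1), block_f)
    keep_other <- other_f[runif(length(other_f)) < cfg$baseline_feature_rate]
    f <- sort(unique(c(keep_block, keep_other)))
    if (length(f) == 0) f <- block_f[1]
    tibble::tibble(id = sprintf("CPD%04d", i),
                   fingerprint = list(fingerprint(f, 2L, cfg$n_features)),
                   targets = list(tgts[mine]))
  })
  association_db(dplyr::bind_rows(rows), targets = tgts)
}

#' Generate two screens with planted target enrichment and overlap
#'
#' Draws screen memberships from the database's compound universe (screens of
#' `n_a` and `n_b` compounds sharing `n_shared`) and assigns activity so that
#' carriers of the designated disease targets are active with
#' `active_excess`-fold elevated probability in both screens, which plants
#' both within-screen target enrichment and an excess of shared actives.
#' Baseline rates are solved so each screen's expected hit rate matches the
#' configured one. `active_excess = 1` is the null configuration.
#'
#' @param cfg A [sim_config()].
#' @param db A [gen_association_db()] database covering at least
#'   `n_a + n_b - n_shared` compounds.
#' @return A list with `screen_a`, `screen_b` (tibbles of `compound_id`,
#'   `active`) and a `truth` record (disease targets, carrier ids, expected
#'   counts).
#' @export
gen_dual_screen <- function(cfg, db) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "association_db"))
  n_universe <- cfg$n_a + cfg$n_b - cfg$n_shared
  if (db$n_compounds < n_universe) {
    abort("association database smaller than the combined screen universe")
  }
  set.seed(cfg$seed + 2L)
  ids <- db$compounds$id[seq_len(n_universe)]
  shared <- ids[seq_len(cfg$n_shared)]
  a_only <- ids[seq.int(cfg$n_shared + 1, cfg$n_a)]
  b_only <- ids[seq.int(cfg$n_a + 1, n_universe)]
  ids_a <- c(shared, a_only)
  ids_b <- c(shared, b_only)
  disease <- target_ids(cfg)[seq_len(cfg$n_disease_targets)]
  carrier_of <- function(id) {
    any(disease %in% db$compounds$targets[[match(id, db$compounds$id)]])
  }
  carriers <- ids[vapply(ids, carrier_of, logical(1))]
  draw <- function(screen_ids, rate) {
    is_c <- screen_ids %in% carriers
    nc <- sum(is_c)
    base <- rate * length(screen_ids) /
      (nc * cfg$active_excess + (length(screen_ids) - nc))
    p <- ifelse(is_c, base * cfg$active_excess, base)
    if (any(p > 1)) {
      abort("requested activity excess infeasible at the given hit rate")
    }
    runif(length(screen_ids)) < p
  }
  act_a <- draw(ids_a, cfg$hit_rate_a)
  act_b <- draw(ids_b, cfg$hit_rate_b)
  list(
    screen_a = tibble::tibble(compound_id = ids_a, active = act_a),
    screen_b = tibble::tibble(compound_id = ids_b, active = act_b),
    truth = list(disease_targets = disease, carriers = carriers,
                 shared_ids = shared,
                 n_shared_actives = sum(act_a[ids_a %in% shared] &
                                          act_b[ids_b %in% shared]))
  )
}

#' Generate a small ontology with a planted enriched branch
#'
#' Builds a rooted DAG (`ontology_depth` levels below the root, branching
#' factor `ontology_branching`, optional diamond edges), annotates `n_genes`
#' genes to random leaf terms, and draws a study set over-sampling genes
#' annotated under the first child of the root by `planted_excess`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `ontology`, `annotations` (direct, columns
#'   `id`/`term`), `study`, `background` and `planted_terms` (the planted
#'   branch's term ids).
#' @export
gen_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  levels <- vector("list", cfg$ontology_depth + 1)
  levels[[1]] <- "GO:R0001"
  cnt <- 1L
  edges <- list()
  for (d in seq_len(cfg$ontology_depth)) {
    above <- levels[[d]]
    lvl <- character()
    for (parent in above) {
      for (b in seq_len(cfg$ontology_branching)) {
        cnt <- cnt + 1L
        id <- sprintf("GO:%06d", cnt)
        lvl <- c(lvl, id)
        edges[[length(edges) + 1]] <- tibble::tibble(child = id,
                                                     parent = parent)
        if (length(above) > 1 && runif(1) < cfg$diamond_rate) {
          second <- sample(setdiff(above, parent), 1)
          edges[[length(edges) + 1]] <- tibble::tibble(child = id,
                                                       parent = second)
        }
      }
    }
    levels[[d + 1]] <- lvl
  }
  all_terms <- unlist(levels)
  terms <- tibble::tibble(id = all_terms,
                          name = paste("synthetic process", all_terms),
                          namespace = "biological_process")
  edges <- dplyr::bind_rows(edges)
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE, vertices = data.frame(name = terms$id))
  ont <- structure(list(terms = terms, edges = edges, graph = g),
                   class = "ontology")
  leaves <- levels[[cfg$ontology_depth + 1]]
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  ann <- purrr::map(genes, function(gid) {
    tibble::tibble(id = gid,
                   term = sample(leaves, min(cfg$terms_per_gene,
                                             length(leaves))))
  }) |> dplyr::bind_rows()
  # planted branch: subtree under the first child of the root
  branch_root <- levels[[2]][1]
  planted <- igraph::subcomponent(g, branch_root, mode = "in")$name
  in_branch <- vapply(genes, function(gid) {
    any(ann$term[ann$id == gid] %in% planted)
  }, logical(1))
  w <- ifelse(in_branch, cfg$planted_excess, 1)
  n_study <- max(1L, round(cfg$study_fraction * cfg$n_genes))
  study <- sample(genes, n_study, prob = w)
  list(ontology = ont, annotations = ann, study = study,
       background = genes, planted_terms = planted)
}

#' Write a synthetic input bundle to a directory
#'
#' Materialises every input the pipeline consumes: fingerprint library TSV,
#' association database TSV, two screen TSVs, OBO ontology, GAF annotations,
#' study/background id lists and a truth record JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- gen_association_db(cfg)
  screens <- gen_dual_screen(cfg, db)
  onto <- gen_ontology(cfg)
  lib <- gen_library(cfg)
  paths <- list(
    library = file.path(dir, "library.tsv"),
    association_db = file.path(dir, "association_db.tsv"),
    screen_a = file.path(dir, "screen_a.tsv"),
    screen_b = file.path(dir, "screen_b.tsv"),
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.gaf"),
    study = file.path(dir, "study_ids.txt"),
    background = file.path(dir, "background_ids.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_fingerprint_tsv(lib, paths$library)
  write_association_db_tsv(db, paths$association_db)
  write_screen(screens$screen_a, paths$screen_a)
  write_screen(screens$screen_b, paths$screen_b)
  write_obo(onto$ontology, paths$ontology)
  write_gaf(onto$annotations, paths$annotations)
  readr::write_lines(onto$study, paths$study)
  readr::write_lines(onto$background, paths$background)
  jsonlite::write_json(
    list(seed = cfg$seed, disease_targets = screens$truth$disease_targets,
         n_carriers = length(screens$truth$carriers),
         n_shared_actives = screens$truth$n_shared_actives,
         planted_terms = onto$planted_terms),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a compound library's fingerprints to TSV
#'
#' Inverse of [read_fingerprints()].
#'
#' @param library A [compound_library()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(library, path) {
  feats <- vapply(library$fingerprint,
                  function(f) paste(f$features, collapse = ","), character(1))
  readr::write_tsv(tibble::tibble(id = library$id, features = feats), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write an association database to TSV
#'
#' Inverse of [read_association_db()].
#'
#' @param db An [association_db()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_association_db_tsv <- function(db, path) {
  feats <- vapply(db$compounds$fingerprint,
                  function(f) paste(f$features, collapse = ","), character(1))
  tgts <- vapply(db$compounds$targets, paste, character(1), collapse = ";")
  readr::write_tsv(tibble::tibble(id = db$compounds$id, features = feats,
                                  targets = tgts),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read/write screen activity tables
#'
#' Screen TSVs have a header and two columns: `compound_id` and `active`
#' (0/1).
#'
#' @param screen A data frame with `compound_id` and `active`.
#' @param path File path.
#' @return `write_screen()` returns `path` invisibly; `read_screen()` a
#'   tibble.
#' @export
write_screen <- function(screen, path) {
  out <- tibble::tibble(compound_id = as.character(screen$compound_id),
                        active = as.integer(as.logical(screen$active)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_screen
#' @export
read_screen <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  tibble::tibble(compound_id = tbl$compound_id, active = tbl$active == 1L)
}

#' Write an ontology to a minimal OBO file
#'
#' Inverse of [parse_obo()] for generated ontologies.
#'
#' @param ont An `ontology`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(ont$terms))) {
    writeLines(c("", "[Term]",
                 paste0("id: ", ont$terms$id[i]),
                 paste0("name: ", ont$terms$name[i]),
                 paste0("namespace: ", ont$terms$namespace[i])), con)
    parents <- ont$edges$parent[ont$edges$child == ont$terms$id[i]]
    for (p in parents) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Write direct annotations as a GAF file
#'
#' Inverse of [parse_annotations()] for generated annotation tables (aspect
#' P, evidence IEA).
#'
#' @param ann A data frame with columns `id`, `term`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, path) {
  rows <- sprintf("DB\t%s\t%s\t\t%s\tREF\tIEA\t\tP\t\t\tgene\ttaxon:0000\t20260101\tDB\t\t",
                  ann$id, ann$id, ann$term)
  readr::write_lines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}
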