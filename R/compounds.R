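#' Construct a molecular graph
#'
#' A minimal connection-table representation of a small molecule: a table of
#' atoms (element symbol, formal charge) and a table of undirected bonds
#' (atom indices, integer bond order). This is the substrate for desalting and
#' circular fingerprinting; no aromaticity perception, stereochemistry or
#' valence model is applied.
#'
#' @param atoms A data frame with columns `element` (character) and `charge`
#'   (integer formal charge; defaults to 0 if absent).
#' @param bonds A data frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (integer bond order; defaults to 1 if absent). Each bond is
#'   stored once; self-loops are rejected.
#' @param id Compound identifier string.
#'
#' @return An object of class `molecular_graph`.
#' @examples
#' g <- molecular_graph(
#'   atoms = data.frame(element = c("C", "O"), charge = c(0L, 0L)),
#'   bonds = data.frame(from = 1, to = 2, order = 2),
#'   id = "formaldehyde-core"
#' )
#' @export
molecular_graph <- function(atoms, bonds = NULL, id = "unnamed") {
  atoms <- tibble::as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  stopifnot(is.character(atoms$element) || is.factor(atoms$element))
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- tibble::tibble(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    bonds$order <- as.integer(bonds$order)
    n <- nrow(atoms)
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n)) {
      abort("bond endpoints must be valid atom indices")
    }
    if (any(bonds$from == bonds$to)) abort("self-loop bonds are not allowed")
    # store each undirected bond once, low index first
    lo <- pmin(bonds$from, bonds$to)
    hi <- pmax(bonds$from, bonds$to)
    bonds$from <- lo
    bonds$to <- hi
    bonds <- dplyr::distinct(bonds, .data$from, .data$to, .keep_all = TRUE)
  }
  structure(list(atoms = atoms, bonds = bonds, id = as.character(id)),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph '%s': %d atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(graph) nrow(graph$atoms)

# connected components as a list of atom-index vectors
graph_components <- function(graph) {
  n <- n_atoms(graph)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (b in seq_len(nrow(graph$bonds))) {
    ri <- find(graph$bonds$from[b])
    rj <- find(graph$bonds$to[b])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

subgraph_of <- function(graph, keep) {
  keep <- sort(keep)
  remap <- match(seq_len(n_atoms(graph)), keep)
  b <- graph$bonds[graph$bonds$from %in% keep & graph$bonds$to %in% keep, ]
  molecular_graph(graph$atoms[keep, ],
                  tibble::tibble(from = remap[b$from], to = remap[b$to],
                                 order = b$order),
                  id = graph$id)
}

#' Desalt a molecular graph
#'
#' Retains the largest covalently connected component of a multi-component
#' structure record (salt/counter-ion removal). Ties on atom count are broken
#' deterministically by the lexicographically smallest canonical feature
#' multiset (the sorted radius-2 atom-environment identifiers of each
#' component).
#'
#' @param graph A [molecular_graph()].
#' @return A `molecular_graph` containing a single connected component.
#' @examples
#' salt <- parse_smiles("CCO.[Na+]", id = "ethanolate")
#' n_desalted <- nrow(desalt(salt)$atoms) # 3: the sodium is dropped
#' @export
desalt <- function(graph) {
  if (!inherits(graph, "molecular_graph")) abort("`graph` must be a molecular_graph")
  if (n_atoms(graph) == 0) abort("cannot desalt an empty molecular graph")
  comps <- graph_components(graph)
  if (length(comps) == 1) return(graph)
  sizes <- lengths(comps)
  cand <- comps[sizes == max(sizes)]
  if (length(cand) == 1) return(subgraph_of(graph, cand[[1]]))
  # tie-break: smallest canonical feature multiset at radius 2
  keys <- lapply(cand, function(idx) {
    sort(atom_environment_ids(subgraph_of(graph, idx), radius = 2L))
  })
  best <- 1
  for (i in seq_along(keys)[-1]) if (lex_less(keys[[i]], keys[[best]])) best <- i
  subgraph_of(graph, cand[[best]])
}

# all atom-environment identifiers over iterations 0..radius (with duplicates)
atom_environment_ids <- function(graph, radius = 2L) {
  n <- n_atoms(graph)
  if (n == 0) return(integer())
  nb <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$from[b]; j <- graph$bonds$to[b]; o <- graph$bonds$order[b]
    nb[[i]] <- rbind(nb[[i]], c(j, o))
    nb[[j]] <- rbind(nb[[j]], c(i, o))
  }
  deg <- vapply(nb, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  ids <- hash31(paste("a", graph$atoms$element, deg, graph$atoms$charge,
                      sep = "|"))
  all_ids <- ids
  if (radius > 0) {
    for (it in seq_len(radius)) {
      new_ids <- integer(n)
      for (i in seq_len(n)) {
        if (deg[i] == 0) {
          new_ids[i] <- ids[i]  # no neighbours: the environment cannot grow
        } else {
          m <- nb[[i]]
          pair <- paste(m[, 2], ids[m[, 1]], sep = ":")
          new_ids[i] <- hash31(paste("e", it, ids[i],
                                     paste(sort_cstr(pair), collapse = ","),
                                     sep = "|"))
        }
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  all_ids
}

#' Construct a fingerprint from an explicit feature set
#'
#' Circular fingerprints are represented as sets of non-negative integer
#' structural feature identifiers, optionally folded to a fixed length. This
#' constructor is the pass-through path for externally computed fingerprints
#' (e.g. ECFP features from a chemistry toolkit).
#'
#' @param features Integer vector of feature identifiers (deduplicated and
#'   sorted internally).
#' @param radius Fingerprint radius the features were computed at (default 2,
#'   the ECFP-4 convention).
#' @param nbits Optional fold length; when given, all features must be in
#'   `[0, nbits)`.
#' @return An object of class `fingerprint`.
#' @export
fingerprint <- function(features, radius = 2L, nbits = NULL) {
  features <- sort(unique(as.integer(features)))
  if (any(features < 0)) abort("fingerprint features must be non-negative")
  if (!is.null(nbits)) {
    nbits <- as.integer(nbits)
    if (any(features >= nbits)) abort("folded features must be < nbits")
  }
  structure(list(features = features, radius = as.integer(radius),
                 nbits = nbits),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d features, radius %d%s>\n",
              length(x$features), x$radius,
              if (is.null(x$nbits)) "" else sprintf(", folded to %d", x$nbits)))
  invisible(x)
}

#' Compute a circular (Morgan/ECFP-style) fingerprint
#'
#' Iterative atom-environment identifier scheme: the initial identifier of an
#' atom is a hash of its element, degree and formal charge; at each iteration
#' up to `radius`, an atom's identifier becomes a hash of its previous
#' identifier together with the sorted (bond order, neighbour identifier)
#' pairs of its neighbours. The fingerprint is the set of all identifiers
#' produced over iterations `0..radius` (so `radius = 2` corresponds to
#' ECFP-4 diameter-4 environments), optionally folded modulo `nbits`. The
#' result is invariant under atom reordering.
#'
#' @param graph A [molecular_graph()].
#' @param radius Number of neighbourhood-expansion iterations (default 2).
#' @param nbits Optional fold length.
#' @return A [fingerprint()].
#' @examples
#' fp <- circular_fingerprint(parse_smiles("CCO", "ethanol"))
#' length(fp$features)
#' @export
circular_fingerprint <- function(graph, radius = 2L, nbits = NULL) {
  if (!inherits(graph, "molecular_graph")) abort("`graph` must be a molecular_graph")
  radius <- as.integer(radius)
  if (radius < 0) abort("`radius` must be >= 0")
  feats <- unique(atom_environment_ids(graph, radius))
  if (!is.null(nbits)) feats <- unique(feats %% as.integer(nbits))
  fingerprint(feats, radius = radius, nbits = nbits)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over the feature sets. Both fingerprints
#' must have been computed at the same radius and fold length.
#'
#' @param a,b [fingerprint()] objects.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(fingerprint(c(1, 2, 3)), fingerprint(c(2, 3, 4))) # 0.5
#' @export
tanimoto <- function(a, b) {
  if (!inherits(a, "fingerprint") || !inherits(b, "fingerprint")) {
    abort("`a` and `b` must be fingerprint objects")
  }
  check_fp_compatible(a, b)
  na <- length(a$features); nb <- length(b$features)
  if (na == 0 && nb == 0) abort("Tanimoto undefined for two empty fingerprints")
  ni <- length(intersect(a$features, b$features))
  ni / (na + nb - ni)
}

check_fp_compatible <- function(a, b) {
  if (a$radius != b$radius ||
      !identical(is.null(a$nbits), is.null(b$nbits)) ||
      (!is.null(a$nbits) && a$nbits != b$nbits)) {
    abort("fingerprints have inconsistent radius/fold parameters")
  }
  invisible(TRUE)
}

#' Assemble a compound library
#'
#' @param entries A data frame with columns `id` (character, unique within a
#'   source), `fingerprint` (list column of [fingerprint()] objects) and
#'   optionally `source` (library name; default "library").
#' @return A tibble of class `compound_library`.
#' @export
compound_library <- function(entries) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("id", "fingerprint") %in% names(entries)))
  if (!"source" %in% names(entries)) entries$source <- "library"
  entries$id <- as.character(entries$id)
  if (anyDuplicated(paste(entries$source, entries$id))) {
    abort("compound ids must be unique within a source")
  }
  if (!all(vapply(entries$fingerprint, inherits, logical(1), "fingerprint"))) {
    abort("`fingerprint` must be a list of fingerprint objects")
  }
  class(entries) <- c("compound_library", class(entries))
  entries
}

#' Collapse duplicate compounds across libraries
#'
#' Groups entries whose pairwise Tanimoto similarity meets `threshold`
#' (transitive closure over the threshold relation) and assigns each group a
#' deterministic canonical id: the lexicographically smallest member id. The
#' default threshold 1.0 gives exact-duplicate semantics — entries are grouped
#' if and only if their feature sets are identical.
#'
#' @param library A [compound_library()] (all entries fingerprinted at common
#'   radius/fold parameters, desalted).
#' @param threshold Tanimoto similarity at or above which two entries are
#'   considered duplicates (default 1.0).
#' @return A tibble with columns `id`, `source`, `canonical_id`, `group_size`,
#'   one row per input entry.
#' @examples
#' lib <- compound_library(tibble::tibble(
#'   id = c("b", "a", "c"),
#'   fingerprint = list(fingerprint(1:3), fingerprint(1:3), fingerprint(4:6))
#' ))
#' deduplicate(lib) # "a" is canonical for the {a, b} group
#' @export
deduplicate <- function(library, threshold = 1.0) {
  if (!inherits(library, "compound_library")) library <- compound_library(library)
  fps <- library$fingerprint
  n <- length(fps)
  if (n == 0) abort("cannot deduplicate an empty library")
  for (i in seq_len(n)) check_fp_compatible(fps[[1]], fps[[i]])
  if (threshold >= 1) {
    key <- vapply(fps, function(f) paste(f$features, collapse = ","), character(1))
    grp <- match(key, key)
  } else {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (tanimoto(fps[[i]], fps[[j]]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    grp <- vapply(seq_len(n), find, integer(1))
  }
  out <- tibble::tibble(id = library$id, source = library$source, .grp = grp)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$.grp),
    canonical_id = sort_cstr(.data$id)[1],
    group_size = dplyr::n()
  )
  dplyr::select(dplyr::ungroup(out), -".grp")
}
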