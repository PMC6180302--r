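#' Parse a SMILES string into a molecular graph
#'
#' A deliberately minimal SMILES reader covering the constructs needed for
#' library ingestion and desalting: organic-subset atoms (`B C N O P S F Cl
#' Br I`, plus lowercase aromatic forms read as their element), bracket atoms
#' with formal charges (e.g. `[Na+]`, `[O-]`, `[NH4+]`), single/double/triple
#' bonds, branches, ring-bond closures (digits and `%nn`), and dot-separated
#' disconnected components. Aromaticity is not perceived (lowercase ring atoms
#' get single ring bonds), and stereo markers `/ \` are read as single bonds.
#' Structures outside this subset should be fingerprinted externally and
#' loaded through [read_fingerprints()].
#'
#' @param smiles A single SMILES string.
#' @param id Compound identifier.
#' @return A [molecular_graph()].
#' @examples
#' parse_smiles("CC(=O)O.[Na+]", id = "sodium-acetate")
#' @export
parse_smiles <- function(smiles, id = "unnamed") {
  stopifnot(is.character(smiles), length(smiles) == 1)
  chars <- strsplit(smiles, "")[[1]]
  elements <- character()
  charges <- integer()
  bonds <- list()
  prev <- NA_integer_       # index of atom awaiting a bond
  pending <- 1L             # bond order for the next bond
  stack <- integer()        # branch return points
  rings <- list()           # closure label -> c(atom, order)
  two_letter <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic <- c("b", "c", "n", "o", "p", "s")

  add_atom <- function(el, chg) {
    elements[length(elements) + 1] <<- el
    charges[length(charges) + 1] <<- chg
    idx <- length(elements)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1]] <<- c(prev, idx, pending)
    }
    prev <<- idx
    pending <<- 1L
    idx
  }
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    nxt2 <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (nxt2 %in% two_letter) {
      add_atom(nxt2, 0L)
      i <- i + 2
    } else if (ch %in% organic) {
      add_atom(ch, 0L)
      i <- i + 1
    } else if (ch %in% aromatic) {
      add_atom(toupper(ch), 0L)
      i <- i + 1
    } else if (ch == "[") {
      close_i <- i + which(chars[seq(i + 1, n)] == "]")[1]
      if (is.na(close_i)) abort(sprintf("unclosed bracket atom in '%s'", smiles))
      body <- paste(chars[seq(i + 1, close_i - 1)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z])(H[0-9]*)?(\\+{1,}|-{1,}|\\+[0-9]+|-[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0) abort(sprintf("cannot parse bracket atom [%s]", body))
      el <- m[3]
      if (el == toupper(el) || nchar(el) > 1) el <- el else el <- toupper(el)
      chg_s <- m[5]
      chg <- 0L
      if (nzchar(chg_s)) {
        sign <- if (substr(chg_s, 1, 1) == "+") 1L else -1L
        num <- gsub("[+-]", "", chg_s)
        chg <- if (nzchar(num)) sign * as.integer(num) else sign * nchar(chg_s)
      }
      add_atom(el, chg)
      i <- close_i + 1
    } else if (ch == "-") { pending <- 1L; i <- i + 1
    } else if (ch == "=") { pending <- 2L; i <- i + 1
    } else if (ch == "#") { pending <- 3L; i <- i + 1
    } else if (ch %in% c(":", "/", "\\")) { pending <- 1L; i <- i + 1
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) abort(sprintf("unbalanced ')' in '%s'", smiles))
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- 1L; i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        lab <- paste(chars[c(i + 1, i + 2)], collapse = "")
        i <- i + 3
      } else {
        lab <- ch
        i <- i + 1
      }
      if (is.null(rings[[lab]])) {
        rings[[lab]] <- c(prev, pending)
        pending <- 1L
      } else {
        open <- rings[[lab]]
        order <- max(open[2], pending)
        bonds[[length(bonds) + 1]] <- c(open[1], prev, order)
        rings[[lab]] <- NULL
        pending <- 1L
      }
    } else {
      abort(sprintf("unsupported SMILES token '%s' in '%s'", ch, smiles))
    }
  }
  if (length(stack) > 0) abort(sprintf("unbalanced '(' in '%s'", smiles))
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings) > 0) {
    abort(sprintf("unclosed ring bond(s) %s in '%s'",
                  paste(open_rings, collapse = ","), smiles))
  }
  if (length(elements) == 0) abort(sprintf("empty SMILES record '%s'", smiles))
  bond_tbl <- if (length(bonds) > 0) {
    do.call(rbind, bonds) |>
      (\(m) tibble::tibble(from = m[, 1], to = m[, 2], order = m[, 3]))()
  } else NULL
  molecular_graph(tibble::tibble(element = elements, charge = charges),
                  bond_tbl, id = id)
}

#' Read a SMILES library file
#'
#' One record per line: a SMILES string, whitespace, then the compound id.
#' Each record is parsed, desalted and fingerprinted.
#'
#' @param path Path to the SMILES file.
#' @param source Library name recorded per entry.
#' @param radius,nbits Fingerprint parameters (see [circular_fingerprint()]).
#' @param desalt Whether to keep only the largest connected component
#'   (default TRUE).
#' @return A [compound_library()] tibble.
#' @export
read_smiles_library <- function(path, source = basename(path), radius = 2L,
                                nbits = NULL, desalt = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("no records in '%s'", path))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(sprintf("line %d of '%s' lacks an id field", bad[1], path))
  }
  entries <- purrr::map(parts, function(p) {
    g <- parse_smiles(p[1], id = p[2])
    if (desalt) g <- desalt(g)
    tibble::tibble(id = p[2],
                   fingerprint = list(circular_fingerprint(g, radius, nbits)))
  })
  out <- dplyr::bind_rows(entries)
  out$source <- source
  compound_library(out)
}

#' Read precomputed fingerprints from TSV
#'
#' Pass-through path for fingerprints computed by an external chemistry
#' toolkit. Format: two tab-separated columns, compound id and a
#' comma-separated list of integer features (no header).
#'
#' @param path Path to the TSV file.
#' @param source Library name recorded per entry.
#' @param radius,nbits Parameters the external fingerprints were computed at.
#' @return A [compound_library()] tibble.
#' @export
read_fingerprints <- function(path, source = basename(path), radius = 2L,
                              nbits = NULL) {
  tbl <- readr::read_tsv(path, col_names = c("id", "features"),
                         col_types = "cc", progress = FALSE)
  fps <- purrr::map(strsplit(tbl$features, ","), function(f) {
    fingerprint(as.integer(f), radius = radius, nbits = nbits)
  })
  compound_library(tibble::tibble(id = as.character(tbl$id), fingerprint = fps,
                                  source = source))
}

#' Write a deduplication map to TSV
#'
#' @param dedup_map Output of [deduplicate()].
#' @param path Destination path; columns `member_id`, `canonical_id`,
#'   `group_size`.
#' @return `path`, invisibly.
#' @export
write_dedup_map <- function(dedup_map, path) {
  out <- tibble::tibble(member_id = dedup_map$id,
                        canonical_id = dedup_map$canonical_id,
                        group_size = dedup_map$group_size)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
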