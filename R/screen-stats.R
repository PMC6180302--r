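#' Screen hit rate
#'
#' Percentage of screened compounds scored active, rounded half-even to one
#' decimal (the convention of screening reports).
#'
#' @param n_active,n_screened Counts with `0 <= n_active <= n_screened`.
#' @return Percentage with one decimal.
#' @examples
#' hit_rate(134, 1600) # 8.4
#' @export
hit_rate <- function(n_active, n_screened) {
  stopifnot(is_scalar_number(n_active), is_scalar_number(n_screened))
  if (n_screened <= 0) abort("`n_screened` must be positive")
  if (n_active < 0 || n_active > n_screened) {
    abort("`n_active` must lie in [0, n_screened]")
  }
  round(100 * n_active / n_screened, 1)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector (at least one value).
#' @return A tibble with columns `mean`, `sem`, `n`. For a single value the
#'   SEM is 0 by convention, with a warning.
#' @examples
#' mean_sem(c(0.34184, 0.38087, 0.20438))
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) abort("`values` is empty")
  if (length(values) == 1) {
    warn("SEM of a single value reported as 0 by convention")
    return(tibble::tibble(mean = values, sem = 0, n = 1L))
  }
  tibble::tibble(mean = mean(values),
                 sem = sd(values) / sqrt(length(values)),
                 n = length(values))
}

check_group_summary <- function(groups, min_groups = 2) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("mean", "sd", "n") %in% names(groups)))
  if (!"label" %in% names(groups)) {
    groups$label <- paste0("group", seq_len(nrow(groups)))
  }
  if (nrow(groups) < min_groups) {
    abort(sprintf("need at least %d groups", min_groups))
  }
  if (any(groups$sd < 0) || any(groups$n < 1)) {
    abort("group summaries need sd >= 0 and n >= 1")
  }
  groups
}

#' Pooled two-sample t-test from group summaries
#'
#' Student's two-tailed t-test with pooled variance, computed from (mean, sd,
#' n) summaries of two groups — the form used for published group-summary
#' tables. Degrees of freedom are `n1 + n2 - 2`.
#'
#' @param groups A data frame with exactly two rows and columns `label`
#'   (optional), `mean`, `sd` (sample SD), `n` (>= 2 each).
#' @return A tibble with `t`, `df`, `p`, and a `degenerate` flag (TRUE when
#'   both SDs are zero; equal means then give p = 1).
#' @examples
#' pooled_t_test_summary(tibble::tibble(
#'   label = c("vehicle", "treated"),
#'   mean = c(155.4, 95.75), sd = c(69.18, 18.77), n = c(8, 8)
#' ))
#' @export
pooled_t_test_summary <- function(groups) {
  groups <- check_group_summary(groups)
  if (nrow(groups) != 2) abort("exactly two groups are required")
  if (any(groups$n < 2)) abort("each group needs n >= 2")
  m <- groups$mean; s <- groups$sd; n <- groups$n
  df <- sum(n) - 2
  sp2 <- sum((n - 1) * s^2) / df
  se <- sqrt(sp2 * sum(1 / n))
  if (se == 0) {
    if (m[1] == m[2]) {
      return(tibble::tibble(t = 0, df = df, p = 1, degenerate = TRUE))
    }
    abort("zero pooled variance with unequal means: t is infinite")
  }
  t <- (m[1] - m[2]) / se
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' One-way ANOVA with Tukey comparisons from group summaries
#'
#' Reconstructs the one-way ANOVA F test and all pairwise Tukey HSD adjusted
#' p-values from (mean, sd, n) group summaries. The error mean square is the
#' pooled within-group variance `sum((n_i - 1) s_i^2) / sum(n_i - 1)`; for
#' equal group sizes the studentized range statistic is
#' `|m_i - m_j| / sqrt(MSE / n)`, and unequal sizes use the Tukey-Kramer
#' standard error `sqrt((MSE / 2) (1/n_i + 1/n_j))`. Adjusted p-values come
#' from the studentized range distribution with `k` groups and the pooled
#' error degrees of freedom.
#'
#' @param groups A data frame with columns `label` (optional), `mean`, `sd`,
#'   `n` (each n >= 2), one row per group.
#' @return An object of class `anova_tukey` with the overall F statistic and
#'   a pairwise comparison table; see `tidy()` and `glance()`.
#' @examples
#' fit <- anova_tukey_summary(tibble::tibble(
#'   label = c("wt+DMSO", "mut+DMSO", "wt+drug", "mut+drug"),
#'   mean = c(1, 1.466, 0.5778, 0.6992),
#'   sd = c(0, 0.22, 0.2458, 0.3278), n = c(6, 6, 6, 6)
#' ))
#' tidy(fit)
#' @export
anova_tukey_summary <- function(groups) {
  groups <- check_group_summary(groups, min_groups = 2)
  if (any(groups$n < 2)) abort("each group needs n >= 2")
  k <- nrow(groups)
  m <- groups$mean; s <- groups$sd; n <- groups$n
  df_err <- sum(n - 1)
  mse <- sum((n - 1) * s^2) / df_err
  grand <- sum(n * m) / sum(n)
  msb <- sum(n * (m - grand)^2) / (k - 1)
  if (mse == 0 && any(m != m[1])) {
    abort("zero error variance with unequal means: statistics are infinite")
  }
  f_stat <- if (mse == 0) 0 else msb / mse
  f_p <- if (mse == 0) 1 else stats::pf(f_stat, k - 1, df_err,
                                        lower.tail = FALSE)
  pairs_idx <- combn(k, 2)
  pairs <- purrr::map(seq_len(ncol(pairs_idx)), function(c_) {
    i <- pairs_idx[1, c_]; j <- pairs_idx[2, c_]
    diff <- m[i] - m[j]
    se <- sqrt((mse / 2) * (1 / n[i] + 1 / n[j]))
    q <- if (se == 0) 0 else abs(diff) / se
    tibble::tibble(group1 = groups$label[i], group2 = groups$label[j],
                   diff = diff, q = q,
                   p_adj = if (q == 0) 1 else
                     ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE))
  }) |> dplyr::bind_rows()
  structure(list(f_statistic = f_stat, f_p = f_p, df = c(k - 1, df_err),
                 mse = mse, pairs = pairs, k = k),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("<anova_tukey: F(%d, %d) = %.3f, p = %.4g; %d pairwise comparisons>\n",
              x$df[1], x$df[2], x$f_statistic, x$f_p, nrow(x$pairs)))
  invisible(x)
}

#' @rdname anova_tukey_summary
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @export
tidy.anova_tukey <- function(x, ...) x$pairs

#' @rdname anova_tukey_summary
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p = x$f_p,
                 df_between = x$df[1], df_error = x$df[2], mse = x$mse,
                 n_groups = x$k)
}

#' Comparative-Ct (2^-ddCt) fold change
#'
#' Relative expression by the comparative threshold-cycle method: per
#' condition, `dCt = Ct_target - mean(Ct_references)` (the arithmetic mean of
#' reference Cts, i.e. the geometric mean of reference quantities), and the
#' fold change of the sample versus the calibrator is
#' `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param ct_target_sample Target-gene Ct in the sample condition.
#' @param ct_refs_sample Reference-gene Ct values in the sample condition
#'   (one or more).
#' @param ct_target_calibrator Target-gene Ct in the calibrator condition.
#' @param ct_refs_calibrator Reference-gene Ct values in the calibrator.
#' @return Fold change (1 means no change).
#' @examples
#' ddct_fold_change(25, c(20, 22), 24, c(20, 22)) # 0.5
#' @export
ddct_fold_change <- function(ct_target_sample, ct_refs_sample,
                             ct_target_calibrator, ct_refs_calibrator) {
  refs_s <- as.numeric(ct_refs_sample)
  refs_c <- as.numeric(ct_refs_calibrator)
  if (length(refs_s) == 0 || length(refs_c) == 0) {
    abort("at least one reference gene Ct is required per condition")
  }
  vals <- c(ct_target_sample, refs_s, ct_target_calibrator, refs_c)
  if (!all(is.finite(vals))) abort("all Ct values must be finite")
  dct_s <- ct_target_sample - mean(refs_s)
  dct_c <- ct_target_calibrator - mean(refs_c)
  2^-(dct_s - dct_c)
}

#' Summary statistics of a protein-interaction network
#'
#' Node count, edge count, average node degree (`2E/N`) and the average local
#' clustering coefficient (per-node triangle density, 0 for nodes of degree
#' < 2) of a simple undirected graph given as an edge list.
#'
#' @param edges A data frame whose first two columns are the edge endpoints.
#'   Duplicate edges (either orientation) and self-loops are removed.
#' @param nodes Optional character vector of node ids, to include isolated
#'   nodes.
#' @return A tibble with `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_local_clustering`.
#' @examples
#' network_summary(tibble::tibble(from = c("a", "b", "c"),
#'                                to = c("b", "c", "a"))) # triangle
#' @export
network_summary <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0 && is.null(nodes)) abort("graph is empty")
  ed <- tibble::tibble(from = as.character(edges[[1]]),
                       to = as.character(edges[[2]]))
  ed <- ed[ed$from != ed$to, ]
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  ed <- ed[!duplicated(key), ]
  verts <- unique(c(ed$from, ed$to, as.character(nodes %||% character())))
  if (length(verts) == 0) abort("graph is empty")
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = verts))
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  tibble::tibble(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
                 avg_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
                 avg_local_clustering = mean(cc))
}

MESH_BRANCHES <- c(
  "Molecular Mechanisms of Pharmacological Action" = "D27.505.519",
  "Physiological Effects of Drugs" = "D27.505.696",
  "Therapeutic Uses" = "D27.505.954"
)

#' Bucket compounds into MeSH D27 branches
#'
#' Routes MeSH tree numbers into the three D27 ("Chemical Actions and Uses")
#' branches — Molecular Mechanisms of Pharmacological Action (D27.505.519),
#' Physiological Effects of Drugs (D27.505.696) and Therapeutic Uses
#' (D27.505.954) — by prefix, and tallies distinct compounds per branch and
#' per depth-2 subcategory (the branch prefix plus one more component). A
#' compound with terms in several branches counts once in each; malformed or
#' non-matching tree numbers are tallied as unclassified.
#'
#' @param assignments A data frame with columns `compound_id` and
#'   `tree_number` (strings like `"D27.505.954.248"`).
#' @return A tibble with columns `level` ("branch" or "subcategory"),
#'   `category`, `n_compounds`.
#' @export
mesh_bucket <- function(assignments) {
  assignments <- tibble::as_tibble(assignments)
  stopifnot(all(c("compound_id", "tree_number") %in% names(assignments)))
  tn <- as.character(assignments$tree_number)
  ok_syntax <- grepl("^[A-Z][0-9]+(\\.[0-9]+)*$", tn)
  if (any(!ok_syntax)) {
    inform(sprintf("mesh_bucket: %d malformed tree number(s) counted as unclassified",
                   sum(!ok_syntax)))
  }
  branch <- rep(NA_character_, length(tn))
  subcat <- rep(NA_character_, length(tn))
  for (b in names(MESH_BRANCHES)) {
    pref <- MESH_BRANCHES[[b]]
    hit <- ok_syntax & (tn == pref | startsWith(tn, paste0(pref, ".")))
    branch[hit] <- b
    rest <- sub(paste0("^", gsub(".", "\\.", pref, fixed = TRUE), "\\.?"),
                "", tn[hit])
    first <- sub("\\..*$", "", rest)
    subcat[hit] <- ifelse(nzchar(first), paste(pref, first, sep = "."), pref)
  }
  branch[is.na(branch)] <- "unclassified"
  cls <- tibble::tibble(compound_id = as.character(assignments$compound_id),
                        branch = branch, subcategory = subcat)
  br <- cls |>
    dplyr::distinct(.data$compound_id, .data$branch) |>
    dplyr::count(.data$branch, name = "n_compounds") |>
    dplyr::transmute(level = "branch", category = .data$branch,
                     .data$n_compounds)
  sc <- cls[!is.na(cls$subcategory), ] |>
    dplyr::distinct(.data$compound_id, .data$subcategory) |>
    dplyr::count(.data$subcategory, name = "n_compounds") |>
    dplyr::transmute(level = "subcategory", category = .data$subcategory,
                     .data$n_compounds)
  dplyr::bind_rows(br, sc)
}
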