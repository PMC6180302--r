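#' Describe two screens with a shared compound subset
#'
#' Container for the cross-screen overlap analysis: the compound ids and
#' active subsets of two screens, their shared compounds, and the observed
#' number of shared actives.
#'
#' @param ids_a,ids_b Character vectors of screened compound ids.
#' @param actives_a,actives_b Character vectors of active compound ids
#'   (subsets of the respective screens).
#' @return An object of class `dual_screen`.
#' @export
dual_screen <- function(ids_a, actives_a, ids_b, actives_b) {
  ids_a <- unique(as.character(ids_a)); ids_b <- unique(as.character(ids_b))
  actives_a <- unique(as.character(actives_a))
  actives_b <- unique(as.character(actives_b))
  if (!all(actives_a %in% ids_a)) abort("actives_a must be a subset of ids_a")
  if (!all(actives_b %in% ids_b)) abort("actives_b must be a subset of ids_b")
  shared <- intersect(ids_a, ids_b)
  observed <- length(intersect(intersect(actives_a, actives_b), shared))
  structure(list(ids_a = ids_a, actives_a = actives_a,
                 ids_b = ids_b, actives_b = actives_b,
                 shared = shared, observed_shared_actives = observed),
            class = "dual_screen")
}

#' Build a dual screen from printed screen dimensions
#'
#' Constructs synthetic id sets matching stated screen sizes when the actual
#' membership lists are unavailable: `n_shared` compounds are common to both
#' screens, screen A's actives include the `observed` shared actives, and the
#' number of screen-B actives falling inside the shared set defaults to the
#' proportional assumption `round(n_shared * n_active_b / n_b)` (overridable
#' via `b_active_shared`).
#'
#' @param n_a,n_active_a Screen A size and number of actives.
#' @param n_b,n_active_b Screen B size and number of actives.
#' @param n_shared Number of compounds screened in both.
#' @param observed Observed number of shared actives.
#' @param b_active_shared Number of screen-B actives among the shared
#'   compounds; default proportional.
#' @return A [dual_screen()].
#' @examples
#' ds <- dual_screen_from_counts(n_a = 1600, n_active_a = 134,
#'                               n_b = 4748, n_active_b = 350,
#'                               n_shared = 1080, observed = 32)
#' ds$observed_shared_actives
#' @export
dual_screen_from_counts <- function(n_a, n_active_a, n_b, n_active_b,
                                    n_shared, observed,
                                    b_active_shared = NULL) {
  b_active_shared <- b_active_shared %||% round(n_shared * n_active_b / n_b)
  if (observed > min(n_active_a, b_active_shared, n_shared)) {
    abort("observed shared actives exceed the logical maximum")
  }
  shared <- sprintf("S%05d", seq_len(n_shared))
  a_only <- sprintf("A%05d", seq_len(n_a - n_shared))
  b_only <- sprintf("B%05d", seq_len(n_b - n_shared))
  ids_a <- c(shared, a_only)
  ids_b <- c(shared, b_only)
  act_b <- c(head(shared, b_active_shared),
             head(b_only, n_active_b - b_active_shared))
  # A-actives: `observed` of them on B-active shared compounds, the rest off
  off_pool <- c(setdiff(shared, head(shared, b_active_shared)), a_only)
  act_a <- c(head(shared, observed), head(off_pool, n_active_a - observed))
  dual_screen(ids_a, act_a, ids_b, act_b)
}

#' @export
print.dual_screen <- function(x, ...) {
  cat(sprintf(
    "<dual_screen: A %d ids (%d active), B %d ids (%d active), %d shared, %d shared actives>\n",
    length(x$ids_a), length(x$actives_a), length(x$ids_b),
    length(x$actives_b), length(x$shared), x$observed_shared_actives))
  invisible(x)
}

#' Permutation test for the shared-active overlap of two screens
#'
#' Shuffles screen A's active labels uniformly over screen A's compounds
#' `n_perm` times, recomputing the number of shared actives each time; the
#' empirical p-value is the fraction of permutations with a count at least
#' the observed one. Because screen B's actives stay fixed, the
#' per-permutation count is exactly a hypergeometric draw (population =
#' screen A compounds, "marked" = B-active shared compounds, draws = screen A
#' actives), and the default path samples it directly with [stats::rhyper()];
#' `shuffle_both = TRUE` instead literally permutes both screens' labels.
#' The analytic upper-tail hypergeometric p-value is returned alongside as an
#' exact oracle.
#'
#' @param ds A [dual_screen()].
#' @param n_perm Number of permutations (default 1e6).
#' @param seed RNG seed.
#' @param shuffle_both Also shuffle screen B's labels (slower, literal
#'   permutation; default FALSE, matching the one-screen shuffle design).
#' @return An object of class `overlap_test`: observed count, null mean,
#'   empirical and analytic p-values, the tabulated null distribution, and
#'   the run parameters.
#' @examples
#' ds <- dual_screen_from_counts(40, 8, 60, 9, 30, 4)
#' tidy(overlap_permutation_test(ds, n_perm = 1e4, seed = 1))
#' @export
overlap_permutation_test <- function(ds, n_perm = 1e6, seed = 1L,
                                     shuffle_both = FALSE) {
  stopifnot(inherits(ds, "dual_screen"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  n_a <- length(ds$ids_a)
  n_act_a <- length(ds$actives_a)
  b_active_shared <- intersect(ds$actives_b, ds$shared)
  m <- length(b_active_shared)
  obs <- ds$observed_shared_actives
  if (obs > min(n_act_a, m)) abort("observed count exceeds the logical maximum")
  set.seed(seed)
  if (!shuffle_both) {
    draws <- rhyper(n_perm, m, n_a - m, n_act_a)
  } else {
    n_b <- length(ds$ids_b)
    n_act_b <- length(ds$actives_b)
    shared_in_a <- ds$ids_a %in% ds$shared
    shared_in_b <- ds$ids_b %in% ds$shared
    pos_a <- which(shared_in_a); pos_b <- which(shared_in_b)
    map_b <- match(ds$ids_a[pos_a], ds$ids_b)  # align shared ids
    draws <- integer(n_perm)
    for (r in seq_len(n_perm)) {
      lab_a <- logical(n_a); lab_a[sample.int(n_a, n_act_a)] <- TRUE
      lab_b <- logical(n_b); lab_b[sample.int(n_b, n_act_b)] <- TRUE
      draws[r] <- sum(lab_a[pos_a] & lab_b[map_b])
    }
  }
  p_emp <- mean(draws >= obs)
  p_ana <- phyper(obs - 1, m, n_a - m, n_act_a, lower.tail = FALSE)
  structure(list(observed = obs, null_mean = mean(draws),
                 p_empirical = p_emp, p_analytic = p_ana,
                 null_distribution = table(draws),
                 n_perm = n_perm, seed = seed, shuffle_both = shuffle_both,
                 n_a = n_a, n_active_a = n_act_a, b_active_shared = m),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  p_txt <- if (x$p_empirical == 0) sprintf("< %.2g", 1 / x$n_perm)
           else format(x$p_empirical)
  cat(sprintf("<overlap_test: observed %d shared actives, null mean %.2f>\n",
              x$observed, x$null_mean))
  cat(sprintf("  empirical p %s (%d permutations), analytic p %.3g\n",
              p_txt, x$n_perm, x$p_analytic))
  invisible(x)
}

#' @rdname overlap_permutation_test
#' @param x An `overlap_test`.
#' @param ... Unused.
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$null_mean,
                 p_empirical = x$p_empirical, p_analytic = x$p_analytic,
                 n_perm = x$n_perm, seed = x$seed)
}

#' @rdname overlap_permutation_test
#' @export
glance.overlap_test <- function(x, ...) tidy(x)

#' @rdname overlap_permutation_test
#' @param object An `overlap_test`.
#' @export
autoplot.overlap_test <- function(object, ...) {
  df <- tibble::tibble(count = as.integer(names(object$null_distribution)),
                       n = as.integer(object$null_distribution))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$n)) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "shared actives per permutation", y = "permutations",
                  title = sprintf("observed = %d, empirical p = %s",
                                  object$observed,
                                  if (object$p_empirical == 0)
                                    sprintf("< %.2g", 1 / object$n_perm)
                                  else signif(object$p_empirical, 3))) +
    ggplot2::theme_minimal()
}

#' Write an overlap test result to JSON
#'
#' @param x An `overlap_test`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(x, path) {
  jsonlite::write_json(
    list(observed = x$observed, null_mean = x$null_mean,
         p_empirical = x$p_empirical,
         p_empirical_text = if (x$p_empirical == 0)
           sprintf("< %.2g", 1 / x$n_perm) else format(x$p_empirical),
         p_analytic = x$p_analytic, n_perm = x$n_perm, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
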