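test_that("hit rates and mean/SEM reproduce worked values", {
  expect_equal(hit_rate(134, 1600), 8.4)
  expect_equal(hit_rate(350, 4748), 7.4)
  expect_equal(hit_rate(0, 50), 0.0)
  expect_error(hit_rate(1, 0), "positive")
  expect_error(hit_rate(5, 4), "n_active")

  ms <- mean_sem(c(0.34184, 0.38087, 0.20438))
  expect_equal(round(ms$mean, 3), 0.309)
  expect_equal(round(ms$sem, 5), 0.05352)
  expect_equal(mean_sem(c(2, 2, 2))$sem, 0)
  # sd = 1, sem = 1/sqrt(3)
  expect_equal(mean_sem(c(1, 2, 3))$sem, 1 / sqrt(3))
  expect_warning(one <- mean_sem(5), "single value")
  expect_equal(one$sem, 0)
  expect_error(mean_sem(numeric()), "empty")
})

test_that("pooled t-tests from summaries agree with raw-data t-tests", {
  # equal means give t = 0, p = 1
  eq <- pooled_t_test_summary(tibble::tibble(mean = c(3, 3), sd = c(1, 2),
                                             n = c(5, 5)))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # degenerate: both sds zero, equal means
  dg <- pooled_t_test_summary(tibble::tibble(mean = c(1, 1), sd = c(0, 0),
                                             n = c(3, 3)))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  expect_error(pooled_t_test_summary(tibble::tibble(mean = c(1, 2),
                                                    sd = c(0, 0), n = c(3, 3))),
               "infinite")
  # round-trip property: summaries of raw samples reproduce t.test with
  # var.equal = TRUE
  set.seed(91)
  for (rep in 1:10) {
    x <- rnorm(sample(3:9, 1), mean = 2)
    y <- rnorm(sample(3:9, 1))
    g <- tibble::tibble(mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
                        n = c(length(x), length(y)))
    ours <- pooled_t_test_summary(g)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
})

test_that("summary ANOVA + Tukey matches aov/TukeyHSD on raw data", {
  set.seed(92)
  for (rep in 1:5) {
    k <- sample(3:4, 1)
    n <- sample(4:6, 1)
    vals <- lapply(1:k, function(i) rnorm(n, mean = i * 0.5))
    g <- tibble::tibble(label = paste0("G", 1:k),
                        mean = vapply(vals, mean, numeric(1)),
                        sd = vapply(vals, sd, numeric(1)), n = n)
    fit <- anova_tukey_summary(g)
    df <- data.frame(y = unlist(vals), grp = factor(rep(paste0("G", 1:k),
                                                        each = n)))
    ref_aov <- aov(y ~ grp, data = df)
    ref_tk <- TukeyHSD(ref_aov)$grp
    ours <- tidy(fit)
    expect_equal(glance(fit)$f_statistic,
                 unname(summary(ref_aov)[[1]]$`F value`[1]))
    for (r in seq_len(nrow(ours))) {
      key <- paste0(ours$group2[r], "-", ours$group1[r])
      key2 <- paste0(ours$group1[r], "-", ours$group2[r])
      row <- if (key %in% rownames(ref_tk)) ref_tk[key, ] else ref_tk[key2, ]
      expect_equal(ours$p_adj[r], unname(row["p adj"]), tolerance = 1e-6)
    }
  }
})

test_that("Tukey at k = 2 collapses to the pooled t-test", {
  set.seed(93)
  for (rep in 1:5) {
    g <- tibble::tibble(mean = rnorm(2), sd = runif(2, 0.5, 2),
                        n = sample(3:8, 2, replace = TRUE))
    tk <- tidy(anova_tukey_summary(g))
    tt <- pooled_t_test_summary(g)
    # studentized range with 2 means: q = |t| * sqrt(2)
    expect_equal(tk$q, abs(tt$t) * sqrt(2))
    expect_equal(tk$p_adj, tt$p, tolerance = 1e-4)
  }
  # all means equal: every pair q = 0, p = 1
  flat <- anova_tukey_summary(tibble::tibble(mean = c(1, 1, 1),
                                             sd = c(0.5, 0.5, 0.5), n = 4))
  expect_true(all(tidy(flat)$p_adj == 1))
})

test_that("comparative-Ct fold changes follow 2^-ddCt", {
  expect_equal(ddct_fold_change(25, c(20, 22), 24, c(20, 22)), 0.5)
  expect_equal(ddct_fold_change(24, 20, 24, 20), 1)   # self-comparison
  expect_equal(ddct_fold_change(23, 20, 24, 20), 2)   # one cycle earlier
  expect_error(ddct_fold_change(25, numeric(), 24, 20), "reference")
  expect_error(ddct_fold_change(Inf, 20, 24, 20), "finite")
})

test_that("network summaries match hand counts and independent degrees", {
  tri <- network_summary(tibble::tibble(from = c("a", "b", "c"),
                                        to = c("b", "c", "a")))
  expect_equal(tri$avg_degree, 2)
  expect_equal(tri$avg_local_clustering, 1)

  star <- network_summary(tibble::tibble(from = "hub",
                                         to = c("l1", "l2", "l3")))
  expect_equal(star$n_nodes, 4)
  expect_equal(star$avg_degree, 1.5)
  expect_equal(star$avg_local_clustering, 0)

  # duplicate edges and self-loops are cleaned before counting
  messy <- network_summary(tibble::tibble(from = c("a", "b", "a", "a"),
                                          to = c("b", "a", "a", "c")))
  expect_equal(messy$n_edges, 2)

  set.seed(94)
  for (rep in 1:5) {
    n <- 12
    e <- t(combn(n, 2))
    e <- e[runif(nrow(e)) < 0.3, , drop = FALSE]
    if (nrow(e) == 0) next
    s <- network_summary(tibble::tibble(from = paste0("v", e[, 1]),
                                        to = paste0("v", e[, 2])))
    # independent mean degree via the edge list itself
    expect_equal(s$avg_degree,
                 mean(table(factor(c(e[, 1], e[, 2]),
                                   levels = unique(c(e[, 1], e[, 2]))))))
  }
  expect_error(network_summary(tibble::tibble(from = character(),
                                              to = character())), "empty")
})

test_that("MeSH tree numbers route to the three D27 branches", {
  asg <- tibble::tibble(
    compound_id = c("m1", "m1", "m2", "m3", "m4"),
    tree_number = c("D27.505.954.248", "D27.505.519.389.745",
                    "D27.505.696.577", "D27.505.954", "Q99.bad..x"))
  expect_message(out <- mesh_bucket(asg), "malformed")
  br <- out[out$level == "branch", ]
  expect_equal(br$n_compounds[br$category == "Therapeutic Uses"], 2)
  expect_equal(br$n_compounds[br$category ==
                                "Molecular Mechanisms of Pharmacological Action"], 1)
  expect_equal(br$n_compounds[br$category == "Physiological Effects of Drugs"], 1)
  expect_equal(br$n_compounds[br$category == "unclassified"], 1)
  sc <- out[out$level == "subcategory", ]
  expect_true("D27.505.954.248" %in% sc$category)
  # m1 counts once in each of two branches
  expect_equal(sum(br$n_compounds), 5)
})
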