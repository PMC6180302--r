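test_that("naive Bayes scores match hand evaluation on the toy database", {
  db <- toy_db()
  # t1: f1 -> ln((1+1)/(2*0.5+1)) = 0; f2 -> ln((2+1)/(2*0.5+1)) = ln(3/2)
  expect_equal(nb_score(fingerprint(c(1, 2)), db, "t1"), log(3 / 2))
  # t2: f1 -> ln(2/2) = 0; f2 -> ln(1/2)
  expect_equal(nb_score(fingerprint(c(1, 2)), db, "t2"), log(1 / 2))
  # declared target with zero annotated compounds scores 0 for any query
  db2 <- association_db(db$compounds, targets = c("t1", "t2", "t_empty"))
  expect_equal(nb_score(fingerprint(c(1, 2, 3)), db2, "t_empty"), 0)
  # empty query: empty sum
  expect_equal(nb_score(fingerprint(integer()), db, "t1"), 0)
  expect_error(nb_score(fingerprint(1), db, "nope"), "unknown target")
})

test_that("nb_score is additive over disjoint queries and ignores unseen features", {
  db <- toy_db()
  a <- fingerprint(1)
  b <- fingerprint(2)
  ab <- fingerprint(c(1, 2))
  for (t in c("t1", "t2")) {
    expect_equal(nb_score(ab, db, t), nb_score(a, db, t) + nb_score(b, db, t))
    # feature 999 never occurs in the db: contributes ln(1/1) = 0
    expect_equal(nb_score(fingerprint(c(1, 2, 999)), db, t),
                 nb_score(ab, db, t))
  }
})

test_that("the k-NN target space is the shortest prefix covering the targets", {
  db <- toy_db()
  # query identical to c1: c1 first with similarity 1
  sp <- knn_target_space(fingerprint(c(1, 2)), db, n_targets = 2)
  expect_equal(sp$id[1], "c1")
  expect_equal(sp$tanimoto[1], 1)
  expect_true(length(unique(unlist(sp$targets))) >= 2)

  # all compounds share one target: space runs until the db is exhausted
  one <- association_db(tibble::tibble(
    id = c("a", "b", "c"),
    fingerprint = list(fingerprint(c(1, 2)), fingerprint(c(1, 3)),
                       fingerprint(c(1, 4))),
    targets = list("t", "t", "t")))
  expect_equal(nrow(knn_target_space(fingerprint(c(1, 2)), one, 10)), 3)

  # 3 compounds, distinct targets, strictly ordered similarity, n_targets=2:
  # exactly the two nearest compounds
  three <- association_db(tibble::tibble(
    id = c("n1", "n2", "n3"),
    fingerprint = list(fingerprint(c(1, 2, 3)), fingerprint(c(1, 2, 9)),
                       fingerprint(c(1, 8, 9))),
    targets = list("t1", "t2", "t3")))
  sp3 <- knn_target_space(fingerprint(c(1, 2, 3)), three, n_targets = 2)
  expect_equal(sp3$id, c("n1", "n2"))

  expect_error(knn_target_space(fingerprint(integer()), db), "empty")
})

test_that("k-NN space agrees with a brute-force full sort on random instances", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 60
    rows <- tibble::tibble(
      id = sprintf("r%03d", sample(900, n)),
      fingerprint = lapply(1:n, function(i) random_fp(48, 0.25)),
      targets = lapply(1:n, function(i)
        sprintf("t%02d", sample(12, sample(1:2, 1)))))
    db <- association_db(rows)
    q <- random_fp(48, 0.25)
    got <- knn_target_space(q, db, n_targets = 10)
    # oracle: independent full sort + prefix walk
    sims <- vapply(rows$fingerprint, function(f) tanimoto(q, f), numeric(1))
    keep <- sims > 0
    o <- order(-sims[keep], rows$id[keep], method = "radix")
    ids <- rows$id[keep][o]; tg <- rows$targets[keep][o]
    seen <- character(); cut <- length(ids)
    for (i in seq_along(ids)) {
      seen <- unique(c(seen, tg[[i]]))
      if (length(seen) >= 10) { cut <- i; break }
    }
    expect_equal(got$id, ids[seq_len(cut)])
  }
})

test_that("predict_targets ranks by score and caps the list at 10", {
  db <- toy_db()
  p <- predict_targets(fingerprint(c(1, 2)), db, query_id = "q")
  expect_equal(p$target[p$rank == 1], "t1")
  expect_equal(p$nb_score[p$rank == 1], log(3 / 2))
  expect_equal(p$nb_score[p$target == "t2"], log(1 / 2))
  expect_equal(p$max_tanimoto[p$target == "t1"], 1)

  # 12 distinct targets, all compounds similar to the query: capped at 10
  many <- association_db(tibble::tibble(
    id = sprintf("m%02d", 1:12),
    fingerprint = lapply(1:12, function(i) fingerprint(c(0, i))),
    targets = lapply(1:12, function(i) sprintf("t%02d", i))))
  pm <- predict_targets(fingerprint(c(0, 1)), many)
  expect_equal(nrow(pm), 10)
  expect_equal(pm$rank, 1:10)
})

test_that("leave-one-out calibration is exact on twin databases and deterministic", {
  db <- twin_db(8)
  calib <- calibrate_precision(db)
  occupied <- calib$bins[calib$bins$n_predictions > 0, ]
  expect_gt(nrow(occupied), 0)
  expect_true(all(occupied$precision == 1))
  # every held-out twin is re-identified via its identical partner
  expect_equal(calib$overall$n_predictions, 16)
  expect_equal(sum(calib$bins$n_predictions), calib$overall$n_predictions)

  calib2 <- calibrate_precision(db)
  expect_identical(tidy(calib), tidy(calib2))

  # mutually disjoint features and targets: no structural neighbour exists,
  # so no occupied bin can report a positive precision
  disjoint <- association_db(tibble::tibble(
    id = paste0("d", 1:4),
    fingerprint = lapply(1:4, function(i) fingerprint(10 * i + 0:2)),
    targets = lapply(1:4, function(i) paste0("t", i))))
  expect_warning(cd <- calibrate_precision(disjoint), "no predictions")
  expect_true(all(cd$bins$n_predictions == 0))

  expect_error(calibrate_precision(toy_db(), folds = 1), "folds")
})

test_that("calibration precisions are frequencies and the lookup falls back sanely", {
  set.seed(51)
  rows <- tibble::tibble(
    id = sprintf("c%03d", 1:40),
    fingerprint = lapply(1:40, function(i) random_fp(64, 0.2)),
    targets = lapply(1:40, function(i) sprintf("t%02d", sample(6, 1))))
  db <- association_db(rows)
  calib <- calibrate_precision(db)
  occ <- calib$bins[calib$bins$n_predictions > 0, ]
  expect_true(all(occ$precision >= 0 & occ$precision <= 1))
  expect_equal(sum(calib$bins$n_predictions), calib$overall$n_predictions)
  prec <- lookup_precision(calib, occurrence = c(1, 4), rank = c(1, 8),
                           max_tanimoto = c(0.9, 0.1))
  expect_true(all(prec >= 0 & prec <= 1))
})

test_that("planted feature blocks make their target the top prediction", {
  cfg <- sim_config(seed = 101)
  db <- gen_association_db(cfg)
  set.seed(202)
  n_q <- 200
  top1 <- logical(n_q)
  block <- seq.int(0, cfg$block_size - 1)  # target T01's feature block
  for (i in seq_len(n_q)) {
    f <- c(block[runif(cfg$block_size) < cfg$association_strength],
           which(runif(cfg$n_features) < cfg$baseline_feature_rate) - 1L)
    q <- fingerprint(unique(f), 2L, cfg$n_features)
    p <- predict_targets(q, db)
    top1[i] <- nrow(p) > 0 && p$target[p$rank == 1] == "T01"
  }
  expect_gte(mean(top1), 0.9)
})
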