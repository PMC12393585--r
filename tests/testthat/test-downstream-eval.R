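test_that("subject split follows largest-remainder counts", {
  ids <- sprintf("P%04d", 1:1000)
  sp <- split_subjects(ids, seed = 3L)
  expect_length(sp$pretrain_train, 425L)
  expect_length(sp$pretrain_val, 75L)
  expect_length(sp$test, 500L)
  all_ids <- c(sp$pretrain_train, sp$pretrain_val, sp$test)
  expect_setequal(all_ids, ids)
  expect_false(anyDuplicated(all_ids) > 0)
  # degenerate single subject lands in the largest bucket
  one <- split_subjects("P1", seed = 1L)
  expect_identical(one$test, "P1")
  expect_length(one$pretrain_train, 0L)
  expect_error(split_subjects(c("a", "a")), "duplicate")
})

test_that("split partition holds for awkward sizes", {
  for (n in c(2L, 7L, 13L, 101L)) {
    ids <- paste0("s", seq_len(n))
    sp <- split_subjects(ids, seed = n)
    parts <- list(sp$pretrain_train, sp$pretrain_val, sp$test)
    expect_identical(sum(lengths(parts)), n)
    expect_setequal(unlist(parts), ids)
  }
})

test_that("cv folds are balanced, deterministic and subject-disjoint", {
  ids <- paste0("q", 1:500)
  f <- make_cv_folds(ids, k = 4L, seed = 5L)
  expect_true(all(table(f) == 125L))
  expect_identical(f, make_cv_folds(ids, k = 4L, seed = 5L))
  g <- make_cv_folds(paste0("r", 1:10), k = 4L, seed = 1L)
  expect_lte(diff(range(table(g))), 1)
  expect_error(make_cv_folds(paste0("x", 1:3), k = 4L), "at least k")
})

test_that("studies inherit their subject's fold", {
  co <- tiny_cohort(n_subjects = 30L, d = 8L)
  f <- make_cv_folds(unique(co$manifest$subject_id), k = 4L, seed = 2L)
  study_fold <- f[co$manifest$subject_id]
  per_subject <- tapply(study_fold, co$manifest$subject_id,
                        function(x) length(unique(x)))
  expect_true(all(per_subject == 1L))
})

test_that("linear probe separates separable data and handles degenerates", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(0, 0, 1, 1)
  pr <- fit_linear_probe(x, y)
  sc <- predict(pr, x)
  expect_identical(unname(compute_metrics(sc, y)["auc"]), 1)
  expect_warning(expect_null(fit_linear_probe(x, c(1, 1, 1, 1))),
                 "single-class")
})

test_that("null features give chance-level held-out AUC", {
  set.seed(6)
  n <- 2000L
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rbinom(n, 1, 0.5)   # independent of x
  tr <- seq_len(n / 2)
  pr <- fit_linear_probe(x[tr, ], y[tr])
  auc <- unname(compute_metrics(predict(pr, x[-tr, ]), y[-tr])["auc"])
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)
})

test_that("coefficient norms shrink as regularisation strengthens", {
  set.seed(7)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- rbinom(60, 1, plogis(x %*% c(1, -1, 0.5, 0, 0)))
  norms <- vapply(c(10, 1, 0.1), function(C) {
    sqrt(sum(mvecho:::probe_coefficients(fit_linear_probe(x, y, C))^2))
  }, 0)
  expect_true(norms[1] > norms[2])
  expect_true(norms[2] > norms[3])
})

test_that("F1 threshold search matches brute force and edge cases", {
  expect_identical(pick_f1_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
                   0.5)
  # all positives: candidate below the minimum predicts everything positive
  expect_lt(pick_f1_threshold(c(0.3, 0.7), c(1, 1)), 0.3)
  expect_warning(th <- pick_f1_threshold(c(0.3, 0.7), c(0, 0)), "undefined")
  expect_true(is.na(th))
  # 10-point instance vs exhaustive search over all candidate thresholds
  set.seed(8)
  sc <- round(runif(10), 2)
  lab <- rbinom(10, 1, 0.4)
  if (sum(lab) == 0) lab[1] <- 1
  th <- pick_f1_threshold(sc, lab)
  f1_at <- function(t) {
    pred <- as.numeric(sc >= t)
    tp <- sum(pred & lab); fp <- sum(pred & !lab); fn <- sum(!pred & lab)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  u <- sort(unique(sc))
  cands <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2)
  expect_equal(f1_at(th), max(vapply(cands, f1_at, 0)))
})

test_that("rank AUC matches the all-pairs oracle including ties", {
  expect_identical(unname(compute_metrics(c(1, 2, 3), c(0, 0, 1))["auc"]), 1)
  expect_equal(unname(compute_metrics(c(1, 2, 3, 4), c(0, 1, 0, 1))["auc"]),
               0.75)
  expect_equal(unname(compute_metrics(rep(2, 6), c(0, 1, 0, 1, 1, 0))["auc"]),
               0.5)
  expect_true(is.na(compute_metrics(1:3, c(1, 1, 1))["auc"]))
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    sc <- sample(round(runif(n), 1), n, replace = TRUE)  # force ties
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    expect_equal(unname(compute_metrics(sc, lab)["auc"]),
                 auc_all_pairs(sc, lab))
  }
})

test_that("rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  sc <- rnorm(80)
  lab <- rbinom(80, 1, 0.3)
  expect_equal(unname(compute_metrics(sc, lab)["auc"]),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("thresholded accuracy and F1 are computed at score >= threshold", {
  m <- compute_metrics(c(0.2, 0.6, 0.7, 0.4), c(0, 1, 1, 1), threshold = 0.5)
  expect_equal(unname(m["accuracy"]), 0.75)
  expect_equal(unname(m["f1"]), 2 * 2 / (2 * 2 + 0 + 1))
  expect_identical(unname(m["n_pos"]), 3)
  na_m <- compute_metrics(c(0.2, 0.6), c(0, 1), threshold = NA)
  expect_true(is.na(na_m["accuracy"]) && is.na(na_m["f1"]))
  expect_false(is.na(na_m["auc"]))
})

test_that("task evaluation has the expected cardinality and determinism", {
  co <- tiny_cohort(n_subjects = 60L, d = 8L, seed = 23L,
                    tasks = small_tasks(3), label_missingness = NULL)
  emb <- baseline_embed(co)
  res <- evaluate_tasks(emb, co$manifest, k = 4L, repeats = 2L, seed = 4L)
  expect_identical(nrow(res), 3L * 4L * 2L)
  res2 <- evaluate_tasks(emb, co$manifest, k = 4L, repeats = 2L, seed = 4L)
  expect_identical(res, res2)
  # fixed folds: repeats are identical rows
  folds <- make_cv_folds(unique(co$manifest$subject_id), k = 4L, seed = 1L)
  r3 <- evaluate_tasks(emb, co$manifest, folds = folds, repeats = 2L, seed = 4L)
  r31 <- r3[r3$rep == 1, setdiff(colnames(r3), "rep")]
  r32 <- r3[r3$rep == 2, setdiff(colnames(r3), "rep")]
  rownames(r31) <- rownames(r32) <- NULL
  expect_identical(r31, r32)
})

test_that("constant embeddings give chance AUC; missing embeddings error", {
  co <- tiny_cohort(n_subjects = 40L, d = 8L, seed = 24L,
                    tasks = small_tasks(2))
  ids <- co$manifest$study_id
  emb <- embedding_table(ids, matrix(1, length(ids), 4L))
  res <- suppressWarnings(
    evaluate_tasks(emb, co$manifest, k = 2L, repeats = 1L, seed = 5L))
  expect_true(all(abs(res$auc - 0.5) < 1e-9))
  expect_error(evaluate_tasks(emb[-1, ], co$manifest, k = 2L, repeats = 1L),
               paste0("no embedding for study ", ids[1]))
})

test_that("no subject crosses its probe's train/test boundary", {
  co <- tiny_cohort(n_subjects = 40L, d = 8L, seed = 25L,
                    tasks = small_tasks(2))
  emb <- baseline_embed(co)
  out <- evaluate_tasks(emb, co$manifest, k = 3L, repeats = 2L, seed = 6L,
                        keep_predictions = TRUE)
  # reconstruct fold assignments per repeat and check subject disjointness
  for (r in unique(out$predictions$rep)) {
    pr <- out$predictions[out$predictions$rep == r, ]
    sub_fold <- unique(data.frame(
      subject = co$manifest$subject_id[match(pr$study_id,
                                             co$manifest$study_id)],
      fold = pr$fold))
    expect_false(anyDuplicated(sub_fold$subject) > 0)
  }
})

test_that("metrics are invariant to study ordering in the input table", {
  co <- tiny_cohort(n_subjects = 40L, d = 8L, seed = 26L,
                    tasks = small_tasks(2))
  emb <- baseline_embed(co)
  res1 <- evaluate_tasks(emb, co$manifest, k = 2L, repeats = 1L, seed = 7L)
  perm <- sample(nrow(emb))
  res2 <- evaluate_tasks(emb[perm, ], co$manifest, k = 2L, repeats = 1L,
                         seed = 7L)
  expect_equal(res1, res2)
})
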