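test_that("masked-view selection follows the clamped count law", {
  set.seed(1)
  expect_length(select_masked_views(40L, 0.5), 20L)
  expect_length(select_masked_views(2L, 0.5), 1L)
  expect_length(select_masked_views(1L, 0.9), 0L)
  expect_length(select_masked_views(40L, 0), 0L)
  expect_length(select_masked_views(3L, 0.95), 2L)  # clamped to m - 1
  expect_error(select_masked_views(5L, 1), "mask ratio")
  expect_error(select_masked_views(0L, 0.5), "m must be")
})

test_that("masked subsets are uniform over indices", {
  set.seed(2)
  counts <- integer(4)
  for (i in 1:10000) {
    s <- select_masked_views(4L, 0.5)
    counts[s] <- counts[s] + 1L
  }
  # each index should appear in ~50% of draws
  expect_true(all(abs(counts / 10000 - 0.5) < 0.02))
})

test_that("gradient reversal is the identity forward and -omega backward", {
  x <- c(-1.5, 0, 2.25)
  g <- gradient_reversal(x, 0.5)
  expect_identical(g$value, x)
  expect_equal(g$backward(c(1, 2, 3)), c(-0.5, -1, -1.5))
  expect_equal(gradient_reversal(x, 0)$backward(c(9, 9, 9)), c(0, 0, 0))
  expect_error(gradient_reversal(x, -1), "omega")
})

test_that("reversed gradient matches finite differences through a chain", {
  # f(grl(x)) with f(u) = sum(u^3); encoder-side gradient must be -omega f'(x)
  omega <- 0.5
  x <- c(0.3, -1.1)
  f_grad <- 3 * x^2
  grl <- gradient_reversal(x, omega)
  ana <- grl$backward(f_grad)
  num <- vapply(seq_along(x), function(i) {
    h <- 1e-6
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (sum(xp^3) - sum(xm^3)) / (2 * h)
  }, 0)
  expect_equal(ana, -omega * num, tolerance = 1e-6)
})

test_that("reconstruction loss equals the masked-position MSE", {
  expect_identical(reconstruction_loss(matrix(1, 2, 3), matrix(1, 2, 3)), 0)
  expect_identical(reconstruction_loss(matrix(0, 1, 2), matrix(1, 1, 2)), 1)
  expect_identical(reconstruction_loss(matrix(0, 0, 4), matrix(0, 0, 4)), 0)
  set.seed(4)
  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(12), 3, 4)
  brute <- mean(vapply(seq_along(a), function(i) (a[i] - b[i])^2, 0))
  expect_equal(reconstruction_loss(a, b), brute)
  expect_error(reconstruction_loss(matrix(0, 2, 2), matrix(0, 3, 2)),
               "shapes differ")
})

test_that("clinical loss averages BCE over observed labels only", {
  expect_identical(clinical_loss(c(1, -2, 0), c(NA, NA, NA)), 0)
  expect_equal(clinical_loss(0, 1), log(2))
  logits <- matrix(c(0.5, -1, 2, 0, 1.5, -0.3), 2, 3)
  labels <- matrix(c(1, 0, NA, 1, NA, 0), 2, 3)
  obs <- !is.na(labels)
  p <- plogis(logits[obs]); y <- labels[obs]
  hand <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(clinical_loss(logits, labels), hand)
  expect_error(clinical_loss(c(0, 0), c(1, 2)), "labels must be")
})

test_that("adversarial losses are multiclass cross-entropies", {
  cfg <- tiny_encoder_config(8L)
  p <- mve_init_params(cfg, seed = 6L)
  # zero heads give uniform class distributions
  p$sex <- lapply(p$sex, function(x) x * 0)
  p$race <- lapply(p$race, function(x) x * 0)
  l <- adversarial_loss(p, rnorm(8), "female", "other")
  expect_equal(unname(l["sex"]), log(3))
  expect_equal(unname(l["race"]), log(4))
  # fixed logits via b2 only: hand-computed softmax CE over 5 studies
  p$sex$b2 <- c(1, -0.5, 0.2)
  sexes <- c("female", "male", "male", "unknown", "female")
  hand <- mean(vapply(sexes, function(s) {
    k <- match(s, c("female", "male", "unknown"))
    -log(exp(p$sex$b2[k]) / sum(exp(p$sex$b2)))
  }, 0))
  got <- mean(vapply(sexes, function(s)
    adversarial_loss(p, rnorm(8), s, "white")["sex"], 0))
  expect_equal(got, hand)
  expect_error(adversarial_loss(p, rnorm(8), "f", "white"), "alphabet")
  expect_error(adversarial_loss(p, rnorm(8), "male", "hispanic"), "alphabet")
})

test_that("analytic gradients match finite differences on the full model", {
  cfg <- tiny_encoder_config(8L)
  p <- mve_init_params(cfg, n_tasks = 2L, seed = 7L)
  set.seed(8)
  study <- list(X = matrix(rnorm(4 * 8), 4, 8), labels = c(1, NA),
                sex = "female", race = "black", masked = c(1L, 3L))
  pc <- pretrain_config(adversarial_weight = 0.7, learning_rate = 1e-3,
                        epochs = 1L, seed = 1L)
  norms <- list(n_recon = 1, n_obs = 1, n_std = 1)
  loss_fn <- function(pp)
    mvecho:::study_loss_grads(study, pp, cfg, pc, norms, mode = "identity",
                              train = FALSE, want_grads = FALSE)$losses["total"]
  r <- mvecho:::study_loss_grads(study, p, cfg, pc, norms, mode = "identity",
                                 train = FALSE, want_grads = TRUE)
  g <- mvecho:::complete_grads(p, r$grads)
  modify <- function(tree, path, i, delta) {
    if (!length(path)) { tree[i] <- tree[i] + delta; return(tree) }
    tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], i, delta)
    tree
  }
  paths <- list(list("agg"), list("mask"), list("layers", 1L, "Wq"),
                list("layers", 1L, "ln1_g"), list("layers", 2L, "W1"),
                list("layers", 2L, "Wo"), list("lnf_g"), list("recon", "W"),
                list("clin", "W"), list("sex", "W1"), list("race", "W2"))
  for (path in paths) {
    leaf <- p; gl <- g
    for (k in path) { leaf <- leaf[[k]]; gl <- gl[[k]] }
    for (i in sample(length(leaf), 2)) {
      h <- 1e-5
      num <- (loss_fn(modify(p, path, i, h)) -
                loss_fn(modify(p, path, i, -h))) / (2 * h)
      expect_lt(abs(num - gl[i]) / max(1e-6, abs(num) + abs(gl[i])), 1e-4)
    }
  }
})

test_that("encoder gradient is linear in omega through the reversal layer", {
  cfg <- tiny_encoder_config(8L)
  p <- mve_init_params(cfg, n_tasks = 2L, seed = 9L)
  set.seed(10)
  study <- list(X = matrix(rnorm(5 * 8), 5, 8), labels = c(0, 1),
                sex = "male", race = "white", masked = 2L)
  norms <- list(n_recon = 1, n_obs = 2, n_std = 1)
  grads_at <- function(omega, mode) {
    pc <- pretrain_config(adversarial_weight = omega, epochs = 1L, seed = 1L)
    mvecho:::complete_grads(p, mvecho:::study_loss_grads(
      study, p, cfg, pc, norms, mode = mode, train = FALSE)$grads)
  }
  g0 <- grads_at(0, "grl")        # no adversarial contribution
  g1 <- grads_at(1, "identity")   # +1 adversarial contribution
  gh <- grads_at(0.5, "grl")      # should be g0 - 0.5 * (g1 - g0)
  for (leaf in c("agg", "lnf_g")) {
    pred <- g0[[leaf]] - 0.5 * (g1[[leaf]] - g0[[leaf]])
    expect_equal(gh[[leaf]], pred, tolerance = 1e-10)
  }
  W0 <- g0$layers[[1]]$Wv; W1 <- g1$layers[[1]]$Wv
  expect_equal(gh$layers[[1]]$Wv, W0 - 0.5 * (W1 - W0), tolerance = 1e-10)
})

test_that("masked view contents never leak into other tokens", {
  cfg <- tiny_encoder_config(8L)
  p <- mve_init_params(cfg, seed = 11L)
  set.seed(12)
  X <- matrix(rnorm(5 * 8), 5, 8)
  fw1 <- mvecho:::mve_forward(X, p, cfg, masked = c(2L, 4L))
  X2 <- X
  X2[c(2, 4), ] <- 99  # change only masked views' input values
  fw2 <- mvecho:::mve_forward(X2, p, cfg, masked = c(2L, 4L))
  unmasked_tokens <- c(1L, 2L, 4L, 6L)  # agg + unmasked views (+1 offset)
  expect_equal(fw1$Z[unmasked_tokens, ], fw2$Z[unmasked_tokens, ])
  expect_equal(fw1$Z, fw2$Z)  # masked rows were replaced by the mask token
})

test_that("early stopping triggers after patience non-improvements", {
  expect_identical(mvecho:::early_stop_epoch(c(1, 1, 1), patience = 1L), 3L)
  expect_identical(mvecho:::early_stop_epoch(c(3, 2, 1), patience = 1L),
                   NA_integer_)
  expect_identical(mvecho:::early_stop_epoch(c(3, 2, 2.5, 2.4, 2.6), 2L), 5L)
  expect_identical(mvecho:::early_stop_epoch(c(1, 2), patience = 0L), 2L)
})

test_that("training rejects overlapping subjects and mismatched dims", {
  co <- tiny_cohort(n_subjects = 12L, d = 8L)
  cfg <- tiny_encoder_config(8L)
  pc <- pretrain_config(epochs = 1L, seed = 1L)
  expect_error(train_mve(co, co, cfg, pc), "share subjects")
  half <- unique(co$manifest$subject_id)[1:6]
  tr <- cohort_subset(co, subject_ids = half)
  va <- cohort_subset(co, subject_ids = setdiff(unique(co$manifest$subject_id),
                                                half))
  expect_error(train_mve(tr, va, tiny_encoder_config(16L), pc),
               "does not match")
})

test_that("smoke training reduces validation reconstruction loss", {
  co <- generate_cohort(cohort_config(n_subjects = 160L, embed_dim = 16L,
                                      n_view_types = 5L, min_views = 3L,
                                      view_count_meanlog = log(8),
                                      view_count_sdlog = 0.3,
                                      max_views_data = 16L,
                                      tasks = small_tasks(2),
                                      calibration_n = 2000L, seed = 14L))
  subj <- unique(co$manifest$subject_id)
  tr <- cohort_subset(co, subject_ids = subj[1:120])
  va <- cohort_subset(co, subject_ids = subj[121:160])
  cfg <- encoder_config(embed_dim = 16L, n_layers = 2L, n_heads = 4L,
                        max_views = 16L, ff_dim = 32L, dropout = 0.1)
  pc <- pretrain_config(learning_rate = 1e-3, epochs = 10L, patience = 10L,
                        seed = 15L)
  ck <- train_mve(tr, va, cfg, pc)
  h <- ck$history
  expect_identical(nrow(h), 10L)
  expect_lt(h$val_recon[10], h$val_recon[1])
  expect_true(all(is.finite(h$val_total)))
  # loss accounting: total is the stated weighted sum, all parts nonnegative
  expect_equal(h$val_total,
               h$val_recon + pc$lambda_clin * h$val_clinical +
                 h$val_sex + h$val_race)
  expect_true(all(h$val_recon >= 0 & h$val_clinical >= 0 &
                    h$val_sex >= 0 & h$val_race >= 0))
})

test_that("with rho = 0 and no heads the objective is flat at zero", {
  co <- tiny_cohort(n_subjects = 12L, d = 8L, seed = 16L)
  subj <- unique(co$manifest$subject_id)
  tr <- cohort_subset(co, subject_ids = subj[1:8])
  va <- cohort_subset(co, subject_ids = subj[-(1:8)])
  pc <- pretrain_config(mask_ratio = 0, adversarial_weight = 0,
                        lambda_clin = 0, epochs = 3L, patience = 10L,
                        seed = 17L)
  ck <- train_mve(tr, va, tiny_encoder_config(8L), pc, adversarial = FALSE)
  expect_true(all(abs(ck$history$train_total) < 1e-12))
  expect_true(all(abs(ck$history$val_total) < 1e-12))
})

test_that("omega = 0 training equals training without the adversarial branch", {
  co <- tiny_cohort(n_subjects = 20L, d = 8L, seed = 18L)
  subj <- unique(co$manifest$subject_id)
  tr <- cohort_subset(co, subject_ids = subj[1:14])
  va <- cohort_subset(co, subject_ids = subj[-(1:14)])
  cfg <- tiny_encoder_config(8L)
  pc <- pretrain_config(adversarial_weight = 0, learning_rate = 1e-3,
                        epochs = 3L, patience = 10L, seed = 19L)
  ck_adv <- train_mve(tr, va, cfg, pc, adversarial = TRUE)
  ck_off <- train_mve(tr, va, cfg, pc, adversarial = FALSE)
  for (leaf in c("agg", "mask", "lnf_g", "lnf_b"))
    expect_identical(ck_adv$params[[leaf]], ck_off$params[[leaf]])
  expect_identical(ck_adv$params$layers, ck_off$params$layers)
  expect_identical(ck_adv$params$recon, ck_off$params$recon)
  expect_identical(ck_adv$params$clin, ck_off$params$clin)
})

test_that("extraction is deterministic and equals batch encoding", {
  co <- tiny_cohort(n_subjects = 10L, d = 8L, seed = 20L)
  subj <- unique(co$manifest$subject_id)
  tr <- cohort_subset(co, subject_ids = subj[1:7])
  va <- cohort_subset(co, subject_ids = subj[-(1:7)])
  cfg <- tiny_encoder_config(8L)
  ck <- train_mve(tr, va, cfg, pretrain_config(epochs = 2L, seed = 21L))
  e1 <- extract_embeddings(ck, co)
  e2 <- extract_embeddings(ck, co)
  expect_identical(e1, e2)
  expect_identical(nrow(e1), nrow(co$manifest))
  expect_identical(ncol(e1), 9L)
  e3 <- encode_batch(co$views, cfg, ck$params)
  expect_equal(e1[, -1], e3[, -1], tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- tiny_cohort(n_subjects = 4L, d = 16L, seed = 22L)
  expect_error(extract_embeddings(ck, bad), "does not match")
})
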