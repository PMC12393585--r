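make_demo_manifest <- function(n = 120L, seed = 1L) {
  set.seed(seed)
  data.frame(study_id = sprintf("st%03d", 1:n),
             subject_id = sprintf("su%03d", 1:n),
             sex = sample(c("female", "male", "unknown"), n, TRUE,
                          prob = c(0.48, 0.46, 0.06)),
             race = sample(c("white", "black", "other", "unknown"), n, TRUE,
                           prob = c(0.66, 0.18, 0.09, 0.07)),
             view_count = sample(5:80, n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("demographic probes find oracle features and not noise", {
  man <- make_demo_manifest(240L)
  n <- nrow(man)
  set.seed(2)
  noise <- matrix(rnorm(n * 6), n, 6)
  folds <- make_cv_folds(man$subject_id, k = 4L, seed = 3L)
  null_auc <- probe_demographics(embedding_table(man$study_id, noise),
                                 man, "sex", folds = folds)$auc
  expect_gte(null_auc, 0.38)
  expect_lte(null_auc, 0.62)
  oracle <- cbind(noise, as.numeric(man$sex == "female"))
  or_auc <- probe_demographics(embedding_table(man$study_id, oracle),
                               man, "sex", folds = folds)$auc
  expect_gte(or_auc, 0.99)
})

test_that("race macro AUC averages the one-vs-rest class AUCs", {
  man <- make_demo_manifest(200L, seed = 4L)
  set.seed(5)
  X <- cbind(matrix(rnorm(nrow(man) * 4), ncol = 4),
             as.numeric(man$race == "white"),
             as.numeric(man$race == "black"))
  tab <- embedding_table(man$study_id, X)
  folds <- make_cv_folds(man$subject_id, k = 3L, seed = 6L)
  pr <- probe_demographics(tab, man, "race", folds = folds)
  pc <- attr(pr, "per_class")
  expect_named(pc, c("white", "black", "other"))
  expect_equal(pr$auc, mean(pc, na.rm = TRUE))
  expect_gte(pc[["white"]], 0.95)
  expect_gte(pc[["black"]], 0.95)
  expect_lte(pc[["other"]], 0.75)  # no signal for 'other'
})

test_that("video-count bins partition all studies", {
  vc <- c(1, 19, 20, 39, 40, 59, 60, 118)
  b <- video_count_bin(vc)
  expect_identical(as.character(b),
                   c("<20", "<20", "20-39", "20-39", "40-59", "40-59",
                     ">=60", ">=60"))
  expect_false(anyNA(video_count_bin(1:200)))
})

test_that("subgroup AUC matches all-pairs oracle per stratum", {
  man <- make_demo_manifest(40L, seed = 7L)
  set.seed(8)
  preds <- data.frame(task = "t1", fold = 1L, rep = 1L,
                      study_id = man$study_id,
                      score = runif(40), label = rbinom(40, 1, 0.5))
  sg <- subgroup_auc(preds, man, "sex")
  for (s in c("female", "male")) {
    keep <- man$sex == s
    sub <- preds[preds$study_id %in% man$study_id[keep], ]
    expect_equal(sg$auc[sg$stratum == s & sg$task == "t1"],
                 auc_all_pairs(sub$score, sub$label))
  }
  expect_false("unknown" %in% sg$stratum)
})

test_that("identity stratum reproduces the overall AUC", {
  man <- make_demo_manifest(60L, seed = 9L)
  man$sex <- "female"  # one stratum covering everything
  set.seed(10)
  preds <- data.frame(task = "t", fold = 1L, rep = 1L,
                      study_id = man$study_id,
                      score = runif(60), label = rbinom(60, 1, 0.4))
  sg <- subgroup_auc(preds, man, "sex")
  expect_equal(sg$auc, auc_all_pairs(preds$score, preds$label))
})

test_that("mixed-effects comparison recovers null, shift and simulated truth", {
  base <- expand.grid(task = paste0("t", 1:8), rep = 1:3,
                      stringsAsFactors = FALSE)
  set.seed(11)
  base$auc <- 0.7 + rnorm(nrow(base), 0, 0.02)
  both <- rbind(cbind(base, model = "A"), cbind(base, model = "B"))
  r0 <- compare_models_mixed(both, reference = "A")
  expect_lt(abs(r0$estimate), 1e-10)
  expect_gte(r0$p, 0.99)
  shifted <- both
  shifted$auc[shifted$model == "B"] <- shifted$auc[shifted$model == "B"] + 0.05
  r1 <- compare_models_mixed(shifted, reference = "A")
  expect_equal(r1$estimate, 0.05, tolerance = 1e-6)
  expect_lt(r1$p, 1e-6)
  # simulation with known effect and between-task variance
  ests <- replicate(100, {
    tau <- rnorm(6, 0, 0.05)
    d <- expand.grid(task = paste0("t", 1:6), rep = 1:2, model = c("A", "B"),
                     stringsAsFactors = FALSE)
    d$auc <- 0.7 + tau[match(d$task, paste0("t", 1:6))] +
      ifelse(d$model == "B", 0.03, 0) + rnorm(nrow(d), 0, 0.01)
    compare_models_mixed(d, reference = "A")$estimate
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.03), 2 * se + 0.002)
})

test_that("few tasks fall back to a paired comparison with a warning", {
  d <- data.frame(task = rep(c("t1", "t2"), each = 2),
                  model = rep(c("A", "B"), 2),
                  auc = c(0.7, 0.75, 0.6, 0.66))
  expect_warning(r <- compare_models_mixed(d, reference = "A"), "paired")
  expect_equal(r$estimate, mean(c(0.05, 0.06)))
  expect_identical(r$method, "paired")
  expect_error(compare_models_mixed(d[d$model == "A", ]), "two models")
})

test_that("Holm adjustment matches the textbook step-down", {
  expect_identical(holm_bonferroni(0.04), 0.04)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(holm_bonferroni(p[perm]), adj[perm])
  }
  expect_error(holm_bonferroni(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("relative improvement is consistent with the printed pairs", {
  expect_identical(relative_improvement(0, 80), 0)
  expect_equal(relative_improvement(8.4, 75), 11.2)
  expect_equal(relative_improvement(9.0, 75), 12.0)
  expect_error(relative_improvement(1, 0), "positive")
})

test_that("a singleton omega grid reduces to single-model evaluation", {
  co <- generate_cohort(cohort_config(n_subjects = 60L, embed_dim = 8L,
                                      n_view_types = 5L, min_views = 3L,
                                      view_count_meanlog = log(8),
                                      view_count_sdlog = 0.3,
                                      max_views_data = 16L,
                                      tasks = small_tasks(2),
                                      calibration_n = 2000L, seed = 27L))
  cfg <- tiny_encoder_config(8L)
  pc <- pretrain_config(learning_rate = 1e-3, epochs = 2L, seed = 28L)
  sw <- suppressWarnings(
    sweep_adversarial(co, omegas = 0, enc_config = cfg, pre_config = pc,
                      k = 2L, repeats = 1L, seed = 29L,
                      include_baseline = FALSE))
  expect_identical(nrow(sw$summary), 1L)
  expect_identical(sw$summary$model, "mve_omega0")
  expect_true(is.finite(sw$summary$clinical_mean_auc))
  expect_true(is.finite(sw$summary$sex_probe_auc))
  # probes share the evaluation fold structure (same seed-derived folds)
  expect_identical(sort(unique(sw$results$fold)), 1:2)
})
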