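# Downstream evaluation: subject-based splitting, subject-disjoint k-fold
# CV, L2 logistic probes, F1-optimised thresholds, AUC/accuracy/F1.

#' Partition subjects into pretrain-train / pretrain-val / test sets
#'
#' Subjects are shuffled by the seeded RNG and cut by largest-remainder
#' rounding of the proportions, so every subject lands in exactly one set
#' and counts are as close to `n * proportions` as integers allow.
#'
#' @param subject_ids Unique subject identifiers.
#' @param proportions Length-3 nonnegative vector summing to 1 for
#'   (pretrain_train, pretrain_val, test); default `c(0.425, 0.075, 0.5)`.
#' @param seed Integer seed.
#' @return A list with character vectors `pretrain_train`, `pretrain_val`,
#'   `test` and the `proportions`/`seed` used.
#' @export
split_subjects <- function(subject_ids, proportions = c(0.425, 0.075, 0.5),
                           seed = 1L) {
  if (length(subject_ids) == 0L) mve_stop("no subjects to split")
  if (anyDuplicated(subject_ids))
    mve_stop("duplicate subject ids passed to split_subjects")
  check_prob_vector(proportions, "proportions")
  if (length(proportions) != 3L) mve_stop("proportions must have length 3")
  n <- length(subject_ids)
  quota <- n * proportions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(quota - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  shuffled <- with_seed(seed, sample(subject_ids))
  cuts <- cumsum(counts)
  list(pretrain_train = shuffled[seq_len(counts[1])],
       pretrain_val = if (counts[2] > 0)
         shuffled[(cuts[1] + 1):cuts[2]] else character(0),
       test = if (counts[3] > 0)
         shuffled[(cuts[2] + 1):cuts[3]] else character(0),
       proportions = proportions, seed = seed)
}

#' Subject-disjoint k-fold assignment
#'
#' @param subject_ids Unique subject identifiers (at least `k` of them).
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @return Named integer vector mapping subject id to fold in `1..k`; fold
#'   sizes differ by at most one.
#' @export
make_cv_folds <- function(subject_ids, k = 4L, seed = 1L) {
  if (anyDuplicated(subject_ids)) mve_stop("duplicate subject ids")
  n <- length(subject_ids)
  if (n < k) mve_stop("need at least k = ", k, " subjects, got ", n)
  shuffled <- with_seed(seed, sample(subject_ids))
  folds <- rep(seq_len(k), length.out = n)
  stats::setNames(folds, shuffled)[subject_ids]
}

#' Fit an L2-regularised logistic probe on frozen embeddings
#'
#' Features are standardised with training-set statistics (constant columns
#' are left centred only), then a ridge logistic regression is fitted.  The
#' regularisation follows the inverse-strength convention: the ridge penalty
#' passed to the solver is `1 / (l2_strength * n)`, so larger `l2_strength`
#' means weaker shrinkage.
#'
#' @param x n x p numeric matrix of embeddings.
#' @param y Binary 0/1 labels (both classes must be present).
#' @param l2_strength Inverse regularisation strength C (default 1).
#' @return An `mve_probe` with a [predict][predict.mve_probe] method
#'   returning probabilities, or `NULL` (with a warning) when `y` is
#'   single-class.
#' @export
fit_linear_probe <- function(x, y, l2_strength = 1) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as.numeric(y)
  tab <- table(y[!is.na(y)])
  if (length(tab) < 2L) {
    warning("single-class training labels; probe skipped", call. = FALSE)
    return(NULL)
  }
  if (min(tab) < 2L) {
    warning("a training class has fewer than 2 observations; probe skipped",
            call. = FALSE)
    return(NULL)
  }
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- sqrt(pmax(0, (colSums(x * x) - n * ctr^2) / (n - 1)))
  if (all(scl < 1e-12)) {
    # constant features carry no information: intercept-only probe
    return(structure(list(fit = NULL, const = mean(y)), class = "mve_probe"))
  }
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  lambda <- 1 / (l2_strength * n)
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl, lambda = lambda),
            class = "mve_probe")
}

#' @rdname fit_linear_probe
#' @param object An `mve_probe`.
#' @param newx Matrix of embeddings to score.
#' @param ... Ignored.
#' @export
predict.mve_probe <- function(object, newx, ...) {
  if (!is.matrix(newx)) newx <- as.matrix(newx)
  if (is.null(object$fit)) return(rep(object$const, nrow(newx)))
  xs <- sweep(sweep(newx, 2L, object$center), 2L, object$scale, "/")
  as.numeric(stats::predict(object$fit, xs, type = "response"))
}

probe_coefficients <- function(probe) {
  as.numeric(stats::coef(probe$fit))[-1L]
}

#' Choose the decision threshold maximising F1 on training scores
#'
#' Candidate thresholds are the midpoints between adjacent sorted unique
#' scores, plus one candidate below the minimum (predict-all-positive).
#' Ties in F1 break toward the lowest threshold.  Predictions use
#' `score >= threshold`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (at least one positive).
#' @return The selected threshold (`NA` with a warning when no positives).
#' @export
pick_f1_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) == 0L) mve_stop("empty score set")
  if (sum(labels == 1) == 0) {
    warning("no positive labels; F1 threshold undefined", call. = FALSE)
    return(NA_real_)
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
  f1 <- vapply(cand, function(th) {
    pred <- as.numeric(scores >= th)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  cand[which.max(f1)]  # which.max takes the first (lowest) maximiser
}

#' Rank-based AUC with half credit for ties, plus thresholded metrics
#'
#' AUC uses the Mann-Whitney formulation
#' `(sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)` on midranks, which
#' gives tied score pairs half credit.  Accuracy and F1 are computed at the
#' supplied threshold (`score >= threshold` predicts positive).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (may be `NA`: accuracy/F1 become
#'   `NA`).
#' @return Named vector `c(auc, accuracy, f1, n_pos, n_neg)`; `auc` is `NA`
#'   when a class is absent.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (is.na(threshold)) {
    acc <- NA_real_; f1 <- NA_real_
  } else {
    pred <- as.numeric(scores >= threshold)
    acc <- mean(pred == labels)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  c(auc = auc, accuracy = acc, f1 = f1, n_pos = n1, n_neg = n0)
}

#' Cross-validated probe evaluation over all clinical tasks
#'
#' For each repeat, fold and task: fits [fit_linear_probe()] on the studies
#' of the other folds with observed labels, picks the F1-optimal threshold
#' on the training scores, and reports AUC/accuracy/F1 on the held-out
#' fold.  Repeats re-randomise the fold assignment (unless `folds` is
#' supplied, in which case all repeats share it and are identical by
#' construction).  Folds are subject-disjoint throughout.
#'
#' @param embeddings Embedding table (data.frame `study_id` + feature
#'   columns) covering every study in the manifest.
#' @param manifest Cohort manifest (see [generate_cohort()]).
#' @param tasks Character vector of task column names; defaults to all
#'   label columns of the manifest.
#' @param folds Optional fixed named fold vector from [make_cv_folds()].
#' @param k Number of folds when `folds` is `NULL`.
#' @param repeats Number of independent repeats (default 5).
#' @param l2 Probe inverse regularisation strength.
#' @param seed Base seed; repeat r derives its own substream.
#' @param keep_predictions Also return the per-study held-out scores
#'   (needed for subgroup analysis).
#' @return A results data.frame (task, fold, repeat, auc, accuracy, f1,
#'   threshold, n_pos, n_neg); with `keep_predictions`, a list
#'   `(results, predictions)`.
#' @export
evaluate_tasks <- function(embeddings, manifest, tasks = NULL, folds = NULL,
                           k = 4L, repeats = 5L, l2 = 1, seed = 1L,
                           keep_predictions = FALSE) {
  tasks <- tasks %||% setdiff(colnames(manifest),
                              c("study_id", "subject_id", "sex", "race",
                                "view_count"))
  missing_emb <- setdiff(manifest$study_id, embeddings$study_id)
  if (length(missing_emb))
    mve_stop("no embedding for study ", missing_emb[1],
             if (length(missing_emb) > 1)
               paste0(" (and ", length(missing_emb) - 1, " more)") else "")
  E <- embedding_matrix(embeddings)
  E <- E[manifest$study_id, , drop = FALSE]
  subjects <- unique(manifest$subject_id)

  res <- list(); preds <- list()
  for (r in seq_len(repeats)) {
    fr <- folds %||% make_cv_folds(subjects, k = k,
                                   seed = derive_seed(seed, paste0("folds/rep", r)))
    study_fold <- unname(fr[manifest$subject_id])
    for (task in tasks) {
      y <- manifest[[task]]
      for (f in sort(unique(study_fold))) {
        tr <- study_fold != f & !is.na(y)
        te <- study_fold == f & !is.na(y)
        if (sum(te) == 0L) next
        if (length(unique(y[tr])) < 2L) {
          warning("task ", task, ", fold ", f, ", repeat ", r,
                  ": single-class training labels; skipped", call. = FALSE)
          next
        }
        probe <- fit_linear_probe(E[tr, , drop = FALSE], y[tr], l2_strength = l2)
        if (is.null(probe)) next
        tr_scores <- predict(probe, E[tr, , drop = FALSE])
        th <- suppressWarnings(pick_f1_threshold(tr_scores, y[tr]))
        sc <- predict(probe, E[te, , drop = FALSE])
        m <- compute_metrics(sc, y[te], th)
        res[[length(res) + 1L]] <- data.frame(
          task = task, fold = f, rep = r,
          auc = unname(m["auc"]), accuracy = unname(m["accuracy"]),
          f1 = unname(m["f1"]), threshold = th,
          n_pos = unname(m["n_pos"]), n_neg = unname(m["n_neg"]))
        if (keep_predictions)
          preds[[length(preds) + 1L]] <- data.frame(
            task = task, fold = f, rep = r,
            study_id = manifest$study_id[te], score = sc, label = y[te])
      }
    }
  }
  results <- do.call(rbind, res)
  if (keep_predictions)
    list(results = results, predictions = do.call(rbind, preds))
  else results
}

#' Mean AUC over tasks from a results table
#'
#' Undefined (NA) fold AUCs are dropped rather than imputed; per-task AUC is
#' the mean over defined folds and repeats, and the summary is the mean over
#' tasks.
#'
#' @param results A results data.frame from [evaluate_tasks()].
#' @return Scalar mean AUC.
#' @export
mean_task_auc <- function(results) {
  per_task <- tapply(results$auc, results$task, mean, na.rm = TRUE)
  mean(per_task, na.rm = TRUE)
}
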