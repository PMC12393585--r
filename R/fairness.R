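# Fairness audit: demographic probes, subgroup decomposition, adversarial
# sweeps, and the comparison statistics.

#' Probe demographic predictability of an embedding table
#'
#' Trains the same L2 logistic probe family as the clinical tasks to predict
#' sex or race from frozen embeddings, cross-validated with subject-disjoint
#' folds.  Sex is female-vs-male AUC among studies with known sex; race is
#' the macro one-vs-rest AUC over the known classes (white, black, other).
#' Unknowns are excluded from probing (they remain real classes only for the
#' adversarial training heads).
#'
#' @param embeddings Embedding table.
#' @param manifest Cohort manifest.
#' @param attribute `"sex"` or `"race"`.
#' @param folds Named fold vector from [make_cv_folds()] (subject -> fold);
#'   built from `seed`/`k` when `NULL`.
#' @param k,seed Fold construction when `folds` is `NULL`.
#' @param l2 Probe inverse regularisation strength.
#' @return A data.frame with one row (attribute, auc, n) plus a `per_class`
#'   attribute for race.
#' @export
probe_demographics <- function(embeddings, manifest, attribute = c("sex", "race"),
                               folds = NULL, k = 4L, seed = 1L, l2 = 1) {
  attribute <- match.arg(attribute)
  known <- manifest[[attribute]] != "unknown"
  man <- manifest[known, , drop = FALSE]
  missing_emb <- setdiff(man$study_id, embeddings$study_id)
  if (length(missing_emb))
    mve_stop("no embedding for study ", missing_emb[1],
             if (length(missing_emb) > 1)
               paste0(" (and ", length(missing_emb) - 1, " more)") else "")
  E <- embedding_matrix(embeddings)
  E <- E[man$study_id, , drop = FALSE]
  folds <- folds %||% make_cv_folds(unique(manifest$subject_id), k = k, seed = seed)
  study_fold <- unname(folds[man$subject_id])
  classes <- if (attribute == "sex") "female" else c("white", "black", "other")

  class_auc <- function(pos_class) {
    y <- as.numeric(man[[attribute]] == pos_class)
    if (length(unique(y)) < 2L) return(NA_real_)
    aucs <- c()
    for (f in sort(unique(study_fold))) {
      tr <- study_fold != f; te <- study_fold == f
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
        warning("class ", pos_class, ", fold ", f,
                ": a class is absent; fold dropped", call. = FALSE)
        next
      }
      probe <- fit_linear_probe(E[tr, , drop = FALSE], y[tr], l2_strength = l2)
      if (is.null(probe)) next
      sc <- predict(probe, E[te, , drop = FALSE])
      aucs <- c(aucs, unname(compute_metrics(sc, y[te])["auc"]))
    }
    if (length(aucs)) mean(aucs) else NA_real_
  }

  per_class <- vapply(classes, class_auc, 0)
  out <- data.frame(attribute = attribute,
                    auc = mean(per_class, na.rm = TRUE),
                    n = nrow(man))
  attr(out, "per_class") <- per_class
  out
}

#' Bin studies by video count
#'
#' The conventional completeness strata: `<20`, `20-39`, `40-59`, `>=60`
#' videos per study.  The four bins partition all view counts.
#'
#' @param view_count Integer vector.
#' @return Factor with levels `<20`, `20-39`, `40-59`, `>=60`.
#' @export
video_count_bin <- function(view_count) {
  cut(view_count, breaks = c(-Inf, 19.5, 39.5, 59.5, Inf),
      labels = c("<20", "20-39", "40-59", ">=60"))
}

#' Within-stratum AUC from pooled held-out predictions
#'
#' Rescorss the predictions produced by `evaluate_tasks(...,
#' keep_predictions = TRUE)` inside demographic or video-count strata, with
#' no refitting: the probe is fixed, only the evaluation population changes.
#' Strata with a single label class for a task are reported as `NA` for that
#' task.
#'
#' @param predictions Predictions data.frame (task, fold, rep, study_id,
#'   score, label).
#' @param manifest Cohort manifest.
#' @param stratify `"sex"` (female/male), `"race"` (white/black/other) or
#'   `"view_count"` (the four bins).  Unknown demographics are excluded.
#' @return Data.frame (stratum, task, auc, n) plus a per-stratum mean AUC
#'   summary in attribute `summary`.
#' @export
subgroup_auc <- function(predictions, manifest,
                         stratify = c("sex", "race", "view_count")) {
  stratify <- match.arg(stratify)
  strat <- switch(stratify,
                  sex = ifelse(manifest$sex %in% c("female", "male"),
                               manifest$sex, NA),
                  race = ifelse(manifest$race %in% c("white", "black", "other"),
                                manifest$race, NA),
                  view_count = as.character(video_count_bin(manifest$view_count)))
  names(strat) <- manifest$study_id
  predictions$stratum <- strat[predictions$study_id]
  predictions <- predictions[!is.na(predictions$stratum), , drop = FALSE]
  rows <- list()
  for (s in unique(predictions$stratum)) {
    for (task in unique(predictions$task)) {
      sub <- predictions[predictions$stratum == s & predictions$task == task, ]
      if (nrow(sub) == 0L) next
      # pool folds within repeat, average AUC over repeats
      aucs <- vapply(unique(sub$rep), function(r) {
        sr <- sub[sub$rep == r, ]
        unname(compute_metrics(sr$score, sr$label)["auc"])
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, task = task, auc = mean(aucs, na.rm = TRUE),
        n = length(unique(sub$study_id)))
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(auc ~ stratum, out, mean, na.rm = TRUE)
  attr(out, "summary") <- summ
  out
}

#' Sweep the adversarial weight
#'
#' Splits subjects (42.5/7.5/50), trains one encoder per omega on the
#' pretrain split, extracts test-set embeddings, evaluates all clinical
#' tasks by subject-disjoint k-fold CV and probes sex/race predictability.
#' One checkpoint per omega is reused across evaluation repeats.
#'
#' @param cohort An `mve_cohort`.
#' @param omegas Adversarial weight grid (default `c(0, 0.1, 0.2, 0.5, 1)`).
#' @param enc_config,pre_config Encoder / pretraining configs (omega in
#'   `pre_config` is overridden per grid point).
#' @param k,repeats,l2 Downstream evaluation settings.
#' @param seed Global seed (split, folds, probes).
#' @param include_baseline Also evaluate the view-grouped averaging
#'   baseline on the same folds.
#' @param verbose Progress messages.
#' @return A list of class `mve_sweep`: `summary` data.frame (one row per
#'   model: clinical mean AUC +- SE over repeats, sex/race probe AUC),
#'   `results` (all metric rows), `checkpoints`, `split`.
#' @export
sweep_adversarial <- function(cohort, omegas = c(0, 0.1, 0.2, 0.5, 1),
                              enc_config, pre_config, k = 4L, repeats = 1L,
                              l2 = 1, seed = 1L, include_baseline = TRUE,
                              verbose = FALSE) {
  stopifnot(inherits(cohort, "mve_cohort"))
  split <- split_subjects(unique(cohort$manifest$subject_id),
                          seed = derive_seed(seed, "split"))
  tr <- cohort_subset(cohort, subject_ids = split$pretrain_train)
  va <- cohort_subset(cohort, subject_ids = split$pretrain_val)
  te <- cohort_subset(cohort, subject_ids = split$test)

  eval_one <- function(emb, label) {
    ev <- evaluate_tasks(emb, te$manifest, k = k, repeats = repeats,
                         l2 = l2, seed = derive_seed(seed, "eval"),
                         keep_predictions = TRUE)
    probe_folds <- make_cv_folds(unique(te$manifest$subject_id), k = k,
                                 seed = derive_seed(seed, "eval/folds/rep1"))
    sexp <- probe_demographics(emb, te$manifest, "sex", folds = probe_folds, l2 = l2)
    racep <- probe_demographics(emb, te$manifest, "race", folds = probe_folds, l2 = l2)
    per_rep <- tapply(ev$results$auc, ev$results$rep, mean, na.rm = TRUE)
    data.frame(model = label,
               clinical_mean_auc = mean(per_rep),
               clinical_se = if (length(per_rep) > 1)
                 stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_,
               sex_probe_auc = sexp$auc, race_probe_auc = racep$auc) ->
      summ
    list(summary = summ, results = cbind(model = label, ev$results),
         predictions = cbind(model = label, ev$predictions))
  }

  summaries <- list(); results <- list(); predictions <- list()
  checkpoints <- list()
  if (include_baseline) {
    if (verbose) message("evaluating foundation-style baseline")
    b <- eval_one(baseline_embed(te), "foundation")
    summaries[["foundation"]] <- cbind(omega = NA_real_, b$summary)
    results[["foundation"]] <- b$results
    predictions[["foundation"]] <- b$predictions
  }
  for (w in omegas) {
    lab <- paste0("mve_omega", w)
    if (verbose) message("training MVE at omega = ", w)
    pc <- pre_config
    pc$adversarial_weight <- w
    ck <- tryCatch(train_mve(tr, va, enc_config, pc),
                   error = function(e) e)
    if (inherits(ck, "error")) {
      warning("training failed at omega = ", w, ": ", conditionMessage(ck),
              call. = FALSE)
      summaries[[lab]] <- data.frame(omega = w, model = lab,
                                     clinical_mean_auc = NA_real_,
                                     clinical_se = NA_real_,
                                     sex_probe_auc = NA_real_,
                                     race_probe_auc = NA_real_)
      next
    }
    checkpoints[[lab]] <- ck
    emb <- extract_embeddings(ck, te)
    r <- eval_one(emb, lab)
    summaries[[lab]] <- cbind(omega = w, r$summary)
    results[[lab]] <- r$results
    predictions[[lab]] <- r$predictions
  }
  structure(list(summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
                 results = do.call(rbind, results),
                 predictions = do.call(rbind, predictions),
                 checkpoints = checkpoints, split = split, seed = seed),
            class = "mve_sweep")
}

#' @export
print.mve_sweep <- function(x, ...) {
  cat("Adversarial sweep:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mixed-effects comparison of two models' task-level AUCs
#'
#' Fits `auc ~ model + (1 | task)` with a random intercept per task and
#' reports the fixed model effect (second model minus first), its standard
#' error and p-value.  With fewer than three tasks, or when the mixed fit
#' fails, falls back to a paired comparison of per-task mean AUCs (with a
#' warning in the former case).
#'
#' @param results Data.frame with columns `task`, `model` (exactly two
#'   levels), `auc`, optionally `rep`/`fold`.
#' @param reference Model level to treat as baseline; default the first.
#' @return Named list `estimate`, `se`, `p`, `method`.
#' @export
compare_models_mixed <- function(results, reference = NULL) {
  mods <- unique(results$model)
  if (length(mods) != 2L) mve_stop("exactly two models required")
  reference <- reference %||% mods[1]
  results$model <- stats::relevel(factor(results$model), ref = reference)
  paired_fallback <- function() {
    pt <- tapply(results$auc, list(results$task, results$model), mean, na.rm = TRUE)
    d <- pt[, 2] - pt[, 1]
    d <- d[is.finite(d)]
    est <- mean(d)
    if (length(d) < 2L || stats::sd(d) == 0) {
      return(list(estimate = est, se = 0,
                  p = if (abs(est) < 1e-12) 1 else 0, method = "paired"))
    }
    se <- stats::sd(d) / sqrt(length(d))
    tv <- est / se
    list(estimate = est, se = se,
         p = 2 * stats::pt(-abs(tv), df = length(d) - 1), method = "paired")
  }
  if (length(unique(results$task)) < 3L) {
    warning("fewer than 3 tasks; using a paired comparison", call. = FALSE)
    return(paired_fallback())
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(auc ~ model + (1 | task), data = results))),
    error = function(e) NULL)
  if (is.null(fit)) return(paired_fallback())
  co <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  if (is.null(co) || nrow(co) < 2L || !all(is.finite(co[2L, c(1L, 2L)])))
    return(paired_fallback())
  p <- co[2L, ncol(co)]
  if (!is.finite(p)) p <- 1
  list(estimate = unname(co[2L, 1L]), se = unname(co[2L, 2L]),
       p = unname(p), method = "mixed")
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    mve_stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Relative improvement in percent of the baseline mean AUC
#'
#' @param delta_auc_points AUC-point improvement.
#' @param baseline_auc_points Baseline mean AUC in points (> 0).
#' @return `100 * delta / baseline`.
#' @export
relative_improvement <- function(delta_auc_points, baseline_auc_points) {
  if (any(baseline_auc_points <= 0)) mve_stop("baseline must be positive")
  100 * delta_auc_points / baseline_auc_points
}
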