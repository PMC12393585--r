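# End-to-end experiment driver: simulate -> split -> pretrain (per omega)
# -> extract -> baseline -> evaluate -> audit, with stage checkpointing.

#' Configure an end-to-end experiment
#'
#' @param cohort_config An [cohort_config()].
#' @param enc_config An [encoder_config()].
#' @param pre_config A [pretrain_config()].
#' @param omegas Adversarial weight grid.
#' @param k,repeats,l2 Downstream evaluation settings.
#' @param out_dir Output directory.
#' @param seed Global seed; all stages derive substreams from it.
#' @return A list of class `mve_experiment_config`.
#' @export
experiment_config <- function(cohort_config, enc_config, pre_config,
                              omegas = c(0, 0.1, 0.2, 0.5, 1), k = 4L,
                              repeats = 1L, l2 = 1, out_dir = "mve_run",
                              seed = 1L) {
  structure(list(cohort_config = cohort_config, enc_config = enc_config,
                 pre_config = pre_config, omegas = omegas, k = as.integer(k),
                 repeats = as.integer(repeats), l2 = l2, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "mve_experiment_config")
}

#' Run the full pipeline
#'
#' Generates (or reloads) the synthetic cohort, splits subjects, trains one
#' encoder per adversarial weight, evaluates clinical tasks and demographic
#' probes for every model including the view-grouped baseline, and writes
#' all artifacts under `out_dir`: cohort files, per-omega checkpoints and
#' embedding tables, `results.csv`, `sweep_summary.csv`, subgroup reports
#' and a machine-readable `run_record.json`.  Completed stages (detected by
#' their output files) are not recomputed on resume.
#'
#' @param xc An [experiment_config()].
#' @param verbose Progress messages.
#' @return The output directory, invisibly.
#' @export
run_experiment <- function(xc, verbose = TRUE) {
  stopifnot(inherits(xc, "mve_experiment_config"))
  dir.create(xc$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  cohort_dir <- file.path(xc$out_dir, "cohort")
  if (file.exists(file.path(cohort_dir, "manifest.csv"))) {
    say("* cohort: reusing ", cohort_dir)
    cohort <- read_cohort(cohort_dir)
  } else {
    say("* cohort: generating ", xc$cohort_config$n_subjects, " subjects")
    cohort <- generate_cohort(xc$cohort_config)
    write_cohort(cohort, cohort_dir)
  }

  split <- split_subjects(unique(cohort$manifest$subject_id),
                          seed = derive_seed(xc$seed, "split"))
  tr <- cohort_subset(cohort, subject_ids = split$pretrain_train)
  va <- cohort_subset(cohort, subject_ids = split$pretrain_val)
  te <- cohort_subset(cohort, subject_ids = split$test)

  models <- list()
  b_path <- file.path(xc$out_dir, "embeddings_foundation.csv")
  if (!file.exists(b_path)) {
    say("* baseline: aggregating ", nrow(te$manifest), " test studies")
    write_embedding_table(baseline_embed(te), b_path, seed = xc$seed,
                          config = xc$cohort_config)
  }
  models[["foundation"]] <- read_embedding_table(b_path)

  for (w in xc$omegas) {
    lab <- paste0("mve_omega", w)
    ck_path <- file.path(xc$out_dir, paste0("checkpoint_", lab, ".rds"))
    em_path <- file.path(xc$out_dir, paste0("embeddings_", lab, ".csv"))
    if (!file.exists(ck_path)) {
      say("* pretrain: omega = ", w)
      pc <- xc$pre_config
      pc$adversarial_weight <- w
      write_checkpoint(train_mve(tr, va, xc$enc_config, pc), ck_path)
    }
    if (!file.exists(em_path)) {
      say("* extract: omega = ", w)
      write_embedding_table(extract_embeddings(read_checkpoint(ck_path), te),
                            em_path, seed = xc$seed, config = xc$enc_config)
    }
    models[[lab]] <- read_embedding_table(em_path)
  }

  res_path <- file.path(xc$out_dir, "results.csv")
  pred_path <- file.path(xc$out_dir, "predictions.csv")
  if (!file.exists(res_path)) {
    all_res <- list(); all_pred <- list()
    for (lab in names(models)) {
      say("* evaluate: ", lab)
      ev <- evaluate_tasks(models[[lab]], te$manifest, k = xc$k,
                           repeats = xc$repeats, l2 = xc$l2,
                           seed = derive_seed(xc$seed, "eval"),
                           keep_predictions = TRUE)
      all_res[[lab]] <- cbind(model = lab, ev$results)
      all_pred[[lab]] <- cbind(model = lab, ev$predictions)
    }
    utils::write.csv(do.call(rbind, all_res), res_path, row.names = FALSE)
    utils::write.csv(do.call(rbind, all_pred), pred_path, row.names = FALSE)
    write_sidecar(res_path, seed = xc$seed, config = xc)
  }
  results <- utils::read.csv(res_path, stringsAsFactors = FALSE)
  predictions <- utils::read.csv(pred_path, stringsAsFactors = FALSE,
                                 colClasses = c(study_id = "character"))

  audit_path <- file.path(xc$out_dir, "sweep_summary.csv")
  if (!file.exists(audit_path)) {
    say("* audit: probes and subgroups")
    probe_folds <- make_cv_folds(unique(te$manifest$subject_id), k = xc$k,
                                 seed = derive_seed(xc$seed, "eval/folds/rep1"))
    summ <- lapply(names(models), function(lab) {
      r <- results[results$model == lab, ]
      per_rep <- tapply(r$auc, r$rep, mean, na.rm = TRUE)
      data.frame(model = lab,
                 clinical_mean_auc = mean(per_rep),
                 clinical_se = if (length(per_rep) > 1)
                   stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_,
                 sex_probe_auc = probe_demographics(models[[lab]], te$manifest,
                                                    "sex", folds = probe_folds,
                                                    l2 = xc$l2)$auc,
                 race_probe_auc = probe_demographics(models[[lab]], te$manifest,
                                                     "race", folds = probe_folds,
                                                     l2 = xc$l2)$auc)
    })
    utils::write.csv(do.call(rbind, summ), audit_path, row.names = FALSE)
    for (strat in c("sex", "race", "view_count")) {
      sg <- lapply(names(models), function(lab)
        cbind(model = lab,
              subgroup_auc(predictions[predictions$model == lab, ], te$manifest,
                           strat)))
      utils::write.csv(do.call(rbind, sg),
                       file.path(xc$out_dir, paste0("subgroup_", strat, ".csv")),
                       row.names = FALSE)
    }
  }

  record <- list(seed = xc$seed, config_hash = config_hash(xc),
                 r_version = as.character(getRversion()),
                 n_studies = nrow(cohort$manifest),
                 n_test_studies = nrow(te$manifest),
                 omegas = xc$omegas, k = xc$k, repeats = xc$repeats)
  jsonlite::write_json(record, file.path(xc$out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(xc$out_dir)
}
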