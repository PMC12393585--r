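# Plain-text persistence: manifest CSV, long-format views CSV, YAML config,
# embedding-table CSV with JSON sidecar, RDS checkpoints, results CSV.
# Every writer records the seed and a config hash in a sidecar so outputs
# are traceable to the run that made them.

sidecar_path <- function(path) paste0(path, ".meta.json")

write_sidecar <- function(path, seed = NULL, config = NULL, extra = list()) {
  meta <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 seed = seed,
                 config_hash = if (!is.null(config)) config_hash(config) else NULL),
            extra)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       sidecar_path(path), auto_unbox = TRUE, pretty = TRUE)
}

#' Write / read a cohort manifest CSV
#'
#' Columns: `study_id`, `subject_id`, `sex`, `race`, `view_count`, then one
#' 0/1/empty column per task.  Reading validates the label alphabet and
#' reports the offending column and row on violation.
#'
#' @param manifest Manifest data.frame.
#' @param path File path.
#' @param seed,config Optional provenance recorded in the sidecar.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path, seed = NULL, config = NULL) {
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  write_sidecar(path, seed = seed, config = config)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) mve_stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(study_id = "character",
                                        subject_id = "character"))
  need <- c("study_id", "subject_id", "sex", "race", "view_count")
  miss <- setdiff(need, colnames(man))
  if (length(miss)) mve_stop("manifest missing column(s): ",
                             paste(miss, collapse = ", "))
  for (col in setdiff(colnames(man), need)) {
    v <- man[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad))
      mve_stop("manifest column '", col, "', row ", bad[1],
               ": label '", v[bad[1]], "' is not 0, 1 or missing")
    man[[col]] <- as.integer(v)
  }
  man
}

#' Write / read per-study view embeddings (long CSV)
#'
#' One row per view: `study_id`, `view_index`, `view_type`, `v1..vd`.
#'
#' @param cohort An `mve_cohort` (or a list with `views`/`view_types`).
#' @param path File path.
#' @param seed,config Optional provenance for the sidecar.
#' @return `read_views` returns `list(views =, view_types =)` of named
#'   per-study matrices / integer vectors.
#' @export
write_views <- function(cohort, path, seed = NULL, config = NULL) {
  rows <- lapply(names(cohort$views), function(sid) {
    V <- cohort$views[[sid]]
    data.frame(study_id = sid, view_index = seq_len(nrow(V)),
               view_type = cohort$view_types[[sid]], V)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c("study_id", "view_index", "view_type",
                     paste0("v", seq_len(ncol(cohort$views[[1]]))))
  utils::write.csv(out, path, row.names = FALSE)
  write_sidecar(path, seed = seed, config = config)
  invisible(path)
}

#' @rdname write_views
#' @export
read_views <- function(path) {
  if (!file.exists(path)) mve_stop("views file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(study_id = "character"))
  need <- c("study_id", "view_index", "view_type")
  if (!all(need %in% colnames(df)))
    mve_stop("views file missing column(s): ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
  vcols <- grep("^v[0-9]+$", colnames(df), value = TRUE)
  if (!length(vcols)) mve_stop("views file has no v1..vd value columns")
  if (any(!is.finite(as.matrix(df[vcols]))))
    mve_stop("non-finite view values in ", path)
  views <- list(); vtypes <- list()
  for (sid in unique(df$study_id)) {
    sub <- df[df$study_id == sid, , drop = FALSE]
    sub <- sub[order(sub$view_index), , drop = FALSE]
    views[[sid]] <- unname(as.matrix(sub[vcols]))
    vtypes[[sid]] <- as.integer(sub$view_type)
  }
  list(views = views, view_types = vtypes)
}

#' Write / read an embedding table CSV
#'
#' @param tab Embedding table (`study_id` + feature columns).
#' @param path File path.
#' @param seed,config Optional provenance for the sidecar.
#' @export
write_embedding_table <- function(tab, path, seed = NULL, config = NULL) {
  utils::write.csv(tab, path, row.names = FALSE)
  write_sidecar(path, seed = seed, config = config,
                extra = list(width = ncol(tab) - 1L))
  invisible(path)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) mve_stop("embedding table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(study_id = "character"))
  if (colnames(df)[1] != "study_id") mve_stop("first column must be study_id")
  df
}

#' Write / read a cohort config as YAML
#'
#' Task specs are serialised field-by-field; reading reconstructs a
#' validated [cohort_config()].
#'
#' @param config An `mve_cohort_config`.
#' @param path File path.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$tasks <- lapply(unname(x$tasks), unclass)
  x$label_missingness <- as.list(x$label_missingness)
  x$sex_marginals <- as.list(x$sex_marginals)
  x$race_marginals <- as.list(x$race_marginals)
  x$studies_per_subject <- as.list(x$studies_per_subject)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) mve_stop("config not found: ", path)
  x <- yaml::read_yaml(path)
  tasks <- lapply(x$tasks, function(t)
    task_spec(t$name, t$target_prevalence, unlist(t$latent_weights),
              t$shortcut_coef_sex %||% 0, t$shortcut_coef_race %||% 0,
              t$intercept %||% NA_real_))
  names(tasks) <- vapply(tasks, `[[`, "", "name")
  cohort_config(
    n_subjects = x$n_subjects,
    studies_per_subject = unlist(x$studies_per_subject),
    view_count_meanlog = x$view_count_meanlog,
    view_count_sdlog = x$view_count_sdlog,
    min_views = x$min_views, max_views_data = x$max_views_data,
    embed_dim = x$embed_dim, n_latent = x$n_latent,
    n_view_types = x$n_view_types,
    sex_marginals = unlist(x$sex_marginals),
    race_marginals = unlist(x$race_marginals),
    demo_signal_strength = x$demo_signal_strength,
    noise_sd = x$noise_sd, tasks = tasks,
    label_missingness = unlist(x$label_missingness),
    calibration_n = x$calibration_n, seed = x$seed)
}

#' Save / load a training checkpoint
#'
#' The checkpoint bundles encoder and head parameters, both configs, the
#' task list, the seed and the full training history.
#'
#' @param checkpoint An `mve_checkpoint`.
#' @param path File path (`.rds`).
#' @export
write_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "mve_checkpoint"))
  saveRDS(checkpoint, path)
  write_sidecar(path, seed = checkpoint$seed,
                config = checkpoint$encoder_config,
                extra = list(best_epoch = checkpoint$best_epoch))
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) mve_stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!inherits(ck, "mve_checkpoint")) mve_stop("not an MVE checkpoint: ", path)
  ck
}

#' Write / read a cohort (manifest + views + config) to a directory
#'
#' @param cohort An `mve_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"),
                 seed = cohort$config$seed, config = cohort$config)
  write_views(cohort, file.path(dir, "views.csv"),
              seed = cohort$config$seed, config = cohort$config)
  write_cohort_config(cohort$config, file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  config <- read_cohort_config(file.path(dir, "cohort_config.yaml"))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  vw <- read_views(file.path(dir, "views.csv"))
  missing_views <- setdiff(man$study_id, names(vw$views))
  if (length(missing_views))
    mve_stop("views file lacks study ", missing_views[1])
  structure(list(manifest = man, views = vw$views[man$study_id],
                 view_types = vw$view_types[man$study_id],
                 generator = make_generator(config), config = config),
            class = "mve_cohort")
}
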