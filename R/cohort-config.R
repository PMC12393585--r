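# Synthetic cohort configuration: task specs and the cohort-level config.

#' Specify one binary clinical task for the synthetic cohort
#'
#' A task is a logistic link on the subject-level latent pathophysiology
#' vector plus optional demographic shortcut terms:
#' \deqn{logit P(y = 1) = b + w'z + c_{sex} x_{sex} + c_{race} x_{race}}
#' where `z` is the K-vector of latent factors, `x_sex` codes
#' female/male/unknown as +1/-1/0 and `x_race` codes white/black/other-or-
#' unknown as +1/-1/0.  The intercept `b` is usually left `NA` and calibrated
#' by [calibrate_intercept()] so that the empirical prevalence matches
#' `target_prevalence`.
#'
#' @param name Task name (unique within a task list).
#' @param target_prevalence Fraction in (0, 1).
#' @param latent_weights Numeric K-vector `w`.
#' @param shortcut_coef_sex,shortcut_coef_race Scalar shortcut coefficients
#'   (default 0: labels depend on pathophysiology only).
#' @param intercept Scalar, or `NA` to calibrate at generation time.
#' @return An object of class `mve_task`.
#' @export
task_spec <- function(name, target_prevalence, latent_weights,
                      shortcut_coef_sex = 0, shortcut_coef_race = 0,
                      intercept = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    mve_stop("task name must be a nonempty string")
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1L ||
      target_prevalence <= 0 || target_prevalence >= 1)
    mve_stop("target_prevalence must lie in (0, 1) for task '", name, "'")
  if (!is.numeric(latent_weights) || any(!is.finite(latent_weights)))
    mve_stop("latent_weights must be finite numerics for task '", name, "'")
  structure(list(name = name,
                 target_prevalence = target_prevalence,
                 latent_weights = as.numeric(latent_weights),
                 shortcut_coef_sex = shortcut_coef_sex,
                 shortcut_coef_race = shortcut_coef_race,
                 intercept = intercept),
            class = "mve_task")
}

#' The default 21-task panel
#'
#' Recreates the prevalence and label-missingness profile of a large
#' multi-view echocardiography cohort: 21 binary tasks spanning structural
#' measurements (aortic root, LV dimensions and mass, atrial volume),
#' function (reduced LVEF, impaired RV function), valve disease at two
#' severity cuts, hemodynamics (TR gradient, E/e', IVC), and clinical
#' diagnoses (cardiomyopathies, myocardial infarction, pulmonary embolism).
#' Prevalences range from 1.8% to 50.1% and missingness from ~2% to ~72%,
#' so the harness exercises both balanced and very rare outcomes.
#'
#' Latent weight vectors are drawn once from a fixed internal seed (so the
#' default panel is stable across sessions) and scaled to a common norm;
#' every task loads on latent factors spread across the factor window
#' structure of [embed_views()], which is what makes label recovery require
#' integrating several view types.
#'
#' @param n_latent Number of latent pathophysiology factors K.
#' @param weight_scale Euclidean norm given to each task's latent weights;
#'   controls the attainable AUC ceiling.
#' @return A list of [task_spec()] objects with a `missingness` attribute
#'   (named per-task missingness probabilities).
#' @export
default_tasks <- function(n_latent = 8L, weight_scale = 2) {
  tab <- data.frame(
    name = c("aortic_root_bsa_high", "lvdd_enlarged", "lavi_high",
             "lvmi_high", "lvef_lt_50", "rv_dysfunction",
             "mild_ar", "mild_as", "mild_mr", "mild_tr",
             "moderate_ar", "moderate_as", "moderate_mr", "moderate_tr",
             "trpg_gt_31", "ee_ratio_gt_15", "dilated_ivc",
             "dilated_cardiomyopathy", "hypertrophic_cardiomyopathy",
             "myocardial_infarction", "pulmonary_embolism"),
    prevalence = c(0.066, 0.100, 0.412, 0.495, 0.155, 0.158,
                   0.213, 0.104, 0.477, 0.501, 0.022, 0.059,
                   0.122, 0.139, 0.335, 0.177, 0.198, 0.067,
                   0.018, 0.073, 0.034),
    missingness = c(0.103, 0.072, 0.287, 0.082, 0.252, 0.063,
                    0.024, 0.024, 0.023, 0.023, 0.024, 0.024,
                    0.023, 0.023, 0.189, 0.567, 0.684, 0.058,
                    0.058, 0.693, 0.724),
    stringsAsFactors = FALSE)
  tasks <- with_seed(600043L, lapply(seq_len(nrow(tab)), function(i) {
    w <- stats::rnorm(n_latent)
    w <- w / sqrt(sum(w^2)) * weight_scale
    task_spec(tab$name[i], tab$prevalence[i], w)
  }))
  names(tasks) <- tab$name
  attr(tasks, "missingness") <- stats::setNames(tab$missingness, tab$name)
  tasks
}

#' Configure a synthetic multi-view echo cohort
#'
#' Defines every knob of the generator.  Defaults emulate the empirical
#' structure of a 7k-study hospital echo cohort: a discretised log-normal
#' view-count law matching median 41 and IQR 34-48 (truncated to
#' `[min_views, max_views_data]`), sex marginals of 51.5%/48.5%
#' female/male among knowns with 5.8% unknown, race marginals of
#' 71.6%/18.5%/9.9% white/black/other among knowns with 6.9% unknown, and
#' the 21-task panel of [default_tasks()].
#'
#' @param n_subjects Number of subjects (0 allowed: empty cohort).
#' @param studies_per_subject Named probability vector over study counts per
#'   subject (names are the counts).
#' @param view_count_meanlog,view_count_sdlog Parameters of the log-normal
#'   view-count law before discretisation/truncation.  The defaults solve
#'   the three printed quantiles (median 41, Q1 34, Q3 48).
#' @param min_views,max_views_data Truncation bounds on views per study.
#' @param embed_dim View-embedding dimension d (default 512; tests shrink it).
#' @param n_latent Number of latent pathophysiology factors K.
#' @param n_view_types Number of echocardiographic view types (default 15).
#' @param sex_marginals,race_marginals Probability vectors (must sum to 1)
#'   over `female/male/unknown` and `white/black/other/unknown`.
#' @param demo_signal_strength Magnitude s of the additive demographic
#'   direction mixed into every view embedding (0 disables the shortcut).
#' @param noise_sd Per-coordinate i.i.d. noise sd of view embeddings.
#' @param tasks List of [task_spec()]; default [default_tasks()].
#' @param label_missingness Named per-task missingness probabilities;
#'   defaults to the `missingness` attribute of `tasks` (0 if absent).
#' @param calibration_n Monte-Carlo size used when calibrating task
#'   intercepts at generation time.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   config including this seed.
#' @return An object of class `mve_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1500L,
                          studies_per_subject = c("1" = 0.80, "2" = 0.15, "3" = 0.05),
                          view_count_meanlog = log(41),
                          view_count_sdlog = log(48 / 34) / (2 * stats::qnorm(0.75)),
                          min_views = 4L,
                          max_views_data = 118L,
                          embed_dim = 512L,
                          n_latent = 8L,
                          n_view_types = 15L,
                          sex_marginals = NULL,
                          race_marginals = NULL,
                          demo_signal_strength = 0.5,
                          noise_sd = 1.0,
                          tasks = default_tasks(n_latent),
                          label_missingness = NULL,
                          calibration_n = 20000L,
                          seed = 1L) {
  if (is.null(sex_marginals))
    sex_marginals <- c(female = 0.515 * (1 - 0.058),
                       male   = 0.485 * (1 - 0.058),
                       unknown = 0.058)
  if (is.null(race_marginals))
    race_marginals <- c(white = 0.716 * (1 - 0.069),
                        black = 0.185 * (1 - 0.069),
                        other = 0.099 * (1 - 0.069),
                        unknown = 0.069)
  check_prob_vector(sex_marginals, "sex_marginals")
  check_prob_vector(race_marginals, "race_marginals")
  check_prob_vector(studies_per_subject, "studies_per_subject")
  if (!identical(sort(names(sex_marginals)), sort(c("female", "male", "unknown"))))
    mve_stop("sex_marginals must be named female/male/unknown")
  if (!identical(sort(names(race_marginals)), sort(c("white", "black", "other", "unknown"))))
    mve_stop("race_marginals must be named white/black/other/unknown")
  if (n_subjects < 0) mve_stop("n_subjects must be >= 0")
  if (embed_dim < 1) mve_stop("embed_dim must be >= 1")
  if (min_views < 1 || max_views_data < min_views)
    mve_stop("need 1 <= min_views <= max_views_data")
  if (demo_signal_strength < 0 || noise_sd < 0)
    mve_stop("demo_signal_strength and noise_sd must be nonnegative")
  for (t in tasks) if (!inherits(t, "mve_task")) mve_stop("tasks must be task_spec objects")
  for (t in tasks) if (length(t$latent_weights) != n_latent)
    mve_stop("task '", t$name, "' has ", length(t$latent_weights),
             " latent weights; config has n_latent = ", n_latent)
  nm <- vapply(tasks, `[[`, "", "name")
  if (anyDuplicated(nm)) mve_stop("duplicated task names")
  if (is.null(label_missingness)) {
    label_missingness <- attr(tasks, "missingness") %||%
      stats::setNames(rep(0, length(tasks)), nm)
  }
  label_missingness <- label_missingness[nm]
  if (any(is.na(label_missingness)) || any(label_missingness < 0 | label_missingness >= 1))
    mve_stop("label_missingness must give every task a probability in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 studies_per_subject = studies_per_subject,
                 view_count_meanlog = view_count_meanlog,
                 view_count_sdlog = view_count_sdlog,
                 min_views = as.integer(min_views),
                 max_views_data = as.integer(max_views_data),
                 embed_dim = as.integer(embed_dim),
                 n_latent = as.integer(n_latent),
                 n_view_types = as.integer(n_view_types),
                 sex_marginals = sex_marginals,
                 race_marginals = race_marginals,
                 demo_signal_strength = demo_signal_strength,
                 noise_sd = noise_sd,
                 tasks = tasks,
                 label_missingness = stats::setNames(as.numeric(label_missingness), nm),
                 calibration_n = as.integer(calibration_n),
                 seed = as.integer(seed)),
            class = "mve_cohort_config")
}

#' @export
print.mve_cohort_config <- function(x, ...) {
  cat("Synthetic echo cohort config:",
      x$n_subjects, "subjects,", length(x$tasks), "tasks, d =", x$embed_dim,
      ", K =", x$n_latent, ",", x$n_view_types, "view types, s =",
      x$demo_signal_strength, ", sigma =", x$noise_sd, "\n")
  invisible(x)
}
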