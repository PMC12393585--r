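# Synthetic cohort generation: latent factors, view-type loadings,
# demographic shortcut directions, calibrated task labels.

# Fixed per-seed generator parameters: one d x K loading matrix per view
# type, plus unit demographic directions.  Each view type "sees" a cyclic
# window of K/2 latent factors, so no single view type carries the full
# pathophysiology state and study-level recovery requires integrating
# several types.  Demographic directions are orthogonalised against the
# span of all loading columns whenever the ambient dimension allows, making
# the shortcut a pure additive direction carrying no clinical information.
make_generator <- function(config) {
  d <- config$embed_dim; K <- config$n_latent; Tn <- config$n_view_types
  win <- max(1L, K %/% 2L)
  with_seed(derive_seed(config$seed, "generator"), {
    loadings <- vector("list", Tn)
    exposure <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      idx <- ((t - 1L + seq_len(win) - 1L) %% K) + 1L
      A <- matrix(0, d, K)
      A[, idx] <- matrix(stats::rnorm(d * win, sd = 1 / sqrt(win)), d, win)
      loadings[[t]] <- A
      exposure[[t]] <- idx
    }
    span <- do.call(cbind, loadings)
    g <- matrix(stats::rnorm(d * 3L), d, 3L)
    qs <- qr(span)
    r <- qs$rank
    if (d - r >= 3L) {
      Qb <- qr.Q(qs, complete = TRUE)[, seq_len(r), drop = FALSE]
      g <- g - Qb %*% (t(Qb) %*% g)
    }
    Q <- qr.Q(qr(g))
    # at d < 3 there is no room for three orthogonal directions; recycle
    Q <- Q[, rep_len(seq_len(ncol(Q)), 3L), drop = FALSE]
    list(loadings = loadings, exposure = exposure,
         dir_sex = Q[, 1L], dir_race1 = Q[, 2L], dir_race2 = Q[, 3L])
  })
}

sex_code <- function(sex) c(female = 1, male = -1, unknown = 0)[sex]
race_code <- function(race) c(white = 1, black = -1, other = 0, unknown = 0)[race]

# Demographic offset added to every view row of a study (length-d vector).
demo_offset <- function(gen, s, sex, race) {
  v <- s * sex_code(sex) * gen$dir_sex
  v <- v + s * switch(race,
                      white = gen$dir_race1,
                      black = -gen$dir_race1,
                      other = gen$dir_race2,
                      unknown = 0 * gen$dir_race2)
  v
}

#' Synthesise the view-embedding matrix of one study
#'
#' Each view row is a view-type-specific linear projection of the subject's
#' latent pathophysiology vector, plus an additive demographic direction and
#' isotropic Gaussian noise:
#' \deqn{v = A_{type} z + s (g_{sex} + g_{race}) + \epsilon,\qquad
#'       \epsilon \sim N(0, \sigma^2 I_d).}
#' The loading matrices `A_t` and unit directions `g` are fixed functions of
#' the config seed (see the package vignette); noise is drawn from the
#' calling RNG state.
#'
#' @param z Latent K-vector.
#' @param view_types Integer vector (length m) of view-type indices in
#'   `1..n_view_types`.
#' @param sex,race Demographic categories (`female/male/unknown`,
#'   `white/black/other/unknown`).
#' @param config An [cohort_config()].
#' @param generator Optional precomputed generator parameters (internal
#'   reuse); rebuilt from the config when `NULL`.
#' @return An m x d numeric matrix.
#' @export
embed_views <- function(z, view_types, sex, race, config, generator = NULL) {
  gen <- generator %||% make_generator(config)
  m <- length(view_types)
  if (m < 1L) mve_stop("a study needs at least one view")
  if (any(view_types < 1L | view_types > config$n_view_types))
    mve_stop("unknown view type (outside 1..", config$n_view_types, ")")
  d <- config$embed_dim
  off <- demo_offset(gen, config$demo_signal_strength, sex, race)
  types <- unique(view_types)
  mu <- matrix(0, config$n_view_types, d)
  for (t in types) mu[t, ] <- as.numeric(gen$loadings[[t]] %*% z) + off
  V <- mu[view_types, , drop = FALSE]
  if (config$noise_sd > 0)
    V <- V + matrix(stats::rnorm(m * d, sd = config$noise_sd), m, d)
  V
}

#' Calibrate a task intercept to hit a target prevalence
#'
#' Bisection on the Monte-Carlo mean of the logistic link
#' `mean(plogis(b + eta))` over draws of the latent/demographic linear
#' predictor `eta`, until the Monte-Carlo prevalence is within `tol` of
#' `task$target_prevalence`.  When the link is fully degenerate (all weights
#' and shortcut coefficients zero) the exact `qlogis(target)` is returned.
#'
#' @param task A [task_spec()].
#' @param latent_dist Function `n -> n x K matrix` of latent draws, or a
#'   function returning `list(z =, sex_code =, race_code =)` when shortcut
#'   coefficients are nonzero.
#' @param n_mc Monte-Carlo sample size (>= 1000).
#' @param seed Seed for the Monte-Carlo draw.
#' @param tol Prevalence tolerance (default 1e-3).
#' @return The calibrated scalar intercept.
#' @export
calibrate_intercept <- function(task, latent_dist, n_mc = 20000L, seed = 1L,
                                tol = 1e-3) {
  if (n_mc < 1000L) mve_stop("n_mc must be >= 1000")
  target <- task$target_prevalence
  draws <- with_seed(seed, latent_dist(n_mc))
  if (is.list(draws)) {
    eta <- as.numeric(draws$z %*% task$latent_weights) +
      task$shortcut_coef_sex * draws$sex_code +
      task$shortcut_coef_race * draws$race_code
  } else {
    eta <- as.numeric(draws %*% task$latent_weights)
  }
  if (all(eta == 0)) return(stats::qlogis(target))
  f <- function(b) mean(stats::plogis(b + eta)) - target
  lo <- -10; hi <- 10; tries <- 0L
  while (f(lo) > 0 || f(hi) < 0) {
    lo <- lo * 2; hi <- hi * 2; tries <- tries + 1L
    if (tries > 6L) mve_stop("intercept calibration failed to bracket the target")
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  mve_stop("intercept calibration did not converge")
}

draw_category <- function(n, marginals) {
  if (n == 0L) return(character(0))
  names(marginals)[sample.int(length(marginals), n, replace = TRUE, prob = marginals)]
}

# Discretised truncated log-normal view counts.
draw_view_counts <- function(n, config) {
  if (n == 0L) return(integer(0))
  out <- integer(n); filled <- 0L
  while (filled < n) {
    cand <- as.integer(round(stats::rlnorm(2L * (n - filled),
                                           config$view_count_meanlog,
                                           config$view_count_sdlog)))
    cand <- cand[cand >= config$min_views & cand <= config$max_views_data]
    take <- min(length(cand), n - filled)
    if (take > 0L) {
      out[(filled + 1L):(filled + take)] <- cand[seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

#' Generate a synthetic multi-view echocardiography cohort
#'
#' Subjects receive demographics, one latent pathophysiology K-vector and a
#' number of studies; every study of a subject shares that subject's sex,
#' race and latents (this within-subject correlation is what makes
#' subject-based splitting meaningful).  Task labels are Bernoulli draws
#' from the calibrated logistic link of each [task_spec()], independently
#' masked to missing per task.  View embeddings come from [embed_views()].
#'
#' The result is a deterministic function of the config (including its
#' seed): rerunning yields a bit-identical manifest and element-wise equal
#' embedding matrices.
#'
#' @param config An [cohort_config()].
#' @return An object of class `mve_cohort`: a list with
#'   `manifest` (data.frame: study_id, subject_id, sex, race, view_count,
#'   one 0/1/NA column per task), `views` (named list of m x d matrices),
#'   `view_types` (named list of integer vectors), `generator`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mve_cohort_config"))
  gen <- make_generator(config)
  n_sub <- config$n_subjects
  tasks <- config$tasks
  K <- config$n_latent

  # calibrate any NA intercepts once, against the marginal latent/demography law
  sexes_mc <- NULL
  demo_sampler <- function(n) {
    list(z = matrix(stats::rnorm(n * K), n, K),
         sex_code = sex_code(draw_category(n, config$sex_marginals)),
         race_code = race_code(draw_category(n, config$race_marginals)))
  }
  for (i in seq_along(tasks)) {
    if (is.na(tasks[[i]]$intercept)) {
      tasks[[i]]$intercept <- calibrate_intercept(
        tasks[[i]], demo_sampler, n_mc = config$calibration_n,
        seed = derive_seed(config$seed, paste0("calibrate/", tasks[[i]]$name)))
    }
  }

  subj <- with_seed(derive_seed(config$seed, "subjects"), {
    sex <- draw_category(n_sub, config$sex_marginals)
    race <- draw_category(n_sub, config$race_marginals)
    ns <- as.integer(names(config$studies_per_subject))[
      sample.int(length(config$studies_per_subject), n_sub, replace = TRUE,
                 prob = config$studies_per_subject)]
    z <- matrix(stats::rnorm(n_sub * K), n_sub, K)
    list(sex = sex, race = race, n_studies = ns, z = z)
  })

  n_studies <- if (n_sub == 0L) 0L else sum(subj$n_studies)
  task_names <- names(tasks)
  manifest <- data.frame(
    study_id = character(n_studies), subject_id = character(n_studies),
    sex = character(n_studies), race = character(n_studies),
    view_count = integer(n_studies), stringsAsFactors = FALSE)
  for (nm in task_names) manifest[[nm]] <- rep(NA_integer_, n_studies)
  views <- vector("list", n_studies)
  vtypes <- vector("list", n_studies)

  if (n_studies > 0L) {
    with_seed(derive_seed(config$seed, "studies"), {
      mcounts <- draw_view_counts(n_studies, config)
      row <- 0L
      for (s in seq_len(n_sub)) {
        for (k in seq_len(subj$n_studies[s])) {
          row <- row + 1L
          sid <- sprintf("S%05d", s)
          manifest$study_id[row] <- sprintf("S%05d-E%02d", s, k)
          manifest$subject_id[row] <- sid
          manifest$sex[row] <- subj$sex[s]
          manifest$race[row] <- subj$race[s]
          m <- mcounts[row]
          manifest$view_count[row] <- m
          vt <- sample.int(config$n_view_types, m, replace = TRUE)
          vtypes[[row]] <- vt
          views[[row]] <- embed_views(subj$z[s, ], vt, subj$sex[s],
                                      subj$race[s], config, gen)
          sc <- sex_code(subj$sex[s]); rc <- race_code(subj$race[s])
          for (nm in task_names) {
            tk <- tasks[[nm]]
            p <- stats::plogis(tk$intercept +
                                 sum(tk$latent_weights * subj$z[s, ]) +
                                 tk$shortcut_coef_sex * sc +
                                 tk$shortcut_coef_race * rc)
            y <- stats::rbinom(1L, 1L, p)
            if (stats::runif(1L) < config$label_missingness[nm]) y <- NA_integer_
            manifest[[nm]][row] <- y
          }
        }
      }
    })
    names(views) <- manifest$study_id
    names(vtypes) <- manifest$study_id
  }

  config$tasks <- tasks  # keep calibrated intercepts with the cohort
  structure(list(manifest = manifest, views = views, view_types = vtypes,
                 generator = gen, config = config),
            class = "mve_cohort")
}

#' @export
print.mve_cohort <- function(x, ...) {
  cat("Synthetic echo cohort:", nrow(x$manifest), "studies,",
      length(unique(x$manifest$subject_id)), "subjects, d =",
      x$config$embed_dim, "\n")
  invisible(x)
}

#' Subset a cohort by subject or study identifiers
#'
#' @param cohort An `mve_cohort`.
#' @param subject_ids,study_ids Exactly one of the two.
#' @return A new `mve_cohort` restricted to the matching studies.
#' @export
cohort_subset <- function(cohort, subject_ids = NULL, study_ids = NULL) {
  stopifnot(inherits(cohort, "mve_cohort"))
  if (is.null(subject_ids) == is.null(study_ids))
    mve_stop("give exactly one of subject_ids or study_ids")
  keep <- if (!is.null(subject_ids)) {
    cohort$manifest$subject_id %in% subject_ids
  } else cohort$manifest$study_id %in% study_ids
  out <- cohort
  out$manifest <- cohort$manifest[keep, , drop = FALSE]
  rownames(out$manifest) <- NULL
  out$views <- cohort$views[cohort$manifest$study_id[keep]]
  out$view_types <- cohort$view_types[cohort$manifest$study_id[keep]]
  out
}

task_names <- function(cohort) names(cohort$config$tasks)
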