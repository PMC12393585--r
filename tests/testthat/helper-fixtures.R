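# Shared small fixtures, built in code.  Everything is seeded so tests are
# deterministic; sizes are kept small enough that the whole suite stays
# fast.

tiny_encoder_config <- function(d = 8L, ...) {
  encoder_config(embed_dim = d, n_layers = 2L, n_heads = 2L, max_views = 16L,
                 ff_dim = 2L * d, dropout = 0, ...)
}

tiny_cohort <- function(n_subjects = 40L, d = 16L, seed = 11L, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, embed_dim = d,
                                n_view_types = 5L, min_views = 3L,
                                view_count_meanlog = log(8),
                                view_count_sdlog = 0.3,
                                max_views_data = 16L,
                                calibration_n = 2000L, seed = seed, ...))
}

# a small task list for fast cohorts
small_tasks <- function(n = 3L, K = 8L, prev = NULL) {
  prev <- prev %||% rep(0.3, n)
  tasks <- lapply(seq_len(n), function(i) {
    w <- sin(seq_len(K) + i)  # fixed, spread over all latents
    task_spec(paste0("task", i), prev[i], w / sqrt(sum(w^2)) * 2)
  })
  names(tasks) <- vapply(tasks, `[[`, "", "name")
  tasks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force all-pairs AUC oracle (half credit for ties)
auc_all_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# independent textbook Holm step-down
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}
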