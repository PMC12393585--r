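# Foundation-style baseline: per-view-group weighted averaging into a fixed
# slot matrix, mirroring the conventional pipeline that groups videos by
# classified view and averages within groups.

#' Configure the view-grouped averaging baseline
#'
#' @param n_groups Number of view-group slots (default 15).
#' @param embed_dim View-embedding dimension d.
#' @param weighting `"uniform"` (default) or `"confidence"` (per-view
#'   scalar weights supplied at aggregation time).
#' @return An object of class `mve_baseline_config`.
#' @export
baseline_config <- function(n_groups = 15L, embed_dim = 512L,
                            weighting = c("uniform", "confidence")) {
  weighting <- match.arg(weighting)
  if (n_groups < 1L) mve_stop("n_groups must be >= 1")
  structure(list(n_groups = as.integer(n_groups),
                 embed_dim = as.integer(embed_dim),
                 weighting = weighting),
            class = "mve_baseline_config")
}

#' Aggregate one study's views into the fixed slot representation
#'
#' Slot `g` holds the (weighted) mean of the view embeddings whose type maps
#' to `g`; slots with no views are zero vectors.  The default configuration
#' reproduces the conventional fixed 15 x 512 representation.
#'
#' @param views m x d matrix of view embeddings.
#' @param view_types Length-m vector of view-type labels.
#' @param config A [baseline_config()].
#' @param group_map Named integer vector mapping each view type to a slot in
#'   `1..n_groups`; by default view type `t` maps to slot `t`.
#' @param weights Optional per-view positive weights (required when
#'   `weighting = "confidence"`).
#' @param flatten Return the slot matrix flattened row-wise to a single
#'   vector of length `n_groups * d` (the probe input); `FALSE` returns the
#'   `n_groups x d` matrix.
#' @return Numeric vector (or matrix when `flatten = FALSE`).
#' @export
aggregate_foundation_style <- function(views, view_types, config,
                                       group_map = NULL, weights = NULL,
                                       flatten = TRUE) {
  if (!is.matrix(views)) views <- matrix(views, nrow = 1L)
  m <- nrow(views)
  if (length(view_types) != m) mve_stop("view_types must match the view rows")
  vt <- as.character(view_types)
  if (is.null(group_map)) {
    slots <- suppressWarnings(as.integer(vt))
    if (any(is.na(slots))) mve_stop("default group_map needs integer view types")
  } else {
    slots <- unname(group_map[vt])
    if (any(is.na(slots)))
      mve_stop("unmapped view type: ",
               paste(unique(vt[is.na(slots)]), collapse = ", "))
  }
  if (any(slots < 1L | slots > config$n_groups))
    mve_stop("view type maps outside 1..", config$n_groups)
  if (config$weighting == "confidence") {
    if (is.null(weights)) mve_stop("confidence weighting needs per-view weights")
    if (length(weights) != m || any(weights <= 0))
      mve_stop("weights must be positive and match the view rows")
  } else weights <- rep(1, m)
  out <- matrix(0, config$n_groups, ncol(views))
  for (gslot in unique(slots)) {
    idx <- which(slots == gslot)
    w <- weights[idx] / sum(weights[idx])
    out[gslot, ] <- colSums(views[idx, , drop = FALSE] * w)
  }
  if (flatten) as.numeric(t(out)) else out
}

#' Baseline embedding table for a whole cohort
#'
#' @param cohort An `mve_cohort`.
#' @param config A [baseline_config()]; defaults to 15 slots at the
#'   cohort's embedding dimension.
#' @param group_map Optional view-type-to-slot map passed to
#'   [aggregate_foundation_style()].
#' @return An embedding table (data.frame `study_id`, `e1..e(n_groups*d)`)
#'   with attribute `representation_width`.
#' @export
baseline_embed <- function(cohort, config = NULL, group_map = NULL) {
  stopifnot(inherits(cohort, "mve_cohort"))
  if (is.null(config))
    config <- baseline_config(n_groups = cohort$config$n_view_types,
                              embed_dim = cohort$config$embed_dim)
  ids <- cohort$manifest$study_id
  E <- t(vapply(ids, function(sid)
    aggregate_foundation_style(cohort$views[[sid]], cohort$view_types[[sid]],
                               config, group_map = group_map),
    numeric(config$n_groups * cohort$config$embed_dim)))
  tab <- embedding_table(ids, E)
  attr(tab, "representation_width") <- config$n_groups * cohort$config$embed_dim
  tab
}
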