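# Multi-view encoder: a permutation-invariant pre-norm transformer over a
# variable-size set of view embeddings.  A learnable aggregation token is
# prepended and its final-layer state is the study-level embedding; padded
# rows are excluded from attention via a key mask.  No positional encodings:
# views form an unordered set.

#' Configure the multi-view encoder
#'
#' @param embed_dim Embedding dimension d (default 512); must be divisible
#'   by `n_heads`.
#' @param n_layers Number of transformer layers (default 2).
#' @param n_heads Attention heads per layer (default 8).
#' @param max_views Maximum views per study M (default 128).
#' @param ff_dim Feed-forward hidden width (default `2 * embed_dim`).
#' @param dropout Dropout probability applied to attention and feed-forward
#'   outputs during training (default 0.1; inference never drops).
#' @param pooling `"aggregation_token"` (default) reads the study embedding
#'   off the aggregation token; `"masked_mean"` averages the view-token
#'   outputs over valid positions (ablation).
#' @param overflow_policy What to do with studies exceeding `max_views`:
#'   `"truncate"` (default, keeps the first M views with a warning) or
#'   `"error"`.
#' @return An object of class `mve_encoder_config`.
#' @export
encoder_config <- function(embed_dim = 512L, n_layers = 2L, n_heads = 8L,
                           max_views = 128L, ff_dim = 2L * embed_dim,
                           dropout = 0.1,
                           pooling = c("aggregation_token", "masked_mean"),
                           overflow_policy = c("truncate", "error")) {
  pooling <- match.arg(pooling)
  overflow_policy <- match.arg(overflow_policy)
  if (embed_dim < 1L || n_layers < 1L || n_heads < 1L || ff_dim < 1L)
    mve_stop("embed_dim, n_layers, n_heads and ff_dim must be positive")
  if (embed_dim %% n_heads != 0L)
    mve_stop("embed_dim (", embed_dim, ") must be divisible by n_heads (", n_heads, ")")
  if (max_views < 1L) mve_stop("max_views must be >= 1")
  if (dropout < 0 || dropout >= 1) mve_stop("dropout must lie in [0, 1)")
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 max_views = as.integer(max_views),
                 ff_dim = as.integer(ff_dim),
                 dropout = dropout,
                 pooling = pooling,
                 overflow_policy = overflow_policy),
            class = "mve_encoder_config")
}

#' Build the boolean validity mask for a padded view set
#'
#' @param m True number of views (>= 1).
#' @param M Capacity (mask length).
#' @param overflow_policy `"truncate"` or `"error"` for `m > M`.
#' @return Logical vector of length `M` with `min(m, M)` leading `TRUE`s.
#' @export
build_padding_mask <- function(m, M, overflow_policy = c("truncate", "error")) {
  overflow_policy <- match.arg(overflow_policy)
  if (m < 1L) mve_stop("empty study: m must be >= 1")
  if (M < 1L) mve_stop("capacity M must be >= 1")
  if (m > M) {
    if (overflow_policy == "error")
      mve_stop("study has ", m, " views, exceeding the capacity of ", M)
    warning("study has ", m, " views; truncating to the first ", M, call. = FALSE)
    m <- M
  }
  rep(c(TRUE, FALSE), c(m, M - m))
}

#' Bundle a padded view matrix with its validity mask
#'
#' @param values m x d (or padded M x d) numeric matrix.
#' @param m True view count; defaults to `nrow(values)`.
#' @param M Capacity; defaults to `max(nrow(values), m)`.
#' @param overflow_policy Passed to [build_padding_mask()].
#' @return An object of class `mve_view_set` with fields `values` (M x d,
#'   zero-padded), `validity`, `m`.
#' @export
view_set <- function(values, m = nrow(values), M = max(nrow(values), m),
                     overflow_policy = c("truncate", "error")) {
  overflow_policy <- match.arg(overflow_policy)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  validity <- build_padding_mask(m, M, overflow_policy)
  out <- matrix(0, M, ncol(values))
  keep <- min(m, M)
  out[seq_len(keep), ] <- values[seq_len(keep), , drop = FALSE]
  structure(list(values = out, validity = validity, m = as.integer(min(m, M))),
            class = "mve_view_set")
}

# ---- parameters -----------------------------------------------------------

#' Initialise encoder and head parameters
#'
#' Truncated-normal (sd 0.02) weights, unit layer-norm gains, zero biases;
#' deterministic given the seed.
#'
#' @param config An [encoder_config()].
#' @param n_tasks Number of clinical auxiliary logits.
#' @param seed Integer seed.
#' @param sex_classes,race_classes Output widths of the adversarial heads
#'   (3 = female/male/unknown, 4 = white/black/other/unknown).
#' @return A nested parameter list (class `mve_params`).
#' @export
mve_init_params <- function(config, n_tasks = 0L, seed = 1L,
                            sex_classes = 3L, race_classes = 4L) {
  d <- config$embed_dim; f <- config$ff_dim; h <- max(2L, d %/% 2L)
  with_seed(seed, {
    mkm <- function(r, c) matrix(rtrunc_norm(r * c), r, c)
    layer <- function() list(
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      Wq = mkm(d, d), bq = rep(0, d), Wk = mkm(d, d), bk = rep(0, d),
      Wv = mkm(d, d), bv = rep(0, d), Wo = mkm(d, d), bo = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d),
      W1 = mkm(d, f), b1 = rep(0, f), W2 = mkm(f, d), b2 = rep(0, d))
    p <- list(
      agg = rtrunc_norm(d), mask = rtrunc_norm(d),
      layers = lapply(seq_len(config$n_layers), function(i) layer()),
      lnf_g = rep(1, d), lnf_b = rep(0, d),
      recon = list(W = mkm(d, d), b = rep(0, d)),
      clin = if (n_tasks > 0L) list(W = mkm(d, n_tasks), b = rep(0, n_tasks)) else NULL,
      sex = list(W1 = mkm(d, h), b1 = rep(0, h),
                 W2 = mkm(h, sex_classes), b2 = rep(0, sex_classes)),
      race = list(W1 = mkm(d, h), b1 = rep(0, h),
                  W2 = mkm(h, race_classes), b2 = rep(0, race_classes)))
    class(p) <- "mve_params"
    p
  })
}

# Apply f to every numeric leaf of a parameter tree (preserves structure).
param_map <- function(p, f) {
  if (is.numeric(p)) return(f(p))
  if (is.list(p)) {
    out <- lapply(p, function(x) if (is.null(x)) NULL else param_map(x, f))
    attributes(out) <- attributes(p)
    return(out)
  }
  p
}

# Combine two parameter trees leaf-wise.
param_zip <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  if (is.list(a)) {
    out <- mapply(function(x, y) if (is.null(x)) NULL else param_zip(x, y, f),
                  a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    return(out)
  }
  a
}

zero_like <- function(p) param_map(p, function(x) x * 0)

# ---- forward pass ---------------------------------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv = inv, g = g)
}

layernorm_bwd <- function(cache, dy) {
  n <- nrow(dy)
  dxhat <- dy * rep(cache$g, each = n)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

# Full forward through the encoder trunk.  X: m x d matrix of view inputs;
# masked: indices (into 1..m) whose rows are replaced by the mask token;
# key_mask: validity of the m view rows (padded rows FALSE).  Returns the
# final-layer-norm output Z ((m+1) x d; row 1 is the aggregation token) plus
# the cache needed for backprop.
mve_forward <- function(X, params, config, masked = integer(0),
                        train = FALSE, key_mask = NULL) {
  m <- nrow(X); d <- config$embed_dim
  if (ncol(X) != d) mve_stop("views have ", ncol(X), " columns; config expects ", d)
  if (is.null(key_mask)) key_mask <- rep(TRUE, m)
  Tk <- rbind(params$agg, X)
  if (length(masked)) Tk[masked + 1L, ] <- rep(params$mask, each = length(masked))
  kmask <- c(TRUE, key_mask)
  n <- m + 1L
  H <- config$n_heads; dh <- d %/% H
  drop_p <- if (train) config$dropout else 0
  caches <- vector("list", config$n_layers)

  for (l in seq_len(config$n_layers)) {
    pl <- params$layers[[l]]
    ln1 <- layernorm_fwd(Tk, pl$ln1_g, pl$ln1_b)
    A1 <- ln1$y
    Q <- add_bias(A1 %*% pl$Wq, pl$bq)
    Km <- add_bias(A1 %*% pl$Wk, pl$bk)
    V <- add_bias(A1 %*% pl$Wv, pl$bv)
    AV <- matrix(0, n, d)
    Ps <- vector("list", H)
    for (h in seq_len(H)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      L <- tcrossprod(Q[, ix, drop = FALSE], Km[, ix, drop = FALSE]) / sqrt(dh)
      P <- softmax_rows(L, keep = kmask)
      Ps[[h]] <- P
      AV[, ix] <- P %*% V[, ix, drop = FALSE]
    }
    O <- add_bias(AV %*% pl$Wo, pl$bo)
    maskO <- if (drop_p > 0)
      matrix(stats::rbinom(n * d, 1L, 1 - drop_p) / (1 - drop_p), n, d) else NULL
    T1 <- Tk + if (is.null(maskO)) O else O * maskO
    ln2 <- layernorm_fwd(T1, pl$ln2_g, pl$ln2_b)
    A2 <- ln2$y
    Hpre <- add_bias(A2 %*% pl$W1, pl$b1)
    Phi <- stats::pnorm(Hpre)
    Hact <- Hpre * Phi
    Fpre <- add_bias(Hact %*% pl$W2, pl$b2)
    maskF <- if (drop_p > 0)
      matrix(stats::rbinom(n * d, 1L, 1 - drop_p) / (1 - drop_p), n, d) else NULL
    T2 <- T1 + if (is.null(maskF)) Fpre else Fpre * maskF
    caches[[l]] <- list(T0 = Tk, ln1 = ln1, A1 = A1, Q = Q, K = Km, V = V,
                        Ps = Ps, AV = AV, maskO = maskO, T1 = T1, ln2 = ln2,
                        A2 = A2, Hpre = Hpre, Phi = Phi, Hact = Hact,
                        maskF = maskF)
    Tk <- T2
  }
  lnf <- layernorm_fwd(Tk, params$lnf_g, params$lnf_b)
  list(Z = lnf$y, lnf = lnf, layers = caches, masked = masked,
       key_mask = key_mask, m = m)
}

# Backward through the trunk.  dZ: gradient w.r.t. the final LN output.
# Returns gradients for all encoder parameters plus dX (gradient w.r.t. the
# unmasked input rows; masked rows accumulate into the mask token).
mve_backward <- function(fw, params, config, dZ) {
  g <- list(layers = vector("list", config$n_layers))
  H <- config$n_heads; d <- config$embed_dim; dh <- d %/% H
  lb <- layernorm_bwd(fw$lnf, dZ)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dT <- lb$dx
  for (l in rev(seq_len(config$n_layers))) {
    cc <- fw$layers[[l]]
    pl <- params$layers[[l]]
    # feed-forward branch
    dFdrop <- dT
    dFpre <- if (is.null(cc$maskF)) dFdrop else dFdrop * cc$maskF
    dW2 <- crossprod(cc$Hact, dFpre)
    db2 <- colSums(dFpre)
    dHact <- tcrossprod(dFpre, pl$W2)
    dHpre <- dHact * (cc$Phi + cc$Hpre * stats::dnorm(cc$Hpre))
    dW1 <- crossprod(cc$A2, dHpre)
    db1 <- colSums(dHpre)
    dA2 <- tcrossprod(dHpre, pl$W1)
    lb2 <- layernorm_bwd(cc$ln2, dA2)
    dT1 <- dT + lb2$dx
    # attention branch
    dOdrop <- dT1
    dO <- if (is.null(cc$maskO)) dOdrop else dOdrop * cc$maskO
    dWo <- crossprod(cc$AV, dO)
    dbo <- colSums(dO)
    dAV <- tcrossprod(dO, pl$Wo)
    dQ <- matrix(0, nrow(dT), d); dK <- dQ; dV <- dQ
    for (h in seq_len(H)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      P <- cc$Ps[[h]]
      dAVh <- dAV[, ix, drop = FALSE]
      dP <- tcrossprod(dAVh, cc$V[, ix, drop = FALSE])
      dV[, ix] <- crossprod(P, dAVh)
      dL <- P * (dP - rowSums(dP * P))
      dQ[, ix] <- dL %*% cc$K[, ix, drop = FALSE] / sqrt(dh)
      dK[, ix] <- crossprod(dL, cc$Q[, ix, drop = FALSE]) / sqrt(dh)
    }
    dWq <- crossprod(cc$A1, dQ); dbq <- colSums(dQ)
    dWk <- crossprod(cc$A1, dK); dbk <- colSums(dK)
    dWv <- crossprod(cc$A1, dV); dbv <- colSums(dV)
    dA1 <- tcrossprod(dQ, pl$Wq) + tcrossprod(dK, pl$Wk) + tcrossprod(dV, pl$Wv)
    lb1 <- layernorm_bwd(cc$ln1, dA1)
    g$layers[[l]] <- list(ln1_g = lb1$dg, ln1_b = lb1$db,
                          Wq = dWq, bq = dbq, Wk = dWk, bk = dbk,
                          Wv = dWv, bv = dbv, Wo = dWo, bo = dbo,
                          ln2_g = lb2$dg, ln2_b = lb2$db,
                          W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dT <- dT1 + lb1$dx
  }
  d_agg <- dT[1L, ]
  dX <- dT[-1L, , drop = FALSE]
  d_mask <- rep(0, d)
  if (length(fw$masked)) {
    d_mask <- colSums(dX[fw$masked, , drop = FALSE])
    dX[fw$masked, ] <- 0
  }
  g$agg <- d_agg; g$mask <- d_mask
  list(grads = g, dX = dX)
}

pooled_embedding <- function(fw, config) {
  if (config$pooling == "aggregation_token") return(fw$Z[1L, ])
  rows <- which(fw$key_mask) + 1L
  colMeans(fw$Z[rows, , drop = FALSE])
}

# ---- public encoding API --------------------------------------------------

#' Encode one study's view set into a study-level embedding
#'
#' The output depends only on the set of valid view rows: it is invariant to
#' their order and to any amount of padding (padded rows are excluded from
#' attention by the key mask and from pooling).
#'
#' @param views An `mve_view_set`, or a plain m x d matrix of valid views.
#' @param config An [encoder_config()].
#' @param params Parameters from [mve_init_params()] or a trained
#'   checkpoint.
#' @return Numeric vector of length `config$embed_dim`.
#' @export
encode_study <- function(views, config, params) {
  if (inherits(views, "mve_view_set")) {
    X <- views$values
    key_mask <- views$validity
  } else {
    if (!is.matrix(views)) views <- matrix(views, nrow = 1L)
    m <- nrow(views)
    if (m > config$max_views) {
      if (config$overflow_policy == "error")
        mve_stop("study has ", m, " views, exceeding the capacity of ",
                 config$max_views)
      warning("study has ", m, " views; truncating to the first ",
              config$max_views, call. = FALSE)
      views <- views[seq_len(config$max_views), , drop = FALSE]
      m <- config$max_views
    }
    X <- views
    key_mask <- rep(TRUE, m)
  }
  if (any(!is.finite(X[key_mask, , drop = FALSE])))
    mve_stop("non-finite values in view embeddings")
  fw <- mve_forward(X, params, config, train = FALSE, key_mask = key_mask)
  pooled_embedding(fw, config)
}

#' Encode a list of studies into an embedding table
#'
#' @param view_list Nonempty named list of view matrices (or
#'   `mve_view_set`s); names become study ids.
#' @param config,params As in [encode_study()].
#' @return A data.frame with `study_id` and `e1..ed` columns (an embedding
#'   table); row i equals `encode_study(view_list[[i]], ...)`.
#' @export
encode_batch <- function(view_list, config, params) {
  if (length(view_list) == 0L) mve_stop("encode_batch needs a nonempty list")
  dims <- vapply(view_list, function(v)
    if (inherits(v, "mve_view_set")) ncol(v$values) else ncol(as.matrix(v)), 0L)
  if (length(unique(dims)) != 1L)
    mve_stop("inconsistent embedding dimension across studies: ",
             paste(unique(dims), collapse = ", "))
  E <- t(vapply(view_list, encode_study, numeric(config$embed_dim),
                config = config, params = params))
  ids <- names(view_list) %||% sprintf("study%04d", seq_along(view_list))
  embedding_table(ids, E)
}

embedding_table <- function(study_ids, E) {
  colnames(E) <- paste0("e", seq_len(ncol(E)))
  out <- data.frame(study_id = study_ids, E, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out
}

embedding_matrix <- function(tab) {
  M <- as.matrix(tab[, setdiff(colnames(tab), "study_id"), drop = FALSE])
  rownames(M) <- tab$study_id
  M
}
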