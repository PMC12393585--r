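# Self-supervised pretraining: masked-view reconstruction with auxiliary
# clinical heads and gradient-reversal adversarial demographic heads.

#' Configure pretraining
#'
#' @param mask_ratio Fraction of views hidden per study (default 0.5).
#' @param adversarial_weight Gradient-reversal weight omega (>= 0).  Omega
#'   scales only the reversed gradient reaching the encoder; the forward
#'   loss value is unchanged.
#' @param lambda_clin Weight of the auxiliary clinical BCE term (0 removes
#'   the clinical heads from the objective).
#' @param learning_rate AdamW learning rate (default 1e-4).
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Studies per optimizer step.
#' @param patience Early-stopping patience on total validation loss.
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param head_lr_multiplier Learning-rate multiplier for the adversarial
#'   discriminator heads (default 10).  The minimax only exerts meaningful
#'   pressure on the encoder while the discriminators stay close to their
#'   optimum against the current embeddings; updating them on a faster
#'   timescale than the encoder is the standard way to keep them there.
#' @param disc_steps Discriminator-only update steps per batch (default 5).
#'   Each step refits the sex/race heads on the batch's already-computed
#'   study embeddings, so the extra cost is negligible; without it the
#'   heads lag the encoder and the reversed gradient merely flips the sign
#'   of the demographic direction instead of shrinking it.
#' @param head_weight_decay Weight decay applied to the discriminator
#'   heads (default 0.1, stronger than the trunk's).  A confident
#'   discriminator has saturated softmax outputs and therefore vanishing
#'   cross-entropy gradients, which removes all adversarial pressure on
#'   the encoder exactly when the demographic signal is strongest; keeping
#'   the head norm bounded keeps its gradients alive.
#' @param seed Seed controlling initialisation, batching, masking, dropout.
#' @return An object of class `mve_pretrain_config`.
#' @export
pretrain_config <- function(mask_ratio = 0.5, adversarial_weight = 0,
                            lambda_clin = 1, learning_rate = 1e-4,
                            epochs = 50L, batch_size = 32L, patience = 5L,
                            weight_decay = 0.01, head_lr_multiplier = 10,
                            disc_steps = 5L, head_weight_decay = 0.1,
                            seed = 1L) {
  if (mask_ratio < 0 || mask_ratio >= 1)
    mve_stop("mask_ratio must lie in [0, 1)")
  if (adversarial_weight < 0) mve_stop("adversarial_weight must be >= 0")
  if (lambda_clin < 0) mve_stop("lambda_clin must be >= 0")
  if (epochs < 1L || batch_size < 1L || patience < 0L)
    mve_stop("epochs/batch_size must be >= 1 and patience >= 0")
  structure(list(mask_ratio = mask_ratio,
                 adversarial_weight = adversarial_weight,
                 lambda_clin = lambda_clin,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 head_lr_multiplier = head_lr_multiplier,
                 disc_steps = as.integer(disc_steps),
                 head_weight_decay = head_weight_decay,
                 seed = as.integer(seed)),
            class = "mve_pretrain_config")
}

#' Draw the set of masked view indices for one study
#'
#' The number of masked views is `floor(rho * m)` clamped to `[1, m - 1]`,
#' so that at least one view is hidden and at least one remains visible;
#' the two degenerate cases yield an empty set: `rho = 0` (no masking
#' requested) and `m = 1` (nothing could remain visible).  The subset is
#' uniform over subsets of that size, drawn from the calling RNG state.
#'
#' @param m Number of views (>= 1).
#' @param rho Masking ratio in `[0, 1)`.
#' @return Integer vector of masked indices (possibly empty).
#' @export
select_masked_views <- function(m, rho) {
  if (m < 1L) mve_stop("m must be >= 1")
  if (rho < 0 || rho >= 1) mve_stop("mask ratio must lie in [0, 1)")
  if (rho == 0 || m == 1L) return(integer(0))
  size <- min(max(floor(rho * m), 1L), m - 1L)
  sort(sample.int(m, size))
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; the backward pass multiplies the incoming
#' gradient by `-omega`.  Used between the study embedding and the
#' adversarial demographic heads so that the heads descend their
#' cross-entropy while the encoder ascends it (scaled by omega).
#'
#' @param x Numeric input (passed through unchanged).
#' @param omega Nonnegative reversal weight.
#' @return A list with `value` (`== x`) and `backward`, a function mapping a
#'   downstream gradient to `-omega * gradient`.
#' @export
gradient_reversal <- function(x, omega) {
  if (omega < 0) mve_stop("omega must be >= 0")
  list(value = x, backward = function(g) -omega * g)
}

#' Masked-view reconstruction loss
#'
#' Mean squared error over the masked positions only; 0 for an empty mask.
#'
#' @param predicted,target Matrices of identical dimension (|S| x d).
#' @return Scalar MSE.
#' @export
reconstruction_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)))
    mve_stop("reconstruction shapes differ: ",
             paste(dim(predicted), collapse = "x"), " vs ",
             paste(dim(target), collapse = "x"))
  if (length(predicted) == 0L) return(0)
  mean((predicted - target)^2)
}

#' Clinical auxiliary loss
#'
#' Mean binary cross-entropy over the observed (non-missing) task-study
#' pairs; 0 when nothing is observed.
#'
#' @param task_logits Numeric matrix (studies x tasks) or vector of logits.
#' @param labels Matching structure with entries in `{0, 1, NA}`.
#' @return Scalar mean BCE.
#' @export
clinical_loss <- function(task_logits, labels) {
  logits <- as.numeric(task_logits); y <- as.numeric(labels)
  if (length(logits) != length(y)) mve_stop("logits and labels differ in length")
  obs <- !is.na(y)
  if (any(!(y[obs] %in% c(0, 1))))
    mve_stop("labels must be 0, 1 or missing")
  if (!any(obs)) return(0)
  l <- logits[obs]; yy <- y[obs]
  # numerically stable log(1 + exp(-|l|)) formulation
  mean(pmax(l, 0) - l * yy + log1p(exp(-abs(l))))
}

softmax_vec <- function(z) { e <- exp(z - max(z)); e / sum(e) }

softmax_ce <- function(logits, class_idx) {
  p <- softmax_vec(logits)
  -log(max(p[class_idx], 1e-300))
}

#' Adversarial demographic losses for one study
#'
#' Multiclass cross-entropy of the sex (3-class) and race (4-class)
#' discriminator heads on a study embedding.  The heads are two-layer GELU
#' perceptrons; during training their gradients reach the encoder through
#' [gradient_reversal()].
#'
#' @param params Parameter tree holding `sex` and `race` head weights.
#' @param embedding Study embedding (length-d vector).
#' @param sex One of `female/male/unknown`.
#' @param race One of `white/black/other/unknown`.
#' @return Named numeric vector `c(sex = , race = )`.
#' @export
adversarial_loss <- function(params, embedding, sex, race) {
  si <- match(sex, c("female", "male", "unknown"))
  ri <- match(race, c("white", "black", "other", "unknown"))
  if (is.na(si)) mve_stop("sex label '", sex, "' outside the 3-class alphabet")
  if (is.na(ri)) mve_stop("race label '", race, "' outside the 4-class alphabet")
  head_logits <- function(hd) {
    h1 <- gelu(as.numeric(embedding %*% hd$W1) + hd$b1)
    as.numeric(h1 %*% hd$W2) + hd$b2
  }
  c(sex = softmax_ce(head_logits(params$sex), si),
    race = softmax_ce(head_logits(params$race), ri))
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

# Decoupled weight decay applied to weight matrices only (biases, tokens and
# layer-norm parameters are excluded, the usual transformer convention).
# One AdamW update.  `subset`, when given, restricts the update to the named
# top-level parameter groups (their optimizer state advances; everything
# else is untouched) — used to run the encoder trunk and the adversarial
# heads on separate optimizers.
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       subset = NULL) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    step <- lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps)
    p2 <- p - step
    if (is.matrix(p)) p2 <- p2 - lr * weight_decay * p
    list(p = p2, m = m2, v = v2)
  }
  walk <- function(p, g, m, v, top) {
    if (is.numeric(p)) return(upd(p, g, m, v))
    out_p <- p; out_m <- m; out_v <- v
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (nm in keys) {
      if (is.null(p[[nm]])) next
      if (top && !is.null(subset) && is.character(nm) && !(nm %in% subset)) next
      if (is.null(g[[nm]])) next
      r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], FALSE)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- walk(params, grads, state$m, state$v, TRUE)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Gradients of the mean sex/race cross-entropy over a set of fixed study
# embeddings, for the discriminator heads only.
adv_head_grads <- function(params, embeds, sex_idx, race_idx) {
  n <- length(embeds)
  g <- list(sex = zero_like(params$sex), race = zero_like(params$race))
  for (i in seq_len(n)) {
    e <- embeds[[i]]
    for (attr_ in c("sex", "race")) {
      hd <- params[[attr_]]
      cls <- if (attr_ == "sex") sex_idx[i] else race_idx[i]
      h1pre <- as.numeric(e %*% hd$W1) + hd$b1
      h1 <- gelu(h1pre)
      logits <- as.numeric(h1 %*% hd$W2) + hd$b2
      p <- softmax_vec(logits)
      dlog <- p; dlog[cls] <- dlog[cls] - 1
      dlog <- dlog / n
      dh1 <- as.numeric(hd$W2 %*% dlog) * dgelu(h1pre)
      g[[attr_]]$W1 <- g[[attr_]]$W1 + outer(e, dh1)
      g[[attr_]]$b1 <- g[[attr_]]$b1 + dh1
      g[[attr_]]$W2 <- g[[attr_]]$W2 + outer(h1, dlog)
      g[[attr_]]$b2 <- g[[attr_]]$b2 + dlog
    }
  }
  g
}

# ---- per-study loss and gradients ----------------------------------------

# One study's forward/backward.  `norms` carries the batch-level
# normalisers: n_recon (studies with a nonempty mask), n_obs (observed
# task-study pairs in the batch), n_std (studies in the batch).
# `mode`: "grl" (reversed adversarial gradient, scaled by -omega),
# "identity" (adversarial gradient passed straight through; used by the
# finite-difference checks) or "detached" (adversarial terms dropped).
study_loss_grads <- function(study, params, enc_config, pre_config, norms,
                             mode = "grl", train = TRUE, want_grads = TRUE) {
  X <- study$X
  m <- nrow(X)
  masked <- study$masked
  fw <- mve_forward(X, params, enc_config, masked = masked, train = train)
  Z <- fw$Z; d <- enc_config$embed_dim
  e <- pooled_embedding(fw, enc_config)
  losses <- c(recon = 0, clinical = 0, sex = 0, race = 0)
  dZ <- matrix(0, nrow(Z), d)
  g <- list()

  # reconstruction head on masked-token outputs
  if (length(masked)) {
    Zs <- Z[masked + 1L, , drop = FALSE]
    pred <- add_bias(Zs %*% params$recon$W, params$recon$b)
    target <- X[masked, , drop = FALSE]
    losses["recon"] <- reconstruction_loss(pred, target)
    if (want_grads) {
      dpred <- 2 * (pred - target) / (length(masked) * d) / norms$n_recon
      g$recon <- list(W = crossprod(Zs, dpred), b = colSums(dpred))
      dZ[masked + 1L, ] <- dZ[masked + 1L, ] + tcrossprod(dpred, params$recon$W)
    }
  } else if (want_grads) {
    g$recon <- list(W = params$recon$W * 0, b = params$recon$b * 0)
  }

  de <- rep(0, d)

  # clinical auxiliary heads
  if (!is.null(params$clin) && pre_config$lambda_clin > 0) {
    logits <- as.numeric(e %*% params$clin$W) + params$clin$b
    losses["clinical"] <- clinical_loss(logits, study$labels)
    if (want_grads) {
      obs <- !is.na(study$labels)
      dlog <- rep(0, length(logits))
      if (any(obs)) {
        p <- stats::plogis(logits[obs])
        dlog[obs] <- (p - study$labels[obs]) * pre_config$lambda_clin / norms$n_obs
      }
      g$clin <- list(W = outer(e, dlog), b = dlog)
      de <- de + as.numeric(params$clin$W %*% dlog)
    }
  } else if (want_grads && !is.null(params$clin)) {
    g$clin <- list(W = params$clin$W * 0, b = params$clin$b * 0)
  }

  # adversarial heads through the gradient reversal layer
  de_adv <- rep(0, d)
  if (mode != "detached") {
    adv <- adversarial_loss(params, e, study$sex, study$race)
    losses["sex"] <- adv["sex"]; losses["race"] <- adv["race"]
    if (want_grads) {
      for (attr_ in c("sex", "race")) {
        hd <- params[[attr_]]
        cls <- if (attr_ == "sex")
          match(study$sex, c("female", "male", "unknown"))
        else match(study$race, c("white", "black", "other", "unknown"))
        h1pre <- as.numeric(e %*% hd$W1) + hd$b1
        h1 <- gelu(h1pre)
        logits <- as.numeric(h1 %*% hd$W2) + hd$b2
        p <- softmax_vec(logits)
        dlog <- p; dlog[cls] <- dlog[cls] - 1
        dlog <- dlog / norms$n_std
        dh1 <- as.numeric(hd$W2 %*% dlog) * dgelu(h1pre)
        g[[attr_]] <- list(W1 = outer(e, dh1), b1 = dh1,
                           W2 = outer(h1, dlog), b2 = dlog)
        de_adv <- de_adv + as.numeric(hd$W1 %*% dh1)
      }
    }
  } else if (want_grads) {
    g$sex <- zero_like(params$sex); g$race <- zero_like(params$race)
  }

  total <- losses["recon"] + pre_config$lambda_clin * losses["clinical"] +
    losses["sex"] + losses["race"]

  if (!want_grads)
    return(list(losses = c(losses, total = unname(total))))

  grl <- gradient_reversal(e, pre_config$adversarial_weight)
  de <- de + switch(mode,
                    grl = grl$backward(de_adv),
                    identity = de_adv,
                    detached = 0)

  if (enc_config$pooling == "aggregation_token") {
    dZ[1L, ] <- dZ[1L, ] + de
  } else {
    rows <- which(fw$key_mask) + 1L
    dZ[rows, ] <- dZ[rows, ] + rep(de / length(rows), each = length(rows))
  }
  bk <- mve_backward(fw, params, enc_config, dZ)
  trunk <- bk$grads
  g$agg <- trunk$agg; g$mask <- trunk$mask
  g$layers <- trunk$layers; g$lnf_g <- trunk$lnf_g; g$lnf_b <- trunk$lnf_b
  list(losses = c(losses, total = unname(total)), grads = g, e = e)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  if (is.null(g)) return(acc)
  if (is.numeric(acc)) return(acc + g)
  keys <- if (is.null(names(acc))) seq_along(acc) else
    union(names(acc), names(g))
  out <- acc
  for (k in keys) out[[k]] <- accumulate_grads(acc[[k]], g[[k]])
  out
}

# Fill any parameter leaves missing from an accumulated gradient tree with
# zeros so the optimizer can walk params and grads in lockstep.
complete_grads <- function(params, g) {
  if (is.numeric(params)) return(if (is.null(g)) params * 0 else g)
  keys <- if (is.null(names(params))) seq_along(params) else names(params)
  out <- params
  for (k in keys) {
    if (is.null(params[[k]])) next
    out[[k]] <- complete_grads(params[[k]], g[[k]])
  }
  out
}

# ---- training -------------------------------------------------------------

cohort_to_studies <- function(cohort, enc_config) {
  tn <- task_names(cohort)
  lapply(seq_len(nrow(cohort$manifest)), function(i) {
    r <- cohort$manifest[i, ]
    X <- cohort$views[[r$study_id]]
    if (nrow(X) > enc_config$max_views) {
      warning("study ", r$study_id, " has ", nrow(X),
              " views; truncating to the first ", enc_config$max_views,
              call. = FALSE)
      X <- X[seq_len(enc_config$max_views), , drop = FALSE]
    }
    list(study_id = r$study_id, X = X,
         labels = as.numeric(r[tn]), sex = r$sex, race = r$race)
  })
}

batch_norms <- function(studies) {
  n_recon <- sum(vapply(studies, function(s) length(s$masked) > 0L, TRUE))
  n_obs <- sum(vapply(studies, function(s) sum(!is.na(s$labels)), 0))
  list(n_recon = max(1L, n_recon), n_obs = max(1L, n_obs),
       n_std = length(studies))
}

eval_loss <- function(studies, params, enc_config, pre_config, mode) {
  tot <- c(recon = 0, clinical = 0, sex = 0, race = 0)
  n_recon <- 0L; n_obs <- 0; n_std <- length(studies)
  per <- lapply(studies, function(s)
    study_loss_grads(s, params, enc_config, pre_config,
                     norms = list(n_recon = 1, n_obs = 1, n_std = 1),
                     mode = mode, train = FALSE, want_grads = FALSE)$losses)
  for (i in seq_along(studies)) {
    s <- studies[[i]]; l <- per[[i]]
    if (length(s$masked)) { tot["recon"] <- tot["recon"] + l["recon"]; n_recon <- n_recon + 1L }
    no <- sum(!is.na(s$labels))
    if (no > 0) { tot["clinical"] <- tot["clinical"] + l["clinical"] * no; n_obs <- n_obs + no }
    tot["sex"] <- tot["sex"] + l["sex"]; tot["race"] <- tot["race"] + l["race"]
  }
  out <- c(recon = unname(tot["recon"]) / max(1L, n_recon),
           clinical = unname(tot["clinical"]) / max(1, n_obs),
           sex = unname(tot["sex"]) / n_std,
           race = unname(tot["race"]) / n_std)
  c(out, total = unname(out["recon"] + pre_config$lambda_clin * out["clinical"] +
                          out["sex"] + out["race"]))
}

# Early-stopping rule: stop after the first epoch whose run of consecutive
# non-improvements exceeds `patience`.  Returns the stopping epoch index, or
# NA if the sequence never triggers it.
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf; bad <- 0L
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best - 1e-12) { best <- val_losses[i]; bad <- 0L }
    else {
      bad <- bad + 1L
      if (bad > patience) return(i)
    }
  }
  NA_integer_
}

#' Pretrain the multi-view encoder
#'
#' Optimises the total objective (masked-view reconstruction MSE +
#' `lambda_clin` x clinical BCE + sex CE + race CE, the adversarial terms
#' reaching the encoder through the gradient reversal layer scaled by
#' `-omega`) with AdamW, early-stopping on total validation loss and
#' restoring the best-validation parameters.  Fully deterministic given the
#' configs.
#'
#' @param train_cohort,val_cohort `mve_cohort`s with disjoint subject sets.
#' @param enc_config An [encoder_config()] (its `embed_dim` must match the
#'   cohort).
#' @param pre_config A [pretrain_config()].
#' @param adversarial Set `FALSE` to drop the adversarial branch from the
#'   objective entirely (ablation; at `omega = 0` the encoder trajectory is
#'   identical either way).
#' @param verbose Print per-epoch losses.
#' @return An `mve_checkpoint`: parameters, both configs, task names,
#'   per-epoch history data.frame, best epoch.
#' @export
train_mve <- function(train_cohort, val_cohort, enc_config, pre_config,
                      adversarial = TRUE, verbose = FALSE) {
  stopifnot(inherits(train_cohort, "mve_cohort"), inherits(val_cohort, "mve_cohort"))
  overlap <- intersect(unique(train_cohort$manifest$subject_id),
                       unique(val_cohort$manifest$subject_id))
  if (length(overlap))
    mve_stop("train and validation cohorts share subjects: ",
             paste(utils::head(overlap, 3L), collapse = ", "))
  if (train_cohort$config$embed_dim != enc_config$embed_dim)
    mve_stop("cohort embed_dim (", train_cohort$config$embed_dim,
             ") does not match encoder config (", enc_config$embed_dim, ")")
  mode <- if (adversarial) "grl" else "detached"
  tn <- task_names(train_cohort)
  train_st <- cohort_to_studies(train_cohort, enc_config)
  val_st <- cohort_to_studies(val_cohort, enc_config)

  params <- mve_init_params(enc_config, n_tasks = length(tn),
                            seed = derive_seed(pre_config$seed, "init"))
  state_enc <- adamw_init(params)
  state_heads <- adamw_init(params)
  trunk_names <- setdiff(names(params), c("sex", "race"))
  sex_levels <- c("female", "male", "unknown")
  race_levels <- c("white", "black", "other", "unknown")

  val_st <- with_seed(derive_seed(pre_config$seed, "valmask"), {
    lapply(val_st, function(s) {
      s$masked <- select_masked_views(nrow(s$X), pre_config$mask_ratio); s })
  })

  history <- NULL
  best <- list(total = Inf, params = params, epoch = 0L)
  val_totals <- numeric(0)

  for (ep in seq_len(pre_config$epochs)) {
    tr_loss <- c(recon = 0, clinical = 0, sex = 0, race = 0, total = 0)
    nb <- 0L
    with_seed(derive_seed(pre_config$seed, paste0("epoch", ep)), {
      ord <- sample.int(length(train_st))
      batches <- split(ord, ceiling(seq_along(ord) / pre_config$batch_size))
      for (bi in batches) {
        bst <- lapply(train_st[bi], function(s) {
          s$masked <- select_masked_views(nrow(s$X), pre_config$mask_ratio); s })
        norms <- batch_norms(bst)
        acc <- NULL
        embeds <- vector("list", length(bst))
        bl <- c(recon = 0, clinical = 0, sex = 0, race = 0, total = 0)
        for (j in seq_along(bst)) {
          s <- bst[[j]]
          r <- study_loss_grads(s, params, enc_config, pre_config, norms,
                                mode = mode, train = TRUE)
          acc <- accumulate_grads(acc, r$grads)
          embeds[[j]] <- r$e
          w <- c(recon = if (length(s$masked)) 1 / norms$n_recon else 0,
                 clinical = sum(!is.na(s$labels)) / norms$n_obs,
                 sex = 1 / norms$n_std, race = 1 / norms$n_std)
          bl <- bl + c(r$losses[c("recon", "clinical", "sex", "race")] *
                         w, total = 0)
        }
        bl["total"] <- bl["recon"] + pre_config$lambda_clin * bl["clinical"] +
          bl["sex"] + bl["race"]
        if (!all(is.finite(bl)))
          mve_stop("non-finite training loss at epoch ", ep,
                   " (", paste(names(bl), round(bl, 4), collapse = ", "), ")")
        acc <- complete_grads(params, acc)
        st <- adamw_step(params, acc, state_enc, pre_config$learning_rate,
                         pre_config$weight_decay, subset = trunk_names)
        params <- st$params; state_enc <- st$state
        if (mode != "detached" && pre_config$disc_steps > 0L) {
          sexi <- match(vapply(bst, `[[`, "", "sex"), sex_levels)
          racei <- match(vapply(bst, `[[`, "", "race"), race_levels)
          for (dstep in seq_len(pre_config$disc_steps)) {
            hg <- adv_head_grads(params, embeds, sexi, racei)
            st <- adamw_step(params, hg, state_heads,
                             pre_config$learning_rate *
                               pre_config$head_lr_multiplier,
                             pre_config$head_weight_decay,
                             subset = c("sex", "race"))
            params <- st$params; state_heads <- st$state
          }
        }
        tr_loss <- tr_loss + bl; nb <- nb + 1L
      }
    })
    tr_loss <- tr_loss / nb
    vl <- eval_loss(val_st, params, enc_config, pre_config, mode)
    history <- rbind(history, data.frame(
      epoch = ep,
      train_recon = unname(tr_loss["recon"]),
      train_clinical = unname(tr_loss["clinical"]),
      train_sex = unname(tr_loss["sex"]),
      train_race = unname(tr_loss["race"]),
      train_total = unname(tr_loss["total"]),
      val_recon = unname(vl["recon"]),
      val_clinical = unname(vl["clinical"]),
      val_sex = unname(vl["sex"]),
      val_race = unname(vl["race"]),
      val_total = unname(vl["total"]),
      row.names = NULL))
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", ep,
                      tr_loss["total"], vl["total"]))
    val_totals <- c(val_totals, vl["total"])
    if (vl["total"] < best$total) best <- list(total = vl["total"],
                                               params = params, epoch = ep)
    if (!is.na(early_stop_epoch(val_totals, pre_config$patience))) break
  }

  structure(list(params = best$params, encoder_config = enc_config,
                 pretrain_config = pre_config, task_names = tn,
                 history = history, best_epoch = best$epoch,
                 seed = pre_config$seed),
            class = "mve_checkpoint")
}

#' @export
print.mve_checkpoint <- function(x, ...) {
  cat("MVE checkpoint: d =", x$encoder_config$embed_dim,
      ", omega =", x$pretrain_config$adversarial_weight,
      ", best epoch", x$best_epoch, "of", nrow(x$history), "run\n")
  invisible(x)
}

#' Extract study-level embeddings from a trained checkpoint
#'
#' All views are visible (no masking, no dropout); the result is
#' deterministic and equals [encode_batch()] with the checkpoint's
#' parameters.
#'
#' @param checkpoint An `mve_checkpoint` from [train_mve()].
#' @param cohort An `mve_cohort` with matching `embed_dim`.
#' @return An embedding table (data.frame `study_id`, `e1..ed`).
#' @export
extract_embeddings <- function(checkpoint, cohort) {
  stopifnot(inherits(checkpoint, "mve_checkpoint"), inherits(cohort, "mve_cohort"))
  if (cohort$config$embed_dim != checkpoint$encoder_config$embed_dim)
    mve_stop("cohort embed_dim (", cohort$config$embed_dim,
             ") does not match checkpoint (", checkpoint$encoder_config$embed_dim, ")")
  encode_batch(cohort$views, checkpoint$encoder_config, checkpoint$params)
}
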