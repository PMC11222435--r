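# Composite-loss training: modification BCE, masked-base and codebook
# signal-classification auxiliary tasks, diversity regulariser, AdamW
# updates, and teacher-student knowledge distillation.

#' Training configuration
#'
#' @param epochs Number of passes over the example set.
#' @param batch_size Examples per optimizer step.
#' @param lr Learning rate (constant; no schedule).
#' @param weight_decay Decoupled weight decay.
#' @param beta1,beta2 Adam running-average coefficients.
#' @param p_mask Fraction of window bases replaced by the mask token.
#' @param p_flip Disjoint fraction of bases replaced by a uniformly random
#'   base (`p_mask + p_flip <= 1`).
#' @param p_signal Fraction of signal blocks masked for the codebook task.
#' @param alpha Weight of the auxiliary losses in the total.
#' @param seed Seed fixing data order, masking and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 1L, batch_size = 64L,
                         lr = 3e-4, weight_decay = 1e-4,
                         beta1 = 0.9, beta2 = 0.999,
                         p_mask = 0.15, p_flip = 0.05, p_signal = 0.15,
                         alpha = 0.1, seed = 1L) {
  rates <- c(p_mask, p_flip, p_signal)
  if (any(rates < 0 | rates > 1) || p_mask + p_flip > 1) {
    stop_invalid("masking rates must lie in [0, 1] with p_mask + p_flip <= 1")
  }
  if (alpha < 0) stop_invalid("`alpha` must be >= 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2,
                 p_mask = p_mask, p_flip = p_flip, p_signal = p_signal,
                 alpha = alpha, seed = as.integer(seed)),
            class = "train_config")
}

#' Mask and flip window bases for the base-prediction task
#'
#' An independent `p_mask` fraction of positions is replaced by the mask
#' token and a disjoint `p_flip` fraction by a base drawn uniformly from
#' the four canonical bases. Targets record the original canonical base at
#' every altered position. Uses the current RNG stream.
#'
#' @param tokens Integer token vector over the 6-symbol vocabulary.
#' @param p_mask,p_flip Masking and flipping rates.
#' @return List with `tokens` (modified) and `targets` (list with
#'   parallel vectors `pos`, 1-based, and `base`, 1..4).
#' @export
mask_bases <- function(tokens, p_mask, p_flip) {
  l <- length(tokens)
  u <- stats::runif(l)
  masked <- u < p_mask
  flipped <- !masked & u < p_mask + p_flip
  out <- tokens
  out[masked] <- TOK_MASK
  if (any(flipped)) {
    out[flipped] <- sample.int(4L, sum(flipped), replace = TRUE)
  }
  altered <- which((masked | flipped) & tokens <= 4L)
  list(tokens = out, targets = list(pos = altered, base = tokens[altered]))
}

#' Mask signal blocks and assign codeword targets
#'
#' A `p_signal` fraction of blocks is chosen; each chosen block's target is
#' the argmax codeword of the softmax over codebook dot products with its
#' local representation (the block projected by `W_S`, computed before
#' masking and without gradient flow). The chosen blocks' samples and their
#' `r`/`q` entries are then set to zero. Uses the current RNG stream.
#'
#' @param blocks s x b signal-block matrix.
#' @param r,q Window-relative indices (may be NULL).
#' @param p_signal Masking rate.
#' @param codebook f x K codeword matrix.
#' @param W_S b x f local projection.
#' @return List with `blocks`, `r`, `q` (masked), `targets` (list with
#'   parallel vectors `idx`, 1-based block row, and `class`, 1..K).
#' @export
mask_signal <- function(blocks, r, q, p_signal, codebook, W_S) {
  K <- ncol(codebook)
  if (K < 2L) stop_invalid("codebook must have at least 2 codewords")
  s <- nrow(blocks)
  chosen <- which(stats::runif(s) < p_signal)
  targets <- list(idx = integer(0), class = integer(0))
  if (length(chosen) > 0L) {
    local <- blocks[chosen, , drop = FALSE] %*% W_S
    logits <- local %*% codebook
    cls <- max.col(logits, ties.method = "first")
    targets <- list(idx = chosen, class = cls)
    blocks[chosen, ] <- 0
    if (!is.null(r)) r[chosen] <- 0L
    if (!is.null(q)) q[chosen] <- 0L
  }
  list(blocks = blocks, r = r, q = q, targets = targets)
}

# Numerically stable helpers.
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
bce_logit <- function(z, y) softplus(-z) + (1 - y) * z
log_softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  x - m - log(rowSums(exp(x - m)))
}

#' Compute the composite loss bundle
#'
#' `L_mod` is the mean binary cross-entropy of the modification logits
#' (soft targets allowed); `L_bases` the mean cross-entropy at altered
#' token positions; `L_signal` the mean cross-entropy of the contextualized
#' codeword softmax against the precomputed targets; `L_diversity` is
#' `log K + sum(p_bar * log(p_bar))` with `p_bar` the batch-average soft
#' codeword assignment distribution (zero iff usage is uniform). The total
#' is `L_mod + alpha * (L_bases + L_signal + L_diversity)`. Components with
#' empty target sets are 0.
#'
#' @param z Numeric vector of modification logits.
#' @param y Numeric vector of (possibly soft) labels.
#' @param base_logits Matrix (n x 4) of base-head logits at altered
#'   positions, or NULL.
#' @param base_targets Integer vector (1..4) matching `base_logits` rows.
#' @param sig_logits Matrix (m x K) of codeword logits at masked blocks, or
#'   NULL.
#' @param sig_targets Integer vector (1..K) matching `sig_logits` rows.
#' @param alpha Auxiliary-loss weight.
#' @param K Codebook size.
#' @return List of class `loss_bundle`: `L_mod`, `L_bases`, `L_signal`,
#'   `L_diversity`, `total`, `p_bar`, `hard_usage`.
#' @export
compute_losses <- function(z, y, base_logits = NULL, base_targets = NULL,
                           sig_logits = NULL, sig_targets = NULL,
                           alpha = 0.1, K = 64L) {
  L_mod <- if (length(z) > 0L) mean(bce_logit(z, y)) else 0
  L_bases <- 0
  if (!is.null(base_logits) && nrow(base_logits) > 0L) {
    ls <- log_softmax_rows(base_logits)
    L_bases <- -mean(ls[cbind(seq_along(base_targets), base_targets)])
  }
  L_signal <- 0; L_diversity <- 0
  p_bar <- NULL; hard_usage <- NULL
  if (!is.null(sig_logits) && nrow(sig_logits) > 0L) {
    ls <- log_softmax_rows(sig_logits)
    L_signal <- -mean(ls[cbind(seq_along(sig_targets), sig_targets)])
    probs <- exp(ls)
    p_bar <- colMeans(probs)
    nz <- p_bar > 0
    L_diversity <- log(K) + sum(p_bar[nz] * log(p_bar[nz]))
    hard <- max.col(probs, ties.method = "first")
    hard_usage <- tabulate(hard, nbins = K) / length(hard)
  }
  total <- L_mod + alpha * (L_bases + L_signal + L_diversity)
  structure(list(L_mod = L_mod, L_bases = L_bases, L_signal = L_signal,
                 L_diversity = L_diversity, total = total,
                 p_bar = p_bar, hard_usage = hard_usage),
            class = "loss_bundle")
}

# One training step over a prepared batch. Each batch element is a list
# with tokens, blocks, r, q, y, base_targets (tibble pos/base),
# sig_targets (tibble idx/class). Returns the loss bundle and flat
# gradients (mean over the batch for L_mod; means over target sets for the
# auxiliary components, matching compute_losses()).
train_step <- function(params, cfg, batch, alpha, train = TRUE) {
  B <- length(batch)
  cache <- forward_batch(params, cfg, batch, train = train)
  bi <- cache$bi
  ys <- vapply(batch, `[[`, numeric(1), "y")
  zs <- cache$z

  # Global row indices of base and signal targets in the concatenated
  # decoder/encoder matrices.
  base_grow <- integer(0); base_tg <- integer(0)
  sig_grow <- integer(0); sig_tg <- integer(0)
  for (b in seq_len(B)) {
    ex <- batch[[b]]
    if (cfg$use_decoder && length(ex$base_targets$pos) > 0L) {
      base_grow <- c(base_grow, (b - 1L) * cfg$l + ex$base_targets$pos)
      base_tg <- c(base_tg, ex$base_targets$base)
    }
    if (length(ex$sig_targets$idx) > 0L) {
      sig_grow <- c(sig_grow, bi$soff[b] + ex$sig_targets$idx)
      sig_tg <- c(sig_tg, ex$sig_targets$class)
    }
  }
  base_logits <- NULL
  if (length(base_grow) > 0L) {
    base_H <- cache$dec_out[base_grow, , drop = FALSE]
    base_logits <- add_row(base_H %*% params$head_base$W, params$head_base$b)
  }
  sig_logits <- NULL
  if (length(sig_grow) > 0L) {
    sig_H <- cache$enc_out[sig_grow, , drop = FALSE]
    sig_logits <- sig_H %*% params$codebook
  }
  loss <- compute_losses(zs, ys, base_logits, base_tg, sig_logits, sig_tg,
                         alpha = alpha, K = ncol(params$codebook))

  g <- new.env(parent = emptyenv())
  ddec_extra <- NULL
  if (!is.null(base_logits)) {
    P <- exp(log_softmax_rows(base_logits))
    P[cbind(seq_along(base_tg), base_tg)] <-
      P[cbind(seq_along(base_tg), base_tg)] - 1
    dlogits <- alpha * P / length(base_tg)
    acc_grad(g, "head_base.W", crossprod(base_H, dlogits))
    acc_grad(g, "head_base.b", colSums(dlogits))
    ddec_extra <- matrix(0, bi$B * cfg$l, cfg$f)
    dH <- tcrossprod(dlogits, params$head_base$W)
    for (j in seq_along(base_grow)) {
      ddec_extra[base_grow[j], ] <- ddec_extra[base_grow[j], ] + dH[j, ]
    }
  }
  denc_extra <- NULL
  if (!is.null(sig_logits)) {
    P <- exp(log_softmax_rows(sig_logits))
    dCE <- P
    dCE[cbind(seq_along(sig_tg), sig_tg)] <-
      dCE[cbind(seq_along(sig_tg), sig_tg)] - 1
    dCE <- dCE / length(sig_tg)
    # Diversity: dL/dP_mi = (log p_bar_i + 1) / M, then through the softmax.
    M <- nrow(P)
    dpb <- (log(pmax(loss$p_bar, 1e-300)) + 1) / M
    dP <- matrix(dpb, M, length(dpb), byrow = TRUE)
    ddiv <- P * (dP - rowSums(dP * P))
    dsig_all <- alpha * (dCE + ddiv)
    acc_grad(g, "codebook", crossprod(sig_H, dsig_all))
    dsig_H <- tcrossprod(dsig_all, params$codebook)
    denc_extra <- matrix(0, bi$n_sig, cfg$f)
    denc_extra[sig_grow, ] <- dsig_H  # sig_grow rows are distinct
  }

  dzs <- (1 / (1 + exp(-zs)) - ys) / B
  backward_batch(params, cfg, cache, g, dzs,
                 ddec_extra = ddec_extra, denc_extra = denc_extra)
  list(loss = loss, grads = g)
}

# AdamW optimizer over flat parameter lists.
adamw_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adamw_update <- function(flat, grads_env, state, tc, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - tc$beta1^state$t
  bc2 <- 1 - tc$beta2^state$t
  for (nm in names(flat)) {
    gr <- grads_env[[nm]]
    if (is.null(gr)) gr <- flat[[nm]] * 0
    state$m[[nm]] <- tc$beta1 * state$m[[nm]] + (1 - tc$beta1) * gr
    state$v[[nm]] <- tc$beta2 * state$v[[nm]] + (1 - tc$beta2) * gr^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    flat[[nm]] <- flat[[nm]] - tc$lr * step - tc$lr * tc$weight_decay * flat[[nm]]
  }
  list(flat = flat, state = state)
}

prepare_batch <- function(params, cfg, examples, idx, tc) {
  lapply(idx, function(i) {
    tokens <- examples$tokens[[i]]
    mb <- mask_bases(tokens, tc$p_mask, tc$p_flip)
    ms <- mask_signal(examples$blocks[[i]], examples$r[[i]], examples$q[[i]],
                      tc$p_signal, params$codebook, params$W_S)
    list(tokens = mb$tokens, blocks = ms$blocks, r = ms$r, q = ms$q,
         y = examples$label[i], base_targets = mb$targets,
         sig_targets = ms$targets)
  })
}

#' Train a model on labeled examples
#'
#' Runs seeded AdamW training with the composite loss: modification BCE on
#' (possibly soft) labels plus `alpha`-weighted masked-base, codebook
#' signal-classification and diversity terms. Data order, masking and
#' dropout are all fixed by `config$seed`; two runs with the same seed give
#' identical histories. Aborts with a diagnostic naming the offending
#' component if any loss becomes non-finite.
#'
#' @param model A `sigmeth_model` from [new_model()].
#' @param examples Example tibble from [extract_examples()] with a `label`
#'   column (hard 0/1 or soft probabilities); rows with NA labels are
#'   dropped.
#' @param config A [train_config()].
#' @param verbose Print a progress line per epoch.
#' @return The model with trained parameters and a `history` tibble (one
#'   row per step: epoch, step, L_mod, L_bases, L_signal, L_diversity,
#'   total, and the hard codeword-usage histogram as a list column).
#' @export
train <- function(model, examples, config = train_config(), verbose = FALSE) {
  examples <- examples[!is.na(examples$label), , drop = FALSE]
  n <- nrow(examples)
  if (n == 0L) stop_invalid("no labeled examples to train on")
  cfg <- model$config
  flat <- flatten_params(model$params)
  state <- adamw_init(flat)
  hist <- list()
  with_rng_seed(config$seed, {
    params <- model$params
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + config$batch_size - 1L, n)]
        batch <- prepare_batch(params, cfg, examples, idx, config)
        res <- train_step(params, cfg, batch, config$alpha, train = TRUE)
        comps <- unlist(res$loss[c("L_mod", "L_bases", "L_signal",
                                   "L_diversity", "total")])
        if (any(!is.finite(comps))) {
          bad <- names(comps)[!is.finite(comps)][1]
          stop_invalid("non-finite loss component %s at step %d", bad, step + 1L)
        }
        upd <- adamw_update(flat, res$grads, state, config)
        flat <- upd$flat; state <- upd$state
        params <- unflatten_params(flat, params)
        step <- step + 1L
        hist[[step]] <- tibble::tibble(
          epoch = ep, step = step,
          L_mod = res$loss$L_mod, L_bases = res$loss$L_bases,
          L_signal = res$loss$L_signal, L_diversity = res$loss$L_diversity,
          total = res$loss$total,
          hard_usage = list(res$loss$hard_usage)
        )
      }
      if (verbose) {
        message(sprintf("epoch %d/%d: total loss %.4f", ep, config$epochs,
                        hist[[step]]$total))
      }
    }
    model$params <- params
  })
  model$history <- dplyr::bind_rows(hist)
  model$train_config <- config
  model
}

#' Predict modification probabilities for examples
#'
#' Deterministic forward pass (dropout disabled).
#'
#' @param model A `sigmeth_model`.
#' @param examples Example tibble from [extract_examples()].
#' @return Numeric vector of probabilities, one per example row.
#' @export
predict_examples <- function(model, examples, chunk_size = 256L) {
  n <- nrow(examples)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (st in seq(1L, n, by = chunk_size)) {
    idx <- st:min(st + chunk_size - 1L, n)
    batch <- lapply(idx, function(i) {
      list(tokens = examples$tokens[[i]], blocks = examples$blocks[[i]],
           r = examples$r[[i]], q = examples$q[[i]])
    })
    z <- forward_batch(model$params, model$config, batch, train = FALSE)$z
    out[idx] <- 1 / (1 + exp(-z))
  }
  out
}

#' Build a soft-labeled dataset from a teacher model
#'
#' Replaces each example's label with the teacher's predicted probability,
#' optionally mixing in hard-labeled examples.
#'
#' @param teacher A trained `sigmeth_model`.
#' @param examples Example tibble.
#' @param hard_examples Optional tibble of hard-labeled examples appended
#'   unchanged.
#' @return Example tibble with soft `label`s (and the hard rows appended).
#' @export
distill <- function(teacher, examples, hard_examples = NULL) {
  examples$label <- predict_examples(teacher, examples)
  if (!is.null(hard_examples)) {
    examples <- dplyr::bind_rows(examples, hard_examples)
  }
  examples
}

#' Stratified balanced sampling of examples
#'
#' Draws exactly `n / 2` examples whose (teacher or ground-truth) label
#' exceeds the threshold and `n / 2` at or below it, mirroring the balanced
#' construction of distillation datasets. Uses the current RNG stream.
#'
#' @param examples Example tibble with a `label` column.
#' @param n Total sample size (even).
#' @param threshold Class threshold on the label.
#' @return Subsampled example tibble (`n` rows).
#' @export
sample_balanced <- function(examples, n, threshold = 0.5) {
  if (n %% 2L != 0L) stop_invalid("`n` must be even")
  pos <- which(examples$label > threshold)
  neg <- which(examples$label <= threshold)
  if (length(pos) < n / 2 || length(neg) < n / 2) {
    stop_invalid("not enough examples per class for a balanced sample of %d", n)
  }
  take <- c(sample(pos, n / 2), sample(neg, n / 2))
  examples[sort(take), , drop = FALSE]
}

#' Masked-base prediction accuracy
#'
#' Masks a fraction of each example's window bases, runs the model, and
#' scores the base head's argmax prediction at the masked positions against
#' the original bases.
#'
#' @param model A trained `sigmeth_model`.
#' @param examples Example tibble.
#' @param p_mask Masking rate.
#' @param seed Seed for the masking draws.
#' @return List with `accuracy` and `n` (number of masked targets).
#' @export
masked_base_accuracy <- function(model, examples, p_mask = 0.15, seed = 1L) {
  params <- model$params; cfg <- model$config
  with_rng_seed(seed, {
    n_ok <- 0L; n_tot <- 0L
    for (i in seq_len(nrow(examples))) {
      mb <- mask_bases(examples$tokens[[i]], p_mask, 0)
      if (length(mb$targets$pos) == 0L) next
      fw <- forward_cached(params, cfg, mb$tokens, examples$blocks[[i]],
                           examples$r[[i]], examples$q[[i]])
      pm <- predict_modification(fw$dec_out, params,
                                 base_positions = mb$targets$pos)
      pred <- max.col(pm$base_logits, ties.method = "first")
      n_ok <- n_ok + sum(pred == mb$targets$base)
      n_tot <- n_tot + length(mb$targets$pos)
    }
    list(accuracy = if (n_tot > 0L) n_ok / n_tot else NA_real_, n = n_tot)
  })
}
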