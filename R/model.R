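# Encoder-decoder attention model over signal blocks and sequence tokens:
# signal projection, hybrid positional encodings, Pre-LN transformer
# encoder, token embedding + sinusoidal encodings, Pre-LN decoder with
# cross-attention, and the modification / base / signal-class heads.

#' Model configuration
#'
#' Presets mirror the published base (f = 384, 12 + 12 layers, 2048-d
#' feed-forward) and small (f = 128, 6 + 6 layers, 1024-d) models; every
#' field can be overridden for desk-scale experiments.
#'
#' @param preset "base", "small", or "custom".
#' @param f Latent dimension (divisible by `H`).
#' @param H Number of attention heads; per-head dimension is `d = f / H`.
#' @param L_enc,L_dec Encoder and decoder layer counts.
#' @param d_ff Feed-forward hidden width.
#' @param b Signal-block width (samples per block).
#' @param l Token window length.
#' @param mode "R9" uses the 4-term positional encoding (absolute cos/sin
#'   plus cosines of the relative reference and query indices); "R10" uses
#'   the 2-term absolute encoding only.
#' @param K Codebook size for the signal-classification auxiliary task.
#' @param dropout Dropout rate applied after attention and feed-forward
#'   sublayers during training.
#' @param use_decoder Set `FALSE` for the signal-only ablation: the
#'   modification head then reads the mean-pooled encoder output.
#' @return A list of class `sigmeth_model_config`.
#' @export
model_config <- function(preset = c("custom", "base", "small"),
                         f = 64L, H = 4L, L_enc = 2L, L_dec = 2L,
                         d_ff = 4L * f, b = 5L, l = 31L,
                         mode = c("R9", "R10"), K = 64L,
                         dropout = 0.1, use_decoder = TRUE) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  if (preset == "base") { f <- 384L; H <- 6L; L_enc <- 12L; L_dec <- 12L; d_ff <- 2048L }
  if (preset == "small") { f <- 128L; H <- 4L; L_enc <- 6L; L_dec <- 6L; d_ff <- 1024L }
  if (f %% H != 0L) stop_invalid("`f` (%d) must be divisible by `H` (%d)", f, H)
  if (L_enc < 0L || L_dec < 0L) stop_invalid("layer counts must be >= 0")
  structure(list(f = as.integer(f), H = as.integer(H), d = as.integer(f / H),
                 L_enc = as.integer(L_enc), L_dec = as.integer(L_dec),
                 d_ff = as.integer(d_ff), b = as.integer(b), l = as.integer(l),
                 vocab = 6L, mode = mode, K = as.integer(K),
                 dropout = dropout, use_decoder = isTRUE(use_decoder)),
            class = "sigmeth_model_config")
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

mat_init <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

attn_params <- function(f) {
  list(Wq = mat_init(f, f), Wk = mat_init(f, f), Wv = mat_init(f, f),
       Wo = mat_init(f, f))
}

ffn_params <- function(f, d_ff) {
  list(W_in = mat_init(f, d_ff), b_in = numeric(d_ff),
       W_out = mat_init(d_ff, f), b_out = numeric(f))
}

ln_params <- function(f) list(g = rep(1, f), b = numeric(f))

#' Initialize model parameters
#'
#' Truncated-normal (sd 0.02) projections, zero biases, unit layer-norm
#' scales. The attention projections for all heads of one layer are stored
#' as f x f matrices whose column blocks are the per-head f x d projections.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays (class `sigmeth_params`).
#' @export
init_params <- function(config, seed = 1L) {
  with_rng_seed(seed, {
    p <- list(
      W_S = mat_init(config$b, config$f),
      E_B = mat_init(config$vocab, config$f),
      enc = lapply(seq_len(config$L_enc), function(i) {
        list(ln1 = ln_params(config$f), attn = attn_params(config$f),
             ln2 = ln_params(config$f), ffn = ffn_params(config$f, config$d_ff))
      }),
      dec = lapply(seq_len(config$L_dec), function(i) {
        list(ln1 = ln_params(config$f), self_attn = attn_params(config$f),
             ln2 = ln_params(config$f), cross_attn = attn_params(config$f),
             ln3 = ln_params(config$f), ffn = ffn_params(config$f, config$d_ff))
      }),
      head_mod = list(w = trunc_normal(config$f), b = 0),
      head_base = list(W = mat_init(config$f, 4L), b = numeric(4L)),
      codebook = mat_init(config$f, config$K)
    )
    structure(p, class = "sigmeth_params")
  })
}

#' Create a model object
#'
#' @param config A [model_config()].
#' @param seed Seed for parameter initialization.
#' @return List of class `sigmeth_model` with `config` and `params`.
#' @export
new_model <- function(config = model_config(), seed = 1L) {
  structure(list(config = config, params = init_params(config, seed),
                 history = NULL),
            class = "sigmeth_model")
}

#' @export
print.sigmeth_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf(
    "<sigmeth_model> %s mode, f=%d H=%d, %d+%d layers, d_ff=%d, l=%d b=%d, K=%d (%.0f parameters)\n",
    cfg$mode, cfg$f, cfg$H, cfg$L_enc, cfg$L_dec, cfg$d_ff, cfg$l, cfg$b,
    cfg$K, np))
  if (!is.null(x$history)) {
    cat(sprintf("  trained for %d steps; final total loss %.4f\n",
                nrow(x$history), x$history$total[nrow(x$history)]))
  }
  invisible(x)
}

# Positional term: pt(j) = 10000^(-4 floor(j/4) / f) in R9 mode and
# 10000^(-2 floor(j/2) / f) in R10 mode (frequencies paired per 2 terms).
pos_term <- function(j, f, mode) {
  if (mode == "R9") 10000^(-4 * (j %/% 4) / f) else 10000^(-2 * (j %/% 2) / f)
}

#' Hybrid positional encoding over signal blocks
#'
#' R9 mode cycles four encodings over the feature columns: cosine and sine
#' of the absolute block position, then cosines of the block's relative
#' reference and query indices. R10 mode uses the absolute cosine/sine pair
#' only. Row index `i` and the `r`/`q` indices are 0-based.
#'
#' @param s Number of signal blocks.
#' @param r,q Length-`s` window-relative reference and query indices
#'   (required in R9 mode; ignored in R10 mode).
#' @param config A [model_config()] (uses `f` and `mode`).
#' @return s x f encoding matrix.
#' @export
positional_encoding <- function(s, r = NULL, q = NULL, config) {
  f <- config$f
  j <- 0:(f - 1L)
  pt <- pos_term(j, f, config$mode)
  i <- 0:(s - 1L)
  P <- matrix(0, s, f)
  if (config$mode == "R9") {
    if (is.null(r) || is.null(q) || length(r) != s || length(q) != s) {
      stop_invalid("R9 positional encoding requires r and q of length s")
    }
    sel0 <- j %% 4L == 0L; sel1 <- j %% 4L == 1L
    sel2 <- j %% 4L == 2L; sel3 <- j %% 4L == 3L
    P[, sel0] <- cos(outer(i, pt[sel0]))
    P[, sel1] <- sin(outer(i, pt[sel1]))
    P[, sel2] <- cos(outer(r, pt[sel2]))
    P[, sel3] <- cos(outer(q, pt[sel3]))
  } else {
    sel0 <- j %% 2L == 0L; sel1 <- j %% 2L == 1L
    P[, sel0] <- cos(outer(i, pt[sel0]))
    P[, sel1] <- sin(outer(i, pt[sel1]))
  }
  P
}

# Standard sinusoidal encoding for the token sequence (0-based positions).
# Memoised: the encoding depends only on (l, f).
.pe_cache <- new.env(parent = emptyenv())

seq_positional_encoding <- function(l, f) {
  key <- sprintf("seq|%d|%d", l, f)
  hit <- .pe_cache[[key]]
  if (!is.null(hit)) return(hit)
  j <- 0:(f - 1L)
  pt <- 10000^(-2 * (j %/% 2) / f)
  i <- 0:(l - 1L)
  P <- matrix(0, l, f)
  even <- j %% 2L == 0L
  P[, even] <- sin(outer(i, pt[even]))
  P[, !even] <- cos(outer(i, pt[!even]))
  .pe_cache[[key]] <- P
  P
}

softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# Add a row vector to every row / scale columns (fast `sweep` substitutes).
add_row <- function(x, b) x + rep(b, each = nrow(x))
mul_row <- function(x, g) x * rep(g, each = nrow(x))

#' Multi-head scaled dot-product attention
#'
#' Computes, per head h, `softmax(Q Wq_h (K Wk_h)^T / sqrt(d)) V Wv_h`,
#' concatenates the heads and projects with `Wo`. Masked key positions
#' receive zero attention weight.
#'
#' @param K,Q,V Input matrices (rows are positions, `f` columns).
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo` (f x f; column blocks are
#'   the per-head projections).
#' @param H Number of heads.
#' @param mask Optional logical vector over key positions; `FALSE` masks a
#'   key out.
#' @return List with `out` (same shape as `Q`'s projection) and `weights`
#'   (list of per-head attention matrices).
#' @export
multi_head_attention <- function(K, Q, V, params, H, mask = NULL) {
  f <- ncol(params$Wq)
  if (ncol(K) != nrow(params$Wk)) stop_invalid("attention input width mismatch")
  d <- f %/% H
  Qp <- Q %*% params$Wq; Kp <- K %*% params$Wk; Vp <- V %*% params$Wv
  heads <- matrix(0, nrow(Qp), f)
  weights <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    scores <- tcrossprod(Qp[, cols, drop = FALSE], Kp[, cols, drop = FALSE]) / sqrt(d)
    if (!is.null(mask)) scores[, !mask] <- -Inf
    A <- softmax_rows(scores)
    weights[[h]] <- A
    heads[, cols] <- A %*% Vp[, cols, drop = FALSE]
  }
  list(out = heads %*% params$Wo, weights = weights)
}

layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  add_row(mul_row(xhat, g), b)
}

# Sigmoid-approximated GELU: x * sigmoid(1.702 x).
gelu_gate <- function(x) 1 / (1 + exp(-1.702 * x))
gelu <- function(x) x * gelu_gate(x)

ffn_forward <- function(x, p) {
  h <- add_row(x %*% p$W_in, p$b_in)
  a <- gelu(h)
  add_row(a %*% p$W_out, p$b_out)
}

#' Encode signal blocks into contextualized representations
#'
#' Projects blocks with `W_S`, adds the hybrid positional encoding, and
#' applies `L_enc` Pre-LN encoder layers (`x + MHA(LN(x))` then
#' `x + FFN(LN(x))`, with a GELU feed-forward).
#'
#' @param blocks s x b signal-block matrix.
#' @param r,q Window-relative indices (R9 mode).
#' @param params Model parameters from [init_params()].
#' @param config A [model_config()].
#' @return s x f contextualized signal matrix.
#' @export
encode_signal <- function(blocks, r = NULL, q = NULL, params, config) {
  s <- nrow(blocks)
  x <- blocks %*% params$W_S + positional_encoding(s, r, q, config)
  for (layer in params$enc) {
    n1 <- layer_norm(x, layer$ln1$g, layer$ln1$b)
    x <- x + multi_head_attention(n1, n1, n1, layer$attn, config$H)$out
    n2 <- layer_norm(x, layer$ln2$g, layer$ln2$b)
    x <- x + ffn_forward(n2, layer$ffn)
  }
  x
}

#' Embed tokens and decode against the contextualized signal
#'
#' Token lookup plus sinusoidal positional encodings, then `L_dec` Pre-LN
#' decoder layers: self-attention over the sequence, cross-attention with
#' queries from the sequence and keys/values from the contextualized
#' signal, and a feed-forward sublayer, each with a residual connection.
#'
#' @param tokens Integer token vector (length `l`, values 1..6).
#' @param enc_out s x f encoder output.
#' @param params,config Model parameters and configuration.
#' @return l x f contextualized sequence matrix.
#' @export
embed_and_decode <- function(tokens, enc_out, params, config) {
  if (any(tokens < 1L | tokens > config$vocab)) {
    stop_invalid("token id outside the 6-symbol vocabulary")
  }
  x <- params$E_B[tokens, , drop = FALSE] +
    seq_positional_encoding(length(tokens), config$f)
  for (layer in params$dec) {
    n1 <- layer_norm(x, layer$ln1$g, layer$ln1$b)
    x <- x + multi_head_attention(n1, n1, n1, layer$self_attn, config$H)$out
    n2 <- layer_norm(x, layer$ln2$g, layer$ln2$b)
    x <- x + multi_head_attention(enc_out, n2, enc_out, layer$cross_attn,
                                  config$H)$out
    n3 <- layer_norm(x, layer$ln3$g, layer$ln3$b)
    x <- x + ffn_forward(n3, layer$ffn)
  }
  x
}

#' Forward pass for one example
#'
#' @param params,config Model parameters and configuration.
#' @param tokens Integer token vector of length `l`.
#' @param blocks s x b signal-block matrix.
#' @param r,q Window-relative indices (R9 mode).
#' @return List with `z` (modification logit for the central cytosine),
#'   `prob`, `enc_out`, `dec_out`.
#' @export
forward_example <- function(params, config, tokens, blocks, r = NULL, q = NULL) {
  enc_out <- encode_signal(blocks, r, q, params, config)
  if (config$use_decoder) {
    dec_out <- embed_and_decode(tokens, enc_out, params, config)
    center <- dec_out[length(tokens) %/% 2L + 1L, ]
  } else {
    dec_out <- NULL
    center <- colMeans(enc_out)
  }
  z <- sum(center * params$head_mod$w) + params$head_mod$b
  list(z = z, prob = 1 / (1 + exp(-z)), enc_out = enc_out, dec_out = dec_out)
}

#' Modification logit from a contextualized sequence
#'
#' Applies the linear modification head to the row of the central cytosine
#' (0-based row `floor(l/2)`), and optionally the base head at requested
#' positions.
#'
#' @param dec_out l x f contextualized sequence.
#' @param params Model parameters.
#' @param base_positions Optional integer vector of 1-based row indices for
#'   which 4-way base logits are returned.
#' @return List with `z`, `prob`, and `base_logits` (NULL or length(pos) x 4).
#' @export
predict_modification <- function(dec_out, params, base_positions = NULL) {
  center <- dec_out[nrow(dec_out) %/% 2L + 1L, ]
  z <- sum(center * params$head_mod$w) + params$head_mod$b
  base_logits <- NULL
  if (!is.null(base_positions) && length(base_positions) > 0L) {
    base_logits <- sweep(dec_out[base_positions, , drop = FALSE] %*%
                           params$head_base$W, 2L, params$head_base$b, `+`)
  }
  list(z = z, prob = 1 / (1 + exp(-z)), base_logits = base_logits)
}
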