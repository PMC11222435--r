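# Cached forward pass and hand-derived backward pass for the
# encoder-decoder model. Gradients are verified against central finite
# differences in the test suite; the backward code must therefore follow
# the forward computation exactly (no approximations).

ln_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- add_row(mul_row(xhat, p$g), p$b)
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dxhat <- mul_row(dy, p$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

mha_fwd <- function(Kin, Qin, Vin, p, H) {
  f <- ncol(p$Wq)
  d <- f %/% H
  Qp <- Qin %*% p$Wq; Kp <- Kin %*% p$Wk; Vp <- Vin %*% p$Wv
  heads <- matrix(0, nrow(Qp), f)
  A <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    sc <- tcrossprod(Qp[, cols, drop = FALSE], Kp[, cols, drop = FALSE]) / sqrt(d)
    A[[h]] <- softmax_rows(sc)
    heads[, cols] <- A[[h]] %*% Vp[, cols, drop = FALSE]
  }
  list(out = heads %*% p$Wo,
       cache = list(Kin = Kin, Qin = Qin, Vin = Vin, Qp = Qp, Kp = Kp,
                    Vp = Vp, A = A, heads = heads, d = d, H = H))
}

# Returns input gradients and parameter gradients for one attention call.
mha_bwd <- function(dout, cache, p) {
  H <- cache$H; d <- cache$d
  dWo <- crossprod(cache$heads, dout)
  dheads <- tcrossprod(dout, p$Wo)
  dQp <- matrix(0, nrow(cache$Qp), ncol(cache$Qp))
  dKp <- matrix(0, nrow(cache$Kp), ncol(cache$Kp))
  dVp <- matrix(0, nrow(cache$Vp), ncol(cache$Vp))
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    A <- cache$A[[h]]
    dh <- dheads[, cols, drop = FALSE]
    dA <- tcrossprod(dh, cache$Vp[, cols, drop = FALSE])
    dVp[, cols] <- crossprod(A, dh)
    ds <- A * (dA - rowSums(dA * A))
    dQp[, cols] <- ds %*% cache$Kp[, cols, drop = FALSE] / sqrt(d)
    dKp[, cols] <- crossprod(ds, cache$Qp[, cols, drop = FALSE]) / sqrt(d)
  }
  list(dK = tcrossprod(dKp, p$Wk), dQ = tcrossprod(dQp, p$Wq),
       dV = tcrossprod(dVp, p$Wv),
       dWq = crossprod(cache$Qin, dQp), dWk = crossprod(cache$Kin, dKp),
       dWv = crossprod(cache$Vin, dVp), dWo = dWo)
}

ffn_fwd <- function(x, p) {
  h <- add_row(x %*% p$W_in, p$b_in)
  gate <- gelu_gate(h)
  a <- h * gate
  y <- add_row(a %*% p$W_out, p$b_out)
  list(y = y, h = h, a = a, gate = gate, x = x)
}

ffn_bwd <- function(dy, cache, p) {
  da <- tcrossprod(dy, p$W_out)
  gate <- cache$gate
  dh <- da * (gate + 1.702 * cache$h * gate * (1 - gate))
  list(dx = tcrossprod(dh, p$W_in),
       dW_in = crossprod(cache$x, dh), db_in = colSums(dh),
       dW_out = crossprod(cache$a, dy), db_out = colSums(dy))
}

# Draw an inverted-dropout mask matrix (NULL when rate is 0 / inference).
drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

apply_drop <- function(x, mask) if (is.null(mask)) x else x * mask

# Forward pass with all intermediates cached for the backward pass.
# `train` enables dropout (using the current RNG stream).
forward_cached <- function(params, cfg, tokens, blocks, r, q,
                           train = FALSE) {
  rate <- if (train) cfg$dropout else 0
  s <- nrow(blocks)
  S0 <- blocks %*% params$W_S
  x <- S0 + positional_encoding(s, r, q, cfg)
  enc_cache <- vector("list", cfg$L_enc)
  for (i in seq_along(params$enc)) {
    lp <- params$enc[[i]]
    c1 <- ln_fwd(x, lp$ln1)
    at <- mha_fwd(c1$y, c1$y, c1$y, lp$attn, cfg$H)
    m1 <- drop_mask(s, cfg$f, rate)
    x_mid <- x + apply_drop(at$out, m1)
    c2 <- ln_fwd(x_mid, lp$ln2)
    ff <- ffn_fwd(c2$y, lp$ffn)
    m2 <- drop_mask(s, cfg$f, rate)
    x_out <- x_mid + apply_drop(ff$y, m2)
    enc_cache[[i]] <- list(ln1 = c1, attn = at$cache, m1 = m1,
                           x_mid = x_mid, ln2 = c2, ffn = ff, m2 = m2)
    x <- x_out
  }
  enc_out <- x

  dec_out <- NULL; dec_cache <- NULL
  if (cfg$use_decoder) {
    l <- length(tokens)
    x <- params$E_B[tokens, , drop = FALSE] + seq_positional_encoding(l, cfg$f)
    dec_cache <- vector("list", cfg$L_dec)
    for (i in seq_along(params$dec)) {
      lp <- params$dec[[i]]
      c1 <- ln_fwd(x, lp$ln1)
      sa <- mha_fwd(c1$y, c1$y, c1$y, lp$self_attn, cfg$H)
      m1 <- drop_mask(l, cfg$f, rate)
      x1 <- x + apply_drop(sa$out, m1)
      c2 <- ln_fwd(x1, lp$ln2)
      ca <- mha_fwd(enc_out, c2$y, enc_out, lp$cross_attn, cfg$H)
      m2 <- drop_mask(l, cfg$f, rate)
      x2 <- x1 + apply_drop(ca$out, m2)
      c3 <- ln_fwd(x2, lp$ln3)
      ff <- ffn_fwd(c3$y, lp$ffn)
      m3 <- drop_mask(l, cfg$f, rate)
      x3 <- x2 + apply_drop(ff$y, m3)
      dec_cache[[i]] <- list(ln1 = c1, self = sa$cache, m1 = m1, x1 = x1,
                             ln2 = c2, cross = ca$cache, m2 = m2, x2 = x2,
                             ln3 = c3, ffn = ff, m3 = m3)
      x <- x3
    }
    dec_out <- x
    center <- dec_out[l %/% 2L + 1L, ]
  } else {
    center <- colMeans(enc_out)
  }
  z <- sum(center * params$head_mod$w) + params$head_mod$b
  list(z = z, enc_out = enc_out, dec_out = dec_out,
       enc_cache = enc_cache, dec_cache = dec_cache,
       tokens = tokens, blocks = blocks, s = s)
}

# Gradient accumulator helpers: flat environment keyed by parameter path.
acc_grad <- function(g, nm, d) {
  cur <- g[[nm]]
  g[[nm]] <- if (is.null(cur)) d else cur + d
  invisible(NULL)
}

# Backward pass for one example. dz: scalar dL/dz. dbase: list(pos, dlogits)
# for the base head (1-based decoder rows, n x 4 gradient). denc_extra:
# additional gradient w.r.t. enc_out (e.g. from the signal-class head).
backward_cached <- function(params, cfg, cache, g,
                            dz = 0, dbase = NULL, denc_extra = NULL) {
  f <- cfg$f
  if (cfg$use_decoder) {
    l <- length(cache$tokens)
    ddec <- matrix(0, l, f)
    center_row <- l %/% 2L + 1L
    if (dz != 0) {
      center <- cache$dec_out[center_row, ]
      acc_grad(g, "head_mod.w", dz * center)
      acc_grad(g, "head_mod.b", dz)
      ddec[center_row, ] <- ddec[center_row, ] + dz * params$head_mod$w
    }
    if (!is.null(dbase) && length(dbase$pos) > 0L) {
      rows <- cache$dec_out[dbase$pos, , drop = FALSE]
      acc_grad(g, "head_base.W", t(rows) %*% dbase$dlogits)
      acc_grad(g, "head_base.b", colSums(dbase$dlogits))
      ddec[dbase$pos, ] <- ddec[dbase$pos, , drop = FALSE] +
        dbase$dlogits %*% t(params$head_base$W)
    }
    denc <- if (is.null(denc_extra)) matrix(0, cache$s, f) else denc_extra
    for (i in rev(seq_along(params$dec))) {
      lp <- params$dec[[i]]; cc <- cache$dec_cache[[i]]
      # FFN sublayer
      dffn_out <- apply_drop(ddec, cc$m3)
      fb <- ffn_bwd(dffn_out, cc$ffn, lp$ffn)
      acc_grad(g, sprintf("dec.%d.ffn.W_in", i), fb$dW_in)
      acc_grad(g, sprintf("dec.%d.ffn.b_in", i), fb$db_in)
      acc_grad(g, sprintf("dec.%d.ffn.W_out", i), fb$dW_out)
      acc_grad(g, sprintf("dec.%d.ffn.b_out", i), fb$db_out)
      lb <- ln_bwd(fb$dx, cc$ln3, lp$ln3)
      acc_grad(g, sprintf("dec.%d.ln3.g", i), lb$dg)
      acc_grad(g, sprintf("dec.%d.ln3.b", i), lb$db)
      dx2 <- ddec + lb$dx
      # Cross-attention sublayer
      dca_out <- apply_drop(dx2, cc$m2)
      ab <- mha_bwd(dca_out, cc$cross, lp$cross_attn)
      acc_grad(g, sprintf("dec.%d.cross_attn.Wq", i), ab$dWq)
      acc_grad(g, sprintf("dec.%d.cross_attn.Wk", i), ab$dWk)
      acc_grad(g, sprintf("dec.%d.cross_attn.Wv", i), ab$dWv)
      acc_grad(g, sprintf("dec.%d.cross_attn.Wo", i), ab$dWo)
      denc <- denc + ab$dK + ab$dV
      lb <- ln_bwd(ab$dQ, cc$ln2, lp$ln2)
      acc_grad(g, sprintf("dec.%d.ln2.g", i), lb$dg)
      acc_grad(g, sprintf("dec.%d.ln2.b", i), lb$db)
      dx1 <- dx2 + lb$dx
      # Self-attention sublayer
      dsa_out <- apply_drop(dx1, cc$m1)
      sb <- mha_bwd(dsa_out, cc$self, lp$self_attn)
      acc_grad(g, sprintf("dec.%d.self_attn.Wq", i), sb$dWq)
      acc_grad(g, sprintf("dec.%d.self_attn.Wk", i), sb$dWk)
      acc_grad(g, sprintf("dec.%d.self_attn.Wv", i), sb$dWv)
      acc_grad(g, sprintf("dec.%d.self_attn.Wo", i), sb$dWo)
      lb <- ln_bwd(sb$dK + sb$dQ + sb$dV, cc$ln1, lp$ln1)
      acc_grad(g, sprintf("dec.%d.ln1.g", i), lb$dg)
      acc_grad(g, sprintf("dec.%d.ln1.b", i), lb$db)
      ddec <- dx1 + lb$dx
    }
    # Embedding rows
    dEB <- matrix(0, cfg$vocab, f)
    for (t in seq_along(cache$tokens)) {
      dEB[cache$tokens[t], ] <- dEB[cache$tokens[t], ] + ddec[t, ]
    }
    acc_grad(g, "E_B", dEB)
  } else {
    denc <- if (is.null(denc_extra)) matrix(0, cache$s, f) else denc_extra
    if (dz != 0) {
      center <- colMeans(cache$enc_out)
      acc_grad(g, "head_mod.w", dz * center)
      acc_grad(g, "head_mod.b", dz)
      denc <- denc + matrix(dz * params$head_mod$w / cache$s, cache$s, f,
                            byrow = TRUE)
    }
  }

  for (i in rev(seq_along(params$enc))) {
    lp <- params$enc[[i]]; cc <- cache$enc_cache[[i]]
    dffn_out <- apply_drop(denc, cc$m2)
    fb <- ffn_bwd(dffn_out, cc$ffn, lp$ffn)
    acc_grad(g, sprintf("enc.%d.ffn.W_in", i), fb$dW_in)
    acc_grad(g, sprintf("enc.%d.ffn.b_in", i), fb$db_in)
    acc_grad(g, sprintf("enc.%d.ffn.W_out", i), fb$dW_out)
    acc_grad(g, sprintf("enc.%d.ffn.b_out", i), fb$db_out)
    lb <- ln_bwd(fb$dx, cc$ln2, lp$ln2)
    acc_grad(g, sprintf("enc.%d.ln2.g", i), lb$dg)
    acc_grad(g, sprintf("enc.%d.ln2.b", i), lb$db)
    dx_mid <- denc + lb$dx
    dat_out <- apply_drop(dx_mid, cc$m1)
    ab <- mha_bwd(dat_out, cc$attn, lp$attn)
    acc_grad(g, sprintf("enc.%d.attn.Wq", i), ab$dWq)
    acc_grad(g, sprintf("enc.%d.attn.Wk", i), ab$dWk)
    acc_grad(g, sprintf("enc.%d.attn.Wv", i), ab$dWv)
    acc_grad(g, sprintf("enc.%d.attn.Wo", i), ab$dWo)
    lb <- ln_bwd(ab$dK + ab$dQ + ab$dV, cc$ln1, lp$ln1)
    acc_grad(g, sprintf("enc.%d.ln1.g", i), lb$dg)
    acc_grad(g, sprintf("enc.%d.ln1.b", i), lb$db)
    denc <- dx_mid + lb$dx
  }
  acc_grad(g, "W_S", t(cache$blocks) %*% denc)
  invisible(NULL)
}

# Flatten structured parameters to the flat name space used by the
# gradient accumulator and optimizer, and back.
flatten_params <- function(p) {
  out <- list()
  out[["W_S"]] <- p$W_S
  out[["E_B"]] <- p$E_B
  for (i in seq_along(p$enc)) {
    lp <- p$enc[[i]]
    for (nm in names(lp$ln1)) out[[sprintf("enc.%d.ln1.%s", i, nm)]] <- lp$ln1[[nm]]
    for (nm in names(lp$attn)) out[[sprintf("enc.%d.attn.%s", i, nm)]] <- lp$attn[[nm]]
    for (nm in names(lp$ln2)) out[[sprintf("enc.%d.ln2.%s", i, nm)]] <- lp$ln2[[nm]]
    for (nm in names(lp$ffn)) out[[sprintf("enc.%d.ffn.%s", i, nm)]] <- lp$ffn[[nm]]
  }
  for (i in seq_along(p$dec)) {
    lp <- p$dec[[i]]
    for (nm in names(lp$ln1)) out[[sprintf("dec.%d.ln1.%s", i, nm)]] <- lp$ln1[[nm]]
    for (nm in names(lp$self_attn)) out[[sprintf("dec.%d.self_attn.%s", i, nm)]] <- lp$self_attn[[nm]]
    for (nm in names(lp$ln2)) out[[sprintf("dec.%d.ln2.%s", i, nm)]] <- lp$ln2[[nm]]
    for (nm in names(lp$cross_attn)) out[[sprintf("dec.%d.cross_attn.%s", i, nm)]] <- lp$cross_attn[[nm]]
    for (nm in names(lp$ln3)) out[[sprintf("dec.%d.ln3.%s", i, nm)]] <- lp$ln3[[nm]]
    for (nm in names(lp$ffn)) out[[sprintf("dec.%d.ffn.%s", i, nm)]] <- lp$ffn[[nm]]
  }
  out[["head_mod.w"]] <- p$head_mod$w
  out[["head_mod.b"]] <- p$head_mod$b
  out[["head_base.W"]] <- p$head_base$W
  out[["head_base.b"]] <- p$head_base$b
  out[["codebook"]] <- p$codebook
  out
}

unflatten_params <- function(flat, template) {
  p <- template
  p$W_S <- flat[["W_S"]]; p$E_B <- flat[["E_B"]]
  for (i in seq_along(p$enc)) {
    for (nm in names(p$enc[[i]]$ln1)) p$enc[[i]]$ln1[[nm]] <- flat[[sprintf("enc.%d.ln1.%s", i, nm)]]
    for (nm in names(p$enc[[i]]$attn)) p$enc[[i]]$attn[[nm]] <- flat[[sprintf("enc.%d.attn.%s", i, nm)]]
    for (nm in names(p$enc[[i]]$ln2)) p$enc[[i]]$ln2[[nm]] <- flat[[sprintf("enc.%d.ln2.%s", i, nm)]]
    for (nm in names(p$enc[[i]]$ffn)) p$enc[[i]]$ffn[[nm]] <- flat[[sprintf("enc.%d.ffn.%s", i, nm)]]
  }
  for (i in seq_along(p$dec)) {
    for (nm in names(p$dec[[i]]$ln1)) p$dec[[i]]$ln1[[nm]] <- flat[[sprintf("dec.%d.ln1.%s", i, nm)]]
    for (nm in names(p$dec[[i]]$self_attn)) p$dec[[i]]$self_attn[[nm]] <- flat[[sprintf("dec.%d.self_attn.%s", i, nm)]]
    for (nm in names(p$dec[[i]]$ln2)) p$dec[[i]]$ln2[[nm]] <- flat[[sprintf("dec.%d.ln2.%s", i, nm)]]
    for (nm in names(p$dec[[i]]$cross_attn)) p$dec[[i]]$cross_attn[[nm]] <- flat[[sprintf("dec.%d.cross_attn.%s", i, nm)]]
    for (nm in names(p$dec[[i]]$ln3)) p$dec[[i]]$ln3[[nm]] <- flat[[sprintf("dec.%d.ln3.%s", i, nm)]]
    for (nm in names(p$dec[[i]]$ffn)) p$dec[[i]]$ffn[[nm]] <- flat[[sprintf("dec.%d.ffn.%s", i, nm)]]
  }
  p$head_mod$w <- flat[["head_mod.w"]]; p$head_mod$b <- flat[["head_mod.b"]]
  p$head_base$W <- flat[["head_base.W"]]; p$head_base$b <- flat[["head_base.b"]]
  p$codebook <- flat[["codebook"]]
  p
}
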