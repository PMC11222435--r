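# Batched forward/backward over a list of examples: every row-wise
# operation (projections, layer norm, feed-forward, dropout, residuals)
# runs once on the row-concatenated matrices of the whole batch; only the
# attention softmax loops over examples (and heads), since attention must
# not mix rows of different examples. Produces gradients identical to the
# per-example path.

# Row index bookkeeping for a batch: signal rows vary per example, token
# rows are a fixed l per example.
batch_index <- function(batch, l) {
  svec <- vapply(batch, function(ex) nrow(ex$blocks), integer(1))
  soff <- cumsum(c(0L, svec))
  list(svec = svec, soff = soff, n_sig = sum(svec),
       B = length(batch), l = l)
}

sig_rows <- function(bi, b) (bi$soff[b] + 1L):(bi$soff[b + 1L])
tok_rows <- function(bi, b) ((b - 1L) * bi$l + 1L):(b * bi$l)

# Per-example multi-head attention over concatenated projections.
attn_apply <- function(Qp, Kp, Vp, bi, rows_q, rows_k, H, d) {
  heads <- matrix(0, nrow(Qp), ncol(Qp))
  A <- vector("list", bi$B)
  for (b in seq_len(bi$B)) {
    rq <- rows_q(bi, b); rk <- rows_k(bi, b)
    Ab <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      sc <- tcrossprod(Qp[rq, cols, drop = FALSE],
                       Kp[rk, cols, drop = FALSE]) / sqrt(d)
      Ab[[h]] <- softmax_rows(sc)
      heads[rq, cols] <- Ab[[h]] %*% Vp[rk, cols, drop = FALSE]
    }
    A[[b]] <- Ab
  }
  list(heads = heads, A = A)
}

attn_apply_bwd <- function(dheads, A, Qp, Kp, Vp, bi, rows_q, rows_k, H, d) {
  dQp <- matrix(0, nrow(Qp), ncol(Qp))
  dKp <- matrix(0, nrow(Kp), ncol(Kp))
  dVp <- matrix(0, nrow(Vp), ncol(Vp))
  for (b in seq_len(bi$B)) {
    rq <- rows_q(bi, b); rk <- rows_k(bi, b)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      Ab <- A[[b]][[h]]
      dh <- dheads[rq, cols, drop = FALSE]
      dA <- tcrossprod(dh, Vp[rk, cols, drop = FALSE])
      dVp[rk, cols] <- dVp[rk, cols, drop = FALSE] + crossprod(Ab, dh)
      ds <- Ab * (dA - rowSums(dA * Ab))
      dQp[rq, cols] <- ds %*% Kp[rk, cols, drop = FALSE] / sqrt(d)
      dKp[rk, cols] <- dKp[rk, cols, drop = FALSE] +
        crossprod(ds, Qp[rq, cols, drop = FALSE]) / sqrt(d)
    }
  }
  list(dQp = dQp, dKp = dKp, dVp = dVp)
}

forward_batch <- function(params, cfg, batch, train = FALSE) {
  rate <- if (train) cfg$dropout else 0
  H <- cfg$H; d <- cfg$d; f <- cfg$f; l <- cfg$l
  bi <- batch_index(batch, l)
  X <- do.call(rbind, lapply(batch, `[[`, "blocks"))
  P <- do.call(rbind, lapply(batch, function(ex) {
    positional_encoding(nrow(ex$blocks), ex$r, ex$q, cfg)
  }))
  x <- X %*% params$W_S + P
  enc_cache <- vector("list", cfg$L_enc)
  for (i in seq_along(params$enc)) {
    lp <- params$enc[[i]]
    c1 <- ln_fwd(x, lp$ln1)
    Qp <- c1$y %*% lp$attn$Wq; Kp <- c1$y %*% lp$attn$Wk
    Vp <- c1$y %*% lp$attn$Wv
    aa <- attn_apply(Qp, Kp, Vp, bi, sig_rows, sig_rows, H, d)
    m1 <- drop_mask(bi$n_sig, f, rate)
    x_mid <- x + apply_drop(aa$heads %*% lp$attn$Wo, m1)
    c2 <- ln_fwd(x_mid, lp$ln2)
    ff <- ffn_fwd(c2$y, lp$ffn)
    m2 <- drop_mask(bi$n_sig, f, rate)
    x_out <- x_mid + apply_drop(ff$y, m2)
    enc_cache[[i]] <- list(ln1 = c1, Qp = Qp, Kp = Kp, Vp = Vp, A = aa$A,
                           heads = aa$heads, m1 = m1, x_mid = x_mid,
                           ln2 = c2, ffn = ff, m2 = m2)
    x <- x_out
  }
  enc_out <- x

  dec_out <- NULL; dec_cache <- NULL; tokens_all <- NULL
  if (cfg$use_decoder) {
    tokens_all <- unlist(lapply(batch, `[[`, "tokens"))
    x <- params$E_B[tokens_all, , drop = FALSE] +
      seq_positional_encoding(l, f)[rep(seq_len(l), bi$B), , drop = FALSE]
    dec_cache <- vector("list", cfg$L_dec)
    for (i in seq_along(params$dec)) {
      lp <- params$dec[[i]]
      c1 <- ln_fwd(x, lp$ln1)
      Qp <- c1$y %*% lp$self_attn$Wq; Kp <- c1$y %*% lp$self_attn$Wk
      Vp <- c1$y %*% lp$self_attn$Wv
      sa <- attn_apply(Qp, Kp, Vp, bi, tok_rows, tok_rows, H, d)
      m1 <- drop_mask(bi$B * l, f, rate)
      x1 <- x + apply_drop(sa$heads %*% lp$self_attn$Wo, m1)
      c2 <- ln_fwd(x1, lp$ln2)
      Qp2 <- c2$y %*% lp$cross_attn$Wq
      Kp2 <- enc_out %*% lp$cross_attn$Wk
      Vp2 <- enc_out %*% lp$cross_attn$Wv
      ca <- attn_apply(Qp2, Kp2, Vp2, bi, tok_rows, sig_rows, H, d)
      m2 <- drop_mask(bi$B * l, f, rate)
      x2 <- x1 + apply_drop(ca$heads %*% lp$cross_attn$Wo, m2)
      c3 <- ln_fwd(x2, lp$ln3)
      ff <- ffn_fwd(c3$y, lp$ffn)
      m3 <- drop_mask(bi$B * l, f, rate)
      x3 <- x2 + apply_drop(ff$y, m3)
      dec_cache[[i]] <- list(ln1 = c1, sQp = Qp, sKp = Kp, sVp = Vp,
                             sA = sa$A, sheads = sa$heads, m1 = m1, x1 = x1,
                             ln2 = c2, cQp = Qp2, cKp = Kp2, cVp = Vp2,
                             cA = ca$A, cheads = ca$heads, m2 = m2, x2 = x2,
                             ln3 = c3, ffn = ff, m3 = m3)
      x <- x3
    }
    dec_out <- x
    center_rows <- (seq_len(bi$B) - 1L) * l + (l %/% 2L + 1L)
    centers <- dec_out[center_rows, , drop = FALSE]
  } else {
    centers <- do.call(rbind, lapply(seq_len(bi$B), function(b) {
      colMeans(enc_out[sig_rows(bi, b), , drop = FALSE])
    }))
    center_rows <- NULL
  }
  z <- as.numeric(centers %*% params$head_mod$w) + params$head_mod$b
  list(z = z, enc_out = enc_out, dec_out = dec_out, centers = centers,
       center_rows = center_rows, enc_cache = enc_cache,
       dec_cache = dec_cache, tokens_all = tokens_all, X = X, bi = bi)
}

# Backward over the batch. dz: length-B vector; ddec_extra/denc_extra:
# gradients w.r.t. dec_out/enc_out rows (concatenated), may be NULL.
backward_batch <- function(params, cfg, cache, g, dz,
                           ddec_extra = NULL, denc_extra = NULL) {
  f <- cfg$f; H <- cfg$H; d <- cfg$d; l <- cfg$l
  bi <- cache$bi
  if (cfg$use_decoder) {
    ddec <- if (is.null(ddec_extra)) matrix(0, bi$B * l, f) else ddec_extra
    acc_grad(g, "head_mod.w", as.numeric(crossprod(cache$centers, dz)))
    acc_grad(g, "head_mod.b", sum(dz))
    ddec[cache$center_rows, ] <- ddec[cache$center_rows, , drop = FALSE] +
      outer(dz, params$head_mod$w)
    denc <- if (is.null(denc_extra)) matrix(0, bi$n_sig, f) else denc_extra
    for (i in rev(seq_along(params$dec))) {
      lp <- params$dec[[i]]; cc <- cache$dec_cache[[i]]
      fb <- ffn_bwd(apply_drop(ddec, cc$m3), cc$ffn, lp$ffn)
      acc_grad(g, sprintf("dec.%d.ffn.W_in", i), fb$dW_in)
      acc_grad(g, sprintf("dec.%d.ffn.b_in", i), fb$db_in)
      acc_grad(g, sprintf("dec.%d.ffn.W_out", i), fb$dW_out)
      acc_grad(g, sprintf("dec.%d.ffn.b_out", i), fb$db_out)
      lb <- ln_bwd(fb$dx, cc$ln3, lp$ln3)
      acc_grad(g, sprintf("dec.%d.ln3.g", i), lb$dg)
      acc_grad(g, sprintf("dec.%d.ln3.b", i), lb$db)
      dx2 <- ddec + lb$dx
      # cross-attention
      dca_out <- apply_drop(dx2, cc$m2)
      acc_grad(g, sprintf("dec.%d.cross_attn.Wo", i),
               crossprod(cc$cheads, dca_out))
      dheads <- tcrossprod(dca_out, lp$cross_attn$Wo)
      ab <- attn_apply_bwd(dheads, cc$cA, cc$cQp, cc$cKp, cc$cVp, bi,
                           tok_rows, sig_rows, H, d)
      acc_grad(g, sprintf("dec.%d.cross_attn.Wq", i),
               crossprod(cc$ln2$y, ab$dQp))
      acc_grad(g, sprintf("dec.%d.cross_attn.Wk", i),
               crossprod(cache$enc_out, ab$dKp))
      acc_grad(g, sprintf("dec.%d.cross_attn.Wv", i),
               crossprod(cache$enc_out, ab$dVp))
      denc <- denc + tcrossprod(ab$dKp, lp$cross_attn$Wk) +
        tcrossprod(ab$dVp, lp$cross_attn$Wv)
      lb <- ln_bwd(tcrossprod(ab$dQp, lp$cross_attn$Wq), cc$ln2, lp$ln2)
      acc_grad(g, sprintf("dec.%d.ln2.g", i), lb$dg)
      acc_grad(g, sprintf("dec.%d.ln2.b", i), lb$db)
      dx1 <- dx2 + lb$dx
      # self-attention
      dsa_out <- apply_drop(dx1, cc$m1)
      acc_grad(g, sprintf("dec.%d.self_attn.Wo", i),
               crossprod(cc$sheads, dsa_out))
      dheads <- tcrossprod(dsa_out, lp$self_attn$Wo)
      sb <- attn_apply_bwd(dheads, cc$sA, cc$sQp, cc$sKp, cc$sVp, bi,
                           tok_rows, tok_rows, H, d)
      acc_grad(g, sprintf("dec.%d.self_attn.Wq", i),
               crossprod(cc$ln1$y, sb$dQp))
      acc_grad(g, sprintf("dec.%d.self_attn.Wk", i),
               crossprod(cc$ln1$y, sb$dKp))
      acc_grad(g, sprintf("dec.%d.self_attn.Wv", i),
               crossprod(cc$ln1$y, sb$dVp))
      dn1 <- tcrossprod(sb$dQp, lp$self_attn$Wq) +
        tcrossprod(sb$dKp, lp$self_attn$Wk) +
        tcrossprod(sb$dVp, lp$self_attn$Wv)
      lb <- ln_bwd(dn1, cc$ln1, lp$ln1)
      acc_grad(g, sprintf("dec.%d.ln1.g", i), lb$dg)
      acc_grad(g, sprintf("dec.%d.ln1.b", i), lb$db)
      ddec <- dx1 + lb$dx
    }
    dEB <- matrix(0, cfg$vocab, f)
    for (v in seq_len(cfg$vocab)) {
      sel <- cache$tokens_all == v
      if (any(sel)) dEB[v, ] <- colSums(ddec[sel, , drop = FALSE])
    }
    acc_grad(g, "E_B", dEB)
  } else {
    denc <- if (is.null(denc_extra)) matrix(0, bi$n_sig, f) else denc_extra
    acc_grad(g, "head_mod.w", as.numeric(crossprod(cache$centers, dz)))
    acc_grad(g, "head_mod.b", sum(dz))
    for (b in seq_len(bi$B)) {
      rs <- sig_rows(bi, b)
      denc[rs, ] <- denc[rs, , drop = FALSE] +
        matrix(dz[b] * params$head_mod$w / bi$svec[b], bi$svec[b], f,
               byrow = TRUE)
    }
  }

  for (i in rev(seq_along(params$enc))) {
    lp <- params$enc[[i]]; cc <- cache$enc_cache[[i]]
    fb <- ffn_bwd(apply_drop(denc, cc$m2), cc$ffn, lp$ffn)
    acc_grad(g, sprintf("enc.%d.ffn.W_in", i), fb$dW_in)
    acc_grad(g, sprintf("enc.%d.ffn.b_in", i), fb$db_in)
    acc_grad(g, sprintf("enc.%d.ffn.W_out", i), fb$dW_out)
    acc_grad(g, sprintf("enc.%d.ffn.b_out", i), fb$db_out)
    lb <- ln_bwd(fb$dx, cc$ln2, lp$ln2)
    acc_grad(g, sprintf("enc.%d.ln2.g", i), lb$dg)
    acc_grad(g, sprintf("enc.%d.ln2.b", i), lb$db)
    dx_mid <- denc + lb$dx
    dat_out <- apply_drop(dx_mid, cc$m1)
    acc_grad(g, sprintf("enc.%d.attn.Wo", i), crossprod(cc$heads, dat_out))
    dheads <- tcrossprod(dat_out, lp$attn$Wo)
    ab <- attn_apply_bwd(dheads, cc$A, cc$Qp, cc$Kp, cc$Vp, bi,
                         sig_rows, sig_rows, H, d)
    acc_grad(g, sprintf("enc.%d.attn.Wq", i), crossprod(cc$ln1$y, ab$dQp))
    acc_grad(g, sprintf("enc.%d.attn.Wk", i), crossprod(cc$ln1$y, ab$dKp))
    acc_grad(g, sprintf("enc.%d.attn.Wv", i), crossprod(cc$ln1$y, ab$dVp))
    dn1 <- tcrossprod(ab$dQp, lp$attn$Wq) + tcrossprod(ab$dKp, lp$attn$Wk) +
      tcrossprod(ab$dVp, lp$attn$Wv)
    lb <- ln_bwd(dn1, cc$ln1, lp$ln1)
    acc_grad(g, sprintf("enc.%d.ln1.g", i), lb$dg)
    acc_grad(g, sprintf("enc.%d.ln1.b", i), lb$db)
    denc <- dx_mid + lb$dx
  }
  acc_grad(g, "W_S", crossprod(cache$X, denc))
  invisible(NULL)
}
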