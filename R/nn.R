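# Internal neural-network primitives.
#
# The network is small enough (and the install environment CPU-only) that
# the forward and backward passes are written directly against BLAS-backed
# base-R matrix operations. Batches are laid out sample-major: a tensor of
# shape (B, L, F) is stored as a (B*L) x F matrix whose rows
# (b-1)*L + 1 .. b*L belong to sample b. Correctness of every gradient is
# pinned by a finite-difference check in the test suite.

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_model_params <- function(cfg, in_dim) {
  K <- cfg$conv_kernel; F <- cfg$conv_filters
  d1 <- cfg$ffn_dense1; ah <- cfg$attn_hidden
  lim_c <- sqrt(6 / (in_dim * K + F))
  conv_init <- function() array(runif(in_dim * K * F, -lim_c, lim_c), dim = c(in_dim, K, F))
  list(
    conv_e_W = conv_init(), conv_e_b = numeric(F),
    conv_p_W = conv_init(), conv_p_b = numeric(F),
    Wq = glorot_mat(F, F), bq = numeric(F),
    Wk = glorot_mat(F, F), bk = numeric(F),
    Wv = glorot_mat(F, F), bv = numeric(F),
    # residual-identity init: the output projections of both sublayers start
    # at zero, so the block begins as stacked layer norms and the conv
    # filters see a direct gradient path; the projections grow from their
    # (non-zero) gradients as training proceeds
    Wo = matrix(0, F, F), bo = numeric(F),
    ln1_g = rep(1, F), ln1_b = numeric(F),
    f1_W = glorot_mat(F, d1), f1_b = numeric(d1),
    f2_W = matrix(0, d1, F), f2_b = numeric(F),
    ln2_g = rep(1, F), ln2_b = numeric(F),
    att_Wh = glorot_mat(F, ah), att_bh = numeric(ah),
    att_uc = runif(ah, -sqrt(3 / ah), sqrt(3 / ah)),
    out_w = glorot_mat(F, 1L), out_b = 0
  )
}

# m += v per row, in place; every call site passes a freshly allocated
# temporary (typically a matmul result), so the mutation is unobservable.
add_rowvec <- function(m, v) cpp_add_rowvec(m, v)

# ---- convolution branch (valid padding, stride 1, ReLU) ------------------

# input: list(kind = "index", iv = sample-major index vector 1..5) or
#        list(kind = "dense", X = (B*Lin) x d matrix); plus B, Lin.
# In index mode the kernel is routed through the frozen one-hot lookup:
# W5[, , o] = lookup %*% W[, o, ], so mutating the lookup would change the
# model (and the frozen-ness test would catch it).
conv_forward <- function(input, W, b, lookup) {
  K <- dim(W)[2L]; F <- dim(W)[3L]
  B <- input$B; Lin <- input$Lin
  Lc <- Lin - K + 1L
  base <- rep.int((seq_len(B) - 1L) * Lin, rep.int(Lc, B))
  if (input$kind == "index") {
    W5 <- array(0, dim = c(nrow(lookup), F, K))
    for (o in seq_len(K)) W5[, , o] <- lookup %*% W[, o, ]
    act <- cpp_conv_forward(input$iv, W5, b, B, Lin, TRUE)
  } else {
    acc <- matrix(0, B * Lc, F)
    for (o in seq_len(K)) {
      rows <- base + seq.int(o, length.out = Lc)
      acc <- acc + input$X[rows, , drop = FALSE] %*% W[, o, ]
    }
    act <- pmax(add_rowvec(acc, b), 0)
  }
  # relu(pre) > 0 iff pre > 0, so the mask is recoverable from act
  list(act = act, mask = act > 0, B = B, Lc = Lc, base = base)
}

conv_backward <- function(dact, cv, input, W, lookup) {
  K <- dim(W)[2L]; F <- dim(W)[3L]
  dpre <- dact * cv$mask
  dW <- array(0, dim = dim(W))
  if (input$kind == "index") {
    d5 <- cpp_conv_backward_w(dpre, input$iv, input$B, input$Lin, K)
    for (o in seq_len(K)) dW[, o, ] <- crossprod(lookup, d5[, , o])
  } else {
    for (o in seq_len(K)) {
      rows <- cv$base + seq.int(o, length.out = cv$Lc)
      dW[, o, ] <- crossprod(input$X[rows, , drop = FALSE], dpre)
    }
  }
  list(dW = dW, db = colSums(dpre))
}

# ---- max pooling ---------------------------------------------------------

maxpool_forward <- function(act, B, Lc, P, S) {
  cpp_maxpool_forward(act, B, Lc, P, S)
}

maxpool_backward <- function(dout, arg, B, Lc) {
  cpp_maxpool_backward(dout, arg, B, Lc)
}

# ---- layer norm (normalises across the feature axis) ---------------------

layernorm_forward <- function(x, g, b, eps = 1e-5) {
  cpp_layernorm_forward(x, g, b, eps)
}

layernorm_backward <- function(dy, ln, g) {
  out <- cpp_layernorm_backward(dy, ln$xhat, ln$inv, g)
  list(dx = out$dx, dg = as.numeric(out$dg), db = as.numeric(out$db))
}

# ---- multi-head scaled dot-product self-attention ------------------------

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# Attention maps are cached as a flat array with dim (Lm, Lm, B*nh), slice
# index (b-1)*nh + h; as_head_array() extracts one sample in the public
# n_heads x Lm x Lm layout.
as_head_array <- function(A, b, nh, Lm) {
  dim(A) <- c(Lm, Lm, length(A) %/% (Lm * Lm))
  aperm(A[, , (b - 1L) * nh + seq_len(nh), drop = FALSE], c(3L, 1L, 2L))
}

mha_forward <- function(X, p, B, Lm, nh, dh, keep_attn, attn_buf = NULL) {
  Q <- add_rowvec(X %*% p$Wq, p$bq)
  K <- add_rowvec(X %*% p$Wk, p$bk)
  V <- add_rowvec(X %*% p$Wv, p$bv)
  need <- Lm * Lm * B * nh
  A <- if (!keep_attn) numeric()
       else if (!is.null(attn_buf) && length(attn_buf) == need) attn_buf
       else numeric(need)
  Ctx <- cpp_mha_forward(Q, K, V, B, Lm, nh, dh, A)
  O <- add_rowvec(Ctx %*% p$Wo, p$bo)
  list(O = O, Q = Q, K = K, V = V, Ctx = Ctx, A = if (keep_attn) A else NULL)
}

mha_backward <- function(dO, mh, X, p, B, Lm, nh, dh) {
  g <- list(Wo = crossprod(mh$Ctx, dO), bo = colSums(dO))
  dCtx <- dO %*% t(p$Wo)
  bk <- cpp_mha_backward(dCtx, mh$A, mh$Q, mh$K, mh$V, B, Lm, nh, dh)
  g$Wq <- crossprod(X, bk$dQ); g$bq <- colSums(bk$dQ)
  g$Wk <- crossprod(X, bk$dK); g$bk <- colSums(bk$dK)
  g$Wv <- crossprod(X, bk$dV); g$bv <- colSums(bk$dV)
  g$dX <- bk$dQ %*% t(p$Wq) + bk$dK %*% t(p$Wk) + bk$dV %*% t(p$Wv)
  g
}

# ---- hierarchical attention pooling --------------------------------------

hier_forward <- function(H, p, B, Lm) {
  n <- B * Lm
  U <- tanh(add_rowvec(H %*% p$att_Wh, p$att_bh))
  sc <- matrix(as.vector(U %*% p$att_uc), Lm, B)   # column = one sample
  mx <- apply(sc, 2L, max)
  E <- exp(sc - rep(mx, each = Lm))
  Wt <- E / rep(colSums(E), each = Lm)
  w <- as.vector(Wt)
  grp <- rep.int(seq_len(B), rep.int(Lm, B))
  S <- rowsum(H * w, grp, reorder = FALSE)
  list(S = S, U = U, w = w, grp = grp)
}

hier_backward <- function(dS, hi, H, p, B, Lm) {
  dSexp <- dS[hi$grp, , drop = FALSE]
  dw <- rowSums(dSexp * H)
  sb <- as.vector(rowsum(hi$w * dw, hi$grp, reorder = FALSE))
  dsc <- hi$w * (dw - sb[hi$grp])
  dU <- tcrossprod(dsc, p$att_uc)
  duc <- as.vector(crossprod(hi$U, dsc))
  dpre <- dU * (1 - hi$U^2)
  dH <- dSexp * hi$w + dpre %*% t(p$att_Wh)
  list(dH = dH, dWh = crossprod(H, dpre), dbh = colSums(dpre), duc = duc)
}

# ---- dropout (inverted) --------------------------------------------------

dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((runif(n * m) >= p) / (1 - p), n, m)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- full forward / backward ---------------------------------------------

nn_forward <- function(params, cfg, in_e, in_p, lookup,
                       train = FALSE, keep_attn = FALSE, attn_buf = NULL) {
  B <- in_e$B
  F <- cfg$conv_filters
  Lm <- cfg$L_merged; Le <- cfg$L_enh; Lp <- cfg$L_prom
  drop <- if (train) cfg$dropout else 0

  cv_e <- conv_forward(in_e, params$conv_e_W, params$conv_e_b, lookup)
  cv_p <- conv_forward(in_p, params$conv_p_W, params$conv_p_b, lookup)
  pl_e <- maxpool_forward(cv_e$act, B, cv_e$Lc, cfg$pool_size, cfg$pool_stride)
  pl_p <- maxpool_forward(cv_p$act, B, cv_p$Lc, cfg$pool_size, cfg$pool_stride)
  stopifnot(pl_e$Lp == Le, pl_p$Lp == Lp)

  tgt_e <- rep.int((seq_len(B) - 1L) * Lm, rep.int(Le, B)) + seq_len(Le)
  tgt_p <- rep.int((seq_len(B) - 1L) * Lm, rep.int(Lp, B)) + Le + seq_len(Lp)
  M <- matrix(0, B * Lm, F)
  M[tgt_e, ] <- pl_e$out
  M[tgt_p, ] <- pl_p$out

  m0 <- dropout_mask(B * Lm, F, drop)
  X <- apply_mask(M, m0)

  mh <- mha_forward(X, params, B, Lm, cfg$n_heads, cfg$head_dim,
                    keep_attn = keep_attn || train, attn_buf = attn_buf)
  m1 <- dropout_mask(B * Lm, F, drop)
  R1 <- X + apply_mask(mh$O, m1)
  ln1 <- layernorm_forward(R1, params$ln1_g, params$ln1_b)

  Z1pre <- add_rowvec(ln1$y %*% params$f1_W, params$f1_b)
  Z1 <- pmax(Z1pre, 0)
  Z2 <- add_rowvec(Z1 %*% params$f2_W, params$f2_b)
  m2 <- dropout_mask(B * Lm, F, drop)
  R2 <- ln1$y + apply_mask(Z2, m2)
  ln2 <- layernorm_forward(R2, params$ln2_g, params$ln2_b)

  hi <- hier_forward(ln2$y, params, B, Lm)
  logits <- as.vector(hi$S %*% params$out_w) + params$out_b
  probs <- 1 / (1 + exp(-logits))

  attn_out <- if (keep_attn)
    lapply(seq_len(B), function(b) as_head_array(mh$A, b, cfg$n_heads, Lm))
    else NULL

  list(probs = probs, logits = logits, attn = attn_out,
       cache = if (train) list(cv_e = cv_e, cv_p = cv_p, pl_e = pl_e, pl_p = pl_p,
                               tgt_e = tgt_e, tgt_p = tgt_p, X = X, mh = mh,
                               ln1 = ln1, Z1 = Z1, Z1mask = Z1pre > 0, ln2 = ln2,
                               hi = hi, m0 = m0, m1 = m1, m2 = m2, B = B,
                               in_e = in_e, in_p = in_p) else NULL,
       hier_weights = matrix(hi$w, B, Lm, byrow = TRUE))
}

nn_backward <- function(dlogit, fw, params, cfg, lookup) {
  cc <- fw$cache
  B <- cc$B; F <- cfg$conv_filters; Lm <- cfg$L_merged
  g <- list()
  g$out_w <- crossprod(cc$hi$S, matrix(dlogit, ncol = 1L))
  g$out_b <- sum(dlogit)
  dS <- outer(dlogit, as.vector(params$out_w))

  hb <- hier_backward(dS, cc$hi, cc$ln2$y, params, B, Lm)
  g$att_Wh <- hb$dWh; g$att_bh <- hb$dbh; g$att_uc <- hb$duc

  l2 <- layernorm_backward(hb$dH, cc$ln2, params$ln2_g)
  g$ln2_g <- l2$dg; g$ln2_b <- l2$db
  dR2 <- l2$dx
  dZ2 <- apply_mask(dR2, cc$m2)
  g$f2_W <- crossprod(cc$Z1, dZ2); g$f2_b <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(params$f2_W)) * cc$Z1mask
  g$f1_W <- crossprod(cc$ln1$y, dZ1); g$f1_b <- colSums(dZ1)
  dln1y <- dR2 + dZ1 %*% t(params$f1_W)

  l1 <- layernorm_backward(dln1y, cc$ln1, params$ln1_g)
  g$ln1_g <- l1$dg; g$ln1_b <- l1$db
  dR1 <- l1$dx
  dO <- apply_mask(dR1, cc$m1)
  mb <- mha_backward(dO, cc$mh, cc$X, params, B, Lm, cfg$n_heads, cfg$head_dim)
  g$Wq <- mb$Wq; g$bq <- mb$bq; g$Wk <- mb$Wk; g$bk <- mb$bk
  g$Wv <- mb$Wv; g$bv <- mb$bv; g$Wo <- mb$Wo; g$bo <- mb$bo
  dX <- dR1 + mb$dX
  dM <- apply_mask(dX, cc$m0)

  dpl_e <- dM[cc$tgt_e, , drop = FALSE]
  dpl_p <- dM[cc$tgt_p, , drop = FALSE]
  dact_e <- maxpool_backward(dpl_e, cc$pl_e$arg, B, cc$cv_e$Lc)
  dact_p <- maxpool_backward(dpl_p, cc$pl_p$arg, B, cc$cv_p$Lc)
  cb_e <- conv_backward(dact_e, cc$cv_e, cc$in_e, params$conv_e_W, lookup)
  cb_p <- conv_backward(dact_p, cc$cv_p, cc$in_p, params$conv_p_W, lookup)
  g$conv_e_W <- cb_e$dW; g$conv_e_b <- cb_e$db
  g$conv_p_W <- cb_p$dW; g$conv_p_b <- cb_p$db
  g
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    g <- as.numeric(gnm)
    state$m[[nm]][] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]][] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]][] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
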