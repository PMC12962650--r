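## Seq2seq Transformer engine: encoder-decoder with multi-head attention,
## pre-layer-norm residual blocks, sinusoidal positional encoding, and
## exact hand-derived backpropagation (finite-difference checked in the
## test-suite). Sequences are rows (positions x features).

#' @keywords internal
softmaxRows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

#' @keywords internal
sinusoidalPe <- function(n_pos, d) {
  pe <- matrix(0, n_pos, d)
  pos <- seq_len(n_pos) - 1L
  for (i in seq_len(d %/% 2L)) {
    f <- 1 / 10000^(2 * (i - 1) / d)
    pe[, 2L * i - 1L] <- sin(pos * f)
    pe[, 2L * i] <- cos(pos * f)
  }
  pe
}

#' @keywords internal
linFwd <- function(x, W, b) list(y = x %*% W + rep(b, each = nrow(x)),
                                 x = x)
#' @keywords internal
linBwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

#' @keywords internal
lnFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

#' @keywords internal
lnBwd <- function(dy, cache, g) {
  n <- ncol(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

#' @keywords internal
initAttn <- function(d, rmat) {
  list(Wq = rmat(d, d), bq = numeric(d), Wk = rmat(d, d), bk = numeric(d),
       Wv = rmat(d, d), bv = numeric(d), Wo = rmat(d, d), bo = numeric(d))
}

#' Multi-head attention forward
#'
#' @param p attention parameter list.
#' @param qx queries input (n_q x d), `kx` keys/values input (n_k x d).
#' @param heads head count (d divisible by heads).
#' @param mask logical n_q x n_k, TRUE where attention is allowed, or NULL.
#' @param bias fixed additive score bias (n_q x n_k) shared across heads,
#'   e.g. a monotonic alignment prior; or NULL.
#' @keywords internal
attnFwd <- function(p, qx, kx, heads, mask = NULL, bias = NULL) {
  d <- ncol(qx); dk <- d %/% heads
  Q <- qx %*% p$Wq + rep(p$bq, each = nrow(qx))
  K <- kx %*% p$Wk + rep(p$bk, each = nrow(kx))
  V <- kx %*% p$Wv + rep(p$bv, each = nrow(kx))
  O <- matrix(0, nrow(qx), d)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk)
    if (!is.null(bias)) S <- S + bias
    if (!is.null(mask)) S[!mask] <- -1e30
    A[[h]] <- softmaxRows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$Wo + rep(p$bo, each = nrow(qx))
  list(y = out, cache = list(qx = qx, kx = kx, Q = Q, K = K, V = V, A = A,
                             O = O, heads = heads))
}

#' @keywords internal
attnBwd <- function(dy, p, cache) {
  heads <- cache$heads
  d <- ncol(cache$Q); dk <- d %/% heads
  dO <- dy %*% t(p$Wo)
  dWo <- crossprod(cache$O, dy); dbo <- colSums(dy)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  list(dqx = dQ %*% t(p$Wq),
       dkx = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = crossprod(cache$qx, dQ), dbq = colSums(dQ),
       dWk = crossprod(cache$kx, dK), dbk = colSums(dK),
       dWv = crossprod(cache$kx, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

#' @keywords internal
initBlock <- function(d, dff, rmat, cross = FALSE) {
  b <- list(ln1 = list(g = rep(1, d), b = numeric(d)),
            attn = initAttn(d, rmat),
            ln2 = list(g = rep(1, d), b = numeric(d)),
            ff = list(W1 = rmat(d, dff), b1 = numeric(dff),
                      W2 = rmat(dff, d), b2 = numeric(d)))
  if (cross) {
    b$lnc <- list(g = rep(1, d), b = numeric(d))
    b$cross <- initAttn(d, rmat)
  }
  b
}

#' Inverted dropout mask (NULL when inactive)
#' @keywords internal
dropMask <- function(nr, nc, pdrop) {
  if (pdrop <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - pdrop) / (1 - pdrop), nr, nc)
}

#' Pre-LN transformer block forward (optionally with cross-attention)
#'
#' `pdrop > 0` applies inverted dropout to each sublayer output before
#' its residual addition (training mode only; draws from the active RNG
#' stream).
#' @keywords internal
blockFwd <- function(p, x, heads, mask = NULL, memory = NULL,
                     mem_mask = NULL, mem_bias = NULL, pdrop = 0) {
  c1 <- lnFwd(x, p$ln1$g, p$ln1$b)
  a1 <- attnFwd(p$attn, c1$y, c1$y, heads, mask)
  m1 <- dropMask(nrow(x), ncol(x), pdrop)
  x1 <- x + if (is.null(m1)) a1$y else a1$y * m1
  cc <- ac <- mc <- NULL
  if (!is.null(memory)) {
    cc <- lnFwd(x1, p$lnc$g, p$lnc$b)
    ac <- attnFwd(p$cross, cc$y, memory, heads, mem_mask, mem_bias)
    mc <- dropMask(nrow(x), ncol(x), pdrop)
    x1 <- x1 + if (is.null(mc)) ac$y else ac$y * mc
  }
  c2 <- lnFwd(x1, p$ln2$g, p$ln2$b)
  h1 <- c2$y %*% p$ff$W1 + rep(p$ff$b1, each = nrow(x))
  r1 <- pmax(h1, 0)
  fy <- r1 %*% p$ff$W2 + rep(p$ff$b2, each = nrow(x))
  mf <- dropMask(nrow(x), ncol(x), pdrop)
  y <- x1 + if (is.null(mf)) fy else fy * mf
  list(y = y, cache = list(c1 = c1, a1 = a1, cc = cc, ac = ac, c2 = c2,
                           h1 = h1, r1 = r1, x = x, x1 = x1,
                           memory = memory, m1 = m1, mc = mc, mf = mf))
}

#' @keywords internal
blockBwd <- function(dy, p, cache, heads) {
  g <- list()
  # feed-forward branch (through its dropout mask)
  dfy <- if (is.null(cache$mf)) dy else dy * cache$mf
  dr1 <- dfy %*% t(p$ff$W2)
  g$ff <- list(dW2 = crossprod(cache$r1, dfy), db2 = colSums(dfy))
  dh1 <- dr1 * (cache$h1 > 0)
  g$ff$dW1 <- crossprod(cache$c2$y, dh1)
  g$ff$db1 <- colSums(dh1)
  dc2y <- dh1 %*% t(p$ff$W1)
  l2 <- lnBwd(dc2y, cache$c2, p$ln2$g)
  g$ln2 <- list(dg = l2$dg, db = l2$db)
  dx1 <- dy + l2$dx
  dmem <- NULL
  if (!is.null(cache$memory)) {
    dcy <- if (is.null(cache$mc)) dx1 else dx1 * cache$mc
    ab <- attnBwd(dcy, p$cross, cache$ac$cache)
    g$cross <- ab[c("dWq", "dbq", "dWk", "dbk", "dWv", "dbv", "dWo", "dbo")]
    dmem <- ab$dkx
    lc <- lnBwd(ab$dqx, cache$cc, p$lnc$g)
    g$lnc <- list(dg = lc$dg, db = lc$db)
    dx1 <- dx1 + lc$dx
  }
  da1 <- if (is.null(cache$m1)) dx1 else dx1 * cache$m1
  a <- attnBwd(da1, p$attn, cache$a1$cache)
  g$attn <- a[c("dWq", "dbq", "dWk", "dbk", "dWv", "dbv", "dWo", "dbo")]
  l1 <- lnBwd(a$dqx + a$dkx, cache$c1, p$ln1$g)
  g$ln1 <- list(dg = l1$dg, db = l1$db)
  list(dx = dx1 + l1$dx, grads = g, dmem = dmem)
}

#' Initialize full seq2seq transformer parameters
#' @keywords internal
initTransformer <- function(config, n_channels, vocab_size, seed) {
  d <- config$hidden; dff <- config$ff_dim
  withSeed(seed, {
    rmat <- function(r, c) matrix(stats::rnorm(r * c) * sqrt(2 / (r + c)), r, c)
    list(
      enc_in = list(W = rmat(n_channels, d), b = numeric(d)),
      enc = lapply(seq_len(config$encoder_layers),
                   function(i) initBlock(d, dff, rmat)),
      enc_ln = list(g = rep(1, d), b = numeric(d)),
      emb = rmat(vocab_size, d),
      dec = lapply(seq_len(config$decoder_layers),
                   function(i) initBlock(d, dff, rmat, cross = TRUE)),
      dec_ln = list(g = rep(1, d), b = numeric(d)),
      interface = list(W = rmat(d, config$output_dim),
                       b = numeric(config$output_dim)),
      out = list(W = rmat(config$output_dim, vocab_size),
                 b = numeric(vocab_size)),
      len_head = list(W = rmat(d, 1L), b = numeric(1L)),
      aux = list(W = rmat(d, vocab_size), b = numeric(vocab_size)))
  })
}

#' Full transformer forward pass
#'
#' @param params from [initTransformer()].
#' @param X encoder input, T' x C (already downsampled neural frames).
#' @param tokens_in 0-based decoder input token ids (SOS-prefixed).
#' @param config adaptor configuration.
#' @param keep_cache retain intermediate activations for the backward
#'   pass.
#' @param cross_bias fixed alignment-prior bias on the decoder's
#'   cross-attention scores (n_dec x n_enc), or NULL.
#' @return list(logits, length_pred, cache).
#' @keywords internal
transformerFwd <- function(params, X, tokens_in, config,
                           keep_cache = FALSE, cross_bias = NULL,
                           pdrop = 0) {
  heads <- config$heads
  x <- X %*% params$enc_in$W + rep(params$enc_in$b, each = nrow(X))
  x <- x + sinusoidalPe(nrow(x), ncol(x))
  encCaches <- vector("list", length(params$enc))
  for (l in seq_along(params$enc)) {
    bf <- blockFwd(params$enc[[l]], x, heads, pdrop = pdrop)
    encCaches[[l]] <- bf$cache
    x <- bf$y
  }
  encLn <- lnFwd(x, params$enc_ln$g, params$enc_ln$b)
  memory <- encLn$y
  pooled <- colMeans(memory)
  lenPred <- as.numeric(pooled %*% params$len_head$W + params$len_head$b)
  n <- length(tokens_in)
  dx <- params$emb[tokens_in + 1L, , drop = FALSE] +
    sinusoidalPe(n, ncol(memory))
  causal <- lower.tri(matrix(TRUE, n, n), diag = TRUE)
  decCaches <- vector("list", length(params$dec))
  for (l in seq_along(params$dec)) {
    bf <- blockFwd(params$dec[[l]], dx, heads, mask = causal,
                   memory = memory, mem_bias = cross_bias, pdrop = pdrop)
    decCaches[[l]] <- bf$cache
    dx <- bf$y
  }
  decLn <- lnFwd(dx, params$dec_ln$g, params$dec_ln$b)
  inter <- linFwd(decLn$y, params$interface$W, params$interface$b)
  logits <- inter$y %*% params$out$W + rep(params$out$b, each = n)
  auxLogits <- memory %*% params$aux$W +
    rep(params$aux$b, each = nrow(memory))
  cache <- if (keep_cache)
    list(X = X, tokens_in = tokens_in, encCaches = encCaches, encLn = encLn,
         memory = memory, pooled = pooled, decCaches = decCaches,
         decLn = decLn, inter = inter, encX = x) else NULL
  list(logits = logits, length_pred = lenPred, aux_logits = auxLogits,
       cache = cache)
}

#' Full transformer backward pass
#'
#' @param dlogits gradient wrt logits (n x V).
#' @param dlen gradient wrt the scalar length prediction.
#' @param daux gradient wrt the frame-wise auxiliary logits (or NULL).
#' @return gradient list mirroring the parameter structure.
#' @keywords internal
transformerBwd <- function(params, cache, dlogits, dlen, config,
                           daux = NULL) {
  heads <- config$heads
  g <- list()
  g$out <- list(dW = crossprod(cache$inter$y, dlogits),
                db = colSums(dlogits))
  dInter <- dlogits %*% t(params$out$W)
  ib <- linBwd(dInter, cache$inter, params$interface$W)
  g$interface <- list(dW = ib$dW, db = ib$db)
  dl <- lnBwd(ib$dx, cache$decLn, params$dec_ln$g)
  g$dec_ln <- list(dg = dl$dg, db = dl$db)
  dx <- dl$dx
  dmem <- matrix(0, nrow(cache$memory), ncol(cache$memory))
  g$dec <- vector("list", length(params$dec))
  for (l in rev(seq_along(params$dec))) {
    bb <- blockBwd(dx, params$dec[[l]], cache$decCaches[[l]], heads)
    g$dec[[l]] <- bb$grads
    dx <- bb$dx
    dmem <- dmem + bb$dmem
  }
  g$emb <- matrix(0, nrow(params$emb), ncol(params$emb))
  ids <- cache$tokens_in + 1L
  for (k in seq_along(ids)) g$emb[ids[k], ] <- g$emb[ids[k], ] + dx[k, ]
  # length head contributes through the pooled encoder memory
  g$len_head <- list(dW = matrix(cache$pooled, ncol = 1L) * dlen,
                     db = dlen)
  dmem <- dmem + (rep(1, nrow(dmem)) %o%
                    as.numeric(params$len_head$W)) * dlen / nrow(dmem)
  if (!is.null(daux)) {
    g$aux <- list(dW = crossprod(cache$memory, daux), db = colSums(daux))
    dmem <- dmem + daux %*% t(params$aux$W)
  } else {
    g$aux <- list(dW = params$aux$W * 0, db = params$aux$b * 0)
  }
  el <- lnBwd(dmem, cache$encLn, params$enc_ln$g)
  g$enc_ln <- list(dg = el$dg, db = el$db)
  de <- el$dx
  g$enc <- vector("list", length(params$enc))
  for (l in rev(seq_along(params$enc))) {
    bb <- blockBwd(de, params$enc[[l]], cache$encCaches[[l]], heads)
    g$enc[[l]] <- bb$grads
    de <- bb$dx
  }
  g$enc_in <- list(dW = crossprod(cache$X, de), db = colSums(de))
  g
}

#' Skeleton of a nested parameter tree: leaf dims and a decay mask
#'
#' Weight decay applies to weight matrices only, not to biases or
#' layer-norm gains/offsets (leaf names b*, g).
#' @keywords internal
treeSkeleton <- function(tree) {
  leaves <- list()
  walk <- function(node, decay) {
    if (is.list(node)) {
      nms <- if (is.null(names(node))) rep("", length(node)) else names(node)
      for (i in seq_along(node))
        walk(node[[i]], decay && !nms[i] %in% c("b", "bq", "bk", "bv", "bo",
                                                "b1", "b2", "g"))
    } else {
      leaves[[length(leaves) + 1L]] <<- list(len = length(node),
                                             dim = dim(node),
                                             decay = decay)
    }
  }
  walk(tree, TRUE)
  lens <- vapply(leaves, `[[`, 1L, "len")
  ends <- cumsum(lens)
  decayMask <- numeric(sum(lens))
  for (i in seq_along(leaves))
    if (leaves[[i]]$decay)
      decayMask[(ends[i] - lens[i] + 1L):ends[i]] <- 1
  list(leaves = leaves, lens = lens, ends = ends, decayMask = decayMask)
}

#' Rebuild a nested tree from a flat vector and its skeleton
#' @keywords internal
rebuildTree <- function(template, skel, flat) {
  k <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    k <<- k + 1L
    to <- skel$ends[k]
    v <- flat[(to - skel$lens[k] + 1L):to]
    if (!is.null(skel$leaves[[k]]$dim)) dim(v) <- skel$leaves[[k]]$dim
    v
  }
  walk(template)
}

#' AdamW update over a nested parameter list
#'
#' Decoupled weight decay on weight matrices only; operates on the
#' flattened parameter vector for speed.
#' @keywords internal
adamStep <- function(params, grads, state, lr, wd = 0, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    skel <- treeSkeleton(params)
    state <- list(t = 0L, skel = skel,
                  m = numeric(sum(skel$lens)), v = numeric(sum(skel$lens)))
  }
  state$t <- state$t + 1L
  t <- state$t
  p <- unlist(params, use.names = FALSE)
  g <- unlist(alignGradTree(params, grads), use.names = FALSE)
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  p <- p - lr * (mhat / (sqrt(vhat) + eps) +
                   wd * state$skel$decayMask * p)
  list(params = rebuildTree(params, state$skel, p), state = state)
}
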