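## Bidirectional LSTM engine: vectorized batched forward and
## backpropagation-through-time, written against BLAS matrix products.
## Sequences are right-padded to the batch maximum and masked; the
## backward pass is exact for variable lengths (state pass-through at
## padded positions). Gradients are finite-difference checked in the
## test-suite.

#' @keywords internal
sigm <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
initLstmParams <- function(n_layers, input_dim, hidden, output_dim, seed) {
  withSeed(seed, {
    mk <- function(r, c) matrix(stats::runif(r * c, -1, 1) / sqrt(c), r, c)
    layers <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      din <- if (l == 1L) input_dim else 2L * hidden
      mkdir <- function() {
        b <- numeric(4L * hidden)
        b[(hidden + 1L):(2L * hidden)] <- 1   # forget-gate bias
        list(W = mk(4L * hidden, din), U = mk(4L * hidden, hidden), b = b)
      }
      layers[[l]] <- list(f = mkdir(), b = mkdir())
    }
    list(layers = layers,
         Wo = mk(output_dim, 2L * hidden), bo = numeric(output_dim))
  })
}

#' One-direction masked LSTM forward over a padded batch
#'
#' @param dirp list(W, U, b).
#' @param inp array [Din, Tmax, B].
#' @param lens integer valid lengths per batch element.
#' @param reverse process time back-to-front (the backward direction).
#' @return list(H = output array [H, Tmax, B], cache).
#' @keywords internal
lstmDirForward <- function(dirp, inp, lens, reverse = FALSE) {
  dims <- dim(inp); Din <- dims[1]; Tmax <- dims[2]; B <- dims[3]
  H <- ncol(dirp$U)
  Zx <- array(dirp$W %*% matrix(inp, Din) + dirp$b, c(4L * H, Tmax, B))
  h <- cs <- matrix(0, H, B)
  Hs <- array(0, c(H, Tmax, B))
  Iv <- Fv <- Gv <- Ov <- Cv <- Cprev <- Hprev <- array(0, c(H, Tmax, B))
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  times <- if (reverse) rev(seq_len(Tmax)) else seq_len(Tmax)
  for (t in times) {
    m <- rep(as.numeric(lens >= t), each = H)
    z <- Zx[, t, , drop = FALSE]; dim(z) <- c(4L * H, B)
    z <- z + dirp$U %*% h
    iG <- sigm(z[i1, , drop = FALSE]); fG <- sigm(z[i2, , drop = FALSE])
    gG <- tanh(z[i3, , drop = FALSE]); oG <- sigm(z[i4, , drop = FALSE])
    Cprev[, t, ] <- cs; Hprev[, t, ] <- h
    cn <- fG * cs + iG * gG
    hn <- oG * tanh(cn)
    cs <- m * cn + (1 - m) * cs
    h <- m * hn + (1 - m) * h
    Iv[, t, ] <- iG; Fv[, t, ] <- fG; Gv[, t, ] <- gG; Ov[, t, ] <- oG
    Cv[, t, ] <- cs; Hs[, t, ] <- h
  }
  list(H = Hs, cache = list(Iv = Iv, Fv = Fv, Gv = Gv, Ov = Ov, Cv = Cv,
                            Cprev = Cprev, Hprev = Hprev, inp = inp,
                            lens = lens, reverse = reverse))
}

#' One-direction masked BPTT
#'
#' @param dirp list(W, U, b).
#' @param cache from [lstmDirForward()].
#' @param dH gradient wrt the direction's outputs, [H, Tmax, B].
#' @return list(dW, dU, db, dInp).
#' @keywords internal
lstmDirBackward <- function(dirp, cache, dH) {
  dims <- dim(dH); H <- dims[1]; Tmax <- dims[2]; B <- dims[3]
  lens <- cache$lens
  dZ <- array(0, c(4L * H, Tmax, B))
  dh <- dc <- matrix(0, H, B)
  times <- if (cache$reverse) rev(seq_len(Tmax)) else seq_len(Tmax)
  for (t in rev(times)) {
    m <- rep(as.numeric(lens >= t), each = H)
    g <- dH[, t, , drop = FALSE]; dim(g) <- c(H, B)
    tot <- g + dh
    dhv <- tot * m
    iG <- cache$Iv[, t, ]; fG <- cache$Fv[, t, ]
    gG <- cache$Gv[, t, ]; oG <- cache$Ov[, t, ]
    dim(iG) <- dim(fG) <- dim(gG) <- dim(oG) <- c(H, B)
    ct <- cache$Cv[, t, ]; cp <- cache$Cprev[, t, ]
    dim(ct) <- dim(cp) <- c(H, B)
    tanc <- tanh(ct)
    dcn <- dc * m + dhv * oG * (1 - tanc^2)
    di <- dcn * gG; df <- dcn * cp; dg <- dcn * iG; doo <- dhv * tanc
    dz <- rbind(di * iG * (1 - iG), df * fG * (1 - fG),
                dg * (1 - gG^2), doo * oG * (1 - oG))
    dZ[, t, ] <- dz
    dh <- crossprod(dirp$U, dz) + tot * (1 - m)
    dc <- dcn * fG + dc * (1 - m)
  }
  dZf <- matrix(dZ, 4L * H)
  list(dW = dZf %*% t(matrix(cache$inp, dim(cache$inp)[1])),
       dU = dZf %*% t(matrix(cache$Hprev, H)),
       db = rowSums(dZf),
       dInp = array(crossprod(dirp$W, dZf), dim(cache$inp)))
}

#' Full bidirectional multi-layer forward
#'
#' @param params from [initLstmParams()].
#' @param inp array [C, Tmax, B]; `lens` valid lengths.
#' @param dropout per-layer output dropout probability (train mode only).
#' @param train logical; dropout active and caches kept only when `TRUE`.
#' @param seed seed for the dropout masks.
#' @return list(Y = output array [D_out, Tmax, B], cache or NULL).
#' @keywords internal
biLstmForward <- function(params, inp, lens, dropout = 0, train = FALSE,
                          seed = NULL) {
  nL <- length(params$layers)
  x <- inp
  caches <- vector("list", nL)
  dmasks <- vector("list", nL)
  for (l in seq_len(nL)) {
    fw <- lstmDirForward(params$layers[[l]]$f, x, lens, reverse = FALSE)
    bw <- lstmDirForward(params$layers[[l]]$b, x, lens, reverse = TRUE)
    H <- dim(fw$H)[1]
    out <- array(0, c(2L * H, dim(x)[2], dim(x)[3]))
    out[seq_len(H), , ] <- fw$H
    out[H + seq_len(H), , ] <- bw$H
    if (train && dropout > 0 && l < nL) {
      mask <- withSeed(if (is.null(seed)) NULL else seed + l, {
        array(stats::rbinom(length(out), 1L, 1 - dropout) / (1 - dropout),
              dim(out))
      })
      out <- out * mask
      dmasks[[l]] <- mask
    }
    caches[[l]] <- list(f = fw$cache, b = bw$cache)
    x <- out
  }
  Y <- array(params$Wo %*% matrix(x, dim(x)[1]) + params$bo,
             c(nrow(params$Wo), dim(x)[2], dim(x)[3]))
  list(Y = Y,
       cache = if (train) list(layers = caches, top = x, dmasks = dmasks,
                               lens = lens) else NULL)
}

#' Full backward pass
#'
#' @param params parameter list.
#' @param cache from [biLstmForward()] with `train = TRUE`.
#' @param dY gradient wrt outputs, [D_out, Tmax, B] (already masked).
#' @return gradient list mirroring `params`.
#' @keywords internal
biLstmBackward <- function(params, cache, dY) {
  nL <- length(params$layers)
  dYf <- matrix(dY, dim(dY)[1])
  topf <- matrix(cache$top, dim(cache$top)[1])
  grads <- list(Wo = dYf %*% t(topf), bo = rowSums(dYf),
                layers = vector("list", nL))
  dx <- array(crossprod(params$Wo, dYf), dim(cache$top))
  for (l in rev(seq_len(nL))) {
    if (!is.null(cache$dmasks[[l]])) dx <- dx * cache$dmasks[[l]]
    H <- dim(dx)[1] %/% 2L
    gf <- lstmDirBackward(params$layers[[l]]$f, cache$layers[[l]]$f,
                          dx[seq_len(H), , , drop = FALSE])
    gb <- lstmDirBackward(params$layers[[l]]$b, cache$layers[[l]]$b,
                          dx[H + seq_len(H), , , drop = FALSE])
    grads$layers[[l]] <- list(f = gf[c("dW", "dU", "db")],
                              b = gb[c("dW", "dU", "db")])
    dx <- gf$dInp + gb$dInp
  }
  grads
}

#' Reorder a gradient tree to a parameter tree (dW -> W naming; unnamed
#' list levels align positionally)
#' @keywords internal
alignGradTree <- function(p, g) {
  if (!is.list(p)) return(g)
  gg <- g
  if (!is.null(names(gg)) && !is.null(names(p))) {
    miss <- !(names(gg) %in% names(p))
    names(gg)[miss] <- sub("^d", "", names(gg)[miss])
    gg <- gg[names(p)]
  }
  Map(alignGradTree, p, gg)
}

#' Flatten/apply parameter updates (SGD with momentum)
#' @keywords internal
sgdStep <- function(params, grads, state, lr, momentum) {
  upd <- function(p, g, v) {
    vn <- momentum * v - lr * g
    list(p = p + vn, v = vn)
  }
  if (is.null(state)) state <- rapply(params, function(x) x * 0, how = "replace")
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, v)
      list(p = lapply(out, `[[`, "p"), v = lapply(out, `[[`, "v"))
    } else upd(p, g, v)
  }
  g <- alignGradTree(params, grads)
  out <- walk(params, g, state)
  list(params = out$p, state = out$v)
}
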