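# Gradient and contract checks for the two trainable engines. The
# backward passes are hand-derived; these tests pin them against central
# finite differences on tiny configurations.

test_that("biLSTM backpropagation matches finite differences", {
  withr::with_seed(1, {
    p <- duovox:::initLstmParams(2L, 3L, 4L, 5L, seed = 7)
    B <- 2L; Tm <- 6L; lens <- c(6L, 4L)
    inp <- array(rnorm(3 * Tm * B), c(3, Tm, B))
    M <- list(matrix(rnorm(6 * 5), 6, 5), matrix(rnorm(4 * 5), 4, 5))
    lossOf <- function(pp) {
      fw <- duovox:::biLstmForward(pp, inp, lens)
      l <- 0
      for (b in 1:B) {
        P <- t(matrix(fw$Y[, seq_len(lens[b]), b], 5))
        l <- l + duovox:::acousticLossGrad(P, M[[b]], 0.1)$loss / B
      }
      l
    }
    fw <- duovox:::biLstmForward(p, inp, lens, train = TRUE)
    dY <- array(0, dim(fw$Y))
    for (b in 1:B) {
      P <- t(matrix(fw$Y[, seq_len(lens[b]), b], 5))
      lg <- duovox:::acousticLossGrad(P, M[[b]], 0.1)
      dY[, seq_len(lens[b]), b] <- t(lg$grad) / B
    }
    gr <- duovox:::biLstmBackward(p, fw$cache, dY)
    eps <- 1e-6
    checkLeaf <- function(get, set, ganal) {
      v <- get(p)
      idx <- sample(length(v), min(4, length(v)))
      for (i in idx) {
        num <- (lossOf(set(p, i, eps)) - lossOf(set(p, i, -eps))) / (2 * eps)
        expect_lt(abs(num - ganal[i]) /
                    max(1e-8, abs(num) + abs(ganal[i])), 1e-3)
      }
    }
    for (l in 1:2) for (dr in c("f", "b")) for (w in c("W", "U", "b")) {
      checkLeaf(function(pp) pp$layers[[l]][[dr]][[w]],
                function(pp, i, d) {
                  pp$layers[[l]][[dr]][[w]][i] <-
                    pp$layers[[l]][[dr]][[w]][i] + d; pp
                },
                gr$layers[[l]][[dr]][[paste0("d", w)]])
    }
    checkLeaf(function(pp) pp$Wo,
              function(pp, i, d) { pp$Wo[i] <- pp$Wo[i] + d; pp }, gr$Wo)
    checkLeaf(function(pp) pp$bo,
              function(pp, i, d) { pp$bo[i] <- pp$bo[i] + d; pp }, gr$bo)
  })
})

test_that("laplacian adjoint is the exact transpose of the forward stencil", {
  withr::with_seed(2, {
    for (k in 1:3) {
      x <- matrix(rnorm(35), 5)
      y <- matrix(rnorm(35), 5)
      # <Lap(x), y> == <x, LapAdjoint(y)>
      expect_equal(sum(duovox:::laplacian2d(x) * y),
                   sum(x * duovox:::lapAdjoint(y)), tolerance = 1e-10)
    }
  })
})

test_that("transformer backpropagation matches finite differences", {
  withr::with_seed(3, {
    cfg <- linguisticAdaptorConfig(encoder_layers = 2L, decoder_layers = 2L,
                                   hidden = 8L, heads = 2L, ff_dim = 12L,
                                   output_dim = 16L)
    V <- 7L
    p <- duovox:::initTransformer(cfg, 5L, V, seed = 11)
    X <- matrix(rnorm(6 * 5), 6, 5)
    dec_in <- c(1L, 4L, 5L)
    target <- c(4L, 5L, 2L)
    lossOf <- function(pp) {
      fw <- duovox:::transformerFwd(pp, X, dec_in, cfg)
      probs <- duovox:::softmaxRows(fw$logits)
      q <- matrix(0.1 / V, 3, V)
      q[cbind(1:3, target + 1L)] <- 0.9 + 0.1 / V
      tokenLoss(probs, q) + lengthLoss(fw$length_pred, 2)
    }
    fw <- duovox:::transformerFwd(p, X, dec_in, cfg, keep_cache = TRUE)
    probs <- duovox:::softmaxRows(fw$logits)
    q <- matrix(0.1 / V, 3, V)
    q[cbind(1:3, target + 1L)] <- 0.9 + 0.1 / V
    dlogits <- (probs - q) / 3
    e <- fw$length_pred - 2
    g <- duovox:::transformerBwd(p, fw$cache, dlogits,
                                 if (abs(e) <= 1) e else sign(e), cfg)
    eps <- 1e-6
    checkPath <- function(path, ganal) {
      get <- function(pp) { v <- pp; for (k in path) v <- v[[k]]; v }
      set <- function(pp, i, d) {
        v <- get(pp); v[i] <- v[i] + d
        if (length(path) == 1) pp[[path[[1]]]] <- v
        else if (length(path) == 2) pp[[path[[1]]]][[path[[2]]]] <- v
        else if (length(path) == 3)
          pp[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- v
        else pp[[path[[1]]]][[path[[2]]]][[path[[3]]]][[path[[4]]]] <- v
        pp
      }
      v <- get(p)
      for (i in sample(length(v), min(3, length(v)))) {
        num <- (lossOf(set(p, i, eps)) - lossOf(set(p, i, -eps))) / (2 * eps)
        expect_lt(abs(num - ganal[i]) /
                    max(1e-8, abs(num) + abs(ganal[i])), 1e-4)
      }
    }
    checkPath(list("enc_in", "W"), g$enc_in$dW)
    checkPath(list("emb"), g$emb)
    checkPath(list("enc", 1L, "attn", "Wq"), g$enc[[1]]$attn$dWq)
    checkPath(list("enc", 2L, "ff", "W1"), g$enc[[2]]$ff$dW1)
    checkPath(list("enc_ln", "g"), g$enc_ln$dg)
    checkPath(list("dec", 1L, "cross", "Wk"), g$dec[[1]]$cross$dWk)
    checkPath(list("dec", 2L, "attn", "Wv"), g$dec[[2]]$attn$dWv)
    checkPath(list("dec", 1L, "lnc", "b"), g$dec[[1]]$lnc$db)
    checkPath(list("interface", "W"), g$interface$dW)
    checkPath(list("out", "W"), g$out$dW)
    checkPath(list("len_head", "W"), g$len_head$dW)
  })
})

test_that("causal masking blocks future teacher tokens", {
  ds <- tinyDataset()
  v <- datasetVocabulary(ds)
  ad <- linguisticAdaptor(4L, v,
                          linguisticAdaptorConfig(encoder_layers = 1L,
                                                  decoder_layers = 1L,
                                                  hidden = 8L, heads = 2L,
                                                  ff_dim = 12L,
                                                  output_dim = 16L),
                          seed = 5)
  X <- matrix(rnorm(4 * 30), 4)
  t1 <- c(3L, 4L, 5L)
  t2 <- c(3L, 4L, 6L)       # only the last teacher token differs
  f1 <- linguisticForward(ad, X, t1)
  f2 <- linguisticForward(ad, X, t2)
  expect_equal(f1$probs[1:3, ], f2$probs[1:3, ], tolerance = 1e-12)
  # distributions are normalized and the pass is deterministic
  expect_true(all(abs(rowSums(f1$probs) - 1) < 1e-6))
  expect_identical(linguisticForward(ad, X, t1)$logits, f1$logits)
  expect_error(linguisticForward(ad, X, rep(3L, 40)), "max_decode_len")
})

test_that("acoustic forward honours the one-frame-per-frame contract", {
  cfg <- acousticAdaptorConfig(n_layers = 2L, hidden_size = 6L)
  ad <- acousticAdaptor(5L, cfg, seed = 2)
  X <- matrix(rnorm(5 * 7), 5)
  Y <- acousticForward(ad, X)
  expect_equal(dim(Y), c(80L, 7L))
  expect_identical(acousticForward(ad, X), Y)    # eval-mode determinism
  expect_error(acousticForward(ad, matrix(0, 4, 7)), "channel mismatch")
  # 768-d interface mode preserves the wider dimension
  ad768 <- acousticAdaptor(5L, acousticAdaptorConfig(n_layers = 1L,
                                                     hidden_size = 6L,
                                                     feature_dim = 768L),
                           seed = 2)
  expect_equal(dim(acousticForward(ad768, X)), c(768L, 7L))
})

test_that("a hand-set single-cell recurrence matches the engine", {
  # 1 layer, 1 unit, 1 channel: follow the cell equations step by step
  p <- duovox:::initLstmParams(1L, 1L, 1L, 1L, seed = 3)
  x <- matrix(c(0.5, -1, 2), 1)
  fw <- duovox:::lstmDirForward(p$layers[[1]]$f, array(x, c(1, 3, 1)), 3L)
  sig <- function(z) 1 / (1 + exp(-z))
  W <- p$layers[[1]]$f$W; U <- p$layers[[1]]$f$U; b <- p$layers[[1]]$f$b
  h <- 0; cs <- 0
  for (t in 1:3) {
    z <- W * x[1, t] + U * h + b
    i <- sig(z[1]); f <- sig(z[2]); g <- tanh(z[3]); o <- sig(z[4])
    cs <- f * cs + i * g
    h <- o * tanh(cs)
    expect_equal(fw$H[1, t, 1], h, tolerance = 1e-12)
  }
})

test_that("dropout masks are handled exactly in the backward pass", {
  withr::with_seed(4, {
    cfg <- linguisticAdaptorConfig(encoder_layers = 1L, decoder_layers = 1L,
                                   hidden = 8L, heads = 2L, ff_dim = 12L,
                                   output_dim = 16L, dropout = 0.3)
    V <- 7L
    p <- duovox:::initTransformer(cfg, 5L, V, seed = 13)
    X <- matrix(rnorm(6 * 5), 6, 5)
    dec_in <- c(1L, 4L)
    target <- c(4L, 2L)
    # identical masks across evaluations via a fixed seed wrapper
    lossOf <- function(pp) duovox:::withSeed(99, {
      fw <- duovox:::transformerFwd(pp, X, dec_in, cfg, pdrop = 0.3)
      probs <- duovox:::softmaxRows(fw$logits)
      q <- matrix(0, 2, V); q[cbind(1:2, target + 1L)] <- 1
      tokenLoss(probs, q) + lengthLoss(fw$length_pred, 1)
    })
    fw <- duovox:::withSeed(99, duovox:::transformerFwd(p, X, dec_in, cfg,
                                                        keep_cache = TRUE,
                                                        pdrop = 0.3))
    probs <- duovox:::softmaxRows(fw$logits)
    q <- matrix(0, 2, V); q[cbind(1:2, target + 1L)] <- 1
    e <- fw$length_pred - 1
    g <- duovox:::transformerBwd(p, fw$cache, (probs - q) / 2,
                                 if (abs(e) <= 1) e else sign(e), cfg)
    eps <- 1e-6
    for (pick in list(list(get = function(pp) pp$enc[[1]]$ff$W1,
                           set = function(pp, i, d) {
                             pp$enc[[1]]$ff$W1[i] <- pp$enc[[1]]$ff$W1[i] + d
                             pp
                           }, g = g$enc[[1]]$ff$dW1),
                      list(get = function(pp) pp$dec[[1]]$cross$Wv,
                           set = function(pp, i, d) {
                             pp$dec[[1]]$cross$Wv[i] <-
                               pp$dec[[1]]$cross$Wv[i] + d
                             pp
                           }, g = g$dec[[1]]$cross$dWv))) {
      v <- pick$get(p)
      for (i in sample(length(v), 3)) {
        num <- (lossOf(pick$set(p, i, eps)) -
                  lossOf(pick$set(p, i, -eps))) / (2 * eps)
        expect_lt(abs(num - pick$g[i]) /
                    max(1e-8, abs(num) + abs(pick$g[i])), 1e-4)
      }
    }
  })
})
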