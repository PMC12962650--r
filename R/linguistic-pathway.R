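## Linguistic pathway: neural -> autoregressive word-token decoding.

#' Linguistic adaptor configuration
#'
#' Attention-based seq2seq Transformer decoding word-token sequences from
#' high-gamma input: the neural frames are linearly projected into the
#' model dimension, positionally encoded, passed through
#' `encoder_layers`/`decoder_layers` pre-LN blocks with `heads` attention
#' heads, and read out through a 1024-dimensional linguistic-feature
#' interface layer onto vocabulary logits plus a scalar length head.
#' Reference settings: 3 + 3 layers, hidden 256, 8 heads, Adam with
#' learning rate 1e-4 and decoupled weight decay 0.01; desk-scale runs
#' shrink `hidden`/`ff_dim` and raise the learning rate.
#'
#' @param encoder_layers,decoder_layers block counts.
#' @param hidden model dimension (divisible by `heads`).
#' @param heads attention heads.
#' @param ff_dim feed-forward inner dimension.
#' @param dropout sublayer dropout probability (training mode only).
#' @param output_dim linguistic feature interface dimension (1024).
#' @param optimizer list(type, lr, weight_decay).
#' @param max_epochs training epoch cap.
#' @param patience early-stop patience (epochs without val improvement).
#' @param label_smoothing KL target smoothing epsilon.
#' @param max_decode_len decoding length cap in tokens.
#' @param downsample temporal average-pooling factor on the neural input.
#' @param augment_sd SD of Gaussian input-noise augmentation applied to
#'   the (pooled) training inputs each epoch; 0 disables.
#' @param align_prior add a monotonic alignment prior to the decoder's
#'   cross-attention: a fixed Gaussian score bias centred on the expected
#'   frame of each output position, with rate and spread estimated from
#'   the training split's word annotations.
#' @param aux_weight weight of the auxiliary frame-wise word
#'   classification loss on the encoder memory (teaches local word
#'   identity; 0 disables).
#' @param lr_decay_epoch epoch after which the learning rate is
#'   multiplied by `lr_decay_factor` and the augmentation SD is halved
#'   (step schedule); `NULL` disables.
#' @param lr_decay_factor multiplicative step-decay factor.
#' @param checkpoint_metric select the returned checkpoint by validation
#'   `"loss"` (teacher-forced) or validation `"wer"` (greedy decoding,
#'   evaluated every `wer_every` epochs).
#' @param wer_every epochs between validation WER evaluations.
#' @param ... named overrides.
#' @return configuration list.
#' @export
linguisticAdaptorConfig <- function(encoder_layers = 3L, decoder_layers = 3L,
                                    hidden = 256L, heads = 8L,
                                    ff_dim = 2L * hidden, dropout = 0,
                                    output_dim = 1024L,
                                    optimizer = list(type = "Adam", lr = 1e-4,
                                                     weight_decay = 0.01),
                                    max_epochs = 150L, patience = 25L,
                                    label_smoothing = 0.1,
                                    max_decode_len = 20L, downsample = 1L,
                                    augment_sd = 0, align_prior = TRUE,
                                    aux_weight = 0,
                                    lr_decay_epoch = NULL,
                                    lr_decay_factor = 0.25,
                                    checkpoint_metric = c("loss", "wer"),
                                    wer_every = 3L, ...) {
  cfg <- c(list(encoder_layers = encoder_layers,
                decoder_layers = decoder_layers, hidden = hidden,
                heads = heads, ff_dim = ff_dim, dropout = dropout,
                output_dim = output_dim,
                optimizer = optimizer, max_epochs = max_epochs,
                patience = patience, label_smoothing = label_smoothing,
                max_decode_len = max_decode_len, downsample = downsample,
                augment_sd = augment_sd, align_prior = align_prior,
                aux_weight = aux_weight,
                lr_decay_epoch = lr_decay_epoch,
                lr_decay_factor = lr_decay_factor,
                checkpoint_metric = match.arg(checkpoint_metric),
                wer_every = wer_every),
           list(...))
  assertThat(cfg$hidden %% cfg$heads == 0, "hidden must be divisible by heads")
  cfg
}

#' Initialize an (untrained) linguistic adaptor
#'
#' @param n_channels input channel count.
#' @param vocab the [Vocabulary-class] defining the token set.
#' @param config see [linguisticAdaptorConfig()].
#' @param seed RNG seed.
#' @return a `LinguisticAdaptor` object.
#' @export
linguisticAdaptor <- function(n_channels, vocab,
                              config = linguisticAdaptorConfig(),
                              seed = 1L) {
  V <- length(tokenIds(vocab))
  params <- initTransformer(config, n_channels, V,
                            deriveSeed(seed, "transformer-init"))
  structure(list(params = params, config = config, vocab = vocab,
                 n_channels = n_channels, history = NULL),
            class = "LinguisticAdaptor")
}

#' @export
print.LinguisticAdaptor <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(paste0("LinguisticAdaptor: %d+%d-layer transformer, hidden ",
                     "%d, %d heads, %d tokens, %s parameters%s\n"),
              x$config$encoder_layers, x$config$decoder_layers,
              x$config$hidden, x$config$heads, nrow(x$params$emb),
              format(np, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' @keywords internal
poolNeural <- function(X, ds) {
  # channels x T -> T' x channels with average pooling over time
  Tn <- ncol(X)
  Tp <- max(1L, Tn %/% ds)
  out <- matrix(0, Tp, nrow(X))
  for (t in seq_len(Tp))
    out[t, ] <- rowMeans(X[, ((t - 1L) * ds + 1L):(t * ds), drop = FALSE])
  out
}

#' Linguistic adaptor forward pass (teacher-forced)
#'
#' Projects the neural input linearly, adds positional encoding, runs the
#' encoder/decoder, and returns per-position token distributions and the
#' scalar length prediction. Deterministic (no stochastic layers).
#'
#' @param adaptor a `LinguisticAdaptor`.
#' @param neural channels x T matrix or [NeuralRecording-class].
#' @param teacher_tokens 0-based target token ids (without SOS/EOS); the
#'   decoder input is the SOS-prefixed sequence.
#' @return list with `probs` (positions x vocabulary, rows sum to 1),
#'   `logits`, and `length_pred`.
#' @export
linguisticForward <- function(adaptor, neural, teacher_tokens) {
  X <- if (is(neural, "NeuralRecording")) hgMatrix(neural) else neural
  if (nrow(X) != adaptor$n_channels)
    stop("channel mismatch: adaptor expects ", adaptor$n_channels,
         " channels, got ", nrow(X), call. = FALSE)
  if (length(teacher_tokens) + 1L > adaptor$config$max_decode_len)
    stop("sequence longer than max_decode_len (",
         adaptor$config$max_decode_len, ")", call. = FALSE)
  ids <- tokenIds(adaptor$vocab)
  dec_in <- c(ids[["<sos>"]], teacher_tokens)
  Xp <- poolNeural(X, adaptor$config$downsample)
  fw <- transformerFwd(adaptor$params, Xp, dec_in, adaptor$config,
                       cross_bias = alignBias(adaptor$align,
                                              length(dec_in), nrow(Xp)))
  list(probs = softmaxRows(fw$logits), logits = fw$logits,
       length_pred = fw$length_pred)
}

#' Token-level KL loss
#'
#' Mean per-position KL divergence `KL(target || prediction)` with
#' one-hot targets optionally label-smoothed to
#' `(1 - eps) one-hot + eps / K uniform`; `0 log 0 = 0`.
#'
#' @param t_pred positions x K matrix of predicted distributions, or a
#'   probability vector for a single position.
#' @param t_target 0-based target ids, or a distribution matrix of the
#'   same shape as `t_pred`.
#' @param smoothing label smoothing epsilon.
#' @return non-negative scalar.
#' @export
tokenLoss <- function(t_pred, t_target, smoothing = 0) {
  if (!is.matrix(t_pred)) t_pred <- matrix(t_pred, nrow = 1L)
  K <- ncol(t_pred)
  if (is.matrix(t_target)) {
    q <- t_target
  } else {
    q <- matrix(smoothing / K, nrow(t_pred), K)
    q[cbind(seq_len(nrow(q)), t_target + 1L)] <-
      1 - smoothing + smoothing / K
  }
  terms <- ifelse(q > 0, q * log(q / pmax(t_pred, 1e-300)), 0)
  mean(rowSums(terms))
}

#' Huber sequence-length loss
#'
#' `0.5 e^2` for `|e| <= delta`, else `delta (|e| - delta / 2)`, with
#' `e = l_pred - l_target` and `delta = 1`.
#'
#' @param l_pred,l_target predicted and target lengths.
#' @param delta Huber transition point.
#' @return non-negative scalar.
#' @export
lengthLoss <- function(l_pred, l_target, delta = 1) {
  e <- abs(l_pred - l_target)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - delta / 2)))
}

#' Compound linguistic loss
#'
#' `L = L_token + lambda1 * L_length` with the default `lambda1 = 1`; the
#' L2 term of the objective is realized as optimizer weight decay (0.01),
#' not as an explicit loss term.
#'
#' @inheritParams tokenLoss
#' @inheritParams lengthLoss
#' @param weights see [lossWeights()].
#' @param smoothing label smoothing epsilon.
#' @return scalar loss.
#' @export
linguisticTotalLoss <- function(t_pred, t_target, l_pred, l_target,
                                weights = lossWeights(), smoothing = 0) {
  tokenLoss(t_pred, t_target, smoothing) +
    weights$lambda1_length * lengthLoss(l_pred, l_target)
}

#' Gaussian alignment-prior bias matrix
#'
#' `bias[k, j] = -((j - a - b k)^2) / (2 sigma^2)` over decoder output
#' positions k and encoder frames j; a linear word-rate model of where
#' output position k should look in time.
#' @keywords internal
alignBias <- function(align, n_dec, n_enc) {
  if (is.null(align)) return(NULL)
  mu <- align$a + align$b * seq_len(n_dec)
  outer(mu, seq_len(n_enc), function(m, j) -0.5 * ((j - m) / align$sigma)^2)
}

#' Fit the linear word-rate alignment model from annotations
#' @keywords internal
estimateAlignment <- function(dataset, trIdx, downsample) {
  ks <- mids <- numeric(0)
  for (i in trIdx) {
    u <- trialUtterances(dataset)[[i]]
    w <- wordIntervals(u)
    if (nrow(w) == 0) next
    mid <- (w$start + w$end) / 2 / sampleRate(u) * 50 / downsample
    ks <- c(ks, seq_len(nrow(w)))
    mids <- c(mids, mid)
  }
  if (length(ks) < 4) return(NULL)
  fit <- stats::lm.fit(cbind(1, ks), mids)
  sigma <- max(2 * stats::sd(fit$residuals), abs(fit$coefficients[2]), 1)
  list(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]),
       sigma = sigma)
}

#' @keywords internal
sentenceTokens <- function(dataset, i) {
  ids <- tokenIds(datasetVocabulary(dataset))
  words <- wordIntervals(trialUtterances(dataset)[[i]])$label
  unname(ids[words])
}

#' Train the linguistic adaptor
#'
#' Teacher-forced training of the compound loss (smoothed token KL +
#' Huber length loss) with AdamW (learning rate and decoupled weight
#' decay from the config). Per-epoch validation loss drives early
#' stopping; the best-validation checkpoint is returned.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param config see [linguisticAdaptorConfig()].
#' @param seed RNG seed.
#' @param channels channel ids to consume (default all).
#' @param train_fraction fraction of the training split to use.
#' @param shuffle_labels randomly permute the sentence-to-token-sequence
#'   pairing of the training split (chance-level control).
#' @param verbose print per-epoch losses.
#' @return trained `LinguisticAdaptor` with `history`.
#' @export
trainLinguistic <- function(dataset, config = linguisticAdaptorConfig(),
                            seed = 1L, channels = NULL, train_fraction = 1,
                            shuffle_labels = FALSE, verbose = FALSE) {
  trIdx <- splitIndices(dataset, "train")
  vaIdx <- splitIndices(dataset, "val")
  if (length(trIdx) == 0 || length(vaIdx) == 0)
    stop("dataset must have non-empty train and val splits", call. = FALSE)
  if (train_fraction < 1) {
    keep <- max(1L, round(train_fraction * length(trIdx)))
    trIdx <- withSeed(deriveSeed(seed, "fraction"),
                      sort(sample(trIdx, keep)))
  }
  vocab <- datasetVocabulary(dataset)
  ids <- tokenIds(vocab)
  eosId <- ids[["<eos>"]]; sosId <- ids[["<sos>"]]
  getX <- function(i) {
    X <- hgMatrix(trialNeural(dataset)[[i]])
    if (!is.null(channels)) X <- X[channels, , drop = FALSE]
    poolNeural(X, config$downsample)
  }
  Xs <- lapply(seq_along(trialNeural(dataset)), getX)
  toks <- lapply(seq_along(trialNeural(dataset)),
                 function(i) sentenceTokens(dataset, i))
  # frame-wise word labels for the auxiliary encoder loss: the token id of
  # the word covering each pooled frame's centre, PAD (0) in silence
  auxLab <- lapply(seq_along(trialNeural(dataset)), function(i) {
    u <- trialUtterances(dataset)[[i]]
    w <- wordIntervals(u)
    nFr <- nrow(Xs[[i]])
    centers <- ((seq_len(nFr) - 0.5) * config$downsample) / 50 *
      sampleRate(u)
    lab <- integer(nFr)
    for (k in seq_len(nrow(w))) {
      inw <- centers >= w$start[k] & centers < w$end[k]
      lab[inw] <- unname(tokenIds(vocab)[w$label[k]])
    }
    lab
  })
  if (shuffle_labels) {
    perm <- withSeed(deriveSeed(seed, "shuffle"), sample(trIdx))
    toks[trIdx] <- toks[perm]
    # the auxiliary loss uses frame-aligned word annotations, which have
    # no shuffled counterpart; disable it so the control carries no
    # residual neural-to-label association
    config$aux_weight <- 0
  }
  nCh <- ncol(Xs[[trIdx[1]]])
  align <- if (isTRUE(config$align_prior))
    estimateAlignment(dataset, trIdx, config$downsample) else NULL
  adaptor <- linguisticAdaptor(nCh, vocab, config, seed = seed)
  adaptor$align <- align
  adaptor$n_channels <- if (is.null(channels))
    nrow(hgMatrix(trialNeural(dataset)[[1]])) else length(channels)
  params <- adaptor$params
  eps <- config$label_smoothing
  V <- length(ids)
  utterLossX <- function(p, i, X, keep_cache = FALSE) {
    tt <- toks[[i]]
    dec_in <- c(sosId, tt)
    target <- c(tt, eosId)
    fw <- transformerFwd(p, X, dec_in, config, keep_cache = keep_cache,
                         cross_bias = alignBias(align, length(dec_in),
                                                nrow(X)),
                         pdrop = if (keep_cache) config$dropout %||% 0 else 0)
    probs <- softmaxRows(fw$logits)
    q <- matrix(eps / V, length(target), V)
    q[cbind(seq_along(target), target + 1L)] <- 1 - eps + eps / V
    loss <- tokenLoss(probs, q) + lengthLoss(fw$length_pred, length(tt))
    auxP <- NULL
    aw <- config$aux_weight %||% 0
    if (aw > 0) {
      auxP <- softmaxRows(fw$aux_logits)
      lab <- auxLab[[i]]
      loss <- loss - aw *
        mean(log(pmax(auxP[cbind(seq_along(lab), lab + 1L)], 1e-300)))
    }
    list(loss = loss, fw = fw, probs = probs, q = q, target = target,
         l_target = length(tt), auxP = auxP)
  }
  utterLoss <- function(p, i, keep_cache = FALSE)
    utterLossX(p, i, Xs[[i]], keep_cache)
  evalLoss <- function(p, idx)
    mean(vapply(idx, function(i) utterLoss(p, i)$loss, numeric(1)))
  valWer <- function(p) {
    mean(vapply(vaIdx, function(i) {
      Xp <- Xs[[i]]
      seqIds <- sosId
      for (k in seq_len(config$max_decode_len)) {
        fw <- transformerFwd(p, Xp, seqIds, config,
                             cross_bias = alignBias(align, length(seqIds),
                                                    nrow(Xp)))
        nxt <- which.max(fw$logits[nrow(fw$logits), ]) - 1L
        seqIds <- c(seqIds, nxt)
        if (nxt == eosId) break
      }
      hyp <- seqIds[-1]
      hyp <- hyp[!(hyp %in% c(sosId, eosId, 0L))]
      if (length(toks[[i]]) == 0) return(0)
      editOps(as.character(toks[[i]]), as.character(hyp))$distance /
        length(toks[[i]])
    }, numeric(1)))
  }
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  best <- list(params = params, val = Inf)
  bestWer <- list(params = params, wer = Inf)
  if (config$max_epochs >= 1) {
    state <- NULL
    stale <- 0L
    lr <- config$optimizer$lr
    augSd <- config$augment_sd
    # the dropout masks draw from this derived stream, so identical seeds
    # give bit-identical training trajectories
    withSeed(deriveSeed(seed, "trainloop"),
    for (ep in seq_len(config$max_epochs)) {
      if (!is.null(config$lr_decay_epoch) && ep == config$lr_decay_epoch + 1L) {
        lr <- lr * config$lr_decay_factor
        augSd <- augSd / 2
      }
      ord <- withSeed(deriveSeed(seed, paste0("lep", ep)), sample(trIdx))
      epLoss <- 0
      for (i in ord) {
        if (augSd > 0) {
          Xa <- withSeed(deriveSeed(seed, paste0("aug", ep, "_", i)),
                         Xs[[i]] + augSd *
                           matrix(stats::rnorm(length(Xs[[i]])),
                                  nrow(Xs[[i]])))
          ul <- utterLossX(params, i, Xa, keep_cache = TRUE)
        } else ul <- utterLoss(params, i, keep_cache = TRUE)
        n <- length(ul$target)
        dlogits <- (ul$probs - ul$q) / n
        e <- ul$fw$length_pred - ul$l_target
        dlen <- if (abs(e) <= 1) e else sign(e)
        daux <- NULL
        if (!is.null(ul$auxP)) {
          lab <- auxLab[[i]]
          daux <- ul$auxP
          daux[cbind(seq_along(lab), lab + 1L)] <-
            daux[cbind(seq_along(lab), lab + 1L)] - 1
          daux <- daux * ((config$aux_weight %||% 0) / length(lab))
        }
        g <- transformerBwd(params, ul$fw$cache, dlogits, dlen, config,
                            daux = daux)
        st <- adamStep(params, g, state, lr,
                       config$optimizer$weight_decay)
        params <- st$params; state <- st$state
        epLoss <- epLoss + ul$loss / length(ord)
      }
      vl <- evalLoss(params, vaIdx)
      vw <- NA_real_
      if (identical(config$checkpoint_metric, "wer") &&
          (ep %% config$wer_every == 0L || ep == config$max_epochs)) {
        vw <- valWer(params)
        if (vw < bestWer$wer - 1e-9)
          bestWer <- list(params = params, wer = vw)
      }
      history <- rbind(history,
                       data.frame(epoch = ep, train = epLoss, val = vl,
                                  val_wer = vw))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val_wer %s",
                        ep, epLoss, vl,
                        if (is.na(vw)) "-" else sprintf("%.3f", vw)))
      if (vl < best$val - 1e-6) {
        best <- list(params = params, val = vl)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    })
    adaptor$params <- if (identical(config$checkpoint_metric, "wer") &&
                          is.finite(bestWer$wer)) bestWer$params
      else best$params
  }
  adaptor$history <- history
  adaptor$channels <- channels
  adaptor
}

#' Greedy autoregressive token decoding
#'
#' Starting from SOS, repeatedly feeds the argmax token back until EOS or
#' `max_len` tokens. Returns the decoded ids without SOS/EOS for
#' downstream use, with the predicted length and the full id sequence as
#' attributes.
#'
#' @param adaptor a `LinguisticAdaptor`.
#' @param neural channels x T matrix or [NeuralRecording-class].
#' @param max_len decoding cap (defaults to the config value).
#' @return `TokenSequence`: integer token ids (0-based, PAD/SOS/EOS
#'   stripped) with attributes `length_pred` and `full` (SOS ... EOS).
#' @export
decodeTokens <- function(adaptor, neural, max_len = NULL) {
  if (is.null(max_len)) max_len <- adaptor$config$max_decode_len
  X <- if (is(neural, "NeuralRecording")) hgMatrix(neural) else neural
  if (nrow(X) != adaptor$n_channels)
    stop("channel mismatch: adaptor expects ", adaptor$n_channels,
         " channels, got ", nrow(X), call. = FALSE)
  ids <- tokenIds(adaptor$vocab)
  sosId <- ids[["<sos>"]]; eosId <- ids[["<eos>"]]
  Xp <- poolNeural(X, adaptor$config$downsample)
  seqIds <- sosId
  lenPred <- NA_real_
  for (k in seq_len(max_len)) {
    fw <- transformerFwd(adaptor$params, Xp, seqIds, adaptor$config,
                         cross_bias = alignBias(adaptor$align,
                                                length(seqIds), nrow(Xp)))
    lenPred <- fw$length_pred
    nxt <- which.max(fw$logits[nrow(fw$logits), ]) - 1L
    seqIds <- c(seqIds, nxt)
    if (nxt == eosId) break
  }
  core <- seqIds[-1]
  core <- core[!(core %in% c(ids[["<pad>"]], sosId, eosId))]
  structure(as.integer(core), class = "TokenSequence",
            length_pred = lenPred, full = as.integer(seqIds))
}
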