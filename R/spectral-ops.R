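## Spectral feature extraction and the loss/metric kernels.
##
## Framing convention: hop 320 samples at 16 kHz gives exactly 50 frames/s,
## matching the neural frame rate, and honours the vocoder's
## 320-samples-per-frame output contract. Frames are centred (mirror
## padding by n_fft/2), frame t centred at sample (t-1)*hop, frame count
## floor(n_samples / hop).

MEL_FLOOR <- 1e-5

#' @keywords internal
hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

#' Short-time Fourier transform (one-sided)
#'
#' @param x numeric waveform.
#' @param n_fft FFT size.
#' @param hop hop length in samples.
#' @return complex matrix, (n_fft/2 + 1) x n_frames.
#' @keywords internal
stft <- function(x, n_fft = 1024L, hop = 320L) {
  n <- length(x)
  nFrames <- max(1L, floor(n / hop))
  xp <- reflectPad(x, n_fft %/% 2L)
  idx <- outer(seq_len(n_fft), (seq_len(nFrames) - 1L) * hop, "+")
  frames <- matrix(xp[idx], nrow = n_fft) * hannWindow(n_fft)
  stats::mvfft(frames)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
}

#' Inverse STFT by windowed overlap-add with window-power normalization
#' @keywords internal
istft <- function(spec, n_fft = 1024L, hop = 320L, n_out = NULL) {
  nFrames <- ncol(spec)
  if (is.null(n_out)) n_out <- nFrames * hop
  full <- rbind(spec, Conj(spec[(n_fft %/% 2L):2L, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  win <- hannWindow(n_fft)
  frames <- frames * win
  pad <- n_fft %/% 2L
  y <- numeric(n_out + 2L * pad)
  wsum <- numeric(n_out + 2L * pad)
  for (t in seq_len(nFrames)) {
    at <- (t - 1L) * hop
    rng <- (at + 1L):(at + n_fft)
    y[rng] <- y[rng] + frames[, t]
    wsum[rng] <- wsum[rng] + win^2
  }
  y <- y / pmax(wsum, 1e-10)
  y[(pad + 1L):(pad + n_out)]
}

#' Mel filterbank matrix (HTK mel scale, triangular filters)
#'
#' @param n_mels number of bands.
#' @param n_fft FFT size.
#' @param sr sample rate in Hz.
#' @param fmin,fmax frequency range in Hz.
#' @return numeric matrix, n_mels x (n_fft/2 + 1).
#' @export
melFilterbank <- function(n_mels = 80L, n_fft = 1024L, sr = 16000,
                          fmin = 0, fmax = 8000) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  nBins <- n_fft %/% 2L + 1L
  freqs <- seq(0, sr / 2, length.out = nBins)
  pts <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, nBins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Centre frequencies of the mel filterbank bands (Hz)
#' @inheritParams melFilterbank
#' @export
melCenterFrequencies <- function(n_mels = 80L, fmin = 0, fmax = 8000) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_mels + 2L))
  pts[2:(n_mels + 1L)]
}

#' Log-mel spectrogram of a waveform
#'
#' The mel-spectrogram operator used throughout: STFT with n_fft 1024 and
#' hop 320, 80 triangular mel bands over 0-8 kHz, natural-log compression
#' with a 1e-5 amplitude floor. At 16 kHz audio this yields exactly 50
#' frames per second, frame-aligned with the neural recordings.
#'
#' @param x waveform (numeric vector or [AnnotatedUtterance-class]).
#' @param sr sample rate of `x` when a bare vector; inputs not at 16 kHz
#'   are resampled with a warning.
#' @param n_mels number of mel bands.
#' @return a [MelSpectrogram-class] (frames x n_mels).
#' @export
melSpectrogram <- function(x, sr = 16000, n_mels = 80L) {
  if (is(x, "AnnotatedUtterance")) { sr <- sampleRate(x); x <- waveform(x) }
  assertThat(length(x) > 0, "waveform must be non-empty")
  if (sr != 16000) {
    warning("resampling input from ", sr, " Hz to 16000 Hz")
    x <- signal::resample(x, 16000, sr)
    sr <- 16000
  }
  fb <- melFilterbank(n_mels = n_mels)
  mag <- Mod(stft(x))
  mel <- fb %*% mag
  vals <- t(log(pmax(mel, MEL_FLOOR)))
  new("MelSpectrogram", values = vals, frameRate = sr / 320,
      sampleRate = sr, hop = 320L)
}

#' @keywords internal
asMelMatrix <- function(x, sr = 16000) {
  if (is(x, "MelSpectrogram")) return(melValues(x))
  if (is.matrix(x)) return(x)
  melValues(melSpectrogram(x, sr = sr))
}

#' @keywords internal
padToCommonFrames <- function(a, b) {
  if (nrow(a) == nrow(b)) return(list(a = a, b = b))
  warning("mel frame counts differ (", nrow(a), " vs ", nrow(b),
          "); padding the shorter with the log floor")
  n <- max(nrow(a), nrow(b))
  padm <- function(m) {
    if (nrow(m) == n) return(m)
    rbind(m, matrix(log(MEL_FLOOR), n - nrow(m), ncol(m)))
  }
  list(a = padm(a), b = padm(b))
}

#' Mel-spectrogram L1 loss
#'
#' Mean absolute difference between the log-mel spectrograms of two
#' waveforms (or between two mel matrices supplied directly); the spectral
#' reconstruction loss of the acoustic pathway.
#'
#' @param x,y waveforms, [MelSpectrogram-class] objects, or mel matrices.
#' @return non-negative scalar.
#' @export
melL1Loss <- function(x, y) {
  m <- padToCommonFrames(asMelMatrix(x), asMelMatrix(y))
  mean(abs(m$a - m$b))
}

#' 5-point Laplacian with mirror padding
#' @keywords internal
laplacian2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- mirrorIndex(0:(nr + 1L), nr)
  ci <- mirrorIndex(0:(nc + 1L), nc)
  p <- m[ri, ci, drop = FALSE]
  p[1:nr, 2:(nc + 1L), drop = FALSE] + p[3:(nr + 2L), 2:(nc + 1L), drop = FALSE] +
    p[2:(nr + 1L), 1:nc, drop = FALSE] + p[2:(nr + 1L), 3:(nc + 2L), drop = FALSE] -
    4 * m
}

#' Laplacian spectral loss
#'
#' Mean absolute difference of the 5-point-Laplacian-filtered log-mel
#' spectrograms. The Laplacian annihilates constants, so this term compares
#' local spectrotemporal edge structure (formant transitions, onsets)
#' rather than overall level.
#'
#' @inheritParams melL1Loss
#' @return non-negative scalar.
#' @export
laplacianLoss <- function(x, y) {
  m <- padToCommonFrames(asMelMatrix(x), asMelMatrix(y))
  mean(abs(laplacian2d(m$a) - laplacian2d(m$b)))
}

#' Loss weight defaults
#'
#' The regularization coefficients of all compound losses: `lambda_lap`
#' weights the Laplacian term in the acoustic adaptor loss, `lambda_fm`
#' and `lambda_mel` weight feature matching and mel reconstruction in the
#' GAN generator loss, `lambda1_length` weights the length term of the
#' linguistic loss, and `weight_decay` is the L2 coefficient realized as
#' optimizer weight decay.
#'
#' @param ... named overrides.
#' @return named list of non-negative weights.
#' @export
lossWeights <- function(...) {
  w <- list(lambda_lap = 0.1, lambda_fm = 2, lambda_mel = 50,
            lambda1_length = 1, weight_decay = 0.01)
  o <- list(...)
  assertThat(all(names(o) %in% names(w)), "unknown loss weight name")
  w[names(o)] <- o
  assertThat(all(unlist(w) >= 0), "loss weights must be non-negative")
  w
}

#' Total acoustic adaptor loss
#'
#' `L = L_Mel + lambda_lap * L_Lap` with the default `lambda_lap = 0.1`.
#'
#' @inheritParams melL1Loss
#' @param weights see [lossWeights()].
#' @return scalar loss.
#' @export
acousticTotalLoss <- function(x, y, weights = lossWeights()) {
  melL1Loss(x, y) + weights$lambda_lap * laplacianLoss(x, y)
}

#' Discriminator output bundle for the GAN losses
#'
#' @param scores numeric vector, one scalar score per discriminator.
#' @param features list (per discriminator) of lists of numeric arrays,
#'   the per-layer feature maps.
#' @return a `DiscriminatorOutputs` list.
#' @export
discriminatorOutputs <- function(scores, features = NULL) {
  if (is.null(features)) features <- rep(list(list()), length(scores))
  assertThat(length(features) == length(scores),
             "one feature list per discriminator required")
  structure(list(scores = as.numeric(scores), features = features),
            class = "DiscriminatorOutputs")
}

#' GAN generator/discriminator losses (least-squares form)
#'
#' Computes the compound generator objective
#' `L_G = sum_k [ L_Adv + lambda_fm * L_FM ] + lambda_mel * L_Mel`
#' with least-squares adversarial terms (generator: `(D_k(x_sae) - 1)^2`;
#' discriminator: `(D_k(x) - 1)^2 + D_k(x_sae)^2`) and per-layer
#' normalized L1 feature matching
#' `L_FM = sum_i ||D^i(x) - D^i(x_sae)||_1 / N_i`. Defaults
#' `lambda_fm = 2`, `lambda_mel = 50`.
#'
#' @param real `DiscriminatorOutputs` for the original speech `x`.
#' @param fake `DiscriminatorOutputs` for the autoencoded speech `x_sae`.
#' @param x,x_sae waveforms for the mel term (or mel matrices); may be
#'   `NULL` to drop the mel term.
#' @param weights see [lossWeights()].
#' @return list with components `generator`, `discriminator`, `adv_g`,
#'   `adv_d`, `fm`, `mel`.
#' @export
ganGeneratorLoss <- function(real, fake, x = NULL, x_sae = NULL,
                             weights = lossWeights()) {
  assertThat(inherits(real, "DiscriminatorOutputs") &&
             inherits(fake, "DiscriminatorOutputs"),
             "real/fake must be DiscriminatorOutputs")
  K <- length(real$scores)
  assertThat(length(fake$scores) == K, "discriminator counts differ")
  fm <- 0
  for (k in seq_len(K)) {
    fr <- real$features[[k]]; ff <- fake$features[[k]]
    if (length(fr) != length(ff))
      stop("feature layer counts differ for discriminator ", k, call. = FALSE)
    for (i in seq_along(fr)) {
      if (length(fr[[i]]) != length(ff[[i]]))
        stop("feature map sizes differ at layer ", i, call. = FALSE)
      fm <- fm + sum(abs(fr[[i]] - ff[[i]])) / length(fr[[i]])
    }
  }
  advG <- sum((fake$scores - 1)^2)
  advD <- sum((real$scores - 1)^2 + fake$scores^2)
  mel <- if (is.null(x) || is.null(x_sae)) 0 else melL1Loss(x, x_sae)
  list(generator = advG + weights$lambda_fm * fm + weights$lambda_mel * mel,
       discriminator = advD, adv_g = advG, adv_d = advD, fm = fm, mel = mel)
}

#' Mel-frequency cepstral coefficients
#'
#' DCT-II of the log-mel spectrogram with the same framing as
#' [melSpectrogram()]; 13 coefficients per frame.
#'
#' @param x waveform, [MelSpectrogram-class], or mel matrix.
#' @param n_coef number of coefficients.
#' @return numeric matrix, frames x n_coef.
#' @export
mfcc <- function(x, n_coef = 13L) {
  m <- asMelMatrix(x)
  K <- ncol(m)
  k <- seq_len(K) - 0.5
  dct <- sqrt(2 / K) *
    t(vapply(seq_len(n_coef) - 1L, function(u) cos(pi * u * k / K),
             numeric(K)))
  dct[1, ] <- dct[1, ] / sqrt(2)
  m %*% t(dct)
}

#' @keywords internal
melFrameProbabilities <- function(m, eps = 1e-8) {
  p <- m - apply(m, 1L, min)
  p <- p + eps
  p / rowSums(p)
}

#' Per-frame KL divergence between probability matrices
#'
#' Rows are distributions; uses the 0 * log 0 = 0 convention.
#' @keywords internal
frameKl <- function(p, q) {
  terms <- ifelse(p > 0, p * log(p / q), 0)
  mean(rowSums(terms))
}

#' Fusion quality metric
#'
#' Compound spectral metric for fused output quality:
#' mel-spectrogram KL divergence plus the L1 MFCC distance,
#' `L = KL(Phi(x_gt), Phi(x_out)) + ||MFCC(x_gt) - MFCC(x_out)||_1`.
#' Each log-mel frame is shifted to be positive and normalized to sum 1
#' (floor 1e-8) so the KL term is well defined; the KL is averaged over
#' frames and the MFCC term is a mean absolute difference.
#'
#' @param x_gt,x_out waveforms of equal duration (or mel matrices).
#' @return non-negative scalar.
#' @export
fusionQualityLoss <- function(x_gt, x_out) {
  m <- padToCommonFrames(asMelMatrix(x_gt), asMelMatrix(x_out))
  kl <- frameKl(melFrameProbabilities(m$a), melFrameProbabilities(m$b))
  kl + mean(abs(mfcc(m$a) - mfcc(m$b)))
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' The noise is scaled against the measured signal power so the realized
#' ratio `10 log10(P_signal / P_noise)` equals `snr_db` exactly (up to
#' floating point), matching the additive-noise reference conditions.
#'
#' @param x non-silent waveform.
#' @param snr_db target SNR in dB.
#' @param seed RNG seed for the noise draw.
#' @return noisy waveform of the same length.
#' @export
addNoiseAtSnr <- function(x, snr_db, seed = NULL) {
  if (is(x, "AnnotatedUtterance")) x <- waveform(x)
  ps <- mean(x^2)
  assertThat(ps > 0, "SNR undefined for silent input")
  withSeed(seed, {
    n <- stats::rnorm(length(x))
    pn <- mean(n^2)
    x + n * sqrt(ps / (pn * 10^(snr_db / 10)))
  })
}
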