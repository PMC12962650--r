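test_that("mel framing: 1 s of 16 kHz audio gives exactly 50 frames", {
  m <- melSpectrogram(sin(2 * pi * 440 * seq_len(16000) / 16000))
  expect_equal(nrow(melValues(m)), 50L)
  expect_equal(ncol(melValues(m)), 80L)
  expect_equal(frameRate(m), 50)
})

test_that("silence maps to the log floor in every bin", {
  m <- melValues(melSpectrogram(numeric(8000)))
  expect_true(all(abs(m - log(1e-5)) < 1e-12))
})

test_that("a pure tone's mel argmax is the band nearest its frequency", {
  cf <- melCenterFrequencies()
  for (f in c(500, 1000, 3000)) {
    m <- melValues(melSpectrogram(sin(2 * pi * f * seq_len(16000) / 16000)))
    # interior frames only (edge frames see the padding)
    amax <- apply(m[5:45, ], 1L, which.max)
    expect_equal(as.integer(names(which.max(table(amax)))),
                 which.min(abs(cf - f)), tolerance = 1)
  }
})

test_that("mel L1 loss: identity, hand value, symmetry, triangle inequality", {
  x <- sin(2 * pi * 300 * seq_len(8000) / 16000)
  expect_identical(melL1Loss(x, x), 0)
  A <- matrix(c(1, 3, 2, 4), 2); B <- matrix(c(1, 3, 1, 3), 2)
  expect_equal(melL1Loss(A, B), 0.5)
  expect_equal(melL1Loss(A, B), melL1Loss(B, A))
  set.seed(1)
  for (k in 1:5) {
    a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
    cm <- matrix(rnorm(12), 3)
    expect_lte(melL1Loss(a, cm), melL1Loss(a, b) + melL1Loss(b, cm) + 1e-12)
  }
})

test_that("laplacian loss annihilates constants and matches the hand stencil", {
  A <- matrix(rnorm(40), 5)
  expect_identical(laplacianLoss(A, A), 0)
  expect_equal(laplacianLoss(A, A + 2.5), 0)
  imp <- matrix(0, 3, 3); imp[2, 2] <- 1
  # centre -4, edge neighbours 1 each plus a mirrored centre contribution
  expect_equal(laplacianLoss(imp, matrix(0, 3, 3)), 4 / 3)
})

test_that("acoustic total loss combines mel and laplacian at lambda 0.1", {
  x <- sin(2 * pi * 500 * seq_len(6400) / 16000)
  expect_identical(acousticTotalLoss(x, x), 0)
  A <- matrix(rnorm(60), 6); B <- matrix(rnorm(60), 6)
  expect_equal(acousticTotalLoss(A, B),
               melL1Loss(A, B) + 0.1 * laplacianLoss(A, B))
})

test_that("GAN losses follow the least-squares form with fm normalization", {
  real <- discriminatorOutputs(1, list(list(matrix(1, 2, 3))))
  fake <- discriminatorOutputs(0, list(list(matrix(1, 2, 3))))
  g <- ganGeneratorLoss(real, fake)
  expect_equal(g$adv_d, 0)       # LSGAN optimum for the discriminator
  expect_equal(g$fm, 0)          # identical feature maps
  fake2 <- discriminatorOutputs(0.5, list(list(matrix(1, 2, 3))))
  expect_equal(ganGeneratorLoss(real, fake2)$adv_g, 0.25)
  # per-layer normalized L1 and the lambda weighting
  r <- discriminatorOutputs(c(1, 1), list(list(matrix(2, 2, 2)), list()))
  f <- discriminatorOutputs(c(0, 0), list(list(matrix(1, 2, 2)), list()))
  out <- ganGeneratorLoss(r, f)
  expect_equal(out$fm, 1)                       # 4 * |1| / 4
  expect_equal(out$generator, out$adv_g + 2 * out$fm)
  # structural error on mismatched layer counts
  bad <- discriminatorOutputs(c(0, 0), list(list(matrix(1, 2, 2),
                                                 matrix(1, 2, 2)), list()))
  expect_error(ganGeneratorLoss(r, bad), "feature layer counts")
})

test_that("mfcc is deterministic, constant on silence, energy-monotone", {
  sil <- mfcc(numeric(4800))
  expect_true(all(abs(sweep(sil, 2, sil[1, ])) < 1e-9))
  x <- sin(2 * pi * 400 * seq_len(4800) / 16000)
  expect_identical(mfcc(x), mfcc(x))
  loud <- mfcc(x); quiet <- mfcc(0.1 * x)
  expect_gt(mean(loud[, 1]), mean(quiet[, 1]))
})

test_that("fusion quality loss: identity zero, closed-form KL, non-negative", {
  x <- sin(2 * pi * 700 * seq_len(6400) / 16000)
  expect_equal(fusionQualityLoss(x, x), 0)
  p <- matrix(c(1, 0), 1); q <- matrix(c(0.5, 0.5), 1)
  expect_equal(duovox:::frameKl(p, q), log(2))
  set.seed(2)
  for (k in 1:20) {
    a <- duovox:::melFrameProbabilities(matrix(rnorm(20), 2))
    b <- duovox:::melFrameProbabilities(matrix(rnorm(20), 2))
    expect_gte(duovox:::frameKl(a, b), -1e-12)
  }
})

test_that("additive noise hits the requested SNR exactly", {
  x <- sin(2 * pi * 440 * seq_len(16000) / 16000)
  for (snr in c(-10, 0, 10)) {
    y <- addNoiseAtSnr(x, snr, seed = 4)
    realized <- 10 * log10(mean(x^2) / mean((y - x)^2))
    expect_lt(abs(realized - snr), 0.1)
  }
  y60 <- addNoiseAtSnr(x, 60, seed = 4)
  expect_lt(sqrt(sum((y60 - x)^2)) / sqrt(sum(x^2)), 0.002)
  expect_identical(addNoiseAtSnr(x, 0, seed = 9), addNoiseAtSnr(x, 0, seed = 9))
  expect_error(addNoiseAtSnr(numeric(100), 0), "silent")
})

test_that("mel framing and vocoder framing agree", {
  u <- tinyUtterance()
  m <- melSpectrogram(u)
  w <- vocode(melValues(m)[1:20, ], n_iter = 5)
  expect_length(w, 20L * 320L)
  expect_equal(nrow(melValues(melSpectrogram(w))), 20L)
})

test_that("griffin-lim round trip preserves vowel spectra and floors silence", {
  inv <- defaultPhonemeInventory()
  x <- duovox:::synthPhoneme(inv$aa, seed = 1)
  m <- melValues(melSpectrogram(x))
  y <- vocode(m, n_iter = 30)
  m2 <- melValues(melSpectrogram(y))
  expect_gt(cor(as.numeric(m), as.numeric(m2[seq_len(nrow(m)), ])), 0.9)
  quiet <- vocode(matrix(log(1e-5), 10, 80), n_iter = 5)
  expect_lt(sqrt(mean(quiet^2)), 1e-3)
})

test_that("non-16 kHz input is resampled with a warning", {
  x <- sin(2 * pi * 440 * seq_len(8000) / 8000)
  expect_warning(m <- melSpectrogram(x, sr = 8000), "resampling")
  expect_equal(nrow(melValues(m)), 50L)   # 1 s at any input rate
})
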