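test_that("spectral subtraction improves SNR on noisy speech", {
  # the noise profile is estimated from the quietest frames, so the
  # signal must contain silence -- as the synthesized utterances do
  clean <- waveform(tinyUtterance())
  withr::with_seed(71, noise <- rnorm(length(clean)))
  noise <- noise * sqrt(mean(clean^2) / mean(noise^2))   # 0 dB overall
  noisy <- clean + noise
  den <- denoiseReference(noisy)
  snr <- function(x) 10 * log10(mean(clean^2) / mean((x - clean)^2))
  expect_gte(snr(den) - snr(noisy), 3)
  expect_lte(sqrt(mean(den^2)), sqrt(mean(noisy^2)) + 1e-12)
  # near-distortionless on already-clean input
  den2 <- denoiseReference(clean)
  expect_gt(cor(den2, clean), 0.95)
  expect_true(all(denoiseReference(numeric(4000)) == 0))
})

test_that("the LTAS baseline transfers the reference's long-term spectrum", {
  v <- tinyVocab()
  u <- tinyUtterance()
  # a spectrally coloured reference: low-passed version of the utterance
  S <- duovox:::stft(waveform(u))
  gain <- exp(-(seq_len(nrow(S)) - 1) / 80)
  ref <- duovox:::istft(S * gain, n_out = length(waveform(u)))
  txt <- paste(vocabWords(v)[c(1, 4)], collapse = " ")
  req <- cloneRequest(ref, txt, v, seed = 2)
  out <- voiceClone(req)
  plain <- waveform(synthesizeUtterance(vocabWords(v)[c(1, 4)], v, seed = 2))
  dist <- function(x) {
    a <- ltas(x); b <- ltas(ref)
    sqrt(mean((log(pmax(a, 1e-8)) - log(pmax(b, 1e-8)))^2))
  }
  expect_lt(dist(as.numeric(out)), dist(plain))
})

test_that("clone request validation and engine registry behave", {
  v <- tinyVocab()
  ref <- sin(2 * pi * 300 * seq_len(16000) / 16000)
  expect_error(cloneRequest(ref, "  ", v), "non-empty")
  expect_error(cloneRequest(ref[1:1000], "word", v), "0.5 s")
  req <- cloneRequest(ref, vocabWords(v)[1], v, engine = "missing")
  expect_error(voiceClone(req), "unknown clone engine")
  registerCloneEngine("echo", function(request) request$reference)
  req2 <- cloneRequest(ref, vocabWords(v)[1], v, engine = "echo")
  expect_identical(voiceClone(req2), ref)
})

test_that("fused duration grows with word count", {
  v <- tinyVocab()
  ref <- waveform(tinyUtterance())
  lens <- vapply(1:3, function(k) {
    req <- cloneRequest(ref, paste(vocabWords(v)[seq_len(k)],
                                   collapse = " "), v, seed = 1)
    length(voiceClone(req))
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("fusion preserves linguistic content better than the acoustic route alone", {
  # pathway stand-ins at their noise ceiling: the "speaker" carries a
  # smooth spectral coloration (the identity the acoustic pathway would
  # supply); the linguistic text is the true word sequence
  v <- tinyVocab()
  colorize <- function(x) {
    S <- duovox:::stft(x)
    gain <- exp(-(seq_len(nrow(S)) - 1) / 120)   # speaker-specific tilt
    duovox:::istft(S * gain, n_out = length(x))
  }
  werFused <- werAcoustic <- fqFused <- fqPlain <- numeric(3)
  withr::with_seed(121, {
    for (k in 1:3) {
      words <- sample(vocabWords(v), 3)
      u <- synthesizeUtterance(words, v, seed = 300 + k, id = paste0("f", k))
      gt <- colorize(waveform(u))
      # acoustic pathway output: vocoded spectrogram of the coloured truth
      acoustic <- vocode(melValues(melSpectrogram(gt)), n_iter = 25)
      req <- cloneRequest(denoiseReference(acoustic),
                          paste(words, collapse = " "), v, seed = k)
      fused <- as.numeric(voiceClone(req))
      recF <- toyRecognize(fused, v)
      recA <- toyRecognize(acoustic, v)
      werFused[k] <- errorRate(words, recF$words)
      werAcoustic[k] <- errorRate(words, recA$words)
      plain <- waveform(synthesizeUtterance(words, v, seed = k,
                                            id = "plain"))
      n <- min(length(fused), length(gt))
      m <- min(length(plain), length(gt))
      ld <- function(x, ref) sqrt(mean((log(pmax(ltas(x), 1e-8)) -
                                          log(pmax(ltas(ref), 1e-8)))^2))
      fqFused[k] <- ld(fused[1:n], gt[1:n])
      fqPlain[k] <- ld(plain[1:m], gt[1:m])
    }
  })
  # linguistic content survives fusion at least as well as the acoustic
  # route alone
  expect_lte(mean(werFused), mean(werAcoustic))
  # the LTAS transfer moves the long-term spectrum onto the target voice
  expect_lt(median(fqFused), median(fqPlain))
})
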