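# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tinyVocab <- function() fixture("tinyVocab", function()
  buildVocabulary(12L, seed = 0))

tinyUtterance <- function() fixture("tinyUtterance", function() {
  v <- tinyVocab()
  synthesizeUtterance(vocabWords(v)[c(2, 5, 9)], v, seed = 1)
})

# small paired dataset: 24 sentences, 16 channels (10 responsive), low noise
tinyDataset <- function() fixture("tinyDataset", function()
  makeDataset(defaultDatasetConfig(n_sentences = 24L, n_channels = 16L,
                                   n_responsive = 10L, noise_sd = 0.3,
                                   n_words = 12L,
                                   words_range = c(2L, 4L)),
              seed = 7))

tinySelection <- function() fixture("tinySelection", function() {
  ds <- tinyDataset()
  comb <- combineRecordings(ds, splitIndices(ds, "train"))
  selectElectrodes(responsivenessTest(comb$recording, comb$onsets))
})

# independent oracle: direct memoized recursion on the definition of
# edit distance over suffixes (editOps itself is an iterative
# prefix-table dynamic program with traceback)
bruteEditDistance <- function(ref, hyp) {
  n <- length(ref); m <- length(hyp)
  memo <- matrix(NA_integer_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- min(rec(i - 1L, j - 1L) + (ref[i] != hyp[j]),
             rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L)
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

expect_rel_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a - b) / max(1e-12, abs(b)), tol)
}

withSeedWave <- function(n, seed) { set.seed(seed); rnorm(n) }

# Monte-Carlo oracle: each substituted reference symbol replaced
# uniformly by one of the other P-1 symbols
simUniformSubstitution <- function(cls, e, draws) {
  P <- length(cls)
  others <- vapply(names(cls), function(s) setdiff(names(cls), s),
                   character(P - 1))
  refIdx <- sample.int(P, draws, replace = TRUE, prob = e / sum(e))
  u <- sample.int(P - 1, draws, replace = TRUE)
  hyps <- others[cbind(u, refIdx)]
  within <- sum(cls[refIdx] == cls[hyps])
  within / (draws - within)
}
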