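## External interfaces: 16 kHz 16-bit PCM mono WAV, TIMIT-style .wrd/.phn
## label files (one "start_sample end_sample label" line per segment,
## half-open sample intervals), HDF5 neural matrices, JSON manifests.

#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param x waveform in [-1, 1] (clipped) or an
#'   [AnnotatedUtterance-class].
#' @param path output file.
#' @param sr sample rate.
#' @return invisibly, `path`.
#' @export
writeWavPcm <- function(x, path, sr = 16000) {
  if (is(x, "AnnotatedUtterance")) { sr <- sampleRate(x); x <- waveform(x) }
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file written by [writeWavPcm()] (or any canonical
#'   16-bit PCM mono RIFF file).
#' @return list with `wave` (numeric in [-1, 1]) and `sr`.
#' @export
readWavPcm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L)
  assertThat(riff == "RIFF", "not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  assertThat(readChar(con, 4L) == "WAVE", "not a WAVE file")
  sr <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0 || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2L, size = 2, endian = "little")
      assertThat(fmt[1] == 1L && fmt[2] == 1L, "only PCM mono supported")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8L))
    } else if (id == "data") {
      wave <- readBin(con, integer(), n = size %/% 2L, size = 2,
                      endian = "little") / 32767
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  list(wave = wave, sr = sr)
}

#' Write TIMIT-style label files
#'
#' One line per segment: `start_sample end_sample label`, half-open
#' intervals.
#'
#' @param intervals data.frame with `start`, `end`, `label`.
#' @param path output file (conventionally `.wrd` or `.phn`).
#' @return invisibly, `path`.
#' @export
writeTimitLabels <- function(intervals, path) {
  lines <- sprintf("%d %d %s", as.integer(intervals$start),
                   as.integer(intervals$end), intervals$label)
  writeLines(lines, path)
  invisible(path)
}

#' Read TIMIT-style label files
#' @param path label file.
#' @return data.frame with `start`, `end`, `label`.
#' @export
readTimitLabels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(start = vapply(parts, function(p) as.integer(p[1]), 1L),
             end = vapply(parts, function(p) as.integer(p[2]), 1L),
             label = vapply(parts, function(p) p[3], ""))
}

#' Write an utterance bundle (WAV + .wrd + .phn)
#'
#' @param utterance an [AnnotatedUtterance-class].
#' @param stem path stem; writes `<stem>.wav`, `<stem>.wrd`, `<stem>.phn`.
#' @return invisibly, the three paths.
#' @export
writeUtterance <- function(utterance, stem) {
  p <- c(paste0(stem, ".wav"), paste0(stem, ".wrd"), paste0(stem, ".phn"))
  writeWavPcm(utterance, p[1])
  writeTimitLabels(wordIntervals(utterance), p[2])
  writeTimitLabels(phonemeIntervals(utterance), p[3])
  invisible(p)
}

#' @keywords internal
needRhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 neural matrix I/O",
         call. = FALSE)
}

#' Write a neural recording to HDF5
#'
#' Datasets `/neural` (channels x frames) and `/blocks` (1-based frame
#' starts), attributes `frame_rate` and `seed`.
#'
#' @param rec a [NeuralRecording-class].
#' @param path output `.h5` file (overwritten).
#' @param seed generating seed recorded as an attribute.
#' @return invisibly, `path`.
#' @export
writeNeuralH5 <- function(rec, path, seed = NA_integer_) {
  needRhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(hgMatrix(rec), path, "neural")
  rhdf5::h5write(blockStarts(rec), path, "blocks")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(frameRate(rec), fid, "frame_rate")
  rhdf5::h5writeAttribute(as.integer(seed), fid, "seed")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a neural recording from HDF5
#' @param path `.h5` file written by [writeNeuralH5()].
#' @return a [NeuralRecording-class].
#' @export
readNeuralH5 <- function(path) {
  needRhdf5()
  hg <- rhdf5::h5read(path, "neural")
  blocks <- as.integer(rhdf5::h5read(path, "blocks"))
  fid <- rhdf5::H5Fopen(path)
  fr <- tryCatch(as.numeric(rhdf5::h5readAttributes(fid, "/")$frame_rate),
                 error = function(e) 50)
  rhdf5::H5Fclose(fid)
  if (length(fr) == 0 || is.na(fr)) fr <- 50
  new("NeuralRecording", hg = hg, frameRate = fr, blockStarts = blocks,
      channelIds = seq_len(nrow(hg)))
}

#' Write a JSON run manifest
#'
#' @param path output file.
#' @param stage stage name.
#' @param config the configuration used.
#' @param seed the seed used.
#' @param inputs character vector of input artifact paths.
#' @param outputs character vector of written artifacts.
#' @return invisibly, `path`.
#' @export
writeManifest <- function(path, stage, config, seed, inputs = character(0),
                          outputs = character(0)) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("duovox")),
                   seed = seed,
                   config = config,
                   config_hash = sprintf("%08x",
                     sum(utf8ToInt(as.character(cfgJson)) *
                           (seq_len(nchar(cfgJson)) %% 997))),
                   inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
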