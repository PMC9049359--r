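# File I/O: native columnar + JSON sidecar interchange, EDF/BDF at the
# boundary, and JSON serialisation of trained models.
#
# The native format is plain text on purpose: EDF's 16-bit quantisation would
# perturb exact regression tests, so EDF/BDF are supported for
# interoperability only.

#' Write a recording as a columnar file with JSON sidecar
#'
#' The data file holds one column per channel (tab-separated, full double
#' precision); the sidecar `<path>.json` records the sampling rate, channel
#' labels and sample count.
#'
#' @param recording a [Recording-class].
#' @param path output file path (sidecar written at `<path>.json`).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "Recording"))
  X <- eegData(recording)
  utils::write.table(format(t(X), digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(format = "ssvepDS-recording", version = 1L,
               fs = sampleRate(recording), channels = channelNames(recording),
               n_samples = nSamples(recording))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording
#'
#' Dispatches on the file extension: `.edf` / `.bdf` go through [readEDF()],
#' anything else is read as the native columnar + JSON sidecar format. A
#' missing or inconsistent sidecar, or a data file with fewer samples than the
#' sidecar declares, is a hard error rather than a silent truncation.
#'
#' @param path file path.
#' @return A [Recording-class].
#' @export
readRecording <- function(path) {
  if (grepl("\\.(edf|bdf)$", path, ignore.case = TRUE))
    return(readEDF(path))
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "ssvepDS-recording"))
    stop("malformed sidecar: ", side)
  X <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(X) <- NULL
  if (nrow(X) != meta$n_samples || ncol(X) != length(meta$channels))
    stop(sprintf("truncated or inconsistent data file: %d x %d read, %d x %d declared",
                 nrow(X), ncol(X), meta$n_samples, length(meta$channels)))
  Recording(t(X), fs = meta$fs, channels = meta$channels)
}

#' Write / read a labeled trial set
#'
#' Sessions are stored as one columnar data file holding all trials
#' concatenated along time, with the sidecar recording the sampling rate,
#' per-trial labels, the trial length and the class count.
#'
#' @param trialset a [TrialSet-class].
#' @param path output path.
#' @return `writeSession`: `path` invisibly; `readSession`: a
#'   [TrialSet-class].
#' @export
writeSession <- function(trialset, path) {
  stopifnot(is(trialset, "TrialSet"))
  X <- do.call(cbind, trials(trialset))
  utils::write.table(format(t(X), digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(format = "ssvepDS-session", version = 1L,
               fs = sampleRate(trialset), channels = channelNames(trialset),
               labels = trialLabels(trialset),
               trial_samples = nSamples(trialset),
               n_classes = nClasses(trialset))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("session file or sidecar missing: ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "ssvepDS-session"))
    stop("malformed sidecar: ", side)
  X <- t(as.matrix(utils::read.table(path, sep = "\t")))
  dimnames(X) <- NULL
  nT <- length(meta$labels)
  if (ncol(X) != nT * meta$trial_samples)
    stop("truncated session data file")
  trialList <- lapply(seq_len(nT), function(i)
    X[, ((i - 1) * meta$trial_samples + 1):(i * meta$trial_samples),
      drop = FALSE])
  TrialSet(trialList, meta$labels, fs = meta$fs, nClasses = meta$n_classes,
           channels = meta$channels)
}

.edfPad <- function(s, width) {
  s <- substr(paste0(s, strrep(" ", width)), 1, width)
  charToRaw(s)
}

#' Write a recording as EDF or BDF
#'
#' Minimal European Data Format writer: EDF stores 16-bit samples, BDF
#' (`format = "bdf"`, the BioSemi 24-bit variant) stores 24-bit samples.
#' Physical scaling is chosen symmetrically from the data range, so the
#' quantisation error is `range / 2^16` (EDF) or `range / 2^24` (BDF) per
#' sample. Data are split into 1-second records when the length allows,
#' otherwise written as a single record.
#'
#' @param recording a [Recording-class].
#' @param path output path.
#' @param format `"edf"` or `"bdf"`.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path, format = c("edf", "bdf")) {
  format <- match.arg(format)
  X <- eegData(recording)
  fs <- sampleRate(recording)
  L <- nrow(X); n <- ncol(X)
  if (n %% round(fs) == 0 && fs == round(fs)) {
    spr <- as.integer(fs); nrec <- n %/% spr; dur <- 1
  } else {
    spr <- n; nrec <- 1L; dur <- n / fs
  }
  digMax <- if (format == "edf") 32767L else 8388607L
  digMin <- if (format == "edf") -32768L else -8388608L
  # the physical range must survive its 8-character ASCII header field
  # exactly, or read-back scaling would not match the one used here
  physMax <- max(abs(range(X)), 1e-12)
  for (dg in 6:1) {
    s <- sprintf("%.*g", dg, physMax * (1 + 10^(-dg)))
    if (nchar(s) <= 7) break
  }
  physMax <- as.numeric(s)
  physMin <- -physMax
  gain <- (physMax - physMin) / (digMax - digMin)

  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "bdf") {
    writeBin(as.raw(255), con)
    writeBin(.edfPad("BIOSEMI", 7), con)
  } else {
    writeBin(.edfPad("0", 8), con)
  }
  writeBin(.edfPad("ssvepDS synthetic recording", 80), con)  # patient id
  writeBin(.edfPad("ssvepDS", 80), con)                      # recording id
  writeBin(.edfPad("01.01.00", 8), con)                      # start date
  writeBin(.edfPad("00.00.00", 8), con)                      # start time
  writeBin(.edfPad(as.character(256L * (1L + L)), 8), con)   # header bytes
  writeBin(.edfPad(if (format == "bdf") "24BIT" else "", 44), con)
  writeBin(.edfPad(as.character(nrec), 8), con)
  writeBin(.edfPad(format(dur, digits = 8), 8), con)
  writeBin(.edfPad(as.character(L), 4), con)
  pad <- function(vals, width)
    writeBin(do.call(c, lapply(vals, .edfPad, width = width)), con)
  pad(channelNames(recording), 16)          # label
  pad(rep("", L), 80)                       # transducer
  pad(rep("uV", L), 8)                      # physical dimension
  pad(rep(paste0("-", s), L), 8)
  pad(rep(s, L), 8)
  pad(rep(as.character(digMin), L), 8)
  pad(rep(as.character(digMax), L), 8)
  pad(rep("", L), 80)                       # prefiltering
  pad(rep(as.character(spr), L), 8)
  pad(rep("", L), 32)                       # reserved

  dig <- round((X - physMin) / gain) + digMin
  dig <- pmin(pmax(dig, digMin), digMax)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(dig[, idx, drop = FALSE])    # per channel, time-contiguous
    v <- as.integer(block)                  # column order = channel blocks
    if (format == "edf") {
      writeBin(v, con, size = 2, endian = "little")
    } else {
      u <- v
      u[u < 0] <- u[u < 0] + 16777216
      b <- rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L)
      writeBin(as.raw(b), con)
    }
  }
  invisible(path)
}

#' Read an EDF or BDF recording
#'
#' Minimal reader for continuous EDF (16-bit) and BioSemi BDF (24-bit) files
#' with identical sampling rates across channels. Annotation channels are not
#' supported.
#'
#' @param path file path; the variant is detected from the magic bytes.
#' @return A [Recording-class] with physically scaled values.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  bdf <- magic[1] == as.raw(255)
  if (!bdf && rawToChar(magic[1]) != "0") stop("malformed EDF header")
  gets <- function(k) rawToChar(readBin(con, "raw", k))
  getn <- function(k) as.numeric(trimws(gets(k)))
  gets(80); gets(80); gets(8); gets(8)
  headerBytes <- getn(8)
  gets(44)
  nrec <- getn(8)
  dur <- getn(8)
  L <- as.integer(getn(4))
  if (!is.finite(nrec) || !is.finite(L) || L < 1) stop("malformed EDF header")
  field <- function(width) vapply(seq_len(L), function(i) gets(width), "")
  labels <- trimws(field(16))
  field(80); field(8)
  physMin <- as.numeric(trimws(field(8)))
  physMax <- as.numeric(trimws(field(8)))
  digMin <- as.numeric(trimws(field(8)))
  digMax <- as.numeric(trimws(field(8)))
  field(80)
  spr <- as.integer(trimws(field(8)))
  field(32)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  if (headerBytes != 256 * (1 + L)) stop("malformed EDF header")
  bps <- if (bdf) 3L else 2L
  n <- nrec * spr[1]
  X <- matrix(0, L, n)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "raw", L * spr[1] * bps)
    if (length(raw) < L * spr[1] * bps)
      stop("truncated data record in ", path)
    if (bdf) {
      b <- matrix(as.integer(raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
    } else {
      v <- readBin(raw, "integer", n = L * spr[1], size = 2,
                   endian = "little")
    }
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    X[, idx] <- t(matrix(v, nrow = spr[1]))
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  X <- X * gain + (physMin - digMin * gain)
  fs <- spr[1] / dur
  Recording(X, fs = fs, channels = labels)
}

#' Serialise / restore a trained model cache
#'
#' Stores the complete per-window-length model cache (filter banks, LDA
#' models, FIR coefficients, configuration) as a single versioned JSON
#' container, full double precision.
#'
#' @param cache a [ModelCache-class].
#' @param path output path.
#' @return `saveModelCache`: `path` invisibly; `loadModelCache`: a
#'   [ModelCache-class].
#' @export
saveModelCache <- function(cache, path) {
  stopifnot(is(cache, "ModelCache"))
  ser <- list(
    format = "ssvepDS-modelcache", version = 1L,
    windows = cache@windows, coeffs = cache@coeffs, fStim = cache@fStim,
    fSample = cache@fSample, chunkSamples = cache@chunkSamples,
    banks = lapply(cache@banks, function(b) list(
      A = b@A, B = b@B, cors = b@cors, windowLen = b@windowLen,
      nComponents = b@nComponents)),
    ldas = lapply(cache@ldas, function(m) list(
      means = m@means, covariance = m@covariance, priors = m@priors,
      gamma = m@gamma)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModelCache
#' @export
loadModelCache <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ser$format, "ssvepDS-modelcache"))
    stop("not a model cache container: ", path)
  asMat <- function(rows) do.call(rbind, lapply(rows, unlist))
  windows <- as.integer(unlist(ser$windows))
  banks <- lapply(seq_along(windows), function(i) {
    b <- ser$banks[[i]]
    new("CCAFilterBank",
        A = lapply(b$A, asMat), B = lapply(b$B, asMat),
        cors = lapply(b$cors, unlist),
        windowLen = as.integer(b$windowLen), fStim = ser$fStim,
        fSample = ser$fSample, nComponents = as.integer(b$nComponents))
  })
  ldas <- lapply(seq_along(windows), function(i) {
    m <- ser$ldas[[i]]
    new("LDAModel", means = asMat(m$means),
        covariance = asMat(m$covariance),
        priors = unlist(m$priors), gamma = as.numeric(m$gamma))
  })
  names(banks) <- names(ldas) <- as.character(windows)
  new("ModelCache", windows = windows, banks = banks, ldas = ldas,
      coeffs = as.numeric(ser$coeffs), fStim = ser$fStim,
      fSample = ser$fSample, chunkSamples = as.integer(ser$chunkSamples))
}
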