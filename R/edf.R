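#' @include AllClasses.R registry.R
NULL

## EDF (European Data Format, 16-bit) reader/writer.
##
## EDF is a fixed-layout format: a 256-byte ASCII header, 256 ASCII bytes
## per signal, then data records of little-endian int16 samples scaled
## channel-wise between a physical and a digital range. This implementation
## covers continuous recordings with one common sampling rate, which is all
## the pipeline produces and consumes.

.padField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

# Format a physical bound so it survives the 8-char field and can be
# parsed back exactly; scaling uses the written string, so the round trip
# is limited only by 16-bit quantization.
.formatPhys <- function(x) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), format = "g", digits = d, width = 1)
    if (nchar(s) <= 8) return(s)
  }
  substr(s, 1, 8)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records. The sampling rate must be a
#' whole number; trailing samples that do not fill a record are dropped
#' with a warning. Each channel is scaled to its own physical range, so
#' quantization error is at most (max - min) / 65535 per channel.
#'
#' @param rec an [EEGRecording-class]; all samples must be finite.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEDF <- function(rec, path) {
  stopIfNot(is(rec, "EEGRecording"), "rec must be an EEGRecording")
  validObject(rec)
  rate <- sampleRate(rec)
  stopIfNot(rate == round(rate), "EDF writer requires an integer sample rate")
  dat <- recordingData(rec)
  if (!all(is.finite(dat))) stop("non-finite sample values; refusing to write")
  ns <- nrow(dat)
  spr <- as.integer(rate)
  nrec <- floor(ncol(dat) / spr)
  stopIfNot(nrec >= 1, "recording shorter than one 1-second EDF record")
  if (nrec * spr < ncol(dat)) {
    warning("dropping ", ncol(dat) - nrec * spr,
            " trailing samples that do not fill an EDF record")
    dat <- dat[, seq_len(nrec * spr), drop = FALSE]
  }

  pmin <- apply(dat, 1, min)
  pmax <- apply(dat, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  pminS <- vapply(pmin, .formatPhys, character(1))
  pmaxS <- vapply(pmax, .formatPhys, character(1))
  pminW <- as.numeric(pminS)
  pmaxW <- as.numeric(pmaxS)
  pminW[pminW > pmin] <- pmin[pminW > pmin]  # widened bound stays a bound
  pmaxW[pmaxW < pmax] <- pmax[pmaxW < pmax]
  pminS <- vapply(pminW, .formatPhys, character(1))
  pmaxS <- vapply(pmaxW, .formatPhys, character(1))
  pminW <- as.numeric(pminS)
  pmaxW <- as.numeric(pmaxS)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8),
    .padField(subjectId(rec), 80),
    .padField(paste("group:", groupLabel(rec), "ref:", rec@reference), 80),
    .padField("01.01.00", 8),
    .padField("00.00.00", 8),
    .padField(256 * (ns + 1), 8),
    .padField("", 44),
    .padField(nrec, 8),
    .padField(1, 8),
    .padField(ns, 4),
    paste(vapply(channelLabels(rec), .padField, character(1), width = 16),
          collapse = ""),
    paste(rep(.padField("", 80), ns), collapse = ""),
    paste(rep(.padField("uV", 8), ns), collapse = ""),
    paste(vapply(pminS, .padField, character(1), width = 8), collapse = ""),
    paste(vapply(pmaxS, .padField, character(1), width = 8), collapse = ""),
    paste(rep(.padField(dmin, 8), ns), collapse = ""),
    paste(rep(.padField(dmax, 8), ns), collapse = ""),
    paste(rep(.padField("", 80), ns), collapse = ""),
    paste(rep(.padField(spr, 8), ns), collapse = ""),
    paste(rep(.padField("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  gain <- (dmax - dmin) / (pmaxW - pminW)
  dig <- round((dat - pminW) * gain + dmin)
  dig[dig < dmin] <- dmin
  dig[dig > dmax] <- dmax
  # records in time order; within a record, each signal's samples in a block
  arr <- array(t(dig), dim = c(spr, nrec, ns))    # sample, record, signal
  out <- as.integer(aperm(arr, c(1, 3, 2)))       # sample, signal, record
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

.readField <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)),
         character(1))
}

#' Read a recording from an EDF file
#'
#' Samples are converted to microvolts using the per-channel physical /
#' digital scaling in the header ("mV" and "V" channels are rescaled).
#' The subject id is taken from the patient field (falling back to the
#' file name) and the group label from the optional manifest.
#'
#' @param path an EDF file.
#' @param labels optional label manifest: either a path readable by
#'   [readLabelManifest()] or a data.frame with columns `subject_id` and
#'   `group`.
#' @param registry optional [PairRegistry-class]; when supplied, the
#'   recording must contain every registry electrode (missing ones are
#'   reported by name).
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path, labels = NULL, registry = NULL) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .readField(con, 8)
  if (version != "0") stop("not an EDF file (bad version field): ", path)
  patient <- .readField(con, 80)
  recinfo <- .readField(con, 80)
  .readField(con, 8); .readField(con, 8)         # date, time
  .readField(con, 8); .readField(con, 44)        # header bytes, reserved
  nrec <- as.integer(.readField(con, 8))
  recdur <- as.numeric(.readField(con, 8))
  ns <- as.integer(.readField(con, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: ", path)
  lab <- .readField(con, 16, ns)
  .readField(con, 80, ns)                        # transducer
  dimu <- .readField(con, 8, ns)
  pmin <- as.numeric(.readField(con, 8, ns))
  pmax <- as.numeric(.readField(con, 8, ns))
  dmin <- as.numeric(.readField(con, 8, ns))
  dmax <- as.numeric(.readField(con, 8, ns))
  .readField(con, 80, ns)                        # prefiltering
  spr <- as.integer(.readField(con, 8, ns))
  .readField(con, 32, ns)                        # reserved
  if (any(is.na(pmin) | is.na(pmax) | is.na(spr)) || any(spr < 1)) {
    stop("malformed EDF signal headers: ", path)
  }
  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal sampling rates are not supported: ", path)
  }
  if (anyDuplicated(lab)) stop("duplicate channel labels in ", path)
  spr1 <- spr[1]
  raw <- readBin(con, integer(), n = nrec * ns * spr1, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < nrec * ns * spr1) stop("truncated EDF data in ", path)
  arr <- array(raw, dim = c(spr1, ns, nrec))
  dig <- matrix(aperm(arr, c(1, 3, 2)), nrow = spr1 * nrec, ncol = ns)
  gain <- (pmax - pmin) / (dmax - dmin)
  phys <- sweep(sweep(dig, 2, dmin), 2, gain, `*`)
  phys <- sweep(phys, 2, pmin, `+`)
  unitScale <- ifelse(dimu == "mV", 1e3, ifelse(dimu == "V", 1e6, 1))
  phys <- sweep(phys, 2, unitScale, `*`)

  sid <- if (nzchar(patient)) strsplit(patient, "\\s+")[[1]][1] else
    sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  grp <- "unknown"
  if (!is.null(labels)) {
    man <- if (is.character(labels)) readLabelManifest(labels) else labels
    hit <- match(sid, man$subject_id)
    if (!is.na(hit)) grp <- man$group[hit]
  }
  ref <- sub("^.*ref: ?", "", recinfo)
  if (identical(ref, recinfo)) ref <- "unknown"
  rec <- EEGRecording(t(phys), spr1 / recdur, lab, subjectId = sid,
                      group = grp, reference = ref)
  if (!is.null(registry)) requireElectrodes(rec, registry)
  rec
}

#' Read / write a cohort label manifest
#'
#' Plain-text, tab-separated, two columns: `subject_id` and `group`.
#'
#' @param path manifest file path.
#' @return `readLabelManifest`: data.frame with `subject_id`, `group`.
#' @export
readLabelManifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopIfNot(all(c("subject_id", "group") %in% names(df)),
            "manifest must have subject_id and group columns")
  df
}

#' @rdname readLabelManifest
#' @param manifest data.frame with columns `subject_id`, `group`.
#' @export
writeLabelManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cohort of recordings as EDF files plus a manifest
#'
#' @param recordings list of [EEGRecording-class] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in recordings) {
    writeEDF(rec, file.path(dir, paste0(subjectId(rec), ".edf")))
  }
  man <- data.frame(
    subject_id = vapply(recordings, subjectId, character(1)),
    group = vapply(recordings, groupLabel, character(1)),
    stringsAsFactors = FALSE
  )
  writeLabelManifest(man, file.path(dir, "manifest.tsv"))
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory of EDF files with a `manifest.tsv`.
#' @param registry optional [PairRegistry-class] used to validate montages.
#' @return list of [EEGRecording-class] objects, in manifest order.
#' @export
readCohort <- function(dir, registry = NULL) {
  man <- readLabelManifest(file.path(dir, "manifest.tsv"))
  lapply(man$subject_id, function(sid) {
    readEDF(file.path(dir, paste0(sid, ".edf")), labels = man,
            registry = registry)
  })
}

#' Re-reference a recording to the averaged mastoids
#'
#' Subtracts the mean of the two mastoid channels from every other channel
#' and drops the mastoids from the output.
#'
#' @param rec an [EEGRecording-class].
#' @param mastoids labels of the two mastoid channels; `TP9`/`TP10` are a
#'   common alias on caps without dedicated `M1`/`M2` electrodes.
#' @return a re-referenced [EEGRecording-class] without mastoid channels.
#' @export
rereferenceMastoids <- function(rec, mastoids = c("M1", "M2")) {
  stopIfNot(length(mastoids) == 2L, "exactly two mastoid labels required")
  labs <- channelLabels(rec)
  idx <- match(mastoids, labs)
  if (anyNA(idx)) {
    stop("mastoid channel(s) absent: ",
         paste(mastoids[is.na(idx)], collapse = ", "),
         " (configure an alias such as TP9/TP10)", call. = FALSE)
  }
  dat <- recordingData(rec)
  refSig <- (dat[idx[1], ] + dat[idx[2], ]) / 2
  keep <- setdiff(seq_along(labs), idx)
  out <- sweep(dat[keep, , drop = FALSE], 2, refSig)
  EEGRecording(out, sampleRate(rec), labs[keep], subjectId = subjectId(rec),
               group = groupLabel(rec),
               reference = paste0("avg(", mastoids[1], ",", mastoids[2], ")"))
}
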