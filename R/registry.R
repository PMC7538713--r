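#' @include AllClasses.R
NULL

# The 28 symmetric left/right pairs of a standard 64-channel 10-20 cap,
# listed row-major into the 7x4 grid (row 0 = first four pairs, ...).
# Region tags follow conventional 10-20 prefixes:
#   Fp/AF/F -> frontal, FT/T/TP -> temporal, FC/C -> central,
#   CP/P -> parietal, PO/O -> occipital.
.DEFAULT_PAIRS <- data.frame(
  left = c("Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7", "FC1",
           "FC3", "FC5", "FT7", "FT9", "C1", "C3", "C5", "T7",
           "CP1", "CP3", "CP5", "TP7", "TP9", "P1", "P3", "P5",
           "P7", "PO3", "PO7", "O1"),
  right = c("Fp2", "AF4", "AF8", "F2", "F4", "F6", "F8", "FC2",
            "FC4", "FC6", "FT8", "FT10", "C2", "C4", "C6", "T8",
            "CP2", "CP4", "CP6", "TP8", "TP10", "P2", "P4", "P6",
            "P8", "PO4", "PO8", "O2"),
  region = c("frontal", "frontal", "frontal", "frontal", "frontal",
             "frontal", "frontal", "central", "central", "central",
             "temporal", "temporal", "central", "central", "central",
             "temporal", "parietal", "parietal", "parietal", "temporal",
             "temporal", "parietal", "parietal", "parietal", "parietal",
             "occipital", "occipital", "occipital"),
  stringsAsFactors = FALSE
)
.DEFAULT_PAIRS$row <- rep(0:6, each = 4)
.DEFAULT_PAIRS$col <- rep(0:3, times = 7)

#' Default symmetric electrode pair registry
#'
#' The 28 left/right mirror pairs of a standard 64-channel 10-20 montage,
#' tagged with their scalp region (frontal, temporal, central, parietal,
#' occipital) and assigned row-major to the 7 x 4 feature-tensor grid.
#' Override with [readPairRegistry()] for other montages.
#'
#' @return a [PairRegistry-class] with 28 entries.
#' @examples
#' reg <- defaultPairRegistry()
#' nrow(registryEntries(reg))  # 28
#' @export
defaultPairRegistry <- function() {
  new("PairRegistry", entries = .DEFAULT_PAIRS)
}

#' Construct a pair registry from a data.frame
#'
#' @param entries data.frame with columns `left`, `right`, `region`,
#'   `row` (0-6), `col` (0-3); must contain exactly 28 pairs whose cells
#'   tile the 7 x 4 grid.
#' @return a validated [PairRegistry-class].
#' @export
pairRegistry <- function(entries) {
  entries$row <- as.integer(entries$row)
  entries$col <- as.integer(entries$col)
  new("PairRegistry", entries = as.data.frame(entries))
}

#' Read a pair registry from a config file
#'
#' One pair per line, tab- or comma-separated:
#' `left right region row col`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a validated [PairRegistry-class].
#' @export
readPairRegistry <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  pairRegistry(df[, c("left", "right", "region", "row", "col")])
}

#' Pair labels of a registry
#'
#' @param registry a [PairRegistry-class].
#' @return character vector like `"C5-C6"`, in registry order.
#' @export
pairLabels <- function(registry) {
  e <- registryEntries(registry)
  paste(e$left, e$right, sep = "-")
}

# All electrode labels a registry requires.
registryElectrodes <- function(registry) {
  e <- registryEntries(registry)
  c(rbind(e$left, e$right))
}

#' Check that a recording carries every registry electrode
#'
#' @param rec an [EEGRecording-class].
#' @param registry a [PairRegistry-class].
#' @return invisibly TRUE; errors naming the missing electrodes otherwise.
#' @export
requireElectrodes <- function(rec, registry) {
  missing <- setdiff(registryElectrodes(registry), channelLabels(rec))
  if (length(missing)) {
    stop("recording '", subjectId(rec), "' is missing required electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
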