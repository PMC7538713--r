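#' @include AllClasses.R registry.R spectral.R
NULL

#' Interhemispheric asymmetry of band power
#'
#' `ln(pLeft) - ln(pRight)`: the difference in natural-log band power
#' between a left electrode and its right-hemisphere mirror. Positive
#' values mean more power on the left. Scale-invariant and antisymmetric
#' in its arguments.
#'
#' @param pLeft,pRight positive band powers (vectorized).
#' @return numeric asymmetry value(s).
#' @examples
#' asymmetry(5, 5)            # 0
#' asymmetry(exp(1) * 2, 2)   # 1
#' @export
asymmetry <- function(pLeft, pRight) {
  if (any(pLeft <= 0) || any(pRight <= 0)) {
    stop("band powers must be positive (log undefined otherwise)")
  }
  log(pLeft) - log(pRight)
}

# Full discrete cross-correlation sequence r[tau] = sum_t x[t] y[t + tau],
# tau in -(n-1)..(n-1), via FFT. Returns list(lag, r).
.ccSequence <- function(x, y) {
  n <- length(x)
  nfft <- nextPow2(2L * n - 1L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  Y <- stats::fft(c(y, rep(0, nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  # index m+1 holds sum_t x[t] y[t+m] (mod nfft); negative lags wrap
  list(lag = c(-(n - 1):-1, 0:(n - 1)),
       r = c(cc[(nfft - n + 2L):nfft], cc[1:n]))
}

#' Min-max normalized cross-correlation at lag zero
#'
#' Computes the full discrete cross-correlation sequence of two
#' equal-length signals over all lags (sum form, no mean subtraction),
#' min-max normalizes the sequence to `[0, 1]`, and returns the
#' normalized value at lag 0. The result is 1 exactly when lag 0 attains
#' the sequence maximum and 0 when it attains the minimum. Note the
#' scalar is the *normalized lag-0* value: the normalized maximum is 1 by
#' construction and carries no information.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return a value in `[0, 1]`.
#' @export
crossCorrelation <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 2L, "sequences must have length >= 2")
  s <- .ccSequence(x, y)
  mn <- min(s$r); mx <- max(s$r)
  if (mx - mn <= 100 * .Machine$double.eps * max(abs(mx), abs(mn), 1)) {
    stop("degenerate cross-correlation sequence (max == min); ",
         "min-max normalization undefined")
  }
  (s$r[s$lag == 0L] - mn) / (mx - mn)
}

#' Additive / subtractive feature fusion
#'
#' `MIX1 = k1/(k1+k2) * f1 + k2/(k1+k2) * f2` and
#' `MIX2 = k1/(k1+k2) * f1 - k2/(k1+k2) * f2`, applied element-wise.
#' With `k1 = k2` the pair is an invertible rotation of `(f1, f2)`:
#' `mix1 + mix2 = f1` and `mix1 - mix2 = f2`.
#'
#' @param f1 asymmetry feature value(s) or matrix.
#' @param f2 cross-correlation feature value(s) or matrix.
#' @param k1,k2 ingredient coefficients in `[0, 1]` with `k1 + k2 > 0`
#'   (defaults 0.5 each).
#' @return list with elements `mix1`, `mix2` shaped like the inputs.
#' @export
mixFeatures <- function(f1, f2, k1 = 0.5, k2 = 0.5) {
  stopIfNot(k1 >= 0 && k1 <= 1 && k2 >= 0 && k2 <= 1,
            "k1 and k2 must lie in [0, 1]")
  stopIfNot(k1 + k2 > 0, "k1 + k2 must be positive")
  w1 <- k1 / (k1 + k2)
  w2 <- k2 / (k1 + k2)
  list(mix1 = w1 * f1 + w2 * f2, mix2 = w1 * f1 - w2 * f2)
}

#' Per-epoch pair features: asymmetry and cross-correlation
#'
#' For every epoch, symmetric electrode pair and band: the
#' interhemispheric asymmetry of Welch band powers of the two channels,
#' and the min-max normalized cross-correlation of their FFT band-filtered
#' signals.
#'
#' @param epochs an [EpochSet-class] containing every registry electrode.
#' @param registry a [PairRegistry-class] (default the 28-pair standard
#'   registry).
#' @param bands list of [Band-class] objects (default theta/alpha/beta).
#' @param nfft Welch FFT length (default 1024).
#' @param segmentSamples,overlapFraction Welch segmentation controls.
#' @return data.frame with one row per (epoch, pair, band): columns
#'   `subjectId`, `group`, `epochIndex`, `pair`, `band`, `asymmetry`,
#'   `crosscorr`.
#' @export
epochFeatures <- function(epochs, registry = defaultPairRegistry(),
                          bands = eegBands(), nfft = 1024L,
                          segmentSamples = NULL, overlapFraction = 0.5) {
  stopIfNot(is(epochs, "EpochSet"), "epochs must be an EpochSet")
  labs <- channelLabels(epochs)
  reg <- registryEntries(registry)
  needed <- registryElectrodes(registry)
  missing <- setdiff(needed, labs)
  if (length(missing)) {
    stop("epochs missing required electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chIdx <- match(needed, labs)           # interleaved left/right
  li <- seq(1, length(chIdx), by = 2)    # rows in the reduced matrix
  ri <- li + 1
  rate <- sampleRate(epochs)
  nE <- nEpochs(epochs)
  nP <- nrow(reg)
  nB <- length(bands)
  bandNames <- vapply(bands, function(b) b@name, character(1))
  pairs <- paste(reg$left, reg$right, sep = "-")

  n <- round(epochs@durationS * rate)
  nfft2 <- nextPow2(2L * n - 1L)
  f <- (seq_len(n) - 1) * rate / n
  folded <- pmin(f, rate - f)
  masks <- lapply(bands, function(b) .inBand(folded, b))

  asymOut <- matrix(NA_real_, nE, nP * nB)
  ccOut <- matrix(NA_real_, nE, nP * nB)
  zpad <- matrix(0, nfft2 - n, length(chIdx))
  for (e in seq_len(nE)) {
    dat <- epochs@epochs[[e]][chIdx, , drop = FALSE]
    w <- .welchPsdMatrix(dat, rate, nfft = nfft,
                         segmentSamples = segmentSamples,
                         overlapFraction = overlapFraction)
    bp <- .bandPowerMatrix(w, bands)                 # channel x band
    Fm <- stats::mvfft(t(dat))                       # samples x channels
    for (b in seq_len(nB)) {
      asymOut[e, (b - 1L) * nP + seq_len(nP)] <-
        asymmetry(bp[li, b], bp[ri, b])
      Fb <- Fm
      Fb[!masks[[b]], ] <- 0
      xb <- Re(stats::mvfft(Fb, inverse = TRUE)) / n
      Xp <- stats::mvfft(rbind(xb, zpad))
      Z <- Conj(Xp[, li, drop = FALSE]) * Xp[, ri, drop = FALSE]
      C <- Re(stats::mvfft(Z, inverse = TRUE)) / nfft2
      seqs <- C[c((nfft2 - n + 2L):nfft2, 1:n), , drop = FALSE]
      mn <- apply(seqs, 2, min)
      mx <- apply(seqs, 2, max)
      degen <- mx - mn <= 100 * .Machine$double.eps *
        pmax(abs(mx), abs(mn), 1)
      if (any(degen)) {
        stop("degenerate cross-correlation for pair(s) ",
             paste(pairs[degen], collapse = ", "), " in band ",
             bandNames[b], " (epoch ", e, ")")
      }
      ccOut[e, (b - 1L) * nP + seq_len(nP)] <- (C[1, ] - mn) / (mx - mn)
    }
  }

  meta <- epochMeta(epochs)
  data.frame(
    subjectId = rep(meta$subjectId, each = nP * nB),
    group = rep(meta$group, each = nP * nB),
    epochIndex = rep(meta$epochIndex, each = nP * nB),
    pair = rep(rep(pairs, nB), nE),
    band = rep(rep(bandNames, each = nP), nE),
    asymmetry = as.vector(t(asymOut)),
    crosscorr = as.vector(t(ccOut)),
    stringsAsFactors = FALSE
  )
}

.SINGLE_LAYERS <- c("alpha", "beta", "theta")

.checkComplete <- function(features, pairs) {
  need <- length(pairs) * 3L
  cnt <- table(paste(features$subjectId, features$epochIndex))
  if (any(cnt != need) ||
      !all(features$pair %in% pairs) ||
      !all(features$band %in% c("alpha", "beta", "theta"))) {
    stop("feature map incomplete: every epoch needs all ", length(pairs),
         " pairs x 3 bands", call. = FALSE)
  }
}

#' Assemble spatial feature tensors
#'
#' Rearranges a pair-feature table into one 7 x 4 x L tensor per epoch,
#' placing each pair's value in its registry grid cell. Single-feature
#' tensors (`L = 3`) stack the alpha, beta, theta layers of one feature;
#' mixed tensors (`L = 6`) stack MIX1 and MIX2 of each band in the order
#' alpha-MIX1, alpha-MIX2, beta-MIX1, beta-MIX2, theta-MIX1, theta-MIX2.
#'
#' @param features data.frame from [epochFeatures()] (any number of
#'   epochs; must be complete over 28 pairs x 3 bands for each).
#' @param registry the [PairRegistry-class] defining cell assignments.
#' @param kind `"single_asymmetry"`, `"single_crosscorr"` or `"mixed"`.
#' @param k1,k2 mixing coefficients for `kind = "mixed"`.
#' @return a [FeatureTensorSet-class].
#' @export
buildTensorSet <- function(features, registry = defaultPairRegistry(),
                           kind = c("mixed", "single_asymmetry",
                                    "single_crosscorr"),
                           k1 = 0.5, k2 = 0.5) {
  kind <- match.arg(kind)
  reg <- registryEntries(registry)
  pairs <- paste(reg$left, reg$right, sep = "-")
  .checkComplete(features, pairs)

  key <- paste(features$subjectId, features$epochIndex, sep = "\r")
  ukey <- unique(key)
  eIdx <- match(key, ukey)
  pIdx <- match(features$pair, pairs)
  row <- reg$row[pIdx] + 1L
  col <- reg$col[pIdx] + 1L
  bIdx <- match(features$band, .SINGLE_LAYERS)
  nE <- length(ukey)

  if (kind == "mixed") {
    L <- 6L
    layers <- as.vector(t(outer(.SINGLE_LAYERS, c("MIX1", "MIX2"),
                                paste, sep = "-")))
    arr <- array(NA_real_, c(nE, 7, 4, L))
    m <- mixFeatures(features$asymmetry, features$crosscorr, k1, k2)
    arr[cbind(eIdx, row, col, 2L * bIdx - 1L)] <- m$mix1
    arr[cbind(eIdx, row, col, 2L * bIdx)] <- m$mix2
  } else {
    L <- 3L
    layers <- .SINGLE_LAYERS
    v <- if (kind == "single_asymmetry") features$asymmetry else
      features$crosscorr
    arr <- array(NA_real_, c(nE, 7, 4, L))
    arr[cbind(eIdx, row, col, bIdx)] <- v
  }
  first <- !duplicated(key)
  meta <- data.frame(subjectId = features$subjectId[first],
                     epochIndex = features$epochIndex[first],
                     group = features$group[first],
                     stringsAsFactors = FALSE)
  new("FeatureTensorSet", data = arr, layerNames = layers, meta = meta,
      kind = kind)
}

#' Build the tensor of a single epoch
#'
#' @inheritParams buildTensorSet
#' @return a 7 x 4 x L array with layer dimnames and `subjectId`,
#'   `epochIndex`, `group` attributes.
#' @export
buildTensor <- function(features, registry = defaultPairRegistry(),
                        kind = c("mixed", "single_asymmetry",
                                 "single_crosscorr"),
                        k1 = 0.5, k2 = 0.5) {
  kind <- match.arg(kind)
  ts <- buildTensorSet(features, registry, kind, k1, k2)
  stopIfNot(nEpochs(ts) == 1L,
            "buildTensor expects the features of exactly one epoch")
  arr <- tensorData(ts)[1, , , , drop = TRUE]
  dimnames(arr) <- list(NULL, NULL, layerNames(ts))
  attr(arr, "subjectId") <- ts@meta$subjectId
  attr(arr, "epochIndex") <- ts@meta$epochIndex
  attr(arr, "group") <- ts@meta$group
  arr
}

#' Export a feature table as tab-separated text
#'
#' Long format, one row per (epoch, pair, band, feature kind) with kinds
#' `asymmetry`, `crosscorr`, `mix1`, `mix2`.
#'
#' @param features data.frame from [epochFeatures()].
#' @param path output path.
#' @param k1,k2 mixing coefficients used for the mix rows.
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(features, path, k1 = 0.5, k2 = 0.5) {
  m <- mixFeatures(features$asymmetry, features$crosscorr, k1, k2)
  base <- features[c("subjectId", "epochIndex", "group", "pair", "band")]
  long <- rbind(
    cbind(base, feature_kind = "asymmetry", value = features$asymmetry),
    cbind(base, feature_kind = "crosscorr", value = features$crosscorr),
    cbind(base, feature_kind = "mix1", value = m$mix1),
    cbind(base, feature_kind = "mix2", value = m$mix2)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
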