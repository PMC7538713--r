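#' @include AllClasses.R
NULL

#' Default EEG frequency bands
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-40 Hz. Band intervals are
#' half-open `[low, high)` so the 8 and 13 Hz bins are not counted twice;
#' the beta band closes its 40 Hz edge (there is no band above it).
#'
#' @return named list of [Band-class] objects (theta, alpha, beta).
#' @export
eegBands <- function() {
  list(
    theta = band("theta", 4, 8),
    alpha = band("alpha", 8, 13),
    beta = band("beta", 13, 40, closedUpper = TRUE)
  )
}

# Logical mask over (folded) frequencies for a band, with a small
# tolerance so exact grid hits land on the intended side of each edge.
.inBand <- function(freq, bd) {
  eps <- 1e-9
  freq >= bd@low - eps &
    (freq < bd@high - eps | (bd@closedUpper & freq <= bd@high + eps))
}

#' Band-limit a signal by FFT masking
#'
#' Forward FFT, zero every bin outside the band (DC always removed),
#' inverse FFT. Accepts a vector or a channels x samples matrix and
#' returns the same shape; output is real.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param rate sampling rate, Hz.
#' @param bd a [Band-class]; must lie below the Nyquist frequency.
#' @return band-limited signal, same shape as `x`.
#' @export
bandFilter <- function(x, rate, bd) {
  stopIfNot(bd@high <= rate / 2, "band extends beyond the Nyquist frequency")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else t(x)   # samples x channels
  n <- nrow(m)
  f <- (seq_len(n) - 1) * rate / n
  folded <- pmin(f, rate - f)
  keep <- .inBand(folded, bd)
  Fm <- stats::mvfft(m)
  Fm[!keep, ] <- 0
  out <- Re(stats::mvfft(Fm, inverse = TRUE)) / n
  if (vec) out[, 1] else t(out)
}

#' Welch power spectral density estimate
#'
#' Splits the signal into overlapping Hamming-windowed segments, averages
#' their modified periodograms on an `nfft`-point grid (zero-padded), and
#' returns a one-sided density normalized so that the integral over
#' frequency approximates the mean signal power.
#'
#' @param x numeric sample vector.
#' @param rate sampling rate, Hz.
#' @param nfft FFT length (default 1024; segments are zero-padded to it).
#' @param segmentSamples Welch segment length; default
#'   `min(length(x), 256)`.
#' @param overlapFraction fractional overlap between segments (default
#'   0.5).
#' @param detrend remove each segment's mean before windowing (default
#'   TRUE), so a constant offset contributes nothing to any band.
#' @return list with `freq` (Hz, length `nfft/2 + 1`) and `power`
#'   (density, signal units squared per Hz).
#' @export
welchPsd <- function(x, rate, nfft = 1024L, segmentSamples = NULL,
                     overlapFraction = 0.5, detrend = TRUE) {
  res <- .welchPsdMatrix(matrix(x, nrow = 1), rate, nfft = nfft,
                         segmentSamples = segmentSamples,
                         overlapFraction = overlapFraction,
                         detrend = detrend)
  list(freq = res$freq, power = res$power[1, ])
}

# Vectorized Welch over the rows of a channels x samples matrix.
# Returns list(freq, power = channels x nfreq matrix).
.welchPsdMatrix <- function(mat, rate, nfft = 1024L, segmentSamples = NULL,
                            overlapFraction = 0.5, detrend = TRUE) {
  ns <- ncol(mat)
  nfft <- as.integer(nfft)
  seg <- if (is.null(segmentSamples)) min(ns, 256L) else
    as.integer(segmentSamples)
  seg <- min(seg, nfft)
  stopIfNot(ns >= seg && seg >= 2L, "signal shorter than one Welch segment")
  step <- max(1L, as.integer(floor(seg * (1 - overlapFraction))))
  starts <- seq.int(1L, ns - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg) - 1) / (seg - 1))  # Hamming
  U <- sum(w^2)
  nfreq <- nfft %/% 2L + 1L
  acc <- matrix(0, nrow(mat), nfreq)
  buf <- matrix(0, nfft, nrow(mat))
  for (s in starts) {
    buf[] <- 0
    segd <- t(mat[, s:(s + seg - 1L), drop = FALSE])
    if (detrend) segd <- sweep(segd, 2, colMeans(segd))
    buf[seq_len(seg), ] <- segd * w
    Y <- stats::mvfft(buf)
    acc <- acc + t(abs(Y[seq_len(nfreq), , drop = FALSE])^2)
  }
  scale <- 1 / (rate * U * length(starts))
  psd <- acc * scale
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nfft %% 2L == 0L) dbl[nfreq] <- 1
  psd <- sweep(psd, 2, dbl, `*`)
  list(freq = (seq_len(nfreq) - 1) * rate / nfft, power = psd)
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the (piecewise-linear) density from the band's
#' lower to its upper edge; densities at the exact edges are obtained by
#' linear interpolation, so adjacent bands tile the spectrum without gaps
#' or double counting.
#'
#' @param psd list with `freq` and `power`, as returned by [welchPsd()].
#' @param bd a [Band-class] within the PSD's frequency range.
#' @return non-negative band power (signal units squared).
#' @export
bandPower <- function(psd, bd) {
  m <- .bandPowerMatrix(list(freq = psd$freq,
                             power = matrix(psd$power, nrow = 1)),
                        list(bd))
  unname(m[1, 1])
}

# Band powers for every row of a Welch matrix result: channels x bands.
# Integrates the piecewise-linear PSD over [low, high] exactly, with
# interpolated values at the band edges.
.bandPowerMatrix <- function(welch, bands) {
  f <- welch$freq
  out <- matrix(NA_real_, nrow(welch$power), length(bands))
  colnames(out) <- vapply(bands, function(b) b@name, character(1))
  for (j in seq_along(bands)) {
    bd <- bands[[j]]
    lo <- max(bd@low, f[1])
    hi <- min(bd@high, f[length(f)])
    stopIfNot(lo < hi, "band outside the PSD frequency range")
    sel <- which(f > lo & f < hi)
    if (length(sel) < 1L) stop("band contains no frequency bins")
    interp <- function(x) {
      i <- findInterval(x, f)
      i <- min(max(i, 1L), length(f) - 1L)
      a <- (x - f[i]) / (f[i + 1] - f[i])
      (1 - a) * welch$power[, i] + a * welch$power[, i + 1]
    }
    fA <- c(lo, f[sel], hi)
    pA <- cbind(interp(lo), welch$power[, sel, drop = FALSE], interp(hi))
    n <- length(fA)
    wts <- c(diff(fA)[1] / 2,
             (fA[seq(3, n)] - fA[seq(1, n - 2)]) / 2,
             diff(fA)[n - 1] / 2)
    out[, j] <- as.vector(pA %*% wts)
  }
  out
}
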