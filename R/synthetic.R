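#' @include AllClasses.R registry.R spectral.R
NULL

.BAND_NAMES <- c("theta", "alpha", "beta")

.namedBandVector <- function(x, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- rep(x, 3)
    names(x) <- .BAND_NAMES
  }
  stopIfNot(all(.BAND_NAMES %in% names(x)),
            paste(what, "must be named with theta, alpha, beta"))
  x[.BAND_NAMES]
}

#' Specify a synthetic two-cohort EEG study
#'
#' Defaults describe the study conditions the pipeline is evaluated under:
#' 16 + 16 subjects, 3-minute recordings at 250 Hz, an alpha-band
#' log-power asymmetry of 0.5 in the MDD group (0 in controls), and
#' symmetric-pair coupling of 0.5 (MDD) vs 0.2 (HC) in every band, over a
#' 1 microvolt-RMS 1/f background.
#'
#' @param nMdd,nHc subjects per cohort.
#' @param durationS recording length, seconds.
#' @param sampleRate sampling rate, Hz (> 80 so the beta band is below
#'   Nyquist).
#' @param bandAmp per-band oscillation RMS amplitude, microvolts (named
#'   theta/alpha/beta, or a scalar).
#' @param asymDelta per-band left-right log-power difference injected in
#'   the MDD group.
#' @param asymDeltaHc same, control group (default 0).
#' @param couplingRho,couplingRhoHc per-band fraction of source variance
#'   shared within a symmetric pair, in `[0, 1]`, for the MDD and HC
#'   groups.
#' @param noiseSigma 1/f background RMS, microvolts.
#' @param artifactRate blink-like transients per minute (0 = off).
#' @param seed integer base seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nMdd = 16L, nHc = 16L, durationS = 180,
                       sampleRate = 250,
                       bandAmp = c(theta = 4, alpha = 5, beta = 3),
                       asymDelta = c(theta = 0, alpha = 0.5, beta = 0),
                       asymDeltaHc = c(theta = 0, alpha = 0, beta = 0),
                       couplingRho = c(theta = 0.5, alpha = 0.5, beta = 0.5),
                       couplingRhoHc = c(theta = 0.2, alpha = 0.2,
                                         beta = 0.2),
                       noiseSigma = 1, artifactRate = 0, seed = 1L) {
  new("CohortSpec",
    nMdd = as.integer(nMdd), nHc = as.integer(nHc),
    durationS = durationS, sampleRate = sampleRate,
    bandAmp = .namedBandVector(bandAmp, "bandAmp"),
    asymDeltaMdd = .namedBandVector(asymDelta, "asymDelta"),
    asymDeltaHc = .namedBandVector(asymDeltaHc, "asymDeltaHc"),
    couplingRhoMdd = .namedBandVector(couplingRho, "couplingRho"),
    couplingRhoHc = .namedBandVector(couplingRhoHc, "couplingRhoHc"),
    noiseSigma = noiseSigma, artifactRate = artifactRate,
    seed = as.integer(seed)
  )
}

# Band-limited Gaussian noise with unit *expected* RMS, one column per
# requested source. FFT-masked white noise rather than sinusoids, so
# cross-correlation features are non-degenerate. Scaling is analytic
# (1/sqrt(fraction of bins kept)), not per-realization: normalizing each
# realization to exactly unit RMS would pin every recording's total band
# energy, making epoch powers within a subject negatively correlated and
# group-level tests conservative.
.narrowbandNoise <- function(n, rate, bd, ncols) {
  w <- matrix(stats::rnorm(n * ncols), n, ncols)
  f <- (seq_len(n) - 1) * rate / n
  keep <- .inBand(pmin(f, rate - f), bd)
  Fw <- stats::mvfft(w)
  Fw[!keep, ] <- 0
  x <- Re(stats::mvfft(Fw, inverse = TRUE)) / n
  x / sqrt(mean(keep))
}

# 1/f ("pink") noise columns with unit expected RMS; the spectrum is
# flattened below 1 Hz so the variance stays finite. Analytic scaling for
# the same reason as above.
.pinkNoise <- function(n, rate, ncols) {
  w <- matrix(stats::rnorm(n * ncols), n, ncols)
  f <- (seq_len(n) - 1) * rate / n
  folded <- pmin(f, rate - f)
  shape <- 1 / sqrt(pmax(folded, 1))
  shape[1] <- 0
  Fw <- stats::mvfft(w) * shape
  x <- Re(stats::mvfft(Fw, inverse = TRUE)) / n
  x / sqrt(mean(shape^2))
}

# A single biphasic blink-like transient: one windowed sine cycle.
.blinkWave <- function(rate, freqHz, ampUv) {
  len <- max(4L, round(rate / freqHz))
  tau <- seq_len(len) / len
  ampUv * sin(2 * pi * tau) * (0.5 - 0.5 * cos(2 * pi * tau))
}

#' Generate one synthetic EEG recording
#'
#' For each band and each symmetric electrode pair, the left and right
#' signals are built from a shared narrowband source (weight
#' `sqrt(rho)`) plus a private narrowband source (weight `sqrt(1 - rho)`),
#' scaled by the band amplitude and by `exp(+delta/4)` on the left /
#' `exp(-delta/4)` on the right so the left-right log-power difference is
#' exactly `delta` in expectation. Independent 1/f noise is added to every
#' channel; the mastoid channels `M1`/`M2` carry 1/f noise only. The
#' output is bit-reproducible given `(seed, subjectIdent)`.
#'
#' @param spec a [CohortSpec-class].
#' @param group `"MDD"` or `"HC"`; selects the group's asymmetry and
#'   coupling parameters.
#' @param subjectIdent subject identifier for the recording.
#' @param seed integer seed for this subject.
#' @return an [EEGRecording-class] with all 28 default-registry pairs plus
#'   `M1`/`M2`.
#' @export
generateSubject <- function(spec, group, subjectIdent, seed) {
  validObject(spec)
  stopIfNot(group %in% GROUP_LEVELS,
            paste("unknown group label:", group))
  bands <- eegBands()
  stopIfNot(spec@sampleRate > 2 * bands$beta@high,
            "sample rate below Nyquist for the requested bands")
  delta <- if (group == "MDD") spec@asymDeltaMdd else spec@asymDeltaHc
  rho <- if (group == "MDD") spec@couplingRhoMdd else spec@couplingRhoHc

  reg <- registryEntries(defaultPairRegistry())
  nPairs <- nrow(reg)
  rate <- spec@sampleRate
  n <- round(spec@durationS * rate)
  labs <- c(rbind(reg$left, reg$right), "M1", "M2")
  leftRow <- seq(1, 2 * nPairs, by = 2)
  rightRow <- leftRow + 1

  dat <- withSeed(seed, {
    m <- matrix(0, length(labs), n)
    for (bn in .BAND_NAMES) {
      src <- .narrowbandNoise(n, rate, bands[[bn]], 3L * nPairs)
      shared <- src[, seq_len(nPairs), drop = FALSE]
      privL <- src[, nPairs + seq_len(nPairs), drop = FALSE]
      privR <- src[, 2L * nPairs + seq_len(nPairs), drop = FALSE]
      a <- spec@bandAmp[bn]
      d <- delta[bn]
      r <- rho[bn]
      base <- sqrt(r) * shared
      m[leftRow, ] <- m[leftRow, ] +
        t(a * exp(d / 4) * (base + sqrt(1 - r) * privL))
      m[rightRow, ] <- m[rightRow, ] +
        t(a * exp(-d / 4) * (base + sqrt(1 - r) * privR))
    }
    if (spec@noiseSigma > 0) {
      m <- m + spec@noiseSigma * t(.pinkNoise(n, rate, length(labs)))
    }
    if (spec@artifactRate > 0) {
      nArt <- stats::rpois(1, spec@artifactRate * spec@durationS / 60)
      frontalRows <- which(labs %in%
        c(reg$left[reg$region == "frontal"], reg$right[reg$region == "frontal"]))
      for (k in seq_len(nArt)) {
        wv <- .blinkWave(rate, stats::runif(1, 0.5, 2), 40)
        t0 <- sample.int(n - length(wv), 1)
        span <- t0 + seq_along(wv) - 1L
        m[frontalRows, span] <- m[frontalRows, span] +
          matrix(wv, length(frontalRows), length(wv), byrow = TRUE)
      }
    }
    m
  })

  EEGRecording(dat, rate, labs, subjectId = subjectIdent, group = group,
               reference = "raw")
}

#' Generate a full two-cohort synthetic study
#'
#' MDD subjects first, then controls; subject `i` (1-based, across the
#' whole cohort) uses seed `spec@seed + i`, so any subject can be
#' regenerated in isolation. Consequence: cohorts whose base seeds differ
#' by less than the cohort size share subjects — space seeds by more than
#' `nMdd + nHc` when independent cohorts are needed.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [EEGRecording-class] objects, length `nMdd + nHc`.
#' @examples
#' \donttest{
#' spec <- cohortSpec(nMdd = 2, nHc = 2, durationS = 10)
#' cohort <- generateCohort(spec)
#' table(vapply(cohort, groupLabel, character(1)))
#' }
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  ids <- c(sprintf("MDD%02d", seq_len(spec@nMdd)),
           sprintf("HC%02d", seq_len(spec@nHc)))
  grp <- rep(GROUP_LEVELS[c(2, 1)], c(spec@nMdd, spec@nHc))
  mapply(function(sid, g, i) generateSubject(spec, g, sid, spec@seed + i),
         ids, grp, seq_along(ids), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}
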