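# Shared fixtures, memoised so expensive cohorts are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Independent brute-force oracle for the min-max normalized lag-0
# cross-correlation: explicit loop over every lag.
bruteForceCC <- function(x, y) {
  n <- length(x)
  lags <- -(n - 1):(n - 1)
  r <- vapply(lags, function(tau) {
    t <- seq_len(n)
    tt <- t + tau
    ok <- tt >= 1 & tt <= n
    sum(x[t[ok]] * y[tt[ok]])
  }, numeric(1))
  list(lags = lags, r = r,
       value = (r[lags == 0] - min(r)) / (max(r) - min(r)))
}

# Independent band-power oracle: raw periodogram (|FFT|^2 / (n * rate)),
# summed over the band's bins. No Welch averaging, no windowing.
periodogramBandPower <- function(x, rate, low, high) {
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  p <- Mod(stats::fft(x))^2 / (n * rate)
  sel <- f >= low & f < high
  2 * sum(p[sel]) * rate / n
}

# Plain trapezoidal integral, independent of the package's internals.
trapzOracle <- function(f, p) {
  n <- length(f)
  sum((p[-1] + p[-n]) * diff(f)) / 2
}

# Two-class toy tensor set: class means +/- mu in the first grid cell of
# the first layer (or in every cell with allCells = TRUE), iid Gaussian
# noise elsewhere.
toyTensorSet <- function(nPerClass = 100, mu = 1, sd = 0.1, L = 6L,
                         seed = 1, allCells = FALSE) {
  set.seed(seed)
  n <- 2L * nPerClass
  arr <- array(stats::rnorm(n * 7 * 4 * L, sd = sd), c(n, 7, 4, L))
  if (allCells) {
    arr[seq_len(nPerClass), , , ] <- arr[seq_len(nPerClass), , , ] + mu
    arr[nPerClass + seq_len(nPerClass), , , ] <-
      arr[nPerClass + seq_len(nPerClass), , , ] - mu
  } else {
    arr[seq_len(nPerClass), 1, 1, 1] <-
      arr[seq_len(nPerClass), 1, 1, 1] + mu
    arr[nPerClass + seq_len(nPerClass), 1, 1, 1] <-
      arr[nPerClass + seq_len(nPerClass), 1, 1, 1] - mu
  }
  grp <- rep(c("MDD", "HC"), each = nPerClass)
  meta <- data.frame(subjectId = sprintf("S%03d", seq_len(n)),
                     epochIndex = 0L, group = grp,
                     stringsAsFactors = FALSE)
  new("FeatureTensorSet", data = arr,
      layerNames = as.character(seq_len(L)), meta = meta, kind = "mixed")
}

# Small random recording with the full default montage plus mastoids.
randomRecording <- function(durationS = 5, rate = 100, seed = 1,
                            subjectId = "R1", group = "unknown") {
  set.seed(seed)
  labs <- c(registryElectrodeLabels(), "M1", "M2")
  EEGRecording(matrix(stats::rnorm(length(labs) * durationS * rate),
                      length(labs)),
               rate, labs, subjectId = subjectId, group = group)
}

registryElectrodeLabels <- function() {
  e <- registryEntries(defaultPairRegistry())
  c(rbind(e$left, e$right))
}

# End-to-end features of a generated cohort (re-reference, band-pass,
# 2 s epochs).
cohortFeatures <- function(spec, durationS = 2) {
  cohort <- generateCohort(spec)
  prep <- lapply(cohort, function(r)
    bandpassFilter(rereferenceMastoids(r)))
  epochFeatures(segmentEpochs(prep, durationS))
}

# The study-condition cohort: 16 + 16 subjects, 180 s, alpha asymmetry
# 0.5 vs 0 and coupling 0.5 vs 0.2 (the package defaults).
studyFeatures <- function() {
  fixture("studyFeatures", function() cohortFeatures(cohortSpec(seed = 101)))
}

# A null cohort: both groups drawn from identical settings.
nullSpec <- function(nPer = 8L, durationS = 60, seed = 1) {
  cohortSpec(nMdd = nPer, nHc = nPer, durationS = durationS,
             asymDelta = c(theta = 0, alpha = 0, beta = 0),
             couplingRho = c(theta = 0.2, alpha = 0.2, beta = 0.2),
             seed = seed)
}

nullFeatures <- function() {
  fixture("nullFeatures", function() cohortFeatures(nullSpec(seed = 202)))
}
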