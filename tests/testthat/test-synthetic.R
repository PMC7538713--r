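test_that("cohort spec validates its parameters", {
  expect_error(cohortSpec(nMdd = 0), ">= 1")
  expect_error(cohortSpec(sampleRate = 60), "Nyquist|beta")
  expect_error(cohortSpec(couplingRho = 1.5), "rho")
  expect_error(cohortSpec(bandAmp = -1), "positive")
  expect_s4_class(cohortSpec(), "CohortSpec")
})

test_that("generation is bit-reproducible given (seed, subject)", {
  spec <- cohortSpec(nMdd = 1, nHc = 1, durationS = 4, seed = 9)
  a <- generateSubject(spec, "MDD", "S1", 77)
  b <- generateSubject(spec, "MDD", "S1", 77)
  expect_identical(recordingData(a), recordingData(b))
  c <- generateSubject(spec, "MDD", "S1", 78)
  expect_false(identical(recordingData(a), recordingData(c)))
  expect_error(generateSubject(spec, "CONTROL", "S1", 1), "unknown group")
})

test_that("cohorts have the requested sizes and labels", {
  spec <- cohortSpec(nMdd = 16, nHc = 16, durationS = 2, seed = 3)
  cohort <- generateCohort(spec)
  expect_length(cohort, 32L)
  expect_equal(sum(vapply(cohort, groupLabel, character(1)) == "MDD"), 16L)
  # reproducible pair
  small <- cohortSpec(nMdd = 1, nHc = 1, durationS = 2, seed = 12)
  c1 <- generateCohort(small)
  c2 <- generateCohort(small)
  expect_identical(lapply(c1, recordingData), lapply(c2, recordingData))
})

test_that("injected log-power asymmetry is recovered by a periodogram oracle", {
  # oracle: raw periodogram band power on the generated channels,
  # averaged over 90 two-second epochs and all pairs
  reg <- registryEntries(defaultPairRegistry())
  for (delta in c(0, 0.25, 0.5)) {
    spec <- cohortSpec(nMdd = 1, nHc = 1, durationS = 180,
                       asymDelta = c(theta = 0, alpha = delta, beta = 0),
                       couplingRho = 0, couplingRhoHc = 0,
                       seed = 40 + round(delta * 100))
    rec <- generateSubject(spec, "MDD", "S", spec@seed + 1)
    dat <- recordingData(rec)
    rate <- sampleRate(rec)
    starts <- seq(1, 180 * rate - 2 * rate + 1, by = 2 * rate)
    li <- match(reg$left, channelLabels(rec))
    ri <- match(reg$right, channelLabels(rec))
    vals <- vapply(starts, function(s) {
      idx <- s:(s + 2 * rate - 1)
      mean(vapply(seq_len(nrow(reg)), function(p) {
        pl <- periodogramBandPower(dat[li[p], idx], rate, 8, 13)
        pr <- periodogramBandPower(dat[ri[p], idx], rate, 8, 13)
        log(pl) - log(pr)
      }, numeric(1)))
    }, numeric(1))
    expect_lt(abs(mean(vals) - delta), 0.1)
  }
})

test_that("all bands stay symmetric when no asymmetry is injected", {
  spec <- cohortSpec(nMdd = 1, nHc = 1, durationS = 180,
                     asymDelta = c(theta = 0, alpha = 0, beta = 0),
                     couplingRho = 0, couplingRhoHc = 0, seed = 55)
  rec <- generateSubject(spec, "MDD", "S", 56)
  feats <- epochFeatures(segmentEpochs(bandpassFilter(
    rereferenceMastoids(rec)), 2))
  for (bn in c("theta", "alpha", "beta")) {
    expect_lt(abs(mean(feats$asymmetry[feats$band == bn])), 0.05)
  }
})

test_that("alpha asymmetry leaks only mildly into neighbouring bands", {
  # Welch windowing leaks some of the strong, asymmetric alpha
  # oscillation into the adjacent bands' power estimates; the induced
  # theta/beta bias must stay well below the injected alpha effect
  spec <- cohortSpec(nMdd = 1, nHc = 1, durationS = 180,
                     couplingRho = 0, couplingRhoHc = 0, seed = 55)
  rec <- generateSubject(spec, "MDD", "S", 56)
  feats <- epochFeatures(segmentEpochs(bandpassFilter(
    rereferenceMastoids(rec)), 2))
  expect_lt(abs(mean(feats$asymmetry[feats$band == "alpha"]) - 0.5), 0.1)
  expect_lt(abs(mean(feats$asymmetry[feats$band == "theta"])), 0.1)
  expect_lt(abs(mean(feats$asymmetry[feats$band == "beta"])), 0.1)
})

test_that("downstream cross-correlation increases with coupling rho", {
  means <- vapply(c(0, 0.4, 0.8), function(rho) {
    spec <- cohortSpec(nMdd = 1, nHc = 1, durationS = 60,
                       asymDelta = 0, couplingRho = rho, seed = 60)
    rec <- generateSubject(spec, "MDD", "S", 61)
    feats <- epochFeatures(segmentEpochs(bandpassFilter(
      rereferenceMastoids(rec)), 2))
    mean(feats$crosscorr)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("blink artifacts land on frontal channels only", {
  spec <- cohortSpec(nMdd = 1, nHc = 1, durationS = 10, bandAmp = 0.01,
                     noiseSigma = 0.001, artifactRate = 30, seed = 70)
  rec <- generateSubject(spec, "HC", "S", 71)
  quiet <- generateSubject(
    cohortSpec(nMdd = 1, nHc = 1, durationS = 10, bandAmp = 0.01,
               noiseSigma = 0.001, artifactRate = 0, seed = 70),
    "HC", "S", 71)
  reg <- registryEntries(defaultPairRegistry())
  frontal <- c(reg$left[reg$region == "frontal"],
               reg$right[reg$region == "frontal"])
  labs <- channelLabels(rec)
  pw <- rowMeans(recordingData(rec)^2)
  pwQuiet <- rowMeans(recordingData(quiet)^2)
  boosted <- pw / pwQuiet > 10
  expect_true(all(labs[boosted] %in% frontal))
  expect_gt(sum(boosted), 0)
})
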