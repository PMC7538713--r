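test_that("default pair registry has the documented structure", {
  reg <- defaultPairRegistry()
  e <- registryEntries(reg)
  expect_equal(nrow(e), 28L)
  expect_true(any(e$left == "C5" & e$right == "C6"))
  # cells tile the 7x4 grid exactly once
  expect_setequal(e$row * 4 + e$col, 0:27)
  expect_setequal(unique(e$region),
                  c("frontal", "temporal", "central", "parietal",
                    "occipital"))
  # no electrode appears twice, labels differ within a pair
  expect_equal(anyDuplicated(c(e$left, e$right)), 0L)
  expect_true(all(e$left != e$right))
})

test_that("user registries are validated on construction", {
  e <- registryEntries(defaultPairRegistry())
  bad <- e
  bad$col[2] <- bad$col[1]
  bad$row[2] <- bad$row[1]
  expect_error(pairRegistry(bad), "bijection")
  expect_error(pairRegistry(e[-1, ]), "28")
})

test_that("registry round-trips through its config file format", {
  reg <- defaultPairRegistry()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(registryEntries(reg), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reg2 <- readPairRegistry(path)
  expect_equal(registryEntries(reg2), registryEntries(reg))
})

test_that("EDF write/read round-trips within 16-bit quantization", {
  rec <- randomRecording(durationS = 5, rate = 100, seed = 3,
                         subjectId = "SUBJ1", group = "MDD")
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_identical(channelLabels(back), channelLabels(rec))
  expect_equal(sampleRate(back), 100)
  expect_identical(subjectId(back), "SUBJ1")
  rng <- apply(recordingData(rec), 1, function(x) diff(range(x)))
  tol <- pmax(rng, 1) / 65535
  err <- abs(recordingData(back) - recordingData(rec))
  expect_true(all(err <= 1.01 * tol))
})

test_that("EDF duration metadata matches a 180 s recording", {
  set.seed(4)
  rec <- EEGRecording(matrix(rnorm(2 * 180 * 250), 2), 250,
                      c("C5", "C6"), subjectId = "LONG")
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_equal(ncol(recordingData(back)) / sampleRate(back), 180)
})

test_that("non-finite samples are refused before writing", {
  rec <- randomRecording(durationS = 2, rate = 100)
  rec@data[1, 5] <- NaN
  expect_error(writeEDF(rec, withr::local_tempfile(fileext = ".edf")),
               "non-finite|finite")
})

test_that("a missing registry electrode is reported by name", {
  rec <- randomRecording(durationS = 2, rate = 100)
  keep <- channelLabels(rec) != "C6"
  crippled <- EEGRecording(recordingData(rec)[keep, ], 100,
                           channelLabels(rec)[keep])
  expect_error(requireElectrodes(crippled, defaultPairRegistry()), "C6")
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(crippled, path)
  expect_error(readEDF(path, registry = defaultPairRegistry()), "C6")
})

test_that("cohort write/read preserves counts and group labels", {
  spec <- cohortSpec(nMdd = 2, nHc = 2, durationS = 5, seed = 5)
  cohort <- generateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(cohort, dir)
  back <- readCohort(dir)
  expect_length(back, 4L)
  groups <- vapply(back, groupLabel, character(1))
  expect_equal(sum(groups == "MDD"), 2L)
  expect_identical(channelLabels(back[[1]]), channelLabels(cohort[[1]]))
})

test_that("mastoid re-referencing subtracts the mastoid average", {
  # zero mastoids leave channels unchanged
  d <- rbind(matrix(rnorm(2 * 50), 2), 0, 0)
  rec <- EEGRecording(d, 50, c("C5", "C6", "M1", "M2"))
  out <- rereferenceMastoids(rec)
  expect_equal(recordingData(out), d[1:2, ], ignore_attr = TRUE)
  expect_false(any(c("M1", "M2") %in% channelLabels(out)))

  # common signal on every channel cancels exactly
  s <- sin(seq_len(50))
  recC <- EEGRecording(rbind(s, s, s, s), 50, c("C5", "C6", "M1", "M2"))
  expect_true(all(abs(recordingData(rereferenceMastoids(recC))) < 1e-12))

  # 4-channel toy against direct arithmetic
  set.seed(6)
  d4 <- matrix(rnorm(4 * 30), 4)
  rec4 <- EEGRecording(d4, 30, c("F3", "F4", "M1", "M2"))
  out4 <- rereferenceMastoids(rec4)
  ref <- (d4[3, ] + d4[4, ]) / 2
  expect_equal(recordingData(out4)[1, ], d4[1, ] - ref,
               ignore_attr = TRUE)
  expect_equal(recordingData(out4)[2, ], d4[2, ] - ref,
               ignore_attr = TRUE)

  # absent mastoids with no alias is an error; alias works
  recA <- EEGRecording(d4, 30, c("F3", "F4", "TP9", "TP10"))
  expect_error(rereferenceMastoids(recA), "M1")
  outA <- rereferenceMastoids(recA, mastoids = c("TP9", "TP10"))
  expect_equal(recordingData(outA)[1, ], d4[1, ] - ref,
               ignore_attr = TRUE)
})
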