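test_that("asymmetry identities hold", {
  expect_identical(asymmetry(5, 5), 0)
  expect_equal(asymmetry(exp(1) * 3, 3), 1)
  set.seed(1)
  a <- runif(20, 0.1, 10); b <- runif(20, 0.1, 10); cc <- runif(20, 0.1, 5)
  expect_equal(asymmetry(a, b), -asymmetry(b, a))
  expect_equal(asymmetry(cc * a, cc * b), asymmetry(a, b),
               tolerance = 1e-12)
  expect_error(asymmetry(0, 1), "positive")
  expect_error(asymmetry(1, -2), "positive")
})

test_that("cross-correlation matches the exhaustive-lag oracle", {
  expect_equal(crossCorrelation(c(1, 2, 1), c(0, 1, 0)),
               bruteForceCC(c(1, 2, 1), c(0, 1, 0))$value)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(crossCorrelation(x, y), bruteForceCC(x, y)$value,
                 tolerance = 1e-10)
  }
})

test_that("cross-correlation attains its boundary values where expected", {
  set.seed(3)
  # self-correlation of band-limited noise peaks at lag 0
  x <- bandFilter(rnorm(500), 250, eegBands()$alpha)
  expect_equal(crossCorrelation(x, x), 1)
  # sine vs half-period-shifted sine: lag 0 is the sequence minimum
  t <- seq_len(500) / 250
  s <- sin(2 * pi * 10 * t)
  y <- -s
  o <- bruteForceCC(s, y)
  expect_equal(which.min(o$r), which(o$lags == 0))   # oracle confirms
  expect_equal(crossCorrelation(s, y), 0)
})

test_that("cross-correlation output is always in [0, 1]", {
  set.seed(4)
  for (i in 1:50) {
    x <- rnorm(30); y <- rnorm(30)
    v <- crossCorrelation(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    o <- bruteForceCC(x, y)
    lag0 <- which(o$lags == 0)
    expect_equal(v == 1, which.max(o$r) == lag0)
    expect_equal(v == 0, which.min(o$r) == lag0)
  }
  expect_error(crossCorrelation(1:3, 1:4), "equal length")
  expect_error(crossCorrelation(rep(0, 10), rep(0, 10)), "degenerate")
})

test_that("mixing follows the weighted sum/difference algebra", {
  m <- mixFeatures(2, 4, 0.5, 0.5)
  expect_equal(m$mix1, 3)
  expect_equal(m$mix2, -1)
  set.seed(5)
  f1 <- matrix(rnorm(28), 7, 4); f2 <- matrix(runif(28), 7, 4)
  m <- mixFeatures(f1, f2, 0.3, 0.3)
  expect_equal(m$mix1 + m$mix2, f1, tolerance = 1e-12)
  expect_equal(m$mix1 - m$mix2, f2, tolerance = 1e-12)
  m10 <- mixFeatures(f1, f2, 1, 0)
  expect_equal(m10$mix1, f1)
  expect_equal(m10$mix2, f1)
  expect_error(mixFeatures(1, 1, 0, 0), "positive")
  expect_error(mixFeatures(1, 1, 2, 0.5), "\\[0, 1\\]")
})

mkEpochSet <- function(epochList, labels, rate = 250) {
  n <- length(epochList)
  new("EpochSet", epochs = epochList,
      subjectId = rep("S1", n), group = rep("MDD", n),
      epochIndex = seq_len(n) - 1L,
      durationS = ncol(epochList[[1]]) / rate,
      sampleRate = rate, channelLabels = labels)
}

test_that("epochFeatures yields 84 + 84 values with the right structure", {
  set.seed(6)
  labs <- registryElectrodeLabels()
  ep <- matrix(rnorm(56 * 500), 56)
  suppressWarnings(es <- mkEpochSet(list(ep, ep * 2), labs))
  f <- epochFeatures(es)
  expect_equal(nrow(f), 2 * 84L)
  expect_equal(sum(f$epochIndex == 0), 84L)
  expect_false(any(is.na(f$asymmetry)))
  expect_true(all(f$crosscorr >= 0 & f$crosscorr <= 1))
  # scaling a whole epoch leaves the (scale-invariant) features unchanged
  expect_equal(f$asymmetry[f$epochIndex == 0],
               f$asymmetry[f$epochIndex == 1], tolerance = 1e-9)
})

test_that("identical left/right channels give asymmetry 0 and ccor 1", {
  set.seed(7)
  labs <- registryElectrodeLabels()
  half <- matrix(rnorm(28 * 500), 28)
  ep <- half[rep(seq_len(28), each = 2), ]   # right = copy of left
  suppressWarnings(es <- mkEpochSet(list(ep), labs))
  f <- epochFeatures(es)
  expect_true(all(abs(f$asymmetry) < 1e-9))
  expect_true(all(f$crosscorr == 1))
})

test_that("a missing electrode is reported by name", {
  labs <- setdiff(registryElectrodeLabels(), "C6")
  ep <- matrix(rnorm(55 * 250), 55)
  suppressWarnings(es <- mkEpochSet(list(ep), labs, rate = 250))
  expect_error(epochFeatures(es), "C6")
})

featureFixture <- function() {
  fixture("tinyFeatures", function() {
    set.seed(8)
    labs <- registryElectrodeLabels()
    eps <- lapply(1:2, function(i) matrix(rnorm(56 * 500), 56))
    suppressWarnings(epochFeatures(mkEpochSet(eps, labs)))
  })
}

test_that("tensor shapes and layer orders match the contract", {
  f <- featureFixture()
  singleA <- buildTensorSet(f, kind = "single_asymmetry")
  singleC <- buildTensorSet(f, kind = "single_crosscorr")
  mixed <- buildTensorSet(f, kind = "mixed")
  expect_equal(dim(tensorData(singleA)), c(2, 7, 4, 3))
  expect_equal(dim(tensorData(singleC)), c(2, 7, 4, 3))
  expect_equal(dim(tensorData(mixed)), c(2, 7, 4, 6))
  expect_identical(layerNames(singleA), c("alpha", "beta", "theta"))
  expect_identical(layerNames(mixed),
                   c("alpha-MIX1", "alpha-MIX2", "beta-MIX1", "beta-MIX2",
                     "theta-MIX1", "theta-MIX2"))
  expect_false(any(is.na(tensorData(mixed))))
})

test_that("tensor cells are a lossless rearrangement of the feature map", {
  f <- featureFixture()
  singleA <- buildTensorSet(f, kind = "single_asymmetry")
  arr <- tensorData(singleA)
  for (e in 1:2) {
    for (bn in c("alpha", "beta", "theta")) {
      layer <- arr[e, , , match(bn, layerNames(singleA))]
      want <- f$asymmetry[f$epochIndex == e - 1 & f$band == bn]
      expect_setequal(as.vector(layer), want)
    }
  }
  # the registry cell of C5-C6 holds exactly that pair's value
  reg <- registryEntries(defaultPairRegistry())
  i <- which(reg$left == "C5")
  v <- f$asymmetry[f$epochIndex == 0 & f$band == "alpha" &
                     f$pair == "C5-C6"]
  expect_equal(arr[1, reg$row[i] + 1, reg$col[i] + 1, 1], v)
})

test_that("mixed tensors reconstruct both single features exactly", {
  f <- featureFixture()
  mixed <- tensorData(buildTensorSet(f, kind = "mixed"))
  singleA <- tensorData(buildTensorSet(f, kind = "single_asymmetry"))
  singleC <- tensorData(buildTensorSet(f, kind = "single_crosscorr"))
  # alpha-MIX1 + alpha-MIX2 = alpha asymmetry (k1 = k2)
  expect_equal(mixed[, , , 1] + mixed[, , , 2], singleA[, , , 1],
               tolerance = 1e-12)
  expect_equal(mixed[, , , 1] - mixed[, , , 2], singleC[, , , 1],
               tolerance = 1e-12)
  expect_equal(mixed[, , , 5] + mixed[, , , 6], singleA[, , , 3],
               tolerance = 1e-12)
})

test_that("incomplete feature maps are rejected", {
  f <- featureFixture()
  expect_error(buildTensorSet(f[-1, ]), "incomplete")
  one <- buildTensor(f[f$epochIndex == 0, ], kind = "mixed")
  expect_equal(dim(one), c(7, 4, 6))
  expect_identical(attr(one, "subjectId"), "S1")
  expect_error(buildTensor(f, kind = "mixed"), "exactly one epoch")
})
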