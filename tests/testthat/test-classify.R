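test_that("metrics match hand-computed confusion tables", {
  m <- computeMetrics(tp = 3, tn = 2, fp = 1, fn = 1)
  expect_equal(unname(m), c(5 / 7, 3 / 4, 2 / 3, 6 / 8))
  expect_equal(unname(computeMetrics(5, 7, 0, 0)), rep(1, 4))
  m2 <- computeMetrics(tp = 4, tn = 3, fp = 3, fn = 4)
  expect_equal(unname(m2[1:3]), rep(0.5, 3))
  w <- capture_warnings(m3 <- computeMetrics(0, 5, 0, 0))
  expect_match(w, "sensitivity", all = FALSE)  # f1 is undefined too
  expect_true(is.na(m3[["sensitivity"]]))
  expect_true(is.na(m3[["f1"]]))
  expect_error(computeMetrics(-1, 0, 0, 0), "non-negative")
})

test_that("accuracy decomposes into class-weighted recalls", {
  set.seed(41)
  for (i in 1:10) {
    cf <- as.list(sample(1:30, 4))
    names(cf) <- c("tp", "tn", "fp", "fn")
    m <- do.call(computeMetrics, cf)
    P <- cf$tp + cf$fn; N <- cf$tn + cf$fp
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("KNN recalls training labels and matches a brute-force vote", {
  ts <- toyTensorSet(nPerClass = 10, mu = 1, sd = 0.3, seed = 42)
  y <- factor(epochMeta(ts)$group, levels = c("HC", "MDD"))
  m1 <- fitClassifier(knnConfig(k = 1), ts)
  expect_equal(as.character(predictLabels(m1, ts)), as.character(y))

  # independent oracle: z-score with training stats, sort all Euclidean
  # distances, majority vote of the 7 nearest
  m7 <- fitClassifier(knnConfig(k = 7), ts)
  q <- toyTensorSet(nPerClass = 15, mu = 1, sd = 0.6, seed = 43)
  X <- matrix(tensorData(ts), nrow = 20)
  Q <- matrix(tensorData(q), nrow = 30)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl); Qs <- scale(Q, ctr, scl)
  oracle <- apply(Qs, 1, function(v) {
    d <- sqrt(colSums((t(Xs) - v)^2))
    names(which.max(table(as.character(y)[order(d)[1:7]])))
  })
  expect_equal(as.character(predictLabels(m7, q)), unname(oracle))
})

test_that("predictions are stateless and deterministic", {
  ts <- toyTensorSet(nPerClass = 20, seed = 44)
  q <- toyTensorSet(nPerClass = 10, sd = 0.5, seed = 45)
  for (cfg in list(knnConfig(), svmConfig(), cnnConfig(epochs = 5))) {
    m <- fitClassifier(cfg, ts, seed = 7)
    p <- predictLabels(m, q)
    # permuting the queries permutes the predictions identically
    perm <- sample(nEpochs(q))
    pPerm <- predictLabels(m, eegmdd:::.subsetTensorSet(q, perm))
    expect_identical(as.character(pPerm), as.character(p)[perm])
    expect_identical(predictLabels(m, q), p)
  }
})

test_that("the CNN learns a separable toy problem", {
  ts <- toyTensorSet(nPerClass = 100, mu = 1, sd = 0.1, seed = 46)
  m <- fitClassifier(cnnConfig(), ts, seed = 8)
  expect_equal(m@flattenLength, 56L)
  acc <- mean(as.character(predictLabels(m, ts)) == epochMeta(ts)$group)
  expect_gte(acc, 0.95)
  # retraining with the same seed reproduces the weights
  m2 <- fitClassifier(cnnConfig(), ts, seed = 8)
  expect_identical(m@weights, m2@weights)
})

test_that("single-class training sets are rejected", {
  ts <- toyTensorSet(nPerClass = 5, seed = 47)
  keep <- epochMeta(ts)$group == "MDD"
  one <- eegmdd:::.subsetTensorSet(ts, which(keep))
  for (cfg in list(knnConfig(), svmConfig(), cnnConfig(epochs = 2))) {
    expect_error(fitClassifier(cfg, one), "single class")
  }
})

test_that("fold assignments partition the data evenly", {
  y <- factor(rep(c("MDD", "HC"), each = 53), levels = c("HC", "MDD"))
  meta <- data.frame(subjectId = rep(sprintf("S%d", 1:10),
                                     length.out = 106))
  for (unit in c("epoch", "subject")) {
    fold <- eegmdd:::withSeed(5,
      eegmdd:::.foldAssignment(y, meta, 10L, unit))
    expect_length(fold, 106L)
    expect_setequal(unique(fold), 1:10)
    if (unit == "epoch") {
      expect_lte(diff(range(table(fold))), 1)
    } else {
      # all epochs of a subject share one fold
      expect_true(all(tapply(fold, meta$subjectId,
                             function(f) length(unique(f))) == 1))
    }
  }
})

test_that("cross-validation separates blobs and stays at chance on noise", {
  ts <- toyTensorSet(nPerClass = 100, mu = 3, sd = 0.2, seed = 48,
                     allCells = TRUE)
  cv <- crossValidate(ts, knnConfig(), folds = 10, repeats = 3, seed = 9)
  s <- cvSummary(cv)
  expect_equal(s$mean[s$metric == "accuracy"], 1)
  expect_equal(nrow(cv@table), 30L)

  # uninformative features: labels shuffled relative to the data
  noise <- toyTensorSet(nPerClass = 200, mu = 0, sd = 1, seed = 49)
  set.seed(50)
  yShuf <- factor(sample(epochMeta(noise)$group), levels = c("HC", "MDD"))
  cvN <- crossValidate(noise, knnConfig(), labels = yShuf, folds = 10,
                       repeats = 3, seed = 10)
  accN <- cvSummary(cvN)$mean[1]
  expect_gte(accN, 0.45); expect_lte(accN, 0.55)
})

test_that("cross-validation is deterministic given the seed", {
  ts <- toyTensorSet(nPerClass = 30, mu = 0.5, sd = 0.5, seed = 51)
  a <- crossValidate(ts, knnConfig(), folds = 5, repeats = 2, seed = 11)
  b <- crossValidate(ts, knnConfig(), folds = 5, repeats = 2, seed = 11)
  expect_identical(a@table, b@table)
  c <- crossValidate(ts, knnConfig(), folds = 5, repeats = 2, seed = 12)
  expect_false(identical(a@table, c@table))
  expect_error(crossValidate(eegmdd:::.subsetTensorSet(ts, 1:9),
                             knnConfig(), folds = 10, repeats = 1,
                             seed = 1),
               "fewer samples than folds")
})

test_that("every epoch is tested exactly once per repeat", {
  # reconstruct coverage from confusion counts: per repeat the tested
  # epochs across folds must sum to n
  ts <- toyTensorSet(nPerClass = 26, seed = 52)
  cv <- crossValidate(ts, knnConfig(), folds = 10, repeats = 2, seed = 13)
  t <- cv@table
  perRepeat <- tapply(t$tp + t$tn + t$fp + t$fn, t$repeat., sum)
  expect_true(all(perRepeat == 52))
  foldSizes <- t$tp + t$tn + t$fp + t$fn
  expect_lte(diff(range(foldSizes)), 1)
})
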