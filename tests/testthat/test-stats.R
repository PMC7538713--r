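test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # groups {1,2,3} vs {2,3,4}: SSB = 1.5, SSW = 4, df (1,4) -> F = 1.5
  res <- anovaOneway(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, 1.5)
  expect_equal(res$df, c(1, 4))
  # identical groups: F = 0
  expect_equal(anovaOneway(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    f <- anovaOneway(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p.value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA preconditions are enforced", {
  expect_error(anovaOneway(1, c(1, 2)), "at least 2")
  expect_error(anovaOneway(c(2, 2), c(3, 3)), "degenerate")
  expect_error(anovaOneway(c(1, NA, 2), c(1, 2)), "finite")
})

# A synthetic feature table with a known group shift in the alpha
# asymmetry cells only; iid normal noise everywhere else.
mkFeatureTable <- function(nPerGroup = 40, shift = 1, seed = 31) {
  set.seed(seed)
  pairs <- pairLabels(defaultPairRegistry())
  grid <- expand.grid(pair = pairs, band = c("theta", "alpha", "beta"),
                      stringsAsFactors = FALSE)
  mk <- function(group, subj) {
    do.call(rbind, lapply(seq_len(nPerGroup), function(e) {
      mu <- ifelse(grid$band == "alpha" & group == "MDD", shift, 0)
      data.frame(subjectId = subj, group = group, epochIndex = e - 1L,
                 pair = grid$pair, band = grid$band,
                 asymmetry = rnorm(nrow(grid), mean = mu, sd = 0.5),
                 crosscorr = pmin(pmax(
                   rnorm(nrow(grid), 0.7, 0.05), 0), 1),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(mk("MDD", "M1"), mk("HC", "H1"))
}

test_that("significance map flags the shifted cells and spares the rest", {
  f <- mkFeatureTable()
  map <- significanceMap(f)
  expect_equal(nrow(map), 28 * 3 * 4)
  aAsym <- map[map$band == "alpha" & map$feature == "asymmetry", ]
  expect_gte(mean(aAsym$flag != "ns"), 0.8)
  tAsym <- map[map$band == "theta" & map$feature == "asymmetry", ]
  expect_lte(mean(tAsym$flag != "ns"), 0.2)
  # group means reflect the injected direction
  expect_true(all(aAsym$mean_MDD > aAsym$mean_HC))
  # flags consistent with p-values
  expect_true(all(map$flag[map$p >= 0.05] == "ns"))
  expect_true(all(map$flag[map$p < 0.01] == "**"))
  expect_true(all(map$p >= 0 & map$p <= 1))
})

test_that("alpha = 0 flags nothing and smaller alpha flags a subset", {
  f <- mkFeatureTable()
  map0 <- significanceMap(f, alpha = 0)
  expect_true(all(map0$flag == "ns"))
  map5 <- significanceMap(f, alpha = 0.05)
  map1 <- significanceMap(f, alpha = 0.01)
  sig5 <- paste(map5$pair, map5$band, map5$feature)[map5$flag != "ns"]
  sig1 <- paste(map1$pair, map1$band, map1$feature)[map1$flag != "ns"]
  expect_true(all(sig1 %in% sig5))
})

test_that("BH adjustment and subject-level aggregation reduce findings", {
  f <- mkFeatureTable()
  raw <- significanceMap(f)
  bh <- significanceMap(f, adjust = "BH")
  expect_true(all(bh$p >= raw$p - 1e-12))
  expect_lte(sum(bh$flag != "ns"), sum(raw$flag != "ns"))
  # subject-level mode needs >= 2 subjects per group
  f2 <- f
  f2$subjectId <- paste0(f2$subjectId,
                         ifelse(f2$epochIndex %% 2 == 0, "a", "b"))
  mapS <- significanceMap(f2, unit = "subject")
  expect_equal(nrow(mapS), nrow(raw))
})

test_that("degenerate inputs raise errors", {
  f <- mkFeatureTable(nPerGroup = 1)
  expect_error(significanceMap(f), "fewer than 2")
  fOne <- mkFeatureTable()
  fOne <- fOne[fOne$group == "MDD", ]
  expect_error(significanceMap(fOne), "both")
})
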