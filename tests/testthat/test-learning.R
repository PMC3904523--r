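mkFeatures <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
}

test_that("noise reduction drops constants and duplicates, keeps the rest", {
  x <- mkFeatures(40, 6)
  x[, 3] <- 5                       # constant
  x[, 5] <- x[, 2]                  # exact duplicate
  nr <- noiseReduction(x)
  expect_equal(unname(nr$mask), c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  # independent check: surviving columns have variance and are not
  # near-duplicates
  expect_true(all(apply(nr$x, 2, var) > 0))
  cm <- abs(cor(nr$x)); diag(cm) <- 0
  expect_true(all(cm < 0.999))
  # full-rank random matrix is untouched
  nr2 <- noiseReduction(mkFeatures(50, 8, seed = 2))
  expect_true(all(nr2$mask))
  expect_error(noiseReduction(matrix(1, 5, 2,
                                     dimnames = list(NULL, c("a", "b")))),
               "every feature")
})

test_that("the GP regressor interpolates a noiseless linear target", {
  x <- mkFeatures(60, 4)
  y <- 2 * x[, 1] - 1
  m <- trainRegressor(x, y, modelSpec(noiseVar = 1e-8), seed = 1)
  expect_lt(max(abs(predict(m, x) - y)), 1e-3)
  expect_error(trainRegressor(x, c(y[-1], NA)), "finite")
})

test_that("the exact GP mean agrees with the library GP at a legal noise level", {
  x <- mkFeatures(70, 5, seed = 8)
  y <- x[, 1] - 0.7 * x[, 4] + rnorm(70, 0, 0.2)
  m <- trainRegressor(x, y, modelSpec(sigma = 0.2, noiseVar = 0.01),
                      seed = 1)
  xs <- scale(x[, m@mask, drop = FALSE], center = m@center,
              scale = m@scale)
  ref <- kernlab::gausspr(xs, y - mean(y), type = "regression",
                          kernel = "rbfdot", kpar = list(sigma = 0.2),
                          var = 0.01, scaled = FALSE)
  expect_equal(predict(m, x),
               as.numeric(predict(ref, xs)) + mean(y), tolerance = 1e-6)
})

test_that("training is deterministic and row-order independent", {
  x <- mkFeatures(80, 6, seed = 5)
  y <- x[, 1] - x[, 2] + rnorm(80, 0, 0.3)
  m1 <- trainRegressor(x, y, seed = 9)
  m2 <- trainRegressor(x, y, seed = 9)
  xtest <- mkFeatures(10, 6, seed = 99)
  expect_identical(predict(m1, xtest), predict(m2, xtest))
  perm <- sample(80)
  m3 <- trainRegressor(x[perm, ], y[perm], seed = 9)
  expect_equal(predict(m3, xtest), predict(m1, xtest), tolerance = 1e-6)
})

test_that("prediction aligns features by name and refuses missing ones", {
  x <- mkFeatures(50, 5)
  y <- x[, 2] + rnorm(50, 0, 0.1)
  m <- trainRegressor(x, y, seed = 2)
  shuffled <- x[, c(4, 1, 5, 2, 3)]
  expect_identical(predict(m, shuffled), predict(m, x))
  expect_error(predict(m, x[, 1:3]), "lacks required features")
  expect_error(predict(m, unname(x)), "feature names")
})

test_that("the GP classifier separates separable labels and is seeded", {
  x <- mkFeatures(100, 4, seed = 3)
  x[, 1] <- x[, 1] + sign(x[, 1])  # open a margin along the first axis
  lab <- factor(ifelse(x[, 1] > 0, "stabilizing", "destabilizing"),
                levels = c("destabilizing", "stabilizing"))
  m <- trainClassifier(x, lab, seed = 4)
  expect_equal(mean(predict(m, x) == lab), 1.0)
  sc <- predict(m, x, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
  m2 <- trainClassifier(x, lab, seed = 4)
  expect_identical(predict(m2, x, type = "score"), sc)
})

test_that("label permutation drives cross-validated AUC to chance", {
  x <- mkFeatures(120, 5, seed = 6)
  set.seed(21)
  lab <- factor(sample(c("destabilizing", "stabilizing"), 120,
                       replace = TRUE),
                levels = c("destabilizing", "stabilizing"))
  rep <- crossValidate(x, lab, protocol = CVProtocol(5, seed = 13))
  expect_lt(abs(reportMetrics(rep)$auc - 0.5), 0.15)
})

test_that("metrics have their closed forms and the AUC matches all-pairs", {
  y <- c(1.2, -0.5, 3.1, 0.0, 2.2)
  m <- computeMetrics(y, y)
  expect_equal(m$pearson_rho, 1)
  expect_equal(m$sigma, 0)
  expect_equal(computeMetrics(-y, y)$pearson_rho, -1)
  expect_error(computeMetrics(rep(1, 5), y), "zero variance")

  set.seed(14)
  scores <- rnorm(300)
  scores[sample(300, 40)] <- scores[sample(300, 40)]  # plant ties
  pos <- runif(300) < 0.4
  lab <- factor(ifelse(pos, "stabilizing", "destabilizing"),
                levels = c("destabilizing", "stabilizing"))
  expect_equal(aucRank(scores, lab), bfAUC(scores, pos))
})

test_that("MCC matches its confusion-matrix definition", {
  truth <- c("d", "d", "s", "s", "s", "d")
  pred <- c("d", "s", "s", "s", "d", "d")
  tp <- 2; tn <- 2; fp <- 1; fn <- 1
  expect_equal(mcc(pred, truth),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(mcc(rep("d", 6), truth), 0)  # degenerate marginal
})

test_that("outlier removal picks the largest residuals and reduces sigma", {
  truth <- rnorm(10)
  pred <- truth
  pred[7] <- truth[7] + 50
  out <- outlierRemoval(pred, truth, 0.1)
  expect_equal(out$removed, 7L)
  expect_equal(computeMetrics(pred[out$keep],
                              truth[out$keep])$pearson_rho, 1)
  expect_equal(outlierRemoval(pred, truth, 0)$keep, 1:10)
  expect_error(outlierRemoval(pred, truth, 1), "fraction")
  set.seed(15)
  for (i in 1:100) {
    t <- rnorm(30); p <- t + rnorm(30)
    k <- outlierRemoval(p, t, 0.1)$keep
    expect_lte(sqrt(mean((p[k] - t[k])^2)), sqrt(mean((p - t)^2)))
  }
})

test_that("fold assignment covers records exactly once in every mode", {
  recs <- data.frame(structureId = rep(sprintf("p%02d", 1:12),
                                       times = rpois(12, 6) + 1),
                     chainId = "A", insert = "")
  recs$position <- ave(seq_len(nrow(recs)), recs$structureId,
                       FUN = seq_along)
  for (mode in c("mutation", "protein", "position")) {
    f <- makeFolds(recs, CVProtocol(5, mode, seed = 3))
    expect_length(f, nrow(recs))
    expect_true(all(f %in% 1:5))
    expect_true(all(base::table(factor(f, levels = 1:5)) > 0))
  }
  # grouped mode never splits a protein across folds
  f <- makeFolds(recs, CVProtocol(5, "protein", seed = 8))
  expect_true(all(tapply(f, recs$structureId,
                         function(x) length(unique(x))) == 1))
  expect_error(makeFolds(recs[1:3, ], CVProtocol(5, "protein")),
               "at least k")
})

test_that("leave-one-out yields singleton test folds", {
  recs <- data.frame(structureId = sprintf("p%d", 1:10), chainId = "A",
                     position = 1:10, insert = "")
  f <- makeFolds(recs, CVProtocol(10, "mutation", seed = 1))
  expect_equal(sort(as.vector(base::table(f))), rep(1L, 10))
})

test_that("pooled CV metrics are recomputable from the audit table", {
  x <- mkFeatures(90, 5, seed = 7)
  y <- x[, 1] + 0.5 * x[, 3] + rnorm(90, 0, 0.4)
  rep <- crossValidate(x, y, protocol = CVProtocol(5, seed = 11),
                       outlierFraction = 0.1)
  aud <- heldOutPredictions(rep)
  m <- reportMetrics(rep)
  expect_equal(cor(aud$prediction, aud$truth), m$pearson_rho)
  expect_equal(sqrt(mean((aud$prediction - aud$truth)^2)), m$sigma)
  keep <- outlierRemoval(aud$prediction, aud$truth, 0.1)$keep
  expect_equal(cor(aud$prediction[keep], aud$truth[keep]),
               m$pearson_rho_trimmed)
  expect_lte(m$sigma_trimmed, m$sigma)
  # every record held out exactly once
  expect_equal(sort(aud$id), 1:90)
})
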