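test_that("stratified folds balance sizes and classes deterministically", {
  y10 <- rep(c(0L, 1L), 5)
  f <- makeFolds(y10, cvConfig(5, seed = 1))
  expect_equal(as.integer(sort(table(f))), rep(2L, 5))

  y11 <- c(y10, 1L)
  f11 <- makeFolds(y11, cvConfig(5, seed = 1))
  expect_equal(as.integer(sort(table(f11))), c(2L, 2L, 2L, 2L, 3L))

  expect_identical(makeFolds(y11, cvConfig(5, seed = 7)),
                   makeFolds(y11, cvConfig(5, seed = 7)))
  expect_error(makeFolds(rep(c(0L, 1L), 2), cvConfig(5, seed = 1)),
               "exceed")

  # class ratio per fold within one sample of the global ratio
  set.seed(3)
  y <- sample(rep(c(0L, 1L), c(60, 40)))
  folds <- makeFolds(y, cvConfig(5, seed = 2))
  for (k in 1:5) {
    expect_equal(sum(y[folds == k] == 1L), 8, tolerance = 0)
    expect_equal(sum(y[folds == k] == 0L), 12, tolerance = 0)
  }
})

test_that("grid search is exhaustive, reproducible, and argmax-consistent", {
  set.seed(4)
  n <- 60
  X <- cbind(s = rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.6),
             z = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  one <- modelSpec("xgboost", grid = list(max_depth = 2,
                                          learning_rate = 0.3,
                                          n_estimators = 15))
  res1 <- gridSearchCV(X, y, one, cvConfig(3, seed = 9))
  expect_equal(res1$bestParams$max_depth, 2)
  expect_equal(nrow(res1$results), 1L)

  spec <- modelSpec("xgboost", grid = list(max_depth = c(1, 3),
                                           learning_rate = c(0.1, 0.3),
                                           n_estimators = 15))
  r1 <- gridSearchCV(X, y, spec, cvConfig(3, seed = 9))
  r2 <- gridSearchCV(X, y, spec, cvConfig(3, seed = 9))
  expect_identical(r1$results$auroc, r2$results$auroc)
  expect_equal(r1$bestAUROC, max(r1$results$auroc))
  expect_error(modelSpec("xgboost", grid = list()), "non-empty")
})

test_that("fold fits never touch their validation rows", {
  # rows of the held-out fold carry NaN; each fold's training matrix is
  # clean by construction, so every fit succeeds and still yields
  # predictions for the poisoned rows
  set.seed(6)
  n <- 40
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  folds <- makeFolds(y, cvConfig(4, seed = 5))
  Xp <- X
  Xp[folds == 1L, ] <- NaN
  for (f in 1:4) {
    tr <- folds != f
    expect_false(anyNA(Xp[tr & folds != 1L, ]))
    fit <- m5Cpredict:::.fitOne("xgboost", Xp[tr & folds != 1L, ,
                                              drop = FALSE],
                                y[tr & folds != 1L],
                                list(max_depth = 2, nrounds = 10),
                                seed = 1)
    sc <- m5Cpredict:::.predictOne("xgboost", fit,
                                   X[folds == f, , drop = FALSE])
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("all three algorithms train, score in [0,1], and respect order", {
  set.seed(11)
  n <- 60
  X <- cbind(s = rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.4),
             z = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  for (alg in c("xgboost", "rf", "svm")) {
    params <- switch(alg,
      xgboost = list(max_depth = 2, eta = 0.3, nrounds = 20),
      rf = list(num.trees = 50),
      svm = list(cost = 1))
    m <- trainModel(X, y, algorithm = alg, params = params, seed = 2)
    sc <- predictScores(m, X)
    expect_true(all(sc >= 0 & sc <= 1))
    perm <- sample(n)
    expect_equal(predictScores(m, X[perm, ]), sc[perm],
                 tolerance = 1e-12)
  }
  expect_error(trainModel(X, y, algorithm = "nn"), "unknown")
})

test_that("training is deterministic and the column contract enforced", {
  set.seed(14)
  n <- 50
  X <- cbind(u = rnorm(n), v = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  probe <- cbind(u = rnorm(10), v = rnorm(10))
  m1 <- trainModel(X, y, params = list(max_depth = 2, nrounds = 15),
                   seed = 8)
  m2 <- trainModel(X, y, params = list(max_depth = 2, nrounds = 15),
                   seed = 8)
  expect_identical(predictScores(m1, probe), predictScores(m2, probe))
  expect_error(predictScores(m1, probe[, "u", drop = FALSE]), "missing")
  # separable toy: training positives all score above 0.5
  Xs <- cbind(f = c(rep(0, 20), rep(10, 20)), g = rnorm(40))
  ys <- rep(c(0L, 1L), each = 20)
  ms <- trainModel(Xs, ys, params = list(max_depth = 1, nrounds = 40))
  expect_true(all(predictScores(ms, Xs[ys == 1L, ]) > 0.5))
})

test_that("model artifacts round-trip through a directory", {
  set.seed(15)
  ss <- simulateSegments(20, 20, effect = 0.8, seed = 2)
  emb <- trainEmbedding(ss, dim = 8, epochs = 2, seed = 3)
  fm <- encodeSegments(ss, model = emb, blocks = c("BIN", "W2V"))
  m <- trainModel(fm, params = list(max_depth = 2, nrounds = 20),
                  seed = 4, embedding = emb)
  d <- file.path(tempdir(), "model-artifact")
  saveModel(m, d)
  back <- loadModel(d)
  X <- featureValues(fm)
  expect_equal(predictScores(back, X), predictScores(m, X),
               tolerance = 1e-7)
  expect_identical(modelFeatures(back), modelFeatures(m))
  expect_equal(decisionThreshold(back), 0.5)
  expect_s4_class(back@embedding, "Word2VecModel")
})

test_that("label-permuted models score near chance on held-out data", {
  set.seed(16)
  aucs <- vapply(1:3, function(r) {
    ss <- simulateSegments(120, 120, effect = 0.6, seed = 20 + r)
    fm <- encodeSegments(ss, blocks = "BIN")
    X <- featureValues(fm)
    y <- sample(segmentLabels(fm))          # permuted labels
    tr <- seq_len(160)
    m <- trainModel(X[tr, ], y[tr],
                    params = list(max_depth = 3, nrounds = 40),
                    seed = r)
    rocCurve(y[-tr], predictScores(m, X[-tr, ]))$auc
  }, 0)
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})
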