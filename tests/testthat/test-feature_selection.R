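test_that("F-scores match hand evaluation and a naive oracle", {
  # positives (0,1,2), negatives (2,3,4): numerator 2, denominator 2
  X <- matrix(c(0, 1, 2, 2, 3, 4), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(unname(featureFscores(X, y)), 1.0)

  # identical values in both classes: zero numerator
  Xc <- matrix(rep(3, 6), ncol = 1, dimnames = list(NULL, "c"))
  expect_equal(unname(featureFscores(Xc, y)), 0)

  # affine invariance for a > 0
  expect_equal(featureFscores(X * 2.7 + 5, y), featureFscores(X, y))

  # naive two-pass oracle on a random matrix
  set.seed(31)
  Xr <- matrix(rnorm(200), 20, 10,
               dimnames = list(NULL, paste0("v", 1:10)))
  yr <- rep(c(0, 1), 10)
  oracle <- vapply(seq_len(10), function(j) {
    xp <- Xr[yr == 1, j]; xn <- Xr[yr == 0, j]
    ((mean(xp) - mean(Xr[, j]))^2 + (mean(xn) - mean(Xr[, j]))^2) /
      (var(xp) + var(xn))
  }, 0)
  expect_equal(unname(featureFscores(Xr, yr)), oracle, tolerance = 1e-12)

  # zero within-class variance with separated means: infinite, first
  Xs <- cbind(sep = rep(c(0, 1), each = 10), noise = rnorm(20))
  ys <- rep(c(0, 1), each = 10)
  rk <- rankByFscore(Xs, ys)
  expect_identical(rankedFeatures(rk)[1], "sep")
  expect_identical(unname(rankingScores(rk)[1]), Inf)
})

test_that("SHAP ranking zeroes constant features and is deterministic", {
  set.seed(5)
  n <- 80
  X <- cbind(signal = rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.3),
             const = rep(1, n),
             noise = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  rk <- rankByShap(X, y, params = list(max_depth = 3, eta = 0.3,
                                       nrounds = 30), seed = 4)
  sc <- rankingScores(rk)
  expect_equal(unname(sc[["const"]]), 0)
  expect_identical(rankedFeatures(rk)[1], "signal")
  rk2 <- rankByShap(X, y, params = list(max_depth = 3, eta = 0.3,
                                        nrounds = 30), seed = 4)
  expect_identical(rankingScores(rk), rankingScores(rk2))
  expect_error(rankByShap(X, rep(1L, n)), "class")
})

test_that("tree attributions equal the exponential-sum Shapley definition", {
  # depth-1 trees on 3 features: brute force over all 2^3 subsets
  set.seed(8)
  n <- 60
  X <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.4) > 0)
  bst <- m5Cpredict:::.fitXGB(X, y, list(max_depth = 1, eta = 0.3,
                                         nrounds = 12), seed = 3)
  contrib <- predict(bst, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  for (r in c(1, 17, 42)) {
    phi <- bruteShapley(bst, as.list(X[r, ]), colnames(X))
    expect_equal(unname(contrib[r, colnames(X)]), unname(phi),
                 tolerance = 1e-4)
  }
})

test_that("mutual information behaves as an information measure", {
  set.seed(12)
  x <- sample(1:4, 400, replace = TRUE)
  y <- sample(1:3, 400, replace = TRUE)
  expect_gte(mutualInformation(x, x), mutualInformation(x, y))
  expect_equal(mutualInformation(x, x),
               -sum(prop.table(table(x)) * log(prop.table(table(x)))),
               tolerance = 1e-12)
})

test_that("greedy mRMR is relevance-first and redundancy-averse", {
  set.seed(77)
  n <- 300
  lab <- rep(c(0L, 1L), each = n / 2)
  strong <- lab + rnorm(n, sd = 0.4)
  weak <- lab + rnorm(n, sd = 2)
  X <- cbind(strong = strong, copy = strong, weak = weak,
             noise = rnorm(n))
  rk <- rankByMrmr(X, lab, nSelect = 4)
  ord <- rankedFeatures(rk)
  # first pick maximizes mutual information with the label
  D <- apply(X, 2, m5Cpredict:::.discretize)
  rel <- apply(D, 2, mutualInformation, b = lab)
  expect_identical(ord[1], names(which.max(rel)))
  # the exact copy of the first pick never precedes the weak but
  # non-redundant feature
  expect_lt(match("weak", ord), match("copy", ord))
  # scores record the criterion at selection time; first equals relevance
  expect_equal(unname(rankingScores(rk)[1]), max(rel), tolerance = 1e-12)
  expect_error(rankByMrmr(cbind(a = c(NA, 1, 2, 3)), c(0, 0, 1, 1)),
               "finite")
})

test_that("rankings serialize to TSV and back", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0, 1), 5)
  rk <- rankByFscore(X, y)
  p <- tempfile(fileext = ".tsv")
  writeRanking(rk, p)
  back <- readRanking(p, method = "fscore")
  expect_identical(rankedFeatures(back), rankedFeatures(rk))
  expect_equal(rankingScores(back), rankingScores(rk), tolerance = 1e-12)
})

test_that("incremental selection follows its contract", {
  set.seed(19)
  n <- 60
  X <- cbind(sig = rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.5),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("n", 1:5))))
  colnames(X)[1] <- "sig"
  y <- rep(c(0L, 1L), each = n / 2)
  rk <- rankByFscore(X, y)
  expect_error(incrementalSelection(rk, X, y, nGrid = integer(0)),
               "non-empty")
  # single-point grid selects every feature
  sel <- incrementalSelection(rk, X, y, nGrid = ncol(X),
                              cv = cvConfig(3, seed = 2),
                              params = list(max_depth = 2, eta = 0.3,
                                            nrounds = 20))
  expect_equal(bestN(sel), ncol(X))
  expect_setequal(selectedFeatures(sel), colnames(X))
  curve <- selectionCurve(sel)
  expect_true(all(curve$auroc >= 0 & curve$auroc <= 1))
  # JSON serialization
  p <- tempfile(fileext = ".json")
  writeSelection(sel, p)
  js <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(js$best_n, bestN(sel))
})
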