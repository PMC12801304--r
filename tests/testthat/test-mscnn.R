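test_that("parameter accounting matches the published architecture", {
  human <- mscnnConfig("human")
  blocks <- countParameters(human, byBlock = TRUE)
  expect_equal(unname(blocks["output"]), 1002)
  expect_equal(unname(blocks["dense"]), 2048500)
  expect_equal(unname(blocks["sepconv"]), 5272576)
  expect_equal(unname(blocks["total"]), 7322078)
  expect_equal(countParameters(mscnnConfig("mouse")), 5488094)
})

test_that("closed-form count equals the instantiated parameter count", {
  set.seed(19)
  for (i in 1:8) {
    cfg <- mscnnConfig(windowSizes = sort(sample(2:6, sample(1:3, 1))),
                       filters = sample(2:9, 1),
                       hiddenUnits = sample(3:12, 1),
                       inputLen = sample(8:12, 1),
                       inputDim = sample(3:7, 1), seed = i)
    expect_equal(modelParameterCount(buildMSCNN(cfg)),
                 countParameters(cfg))
  }
  # and for the full-size human architecture
  big <- buildMSCNN(mscnnConfig("human"))
  expect_equal(modelParameterCount(big), 7322078)
})

test_that("branch output lengths follow the valid-convolution geometry", {
  cfg <- mscnnConfig("human", filters = 3L, hiddenUnits = 4L,
                     inputDim = 5L)
  model <- buildMSCNN(cfg)
  X <- array(rnorm(2 * 20 * 5), c(2, 20, 5))
  ns <- asNamespace("EpitopeRAG")
  for (b in seq_along(cfg@windowSizes)) {
    sc <- ns$sepConvForward(X, model@weights$conv[[b]]$K,
                            model@weights$conv[[b]]$Wp,
                            model@weights$conv[[b]]$b)
    expect_equal(dim(sc$Y)[2], 20 - cfg@windowSizes[b] + 1)
  }
  # windows 2,4,6,8 on length 20 give 19,17,15,13 positions
  expect_equal(20 - cfg@windowSizes + 1, c(19L, 17L, 15L, 13L))
})

test_that("the separable-conv forward pass matches the loop oracle", {
  ns <- asNamespace("EpitopeRAG")
  set.seed(20)
  for (i in 1:5) {
    L <- sample(5:8, 1); D <- sample(3:5, 1); w <- sample(2:3, 1)
    F_ <- sample(2:4, 1); n <- sample(1:4, 1)
    X <- array(rnorm(n * L * D), c(n, L, D))
    K <- matrix(rnorm(w * D), w, D)
    Wp <- matrix(rnorm(D * F_), D, F_)
    b <- rnorm(F_)
    fast <- ns$sepConvForward(X, K, Wp, b)$Y
    for (s in 1:n)
      expect_equal(matrix(fast[s, , ], L - w + 1, F_),
                   loopSepConv(matrix(X[s, , ], L, D), K, Wp, b),
                   tolerance = 1e-6)
  }
})

test_that("softmax outputs are proper probabilities", {
  cfg <- mscnnConfig(windowSizes = c(2L, 3L), filters = 4L,
                     hiddenUnits = 5L, inputLen = 6L, inputDim = 3L,
                     seed = 1)
  model <- buildMSCNN(cfg)
  X <- array(rnorm(7 * 6 * 3), c(7, 6, 3))
  fw <- asNamespace("EpitopeRAG")$mscnnForwardPass(model@weights, cfg, X)
  expect_equal(rowSums(fw$probs), rep(1, 7), tolerance = 1e-12)
  expect_true(all(fw$probs >= 0))
})

test_that("max-pooling makes branch outputs translation invariant", {
  cfg <- mscnnConfig(windowSizes = 2L, filters = 3L, hiddenUnits = 4L,
                     inputLen = 10L, inputDim = 4L, seed = 2)
  model <- buildMSCNN(cfg)
  ns <- asNamespace("EpitopeRAG")
  motif <- matrix(rnorm(2 * 4, sd = 5), 2, 4)
  pooledAt <- function(pos) {
    x <- matrix(0, 10, 4)
    x[pos:(pos + 1), ] <- motif
    X <- array(x, c(1, 10, 4))
    sc <- ns$sepConvForward(X, model@weights$conv[[1]]$K,
                            model@weights$conv[[1]]$Wp,
                            model@weights$conv[[1]]$b)
    ns$maxPoolRelu(sc$Y)$M
  }
  # a pattern well inside the valid range pools identically anywhere
  expect_equal(pooledAt(2), pooledAt(7), tolerance = 1e-9)
})

test_that("training learns a separable toy problem to accuracy 1", {
  set.seed(22)
  n <- 100; lab <- rep(0:1, each = 50)
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(24, sd = 0.1), 6, 4)
    if (lab[i] == 1) m[2:3, ] <- m[2:3, ] + 2
    m
  })
  names(mats) <- paste0("s", seq_len(n))
  cfg <- mscnnConfig(windowSizes = 2L, filters = 3L, hiddenUnits = 8L,
                     inputLen = 6L, inputDim = 4L, dropout = 0.2,
                     batchSize = 16L, epochs = 20L, seed = 2)
  model <- trainMSCNN(buildMSCNN(cfg), EmbeddingSet(mats), lab)
  expect_equal(tail(trainingHistory(model)$accuracy, 1), 1.0)
  expect_true(model@trained)
})

test_that("zero epochs leave the model unchanged with empty history", {
  cfg <- mscnnConfig(windowSizes = 2L, filters = 2L, hiddenUnits = 3L,
                     inputLen = 5L, inputDim = 3L, epochs = 0L, seed = 3)
  model <- buildMSCNN(cfg)
  X <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  out <- trainMSCNN(model, X, rep(0:1, 3))
  expect_identical(out@weights, model@weights)
  expect_equal(nrow(trainingHistory(out)), 0)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(23)
  X <- array(rnorm(30 * 5 * 3), c(30, 5, 3))
  lab <- rep(0:1, 15)
  cfg <- mscnnConfig(windowSizes = 2L, filters = 2L, hiddenUnits = 3L,
                     inputLen = 5L, inputDim = 3L, epochs = 2L,
                     batchSize = 8L, seed = 11)
  h1 <- trainingHistory(trainMSCNN(buildMSCNN(cfg), X, lab))
  h2 <- trainingHistory(trainMSCNN(buildMSCNN(cfg), X, lab))
  expect_identical(h1, h2)
})

test_that("training input contracts are enforced", {
  cfg <- mscnnConfig(windowSizes = 2L, filters = 2L, hiddenUnits = 3L,
                     inputLen = 5L, inputDim = 3L, seed = 1)
  model <- buildMSCNN(cfg)
  X <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  expect_error(trainMSCNN(model, X, c(0, 0, 0, 0)), "two classes")
  expect_error(trainMSCNN(model, X, c(0, 1)), "one label per")
  expect_error(mscnnConfig(windowSizes = 20L, inputLen = 20L),
               "window")
})

test_that("predictions threshold scores and ignore batch partitioning", {
  set.seed(24)
  cfg <- mscnnConfig(windowSizes = c(2L, 3L), filters = 3L,
                     hiddenUnits = 4L, inputLen = 6L, inputDim = 3L,
                     batchSize = 4L, epochs = 1L, seed = 5)
  X <- array(rnorm(10 * 6 * 3), c(10, 6, 3))
  model <- trainMSCNN(buildMSCNN(cfg), X, rep(0:1, 5))
  batched <- predictMSCNN(model, X)
  oneByOne <- do.call(rbind, lapply(1:10, function(i)
    predictMSCNN(model, X[i, , , drop = FALSE])))
  expect_equal(batched$score, oneByOne$score, tolerance = 1e-6)
  expect_equal(batched$label_pred, as.integer(batched$score >= 0.5))
  # threshold 1.0 marks nothing positive unless the score is exactly 1
  strict <- predictMSCNN(model, X, threshold = 1.0)
  expect_true(all(strict$label_pred[strict$score < 1] == 0))
})

test_that("stratified folds partition the data evenly by class", {
  set.seed(25)
  lab <- c(rep(1, 23), rep(0, 52))
  fold <- stratifiedFolds(lab, folds = 5, seed = 9)
  sizes <- table(fold)
  expect_equal(sum(sizes), 75)
  expect_lte(diff(range(sizes)), 1)
  perFoldPos <- tapply(lab, fold, sum)
  expect_lte(diff(range(perFoldPos)), 1)
  expect_identical(stratifiedFolds(lab, folds = 5, seed = 9), fold)
  expect_false(identical(stratifiedFolds(lab, folds = 5, seed = 10), fold))
})

test_that("cross-validation reports per-fold metrics with mean and sd", {
  set.seed(26)
  n <- 60; lab <- rep(0:1, each = 30)
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(15, sd = 0.1), 5, 3)
    if (lab[i] == 1) m[2:3, ] <- m[2:3, ] + 3
    m
  })
  names(mats) <- paste0("s", seq_len(n))
  cfg <- mscnnConfig(windowSizes = 2L, filters = 4L, hiddenUnits = 8L,
                     inputLen = 5L, inputDim = 3L, epochs = 30L,
                     batchSize = 10L, dropout = 0.1, seed = 7)
  cv <- suppressWarnings(
    crossValidate(EmbeddingSet(mats), lab, cfg, folds = 3, seed = 1))
  expect_length(cv$perFold, 3)
  expect_setequal(cv$summary$metric,
                  c("sensitivity", "specificity", "accuracy", "mcc",
                    "precision", "f1", "auc"))
  expect_true(all(is.finite(cv$summary$mean)))
  expect_gte(cv$summary$mean[cv$summary$metric == "auc"], 0.9)
})

test_that("model checkpoints round-trip", {
  cfg <- mscnnConfig(windowSizes = 2L, filters = 2L, hiddenUnits = 3L,
                     inputLen = 5L, inputDim = 3L, seed = 1)
  model <- buildMSCNN(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  expect_identical(loadModel(f)@weights, model@weights)
})
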