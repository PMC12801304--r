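#' Create an MSCNN configuration
#'
#' Defaults reproduce the published full-size architecture and training
#' recipe: parallel separable-convolution branches over windows
#' \{2,4,6,8\} (human profile; the mouse profile drops window 8),
#' 1024 filters per branch, global max-pooling, concatenation, dropout
#' 0.7, a 500-unit hidden layer and a 2-class softmax output, trained
#' with Adam at learning rate 1e-3, batch size 256, 20 epochs,
#' categorical cross-entropy and L2 1e-3 on the dense layers.  All
#' sizes are configurable, so the same code runs at desk scale (e.g.
#' dim 32, 64 filters).
#'
#' @param host \code{"human"} (windows 2,4,6,8) or \code{"mouse"}
#'   (windows 2,4,6); ignored when \code{windowSizes} is given.
#' @param windowSizes integer vector of depthwise window widths.
#' @param filters pointwise output channels per branch.
#' @param hiddenUnits hidden dense layer width.
#' @param classes number of output classes.
#' @param dropout dropout rate after concatenation.
#' @param l2Penalty L2 coefficient on dense weights (Keras-style
#'   \code{lambda * sum(w^2)}).
#' @param learningRate,batchSize,epochs Adam training settings.
#' @param inputLen,inputDim expected input shape (rows x columns).
#' @param l2OnConv also penalize convolution weights (default FALSE).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return an [MSCNNConfig-class].
#' @examples
#' cfg <- mscnnConfig("human")
#' countParameters(cfg)  # 7322078
#' @export
mscnnConfig <- function(host = c("human", "mouse"), windowSizes = NULL,
                        filters = 1024L, hiddenUnits = 500L, classes = 2L,
                        dropout = 0.7, l2Penalty = 1e-3,
                        learningRate = 1e-3, batchSize = 256L,
                        epochs = 20L, inputLen = 20L, inputDim = 1280L,
                        l2OnConv = FALSE, seed = 1L) {
  host <- match.arg(host)
  if (is.null(windowSizes))
    windowSizes <- if (host == "mouse") c(2L, 4L, 6L) else c(2L, 4L, 6L, 8L)
  new("MSCNNConfig", windowSizes = as.integer(windowSizes),
      filters = as.integer(filters), hiddenUnits = as.integer(hiddenUnits),
      classes = as.integer(classes), dropout = dropout,
      l2Penalty = l2Penalty, learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      inputLen = as.integer(inputLen), inputDim = as.integer(inputDim),
      l2OnConv = isTRUE(l2OnConv), seed = as.integer(seed))
}

#' Closed-form trainable-parameter count
#'
#' Per window w: depthwise kernel w*D, pointwise kernel D*F plus F
#' biases.  Dense block: F*B*H weights + H biases (B = number of
#' windows); output layer: H*C + C.  Equals the instantiated model's
#' parameter count for every valid configuration.  For the full-size
#' human profile the blocks are 5,272,576 (separable conv), 2,048,500
#' (hidden dense) and 1,002 (output), totalling 7,322,078.
#'
#' @param config an [MSCNNConfig-class].
#' @param byBlock return the per-block breakdown instead of the total.
#' @return integer count (or named vector when \code{byBlock = TRUE}).
#' @export
countParameters <- function(config, byBlock = FALSE) {
  stopifnot(is(config, "MSCNNConfig"))
  D <- as.numeric(config@inputDim)
  F_ <- as.numeric(config@filters)
  H <- as.numeric(config@hiddenUnits)
  C <- as.numeric(config@classes)
  B <- length(config@windowSizes)
  conv <- sum(vapply(config@windowSizes,
                     function(w) w * D + D * F_ + F_, numeric(1)))
  dense <- F_ * B * H + H
  output <- H * C + C
  if (byBlock)
    return(c(sepconv = conv, dense = dense, output = output,
             total = conv + dense + output))
  conv + dense + output
}

#' Parameter count of an instantiated model
#' @param model an [MSCNNModel-class].
#' @return total number of trainable scalars across all weight arrays.
#' @export
modelParameterCount <- function(model) {
  stopifnot(is(model, "MSCNNModel"))
  sum(vapply(flattenWeights(model@weights), length, integer(1)))
}

flattenWeights <- function(w) {
  out <- list()
  for (b in seq_along(w$conv)) {
    out[[paste0("K", b)]] <- w$conv[[b]]$K
    out[[paste0("Wp", b)]] <- w$conv[[b]]$Wp
    out[[paste0("bp", b)]] <- w$conv[[b]]$b
  }
  out$W1 <- w$W1; out$b1 <- w$b1; out$W2 <- w$W2; out$b2 <- w$b2
  out
}

glorot <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained MSCNN
#'
#' Allocates Glorot-uniform kernels (zero biases) for each
#' separable-convolution branch, the hidden dense layer and the softmax
#' output layer, seeded from \code{config@seed}.
#'
#' @param config an [MSCNNConfig-class].
#' @return an untrained [MSCNNModel-class].
#' @export
buildMSCNN <- function(config) {
  stopifnot(is(config, "MSCNNConfig"))
  validObject(config)
  D <- config@inputDim; F_ <- config@filters
  weights <- withLocalSeed(config@seed, {
    conv <- lapply(config@windowSizes, function(w) {
      list(K = glorot(w, D, w, 1),
           Wp = glorot(D, F_, D, F_),
           b = numeric(F_))
    })
    B <- length(config@windowSizes)
    list(conv = conv,
         W1 = glorot(F_ * B, config@hiddenUnits, F_ * B,
                     config@hiddenUnits),
         b1 = numeric(config@hiddenUnits),
         W2 = glorot(config@hiddenUnits, config@classes,
                     config@hiddenUnits, config@classes),
         b2 = numeric(config@classes))
  })
  new("MSCNNModel", config = config, weights = weights, trained = FALSE,
      history = data.frame(epoch = integer(0), loss = numeric(0),
                           accuracy = numeric(0)))
}

setMethod("show", "MSCNNModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "MSCNN %s: windows {%s}, %d filters, %d hidden, input %dx%d\n",
    if (object@trained) "(trained)" else "(untrained)",
    paste(cfg@windowSizes, collapse = ","), cfg@filters,
    cfg@hiddenUnits, cfg@inputLen, cfg@inputDim))
  cat("  trainable parameters:", modelParameterCount(object), "\n")
  if (nrow(object@history))
    cat(sprintf("  final epoch loss %.4f, accuracy %.4f\n",
                utils::tail(object@history$loss, 1),
                utils::tail(object@history$accuracy, 1)))
})

# Linear separable-convolution op: depthwise kernel K (w x D) summed
# over the window per channel, then pointwise mixing Wp (D x F) + bias.
# X: n x L x D array.  Returns Y (n x P x F) and the depthwise output
# Z (n x P x D), P = L - w + 1.
sepConvForward <- function(X, K, Wp, b) {
  n <- dim(X)[1]; L <- dim(X)[2]; D <- dim(X)[3]
  w <- nrow(K); P <- L - w + 1L; F_ <- ncol(Wp)
  Z <- array(0, c(n, P, D))
  for (j in seq_len(w)) {
    Xs <- X[, j:(j + P - 1L), , drop = FALSE]
    Z <- Z + sweep(Xs, 3, K[j, ], "*")
  }
  Ymat <- matrix(Z, n * P, D) %*% Wp
  Ymat <- sweep(Ymat, 2, b, "+")
  list(Y = array(Ymat, c(n, P, F_)), Z = Z)
}

# Max over positions of relu(Y).  Returns pooled n x F matrix and the
# argmax position per (sample, filter).
maxPoolRelu <- function(Y) {
  n <- dim(Y)[1]; P <- dim(Y)[2]; F_ <- dim(Y)[3]
  M <- matrix(pmax(Y[, 1, ], 0), n, F_)
  arg <- matrix(1L, n, F_)
  if (P > 1) for (p in 2:P) {
    Yp <- matrix(pmax(Y[, p, ], 0), n, F_)
    upd <- Yp > M
    M[upd] <- Yp[upd]
    arg[upd] <- p
  }
  list(M = M, arg = arg)
}

softmaxRows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mscnnForwardPass <- function(weights, config, X, training = FALSE) {
  n <- dim(X)[1]
  branches <- lapply(seq_along(config@windowSizes), function(b) {
    sc <- sepConvForward(X, weights$conv[[b]]$K, weights$conv[[b]]$Wp,
                         weights$conv[[b]]$b)
    mp <- maxPoolRelu(sc$Y)
    list(Z = sc$Z, M = mp$M, arg = mp$arg)
  })
  H0 <- do.call(cbind, lapply(branches, `[[`, "M"))
  mask <- NULL
  H0d <- H0
  if (training && config@dropout > 0) {
    keep <- 1 - config@dropout
    mask <- matrix(stats::rbinom(length(H0), 1, keep) / keep,
                   nrow(H0), ncol(H0))
    H0d <- H0 * mask
  }
  A1pre <- sweep(H0d %*% weights$W1, 2, weights$b1, "+")
  A1 <- pmax(A1pre, 0)
  logits <- sweep(A1 %*% weights$W2, 2, weights$b2, "+")
  probs <- softmaxRows(logits)
  list(probs = probs, branches = branches, H0 = H0, H0d = H0d,
       mask = mask, A1pre = A1pre, A1 = A1)
}

mscnnLoss <- function(fw, yIdx, weights, config) {
  n <- length(yIdx)
  p <- pmax(fw$probs[cbind(seq_len(n), yIdx)], 1e-12)
  ce <- -mean(log(p))
  pen <- config@l2Penalty * (sum(weights$W1^2) + sum(weights$W2^2))
  if (config@l2OnConv)
    pen <- pen + config@l2Penalty *
      sum(vapply(weights$conv,
                 function(cv) sum(cv$K^2) + sum(cv$Wp^2), numeric(1)))
  ce + pen
}

mscnnBackward <- function(fw, X, yIdx, weights, config) {
  n <- dim(X)[1]
  C <- config@classes
  onehot <- matrix(0, n, C)
  onehot[cbind(seq_len(n), yIdx)] <- 1
  dlogits <- (fw$probs - onehot) / n
  l2 <- config@l2Penalty
  grads <- list(conv = vector("list", length(weights$conv)))
  grads$W2 <- crossprod(fw$A1, dlogits) + 2 * l2 * weights$W2
  grads$b2 <- colSums(dlogits)
  dA1 <- tcrossprod(dlogits, weights$W2) * (fw$A1pre > 0)
  grads$W1 <- crossprod(fw$H0d, dA1) + 2 * l2 * weights$W1
  grads$b1 <- colSums(dA1)
  dH0 <- tcrossprod(dA1, weights$W1)
  if (!is.null(fw$mask)) dH0 <- dH0 * fw$mask
  F_ <- config@filters
  for (b in seq_along(weights$conv)) {
    br <- fw$branches[[b]]
    w <- nrow(weights$conv[[b]]$K)
    P <- config@inputLen - w + 1L
    dM <- dH0[, ((b - 1) * F_ + 1):(b * F_), drop = FALSE]
    dM <- dM * (br$M > 0)  # relu clipped max passes no gradient
    dY <- array(0, c(n, P, F_))
    idx <- cbind(rep(seq_len(n), times = F_), as.vector(br$arg),
                 rep(seq_len(F_), each = n))
    dY[idx] <- as.vector(dM)
    dYmat <- matrix(dY, n * P, F_)
    Zmat <- matrix(br$Z, n * P, config@inputDim)
    gWp <- crossprod(Zmat, dYmat)
    gb <- colSums(dYmat)
    dZ <- array(tcrossprod(dYmat, weights$conv[[b]]$Wp),
                c(n, P, config@inputDim))
    gK <- matrix(0, w, config@inputDim)
    for (j in seq_len(w)) {
      Xs <- X[, j:(j + P - 1L), , drop = FALSE]
      gK[j, ] <- colSums(matrix(dZ * Xs, n * P, config@inputDim))
    }
    if (config@l2OnConv) {
      gWp <- gWp + 2 * l2 * weights$conv[[b]]$Wp
      gK <- gK + 2 * l2 * weights$conv[[b]]$K
    }
    grads$conv[[b]] <- list(K = gK, Wp = gWp, b = gb)
  }
  grads
}

adamInit <- function(weights) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(weights), v = zero(weights), t = 0L)
}

adamStep <- function(weights, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, g, m, v) {
    if (is.list(w)) {
      if (!is.null(names(w))) g <- g[names(w)]  # align by name, not position
      out <- Map(upd, w, g, m, v)
      return(list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(weights, grads, state$m, state$v)
  list(weights = out$w, state = list(m = out$m, v = out$v, t = t))
}

#' Convert embeddings to a sample x position x dimension array
#'
#' @param x an [EmbeddingSet-class] (or list of equal-shape matrices)
#'   whose matrices all share one shape.
#' @return numeric array n x L x D with sample names on the first
#'   dimension.
#' @export
embeddingsToArray <- function(x) {
  if (is(x, "EmbeddingSet")) x <- x@matrices
  stopifnot(length(x) > 0)
  shape <- dim(x[[1]])
  if (!all(vapply(x, function(m) identical(dim(m), shape), logical(1))))
    stop("all matrices must share one shape (standardize first)",
         call. = FALSE)
  arr <- array(0, c(length(x), shape[1], shape[2]),
               dimnames = list(names(x), NULL, NULL))
  for (i in seq_along(x)) arr[i, , ] <- x[[i]]
  arr
}

checkInputShape <- function(X, config) {
  if (length(dim(X)) != 3 || dim(X)[2] != config@inputLen ||
      dim(X)[3] != config@inputDim)
    stop("input must be n x ", config@inputLen, " x ", config@inputDim,
         " (got ", paste(dim(X), collapse = " x "), ")", call. = FALSE)
}

#' Train an MSCNN by mini-batch Adam
#'
#' Optimizes categorical cross-entropy plus the L2 penalty on the dense
#' weights for \code{config@epochs} epochs at the configured learning
#' rate and batch size, with seeded shuffling and inverted dropout.
#' Reproducible for a fixed seed on one machine.  With
#' \code{epochs = 0} the model is returned unchanged with an empty
#' history.
#'
#' @param model an [MSCNNModel-class] from [buildMSCNN()].
#' @param x training embeddings: an [EmbeddingSet-class], list of
#'   matrices, or an n x L x D array.
#' @param labels numeric 0/1 vector (1 = inducing), one per sample;
#'   both classes must be present.
#' @param epochs optional override of \code{config@epochs}.
#' @return the trained [MSCNNModel-class] with per-epoch history
#'   (mean batch loss, training accuracy).
#' @export
trainMSCNN <- function(model, x, labels, epochs = NULL) {
  stopifnot(is(model, "MSCNNModel"))
  config <- model@config
  X <- if (is.array(x) && length(dim(x)) == 3) x else embeddingsToArray(x)
  checkInputShape(X, config)
  n <- dim(X)[1]
  if (length(labels) != n)
    stop("need exactly one label per embedding", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% 0:(config@classes - 1)))
    stop("labels must be integers in 0..", config@classes - 1,
         call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("training requires at least two classes", call. = FALSE)
  nEpochs <- if (is.null(epochs)) config@epochs else as.integer(epochs)
  if (nEpochs == 0) return(model)
  yIdx <- as.integer(labels) + 1L
  weights <- model@weights
  state <- adamInit(weights)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  withLocalSeed(deriveSeed(config@seed, "train"), {
    for (epoch in seq_len(nEpochs)) {
      ord <- sample.int(n)
      losses <- c(); correct <- 0L
      for (start in seq(1, n, by = config@batchSize)) {
        bi <- ord[start:min(start + config@batchSize - 1L, n)]
        Xb <- X[bi, , , drop = FALSE]
        fw <- mscnnForwardPass(weights, config, Xb, training = TRUE)
        loss <- mscnnLoss(fw, yIdx[bi], weights, config)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        losses <- c(losses, loss)
        correct <- correct +
          sum(max.col(fw$probs, ties.method = "first") == yIdx[bi])
        grads <- mscnnBackward(fw, Xb, yIdx[bi], weights, config)
        step <- adamStep(weights, grads, state, config@learningRate)
        weights <- step$weights
        state <- step$state
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                     accuracy = correct / n))
    }
  })
  new("MSCNNModel", config = config, weights = weights, trained = TRUE,
      history = hist)
}

#' Predict class scores with a trained MSCNN
#'
#' Runs the deterministic forward pass (no dropout) in batches and
#' thresholds the inducing-class softmax probability.
#'
#' @param model a trained [MSCNNModel-class].
#' @param x embeddings as in [trainMSCNN()].
#' @param threshold decision threshold on the inducing-class
#'   probability (default 0.5).
#' @return data.frame with \code{epitope_id}, \code{score} (probability
#'   of class 1) and \code{label_pred} (1 exactly when
#'   \code{score >= threshold}).
#' @export
predictMSCNN <- function(model, x, threshold = 0.5) {
  stopifnot(is(model, "MSCNNModel"))
  config <- model@config
  X <- if (is.array(x) && length(dim(x)) == 3) x else embeddingsToArray(x)
  checkInputShape(X, config)
  n <- dim(X)[1]
  ids <- dimnames(X)[[1]]
  if (is.null(ids)) ids <- as.character(seq_len(n))
  scores <- numeric(n)
  for (start in seq(1, n, by = config@batchSize)) {
    bi <- start:min(start + config@batchSize - 1L, n)
    fw <- mscnnForwardPass(model@weights, config,
                           X[bi, , , drop = FALSE], training = FALSE)
    scores[bi] <- fw$probs[, 2]
  }
  data.frame(epitope_id = ids, score = scores,
             label_pred = as.integer(scores >= threshold),
             stringsAsFactors = FALSE)
}

#' Training history of a model
#' @param model an [MSCNNModel-class].
#' @return data.frame of per-epoch loss and accuracy.
#' @export
trainingHistory <- function(model) {
  stopifnot(is(model, "MSCNNModel"))
  model@history
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the configuration, weights and
#' training history (R-native serialization).
#'
#' @param model an [MSCNNModel-class].
#' @param path checkpoint path.
#' @return \code{saveModel} returns \code{path} invisibly;
#'   \code{loadModel} returns the [MSCNNModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "MSCNNModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "MSCNNModel"))
  model
}

#' Stratified k-fold assignment
#'
#' Samples are shuffled within class (seeded) and folds assigned
#' cyclically across the class-ordered sequence, so fold sizes differ
#' by at most one and per-class proportions per fold are within one
#' sample of the global proportions.
#'
#' @param labels class labels.
#' @param folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer fold id per sample.
#' @export
stratifiedFolds <- function(labels, folds = 5L, seed = 1L) {
  folds <- assertCount(folds, "folds", min = 2L)
  n <- length(labels)
  if (n < folds) stop("need at least as many samples as folds",
                      call. = FALSE)
  withLocalSeed(deriveSeed(seed, "folds"), {
    ord <- unlist(lapply(split(seq_len(n), labels), sample),
                  use.names = FALSE)
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(folds), n)
    fold
  })
}

#' Cross-validate the classifier on (optionally enriched) embeddings
#'
#' Stratified k-fold cross-validation: each fold's model is trained on
#' the remaining folds and evaluated on the held-out fold.  When a
#' reference \code{database} (+ \code{kg}, \code{relMap}) is supplied,
#' all queries are first enriched with [enrichDataset()]; retrieval
#' self-exclusion by id guarantees no query ever retrieves itself from
#' the database.
#'
#' @param queries an [EmbeddingSet-class] of standardized query
#'   embeddings.
#' @param labels 0/1 labels, one per query.
#' @param config an [MSCNNConfig-class].
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param database,kg,relMap optional fusion inputs (see
#'   [enrichDataset()]); omit for a query-only model.
#' @param k,queryFraction fusion settings.
#' @return list with \code{perFold} (list of metric vectors),
#'   \code{summary} (data.frame of per-metric mean and sd) and
#'   \code{folds} (the assignment).
#' @export
crossValidate <- function(queries, labels, config, folds = 5L, seed = 1L,
                          database = NULL, kg = NULL, relMap = NULL,
                          k = 5L, queryFraction = 0.9) {
  stopifnot(is(queries, "EmbeddingSet"))
  fused <- if (is.null(database)) queries else
    enrichDataset(queries, database, kg, relMap, k = k,
                  queryFraction = queryFraction)
  X <- embeddingsToArray(fused)
  fold <- stratifiedFolds(labels, folds, seed)
  perFold <- lapply(seq_len(folds), function(f) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(labels[te])) < 2 ||
        length(unique(labels[tr])) < 2)
      stop("fold ", f, " contains a single class; use fewer folds or ",
           "more data", call. = FALSE)
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, paste0("fold", f))
    model <- trainMSCNN(buildMSCNN(cfg), X[tr, , , drop = FALSE],
                        labels[tr])
    preds <- predictMSCNN(model, X[te, , , drop = FALSE])
    cm <- confusionCounts(labels[te], preds$label_pred)
    computeMetrics(cm, scores = preds$score, labelsTrue = labels[te])
  })
  mat <- do.call(rbind, perFold)
  list(perFold = perFold,
       summary = data.frame(metric = colnames(mat),
                            mean = colMeans(mat),
                            sd = apply(mat, 2, stats::sd),
                            row.names = NULL),
       folds = fold)
}
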