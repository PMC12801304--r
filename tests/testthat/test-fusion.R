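test_that("l2Distance matches the flattened brute-force definition", {
  expect_equal(l2Distance(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(l2Distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  set.seed(8)
  q <- matrix(rnorm(20 * 40), 20, 40)
  e <- matrix(rnorm(20 * 40), 20, 40)
  brute <- 0
  for (i in 1:20) for (j in 1:40) brute <- brute + (q[i, j] - e[i, j])^2
  expect_equal(l2Distance(q, e), sqrt(brute), tolerance = 1e-9)
  expect_error(l2Distance(q, matrix(0, 2, 2)), "shape")
})

test_that("top-k retrieval matches exhaustive argsort ranking with ties", {
  db <- randomEmbeddingSet(10, L = 4, D = 3, seed = 2)
  q <- matrix(0, 4, 3)
  res <- retrieveTopK(q, db, k = 5)
  brute <- sort(vapply(embeddingList(db), l2Distance, numeric(1), q = q))
  expect_equal(res$distances, unname(brute[1:5]))
  expect_equal(res$neighbour_ids, names(brute)[1:5])
  expect_false(is.unsorted(res$distances))
  # an exact duplicate (different id) comes first at distance 0
  dup <- EmbeddingSet(c(embeddingList(db), list(copy = db[["e3"]])))
  res2 <- retrieveTopK(db[["e3"]], dup, k = 3, queryId = "e3")
  expect_equal(res2$neighbour_ids[1], "copy")
  expect_equal(res2$distances[1], 0)
  # exact ties break by ascending database index
  tied <- EmbeddingSet(list(a = matrix(1, 2, 2), b = matrix(1, 2, 2),
                            c = matrix(9, 2, 2)))
  expect_equal(retrieveTopK(matrix(0, 2, 2), tied, k = 2)$neighbour_ids,
               c("a", "b"))
})

test_that("self-exclusion removes the query id before ranking", {
  db <- randomEmbeddingSet(6, L = 3, D = 3, seed = 9)
  res <- retrieveTopK(db[["e1"]], db, k = 5, queryId = "e1")
  expect_false("e1" %in% res$neighbour_ids)
  expect_error(retrieveTopK(db[["e1"]], db, k = 6, queryId = "e1"),
               "self-exclusion")
})

test_that("the worked weighting example reproduces hand arithmetic", {
  kg <- workedExampleKG()
  cw <- contextWeights(paste0("e", 1:5), kg, relationshipMap("human"))
  # e1/e2 share host (+1.0) and molecule (+0.5): scores 2.5 each
  expect_equal(cw$scores, c(2.5, 2.5, 1, 1, 1))
  expect_equal(cw$weights, c(0.3125, 0.3125, 0.125, 0.125, 0.125))
  expect_equal(sum(cw$weights), 1, tolerance = 1e-9)
})

test_that("property-less neighbourhoods get exactly uniform weights", {
  kg <- buildKG(PeptideSet(paste0("x", 1:5),
                           rep("ACDEFGHK", 5)))  # no metadata at all
  cw <- contextWeights(paste0("x", 1:5), kg, relationshipMap("human"))
  expect_identical(cw$weights, rep(0.2, 5))
  # ids entirely absent from the graph behave the same
  cw2 <- contextWeights(paste0("y", 1:5), kg, relationshipMap("human"))
  expect_identical(cw2$weights, rep(0.2, 5))
  expect_error(contextWeights("x1", kg, relationshipMap("human")),
               "at least two")
})

test_that("weights are symmetric, normalized and permutation-equivariant", {
  kg <- buildKG(randomPeptides(40, seed = 13))
  relMap <- relationshipMap("human")
  ids <- epitopeIds(kg)
  for (s in 1:20) {
    set.seed(s)
    pick <- sample(ids, 5)
    cw <- contextWeights(pick, kg, relMap)
    expect_equal(sum(cw$weights), 1, tolerance = 1e-9)
    expect_true(all(cw$weights >= 0))
    perm <- sample(5)
    cwP <- contextWeights(pick[perm], kg, relMap)
    expect_equal(cwP$weights, cw$weights[perm], tolerance = 1e-12)
  }
})

test_that("adding a shared category never decreases the pair's weights", {
  base <- PeptideSet(paste0("e", 1:5), rep("ACDEFGHK", 5),
                     host = c("human", "human", "h3", "h4", "h5"))
  more <- base
  df <- peptideRecords(base)
  df$source_molecule <- c("gag", "gag", NA, NA, NA)
  more <- PeptideSet(df$epitope_id, df$sequence, host = df$host,
                     source_molecule = df$source_molecule)
  relMap <- relationshipMap("human")
  w0 <- contextWeights(paste0("e", 1:5), buildKG(base), relMap)$weights
  w1 <- contextWeights(paste0("e", 1:5), buildKG(more), relMap)$weights
  expect_true(all(w1[1:2] >= w0[1:2]))
  expect_true(all(w1[3:5] <= w0[3:5]))
})

test_that("zero increments reproduce the uniform weighting exactly", {
  kg <- buildKG(randomPeptides(20, seed = 17))
  zero <- relationshipMap(c(host = 0, source_molecule = 0,
                            source_organism = 0, molecule_parent = 0))
  ids <- epitopeIds(kg)[1:5]
  expect_identical(contextWeights(ids, kg, zero)$weights, rep(0.2, 5))
  expect_error(relationshipMap(c(host = -1)), ">= 0")
})

test_that("labels never influence weighting unless explicitly opted in", {
  ps <- PeptideSet(paste0("e", 1:5), rep("ACDEFGHK", 5),
                   label = c(1, 1, 0, 0, 0))
  kg <- buildKG(ps)
  relMap <- relationshipMap("human")
  off <- contextWeights(paste0("e", 1:5), kg, relMap)
  expect_identical(off$weights, rep(0.2, 5))
  on <- contextWeights(paste0("e", 1:5), kg, relMap, useLabel = TRUE)
  expect_gt(on$weights[3], on$weights[1])  # larger shared-label block
})

test_that("weighted average and fusion follow the closed forms", {
  m <- matrix(rnorm(12), 3, 4)
  expect_equal(weightedAverage(list(m, m, m), c(0.2, 0.3, 0.5)), m)
  expect_equal(weightedAverage(list(matrix(2, 1, 1), matrix(4, 1, 1)),
                               c(0.5, 0.5)), matrix(3, 1, 1))
  # loop oracle on 5 seeded matrices
  set.seed(21)
  mats <- replicate(5, matrix(rnorm(20), 4, 5), simplify = FALSE)
  w <- runif(5); w <- w / sum(w)
  brute <- matrix(0, 4, 5)
  for (i in 1:5) for (r in 1:4) for (c in 1:5)
    brute[r, c] <- brute[r, c] + w[i] * mats[[i]][r, c]
  expect_equal(weightedAverage(mats, w), brute, tolerance = 1e-9)
  # fusion arithmetic and degenerate cases
  expect_equal(fuseEmbedding(matrix(10, 1, 1), matrix(0, 1, 1), 0.9),
               matrix(9, 1, 1))
  q <- matrix(rnorm(6), 2, 3); ctx <- matrix(rnorm(6), 2, 3)
  expect_equal(fuseEmbedding(q, ctx, 1), q)
  expect_equal(fuseEmbedding(q, q, 0.3), q)
  a <- 2.5
  expect_equal(fuseEmbedding(a * q, a * ctx, 0.9),
               a * fuseEmbedding(q, ctx, 0.9))
  expect_error(fuseEmbedding(q, ctx, 1.2), "queryFraction")
})

test_that("enrichDataset composes the four component operations", {
  db <- randomEmbeddingSet(8, L = 4, D = 6, seed = 30, prefix = "d")
  kg <- buildKG(randomPeptides(8, seed = 30, prefix = "d"))
  relMap <- relationshipMap("human")
  queries <- randomEmbeddingSet(20, L = 4, D = 6, seed = 31, prefix = "q")
  fused <- enrichDataset(queries, db, kg, relMap, k = 5)
  expect_equal(epitopeIds(fused), epitopeIds(queries))
  for (id in epitopeIds(queries)) {
    q <- queries[[id]]
    top <- retrieveTopK(q, db, k = 5, queryId = id)
    cw <- contextWeights(top$neighbour_ids, kg, relMap)
    manual <- fuseEmbedding(
      q, weightedAverage(embeddingList(db)[top$index], cw$weights), 0.9)
    expect_equal(fused[[id]], manual, tolerance = 1e-12)
  }
  # property-less database: fused = 0.9 q + 0.1 mean of the 5 nearest
  bare <- buildKG(randomPeptides(8, seed = 32, prefix = "d",
                                 withMeta = FALSE))
  f1 <- enrichDataset(queries[1], db, bare, relMap, k = 5)
  top <- retrieveTopK(queries[[1]], db, k = 5, queryId = epitopeIds(queries)[1])
  meanCtx <- Reduce(`+`, embeddingList(db)[top$index]) / 5
  expect_equal(f1[[1]], 0.9 * queries[[1]] + 0.1 * meanCtx,
               tolerance = 1e-12)
  # empty query list
  expect_length(enrichDataset(EmbeddingSet(), db, kg, relMap), 0)
})

test_that("retrieval audit rows are consistent with enrichment", {
  db <- randomEmbeddingSet(6, L = 3, D = 4, seed = 40, prefix = "d")
  kg <- buildKG(randomPeptides(6, seed = 40, prefix = "d"))
  queries <- randomEmbeddingSet(3, L = 3, D = 4, seed = 41, prefix = "q")
  audit <- retrievalAudit(queries, db, kg, relationshipMap("mouse"), k = 4)
  expect_equal(nrow(audit), 12)
  expect_equal(unique(audit$rank), 1:4)
  byQuery <- split(audit$weight, audit$query_id)
  for (w in byQuery) expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("built-in relationship maps carry the tuned profile values", {
  h <- relationshipIncrements(relationshipMap("human"))
  m <- relationshipIncrements(relationshipMap("mouse"))
  expect_equal(h[["host"]], 1.0)
  expect_equal(h[["source_molecule"]], 0.5)
  expect_equal(h[["source_organism"]], 0.6)
  expect_equal(h[["molecule_parent"]], 0.4)
  expect_equal(m[["source_molecule"]], 0.6)
  expect_equal(m[["source_organism"]], 0.5)
})
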