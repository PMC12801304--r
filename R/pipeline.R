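#' Run the full classification pipeline on simulated or supplied data
#'
#' Chains the stages simulate -> embed -> build-kg -> fuse -> train ->
#' predict -> evaluate and writes every artifact (peptide tables,
#' embedding containers, KG triples, fused embeddings, model
#' checkpoint, predictions, metrics report and a replayable manifest)
#' under \code{outDir}.  With the same config and seed the metrics
#' report reproduces to floating-point tolerance.
#'
#' The \code{host} profile selects both the classifier window set
#' (human \{2,4,6,8\}, mouse \{2,4,6\}) and the relationship map.
#'
#' @param outDir output directory (created if missing).
#' @param host \code{"human"} or \code{"mouse"} profile.
#' @param seed master seed for every stage.
#' @param nTrain,nTest,nDb simulated set sizes (balanced train/test;
#'   the database uses the curated-set class ratio).
#' @param embeddingDim embedding dimension.
#' @param motifStrength,kgInformativeness,noiseScale generator signal
#'   settings (see [simulateEpitopes()]).
#' @param k,queryFraction fusion settings (defaults 5 and 0.9).
#' @param config optional [MSCNNConfig-class]; default is a desk-scale
#'   configuration (64 filters, 64 hidden units, 30 epochs, batch 64; dropout, L2 and learning rate keep their full-size values)
#'   with the host profile's windows.
#' @param queryOnly skip fusion and classify raw query embeddings
#'   (baseline for measuring the contribution of the KG context).
#' @param verbose log stage progress.
#' @return list with \code{metrics}, \code{predictions}, \code{model},
#'   \code{manifest} (also written as JSON under \code{outDir}).
#' @export
runPipeline <- function(outDir, host = c("human", "mouse"), seed = 1L,
                        nTrain = 200L, nTest = 80L, nDb = 100L,
                        embeddingDim = 32L, motifStrength = 0.9,
                        kgInformativeness = 0.8, noiseScale = 0.5,
                        k = 5L, queryFraction = 0.9, config = NULL,
                        queryOnly = FALSE, verbose = TRUE) {
  host <- match.arg(host)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", ..., "]")
  if (is.null(config))
    config <- mscnnConfig(host, filters = 64L, hiddenUnits = 64L,
                          epochs = 30L, batchSize = 64L,
                          inputDim = as.integer(embeddingDim),
                          seed = deriveSeed(seed, "model"))
  say("simulate: train n=", nTrain, ", test n=", nTest, ", db n=", nDb)
  embSeed <- deriveSeed(seed, "embedder")  # one embedding space for all sets
  half <- function(n) c(ceiling(n / 2), floor(n / 2))
  tr <- simulateEpitopes(half(nTrain)[1], half(nTrain)[2],
                         embeddingDim = embeddingDim,
                         motifStrength = motifStrength,
                         kgInformativeness = kgInformativeness,
                         noiseScale = noiseScale,
                         seed = deriveSeed(seed, "trainset"),
                         embedderSeed = embSeed, idPrefix = "tr")
  te <- simulateEpitopes(half(nTest)[1], half(nTest)[2],
                         embeddingDim = embeddingDim,
                         motifStrength = motifStrength,
                         kgInformativeness = kgInformativeness,
                         noiseScale = noiseScale,
                         seed = deriveSeed(seed, "testset"),
                         embedderSeed = embSeed, idPrefix = "te")
  db <- simulateKnowledgeDB(nDb, queryIds = c(epitopeIds(tr$peptides),
                                              epitopeIds(te$peptides)),
                            embeddingDim = embeddingDim,
                            motifStrength = motifStrength,
                            kgInformativeness = kgInformativeness,
                            noiseScale = noiseScale,
                            seed = deriveSeed(seed, "dbset"),
                            embedderSeed = embSeed)
  writePeptides(tr$peptides, file.path(outDir, "train_peptides.csv"))
  writePeptides(te$peptides, file.path(outDir, "test_peptides.csv"))
  writePeptides(db$peptides, file.path(outDir, "db_peptides.csv"))
  saveEmbeddings(db$embeddings, file.path(outDir, "db_embeddings.tsv"))
  exportTriples(db$kg, file.path(outDir, "db_triples.tsv"))
  relMap <- relationshipMap(host)
  if (queryOnly) {
    say("fuse: skipped (query-only baseline)")
    fusedTr <- tr$embeddings
    fusedTe <- te$embeddings
  } else {
    say("fuse: k=", k, ", queryFraction=", queryFraction)
    fusedTr <- enrichDataset(tr$embeddings, db$embeddings, db$kg, relMap,
                             k = k, queryFraction = queryFraction)
    fusedTe <- enrichDataset(te$embeddings, db$embeddings, db$kg, relMap,
                             k = k, queryFraction = queryFraction)
  }
  saveEmbeddings(fusedTr, file.path(outDir, "train_fused.tsv"))
  saveEmbeddings(fusedTe, file.path(outDir, "test_fused.tsv"))
  say("train: windows {", paste(config@windowSizes, collapse = ","),
      "}, ", config@epochs, " epochs")
  model <- trainMSCNN(buildMSCNN(config), fusedTr,
                      unname(peptideLabels(tr$peptides)))
  saveModel(model, file.path(outDir, "model.rds"))
  utils::write.csv(trainingHistory(model),
                   file.path(outDir, "training_history.csv"),
                   row.names = FALSE)
  say("predict")
  preds <- predictMSCNN(model, fusedTe)
  utils::write.csv(preds, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)
  say("evaluate")
  truth <- unname(peptideLabels(te$peptides))
  metrics <- computeMetrics(confusionCounts(truth, preds$label_pred),
                            scores = preds$score, labelsTrue = truth)
  metricsReport(metrics, file.path(outDir, "metrics.json"))
  manifest <- list(
    host = host, seed = seed, nTrain = nTrain, nTest = nTest, nDb = nDb,
    embeddingDim = embeddingDim, motifStrength = motifStrength,
    kgInformativeness = kgInformativeness, noiseScale = noiseScale,
    k = k, queryFraction = queryFraction, queryOnly = queryOnly,
    windowSizes = config@windowSizes, filters = config@filters,
    hiddenUnits = config@hiddenUnits, epochs = config@epochs,
    batchSize = config@batchSize, learningRate = config@learningRate,
    dropout = config@dropout, l2Penalty = config@l2Penalty,
    relationshipMap = as.list(relationshipIncrements(relMap)),
    artifacts = c("train_peptides.csv", "test_peptides.csv",
                  "db_peptides.csv", "db_embeddings.tsv",
                  "db_triples.tsv", "train_fused.tsv", "test_fused.tsv",
                  "model.rds", "training_history.csv",
                  "predictions.csv", "metrics.json"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", outDir)
  list(metrics = metrics, predictions = preds, model = model,
       manifest = manifest)
}
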