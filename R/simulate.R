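#' Simulate an epitope data set with planted signal
#'
#' Generates labelled peptides, a knowledge graph and standardized
#' embeddings with the statistical structure the retrieval-fusion
#' classifier assumes:
#' \itemize{
#'   \item \emph{Sequence signal}: inducing peptides carry
#'     \code{motif} at \code{motifPos} with probability
#'     \code{motifStrength}; noninducing peptides never carry it at
#'     that position.
#'   \item \emph{Contextual signal}: each class prefers its own pool
#'     of source molecules and organisms; with probability
#'     \code{kgInformativeness} a record draws from its class pool,
#'     otherwise from the full pool, so shared-metadata co-membership
#'     correlates with class.  Molecule parents are derived from
#'     molecules (two molecules per parent); hosts are drawn uniformly
#'     and carry no class signal.
#'   \item \emph{Embeddings}: the deterministic synthetic embedder
#'     plus i.i.d. Gaussian noise at \code{noiseScale}, standardized
#'     to 20 rows.
#' }
#' Everything is reproducible for a fixed \code{seed}.
#'
#' @param nInducing,nNoninducing class sizes.
#' @param lengthRange inclusive peptide length range (default 8-20).
#' @param motif short amino-acid string planted in inducing peptides
#'   (default "LP").
#' @param motifPos planted position (default 1, the N-terminus).
#' @param motifStrength probability an inducing peptide carries the
#'   motif (default 0.9).
#' @param kgInformativeness probability metadata is drawn from the
#'   class-preferred pool (default 0.8; 0 = metadata independent of
#'   class).
#' @param nMolecules,nOrganisms metadata pool sizes (defaults 6, 4).
#' @param hosts host names sampled uniformly (default human, mouse).
#' @param embeddingDim embedding dimension (default 32, desk scale).
#' @param noiseScale sd of the additive embedding noise (default 0.5).
#' @param seed integer seed for sequences, metadata and noise.
#' @param embedderSeed seed selecting the synthetic embedder's fixed
#'   per-letter representation table.  This plays the role of the
#'   pretrained model's frozen weights: keep it identical across every
#'   set (queries, held-out test, reference database) that must live in
#'   one embedding space, and do not tie it to the per-dataset
#'   \code{seed}.
#' @param idPrefix prefix for generated epitope ids.
#' @return list with \code{peptides} ([PeptideSet-class]), \code{kg}
#'   ([KnowledgeGraph-class]) and \code{embeddings}
#'   ([EmbeddingSet-class], standardized to 20 rows).
#' @examples
#' sim <- simulateEpitopes(10, 10, seed = 1)
#' sim$peptides
#' @export
simulateEpitopes <- function(nInducing = 100L, nNoninducing = 100L,
                             lengthRange = c(8L, 20L), motif = "LP",
                             motifPos = 1L, motifStrength = 0.9,
                             kgInformativeness = 0.8, nMolecules = 6L,
                             nOrganisms = 4L,
                             hosts = c("human", "mouse"),
                             embeddingDim = 32L, noiseScale = 0.5,
                             seed = 1L, embedderSeed = 20L,
                             idPrefix = "syn") {
  nInducing <- assertCount(nInducing, "nInducing")
  nNoninducing <- assertCount(nNoninducing, "nNoninducing")
  if (nchar(motif) > lengthRange[1] - motifPos + 1)
    stop("motif does not fit inside the minimum peptide length",
         call. = FALSE)
  if (motifStrength < 0 || motifStrength > 1 ||
      kgInformativeness < 0 || kgInformativeness > 1)
    stop("motifStrength and kgInformativeness must lie in [0, 1]",
         call. = FALSE)
  n <- nInducing + nNoninducing
  label <- c(rep(1, nInducing), rep(0, nNoninducing))
  molPool <- paste0("mol_", seq_len(nMolecules))
  orgPool <- paste0("org_", seq_len(nOrganisms))
  molClass <- list(`1` = molPool[seq_len(ceiling(nMolecules / 2))],
                   `0` = molPool[-seq_len(ceiling(nMolecules / 2))])
  orgClass <- list(`1` = orgPool[seq_len(ceiling(nOrganisms / 2))],
                   `0` = orgPool[-seq_len(ceiling(nOrganisms / 2))])
  motifLetters <- strsplit(toupper(motif), "")[[1]]
  motifSpan <- motifPos:(motifPos + length(motifLetters) - 1L)
  gen <- withLocalSeed(deriveSeed(seed, "records"), {
    len <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      letters20 <- sample(AA_ALPHABET_20, len[i], replace = TRUE)
      if (label[i] == 1) {
        if (runif(1) < motifStrength) letters20[motifSpan] <- motifLetters
      } else {
        while (all(letters20[motifSpan] == motifLetters))
          letters20[motifSpan] <- sample(AA_ALPHABET_20,
                                         length(motifSpan),
                                         replace = TRUE)
      }
      paste(letters20, collapse = "")
    }, character(1))
    pick <- function(classPool, fullPool) {
      if (runif(1) < kgInformativeness) sample(classPool, 1)
      else sample(fullPool, 1)
    }
    mol <- vapply(seq_len(n), function(i)
      pick(molClass[[as.character(label[i])]], molPool), character(1))
    org <- vapply(seq_len(n), function(i)
      pick(orgClass[[as.character(label[i])]], orgPool), character(1))
    host <- sample(hosts, n, replace = TRUE)
    list(seqs = seqs, mol = mol, org = org, host = host)
  })
  parent <- paste0("parent_",
                   (match(gen$mol, molPool) - 1L) %/% 2L + 1L)
  ids <- sprintf("%s_%04d", idPrefix, seq_len(n))
  peptides <- PeptideSet(ids, gen$seqs, host = gen$host, label = label,
                         source_molecule = gen$mol,
                         molecule_parent = parent,
                         source_organism = gen$org)
  mats <- withLocalSeed(deriveSeed(seed, "noise"), {
    lapply(seq_len(n), function(i) {
      m <- syntheticEmbed(gen$seqs[i], embeddingDim, seed = embedderSeed)
      m + matrix(rnorm(length(m), sd = noiseScale), nrow(m), ncol(m))
    })
  })
  names(mats) <- ids
  list(peptides = peptides, kg = buildKG(peptides),
       embeddings = standardizeLength(EmbeddingSet(mats), 20L))
}

#' Simulate a reference knowledge database
#'
#' Generates a reference set with the same generative structure as
#' [simulateEpitopes()] but with the class imbalance of a curated
#' knowledge set (169 inducing : 554 noninducing, scaled to
#' \code{nDb} by rounding), and ids guaranteed disjoint from any
#' provided query ids.
#'
#' @param nDb total database size (must be at least the retrieval
#'   depth you will use).
#' @param queryIds optional character vector the generated ids must be
#'   disjoint from (checked, and enforced by a distinct prefix).
#' @param inducingFraction class ratio (default 169/723).
#' @param seed integer seed.
#' @param ... further arguments passed to [simulateEpitopes()].
#' @return list with \code{peptides}, \code{kg}, \code{embeddings}.
#' @examples
#' db <- simulateKnowledgeDB(100, seed = 1)
#' sum(peptideLabels(db$peptides) == 1)  # 23
#' @export
simulateKnowledgeDB <- function(nDb, queryIds = NULL,
                                inducingFraction = 169 / 723, seed = 1L,
                                ...) {
  nDb <- assertCount(nDb, "nDb")
  nInd <- round(nDb * inducingFraction)
  nInd <- max(1L, min(nDb - 1L, as.integer(nInd)))
  out <- simulateEpitopes(nInducing = nInd, nNoninducing = nDb - nInd,
                          seed = seed, idPrefix = "kgdb", ...)
  if (!is.null(queryIds) &&
      length(intersect(epitopeIds(out$peptides), queryIds)))
    stop("generated database ids collide with query ids", call. = FALSE)
  out
}
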