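#' Built-in and custom relationship maps
#'
#' Returns the category-to-increment map governing contextual
#' weighting.  The built-in host profiles carry the tuned values:
#' \code{"human"} = \{host 1.0, source_molecule 0.5, source_organism
#' 0.6, molecule_parent 0.4\} and \code{"mouse"} = \{host 1.0,
#' source_molecule 0.6, source_organism 0.5, molecule_parent 0.4\}.
#' Host is anchored at 1.0 as the most predictive shared property,
#' molecule parent contributes least.
#'
#' @param x \code{"human"}, \code{"mouse"}, or a named non-negative
#'   numeric vector over a subset of \{host, source_molecule,
#'   source_organism, molecule_parent\}.
#' @return a [RelationshipMap-class].
#' @examples
#' relationshipMap("human")
#' relationshipMap(c(host = 1, source_molecule = 0.5))
#' @export
relationshipMap <- function(x = "human") {
  if (is.character(x) && length(x) == 1) {
    inc <- switch(x,
      human = c(host = 1.0, source_molecule = 0.5,
                source_organism = 0.6, molecule_parent = 0.4),
      mouse = c(host = 1.0, source_molecule = 0.6,
                source_organism = 0.5, molecule_parent = 0.4),
      stop("unknown profile '", x, "'; use 'human', 'mouse' or a ",
           "named numeric vector", call. = FALSE))
  } else {
    inc <- x
    if (any(!is.finite(inc)) || any(inc < 0))
      stop("relationship increments must be finite and >= 0",
           call. = FALSE)
  }
  new("RelationshipMap", increments = inc)
}

#' Increment values of a RelationshipMap
#' @param x a [RelationshipMap-class].
#' @return named numeric vector of increments.
#' @export
relationshipIncrements <- function(x) {
  stopifnot(is(x, "RelationshipMap"))
  x@increments
}

setMethod("show", "RelationshipMap", function(object) {
  cat("RelationshipMap:",
      paste(names(object@increments), object@increments, sep = "=",
            collapse = ", "), "\n")
})

#' Euclidean (L2) distance between two embedding matrices
#'
#' The square root of the sum of squared elementwise differences,
#' treating each L x D matrix as its flattened vector.
#'
#' @param q,e numeric matrices of identical shape.
#' @return non-negative scalar.
#' @export
l2Distance <- function(q, e) {
  if (!identical(dim(q), dim(e)))
    stop("matrices must have identical shape", call. = FALSE)
  sqrt(sum((q - e)^2))
}

#' Retrieve the k nearest reference embeddings
#'
#' Ranks every database entry by L2 distance to the query and returns
#' the \code{k} closest, sorted by ascending distance with ties broken
#' by ascending database index (a total order, so retrieval is
#' reproducible).  A database entry whose id equals \code{queryId} is
#' excluded before ranking, so a query never retrieves itself.
#'
#' @param q query matrix (same shape as the database entries).
#' @param database an [EmbeddingSet-class].
#' @param k number of neighbours (default 5).
#' @param queryId optional id of the query, excluded from the
#'   candidates.
#' @return list with \code{neighbour_ids}, \code{distances}
#'   (non-decreasing) and \code{index} (database positions).
#' @export
retrieveTopK <- function(q, database, k = 5L, queryId = NULL) {
  stopifnot(is(database, "EmbeddingSet"))
  k <- assertCount(k, "k")
  ids <- names(database@matrices)
  keep <- if (is.null(queryId)) seq_along(ids) else which(ids != queryId)
  if (length(keep) < k)
    stop("database holds ", length(keep),
         " candidates after self-exclusion but k = ", k, call. = FALSE)
  qv <- as.numeric(q)
  d <- vapply(keep, function(i) {
    m <- database@matrices[[i]]
    if (length(m) != length(qv))
      stop("database entry ", ids[i], " has a different shape than the query",
           call. = FALSE)
    sqrt(sum((qv - as.numeric(m))^2))
  }, numeric(1))
  ord <- order(d, keep)[seq_len(k)]
  list(neighbour_ids = ids[keep[ord]], distances = d[ord],
       index = keep[ord])
}

#' Contextual weights for a retrieved neighbour set
#'
#' Implements the three-step weighting scheme: every retrieved epitope
#' starts with score S = 1.0; for each unordered pair and each
#' relationship category (host, source molecule, source organism,
#' molecule parent) where both epitopes carry exactly the same
#' non-absent value, the category's increment from the relationship map
#' is added to both scores (at most once per category per pair); the
#' weights are the scores normalized by their sum.  If none of the
#' retrieved epitopes has any queryable property the weights are
#' uniform, 1/k (0.2 for the default k = 5).
#'
#' Ids not present in the graph are treated as property-less.  The
#' IFN-gamma label is never a weighting category unless
#' \code{useLabel = TRUE} is given explicitly (an opt-in mirroring the
#' leakage ablation; the label then acts as an extra category with
#' increment \code{labelIncrement}).
#'
#' @param neighbourIds character vector of k >= 2 epitope ids.
#' @param kg a [KnowledgeGraph-class].
#' @param relMap a [RelationshipMap-class].
#' @param useLabel logical opt-in to include the class label as a
#'   shared category (off by default to avoid leakage).
#' @param labelIncrement increment used when \code{useLabel = TRUE}.
#' @return list with \code{weights} (sum to 1) and \code{scores}
#'   (accumulated S values), both ordered like \code{neighbourIds}.
#' @examples
#' ps <- PeptideSet(paste0("e", 1:5), rep("ACDEFGHK", 5),
#'                  host = c("human", "human", "h3", "h4", "h5"),
#'                  source_molecule = c("gag", "gag", "m3", "m4", "m5"))
#' cw <- contextWeights(paste0("e", 1:5), buildKG(ps), relationshipMap("human"))
#' cw$weights  # 0.3125 0.3125 0.125 0.125 0.125
#' @export
contextWeights <- function(neighbourIds, kg, relMap,
                           useLabel = FALSE, labelIncrement = 1.0) {
  stopifnot(is(kg, "KnowledgeGraph"), is(relMap, "RelationshipMap"))
  k <- length(neighbourIds)
  if (k < 2) stop("at least two retrieved epitopes are required",
                  call. = FALSE)
  assertFlag(useLabel, "useLabel")
  known <- epitopeIds(kg)
  props <- lapply(neighbourIds, function(id) {
    if (!(id %in% known))
      return(list(host = NA_character_, source_molecule = NA_character_,
                  molecule_parent = NA_character_,
                  source_organism = NA_character_, label = NA_real_))
    p <- epitopeProperties(kg, id)
    p$label <- kg@epitopeAttrs$label[kg@epitopeAttrs$epitope_id == id]
    p
  })
  inc <- relMap@increments
  if (useLabel) inc <- c(inc, label = labelIncrement)
  scores <- rep(1.0, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      for (cat in names(inc)) {
        a <- props[[i]][[cat]]
        b <- props[[j]][[cat]]
        shared <- if (cat == "label") {
          !is.na(a) && !is.na(b) && a == b
        } else propEqual(a, b)
        if (shared) {
          scores[i] <- scores[i] + inc[[cat]]
          scores[j] <- scores[j] + inc[[cat]]
        }
      }
    }
  }
  list(weights = scores / sum(scores), scores = scores)
}

#' Weighted average of neighbour embeddings
#'
#' Elementwise convex combination of the k retrieved matrices with
#' their contextual weights, producing the single knowledge-informed
#' context embedding.
#'
#' @param neighbours list of k matrices of identical shape (or an
#'   [EmbeddingSet-class]).
#' @param weights numeric vector of length k (typically
#'   \code{contextWeights(...)$weights}).
#' @return a matrix of the common shape.
#' @export
weightedAverage <- function(neighbours, weights) {
  if (is(neighbours, "EmbeddingSet")) neighbours <- neighbours@matrices
  k <- length(neighbours)
  if (length(weights) != k)
    stop("weights must have one entry per neighbour", call. = FALSE)
  shape <- dim(neighbours[[1]])
  out <- matrix(0, shape[1], shape[2])
  for (i in seq_len(k)) {
    if (!identical(dim(neighbours[[i]]), shape))
      stop("all neighbour matrices must share one shape", call. = FALSE)
    out <- out + weights[i] * neighbours[[i]]
  }
  out
}

#' Fuse a query embedding with its knowledge-informed context
#'
#' Convex combination \code{queryFraction * query +
#' (1 - queryFraction) * context}.  The default 0.9 (a 9:1 ratio)
#' preserves the dominant protein-language-model signal while mixing in
#' contextual information; heavier context shares tend to overfit when
#' the reference database is small relative to the query load.
#'
#' @param query,context matrices of identical shape.
#' @param queryFraction real in [0, 1].
#' @return fused matrix of the same shape.
#' @export
fuseEmbedding <- function(query, context, queryFraction = 0.9) {
  if (!identical(dim(query), dim(context)))
    stop("query and context must have identical shape", call. = FALSE)
  if (!is.numeric(queryFraction) || length(queryFraction) != 1 ||
      is.na(queryFraction) || queryFraction < 0 || queryFraction > 1)
    stop("queryFraction must lie in [0, 1]", call. = FALSE)
  queryFraction * query + (1 - queryFraction) * context
}

#' Enrich a query set by retrieval, contextual weighting and fusion
#'
#' For every query: retrieve the k nearest database embeddings
#' (excluding any entry with the query's own id), weight them by shared
#' knowledge-graph properties, average, and fuse with the query at
#' \code{queryFraction}.  Deterministic for fixed inputs.
#'
#' @param queries,database [EmbeddingSet-class] objects of matching
#'   shapes (standardize first).
#' @param kg a [KnowledgeGraph-class] describing the database epitopes.
#' @param relMap a [RelationshipMap-class].
#' @param k retrieval depth (default 5).
#' @param queryFraction query share of the fusion (default 0.9).
#' @param verbose log per-query neighbour ids and weights.
#' @return an [EmbeddingSet-class] of fused embeddings, same ids and
#'   order as \code{queries}.
#' @seealso [retrievalAudit()] for the per-query audit table.
#' @export
enrichDataset <- function(queries, database, kg, relMap, k = 5L,
                          queryFraction = 0.9, verbose = FALSE) {
  stopifnot(is(queries, "EmbeddingSet"), is(database, "EmbeddingSet"))
  fused <- lapply(names(queries@matrices), function(id) {
    q <- queries@matrices[[id]]
    top <- retrieveTopK(q, database, k = k, queryId = id)
    cw <- contextWeights(top$neighbour_ids, kg, relMap)
    if (verbose)
      message(id, ": ", paste(top$neighbour_ids,
                              sprintf("(w=%.3f)", cw$weights),
                              collapse = " "))
    ctx <- weightedAverage(database@matrices[top$index], cw$weights)
    fuseEmbedding(q, ctx, queryFraction)
  })
  names(fused) <- names(queries@matrices)
  EmbeddingSet(fused)
}

#' Per-query retrieval audit table
#'
#' Recomputes retrieval and weighting for every query and returns the
#' audit rows (query_id, neighbour_id, rank, distance, score, weight)
#' suitable for writing as TSV.
#'
#' @inheritParams enrichDataset
#' @return data.frame with one row per (query, neighbour) pair.
#' @export
retrievalAudit <- function(queries, database, kg, relMap, k = 5L) {
  stopifnot(is(queries, "EmbeddingSet"))
  rows <- lapply(names(queries@matrices), function(id) {
    top <- retrieveTopK(queries@matrices[[id]], database, k = k,
                        queryId = id)
    cw <- contextWeights(top$neighbour_ids, kg, relMap)
    data.frame(query_id = id, neighbour_id = top$neighbour_ids,
               rank = seq_len(k), distance = top$distances,
               score = cw$scores, weight = cw$weights,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
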