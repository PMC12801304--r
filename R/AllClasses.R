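#' PeptideSet: a validated collection of epitope records
#'
#' Holds one row per epitope with its sequence and the biological
#' metadata used by the knowledge graph: host, source molecule,
#' molecule parent, source organism, and an optional binary label
#' (1 = IFN-gamma inducing, 0 = noninducing).  Sequences are restricted
#' to the 20 canonical amino-acid letters and epitope ids must be
#' unique; records violating either rule are rejected at construction.
#'
#' @slot records data.frame with columns \code{epitope_id},
#'   \code{sequence}, \code{host}, \code{label}, \code{source_molecule},
#'   \code{molecule_parent}, \code{source_organism}.  Absent metadata is
#'   \code{NA}, never the empty string.
#' @seealso [PeptideSet()], [readPeptides()], [filterByLength()]
#' @exportClass PeptideSet
setClass("PeptideSet", representation(records = "data.frame"))

setValidity("PeptideSet", function(object) {
  df <- object@records
  need <- c("epitope_id", "sequence", "host", "label",
            "source_molecule", "molecule_parent", "source_organism")
  if (!all(need %in% names(df)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$epitope_id))
    return("epitope_id values must be unique")
  if (nrow(df) > 0) {
    if (any(is.na(df$sequence)) || any(nchar(df$sequence) == 0))
      return("sequences must be non-empty")
    bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET_20, collapse = "")),
                 df$sequence)
    if (any(bad))
      return("sequences must contain only the 20 canonical amino-acid letters")
    lab <- df$label[!is.na(df$label)]
    if (length(lab) && !all(lab %in% c(0, 1)))
      return("labels must be 0, 1 or NA")
    for (col in c("host", "source_molecule", "molecule_parent",
                  "source_organism")) {
      v <- df[[col]]
      if (any(!is.na(v) & trimws(v) == ""))
        return(paste0(col, " must be NA when absent, not an empty string"))
    }
  }
  TRUE
})

#' EmbeddingSet: per-residue embedding matrices keyed by epitope id
#'
#' A named list of L x D real matrices (rows = residue positions,
#' columns = embedding dimensions), all sharing the same dimension D.
#' Row counts may differ before length standardization; after
#' [standardizeLength()] every matrix has exactly the target row count.
#'
#' @slot matrices named list of numeric matrices with a common column
#'   count; all entries finite.
#' @slot dim integer, the shared embedding dimension D.
#' @seealso [EmbeddingSet()], [standardizeLength()], [saveEmbeddings()]
#' @exportClass EmbeddingSet
setClass("EmbeddingSet",
         representation(matrices = "list", dim = "integer"))

setValidity("EmbeddingSet", function(object) {
  m <- object@matrices
  if (length(m) == 0) return(TRUE)
  if (is.null(names(m)) || any(names(m) == "") || anyDuplicated(names(m)))
    return("matrices must be uniquely named by epitope_id")
  if (!all(vapply(m, is.matrix, logical(1))))
    return("all elements must be matrices")
  if (!all(vapply(m, ncol, integer(1)) == object@dim))
    return("all matrices must have ncol equal to the embedding dimension")
  if (!all(vapply(m, function(x) all(is.finite(x)), logical(1))))
    return("all embedding entries must be finite")
  TRUE
})

#' KnowledgeGraph: typed epitope-context graph
#'
#' An in-process property graph with node types Epitope, Molecule,
#' MoleculeParent and Organism and edge relations DERIVED_FROM
#' (Epitope to Molecule), ORIGINATES_FROM (Epitope to Organism),
#' BELONGS_TO (Molecule to MoleculeParent) and IS_VARIANT_OF (accepted
#' on import, unused by weighting).  It answers the four per-epitope
#' property queries that drive contextual weighting.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{node_type},
#'   \code{name}.
#' @slot edges data.frame with columns \code{subject}, \code{relation},
#'   \code{object}; every endpoint is a node.
#' @slot epitopeAttrs data.frame of per-epitope attributes
#'   (\code{node_id}, \code{epitope_id}, \code{sequence}, \code{host},
#'   \code{label}, \code{molecule_parent}).
#' @seealso [buildKG()], [epitopeProperties()], [exportTriples()]
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
         representation(nodes = "data.frame", edges = "data.frame",
                        epitopeAttrs = "data.frame"))

KG_RELATIONS <- c("DERIVED_FROM", "ORIGINATES_FROM", "IS_VARIANT_OF",
                  "BELONGS_TO")
KG_NODE_TYPES <- c("Epitope", "Molecule", "MoleculeParent", "Organism")

setValidity("KnowledgeGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("node_id", "node_type", "name") %in% names(nd)))
    return("nodes must have columns node_id, node_type, name")
  if (!all(c("subject", "relation", "object") %in% names(ed)))
    return("edges must have columns subject, relation, object")
  if (anyDuplicated(nd$node_id)) return("node_id values must be unique")
  if (nrow(nd) && !all(nd$node_type %in% KG_NODE_TYPES))
    return(paste("node_type must be one of:",
                 paste(KG_NODE_TYPES, collapse = ", ")))
  if (nrow(ed)) {
    if (!all(ed$relation %in% KG_RELATIONS))
      return(paste("relation must be one of:",
                   paste(KG_RELATIONS, collapse = ", ")))
    if (!all(ed$subject %in% nd$node_id) || !all(ed$object %in% nd$node_id))
      return("every edge endpoint must exist in nodes")
    epi <- nd$node_id[nd$node_type == "Epitope"]
    epiEdges <- ed[ed$subject %in% epi, , drop = FALSE]
    if (nrow(epiEdges) &&
        anyDuplicated(paste(epiEdges$subject, epiEdges$relation)))
      return("an Epitope node may have at most one outgoing edge per relation")
  }
  TRUE
})

#' RelationshipMap: category-to-increment weights for contextual scoring
#'
#' Maps the four shareable biological categories (host, source_molecule,
#' source_organism, molecule_parent) to the non-negative increment added
#' to both epitopes of a retrieved pair when they share that category.
#'
#' The built-in maps are host-profile specific:
#' human = \{host 1.0, source_molecule 0.5, source_organism 0.6,
#' molecule_parent 0.4\}; mouse = \{host 1.0, source_molecule 0.6,
#' source_organism 0.5, molecule_parent 0.4\}.
#'
#' @slot increments named numeric vector, names a subset of the four
#'   categories, all values >= 0, at least one category present.
#' @seealso [relationshipMap()], [contextWeights()]
#' @exportClass RelationshipMap
setClass("RelationshipMap", representation(increments = "numeric"))

RELMAP_CATEGORIES <- c("host", "source_molecule", "source_organism",
                       "molecule_parent")

setValidity("RelationshipMap", function(object) {
  inc <- object@increments
  if (length(inc) < 1) return("at least one category must be present")
  if (is.null(names(inc)) || !all(names(inc) %in% RELMAP_CATEGORIES))
    return(paste("increment names must be among:",
                 paste(RELMAP_CATEGORIES, collapse = ", ")))
  if (anyDuplicated(names(inc))) return("duplicate category names")
  if (any(!is.finite(inc)) || any(inc < 0))
    return("all increments must be finite and >= 0")
  TRUE
})

#' MSCNNConfig: architecture and training settings for the classifier
#'
#' Bundles the multi-scale separable-convolution architecture (window
#' sizes, filters, hidden units) with the training hyperparameters
#' (Adam learning rate, batch size, epochs, dropout, L2 penalty).
#' Full-size defaults follow the published architecture: windows
#' \{2,4,6,8\} for the human profile (\{2,4,6\} for mouse), 1024 filters,
#' 500 hidden units, dropout 0.7, L2 1e-3, learning rate 1e-3, batch
#' size 256, 20 epochs, 20 x 1280 inputs.
#'
#' @slot windowSizes integer vector of depthwise window widths, each
#'   strictly less than \code{inputLen}.
#' @slot filters,hiddenUnits,classes positive integers.
#' @slot dropout numeric in [0, 1).
#' @slot l2Penalty,learningRate non-negative numerics.
#' @slot batchSize,epochs,inputLen,inputDim positive integers
#'   (\code{epochs} may be 0).
#' @slot l2OnConv logical; also penalize convolution weights.
#' @slot seed integer RNG seed for initialization/shuffling/dropout.
#' @seealso [mscnnConfig()], [buildMSCNN()], [countParameters()]
#' @exportClass MSCNNConfig
setClass("MSCNNConfig", representation(
  windowSizes = "integer", filters = "integer", hiddenUnits = "integer",
  classes = "integer", dropout = "numeric", l2Penalty = "numeric",
  learningRate = "numeric", batchSize = "integer", epochs = "integer",
  inputLen = "integer", inputDim = "integer", l2OnConv = "logical",
  seed = "integer"))

setValidity("MSCNNConfig", function(object) {
  if (length(object@windowSizes) < 1 || any(object@windowSizes < 1))
    return("windowSizes must be positive integers")
  if (any(object@windowSizes >= object@inputLen))
    return("every window size must be smaller than inputLen")
  if (object@filters < 1 || object@hiddenUnits < 1 || object@classes < 2)
    return("filters, hiddenUnits must be >= 1 and classes >= 2")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@l2Penalty < 0 || object@learningRate <= 0)
    return("l2Penalty must be >= 0 and learningRate > 0")
  if (object@batchSize < 1 || object@epochs < 0)
    return("batchSize must be >= 1 and epochs >= 0")
  if (object@inputLen < 2 || object@inputDim < 1)
    return("inputLen must be >= 2 and inputDim >= 1")
  TRUE
})

#' MSCNNModel: an (un)trained multi-scale separable-conv classifier
#'
#' @slot config the [MSCNNConfig-class] the model was built from.
#' @slot weights list of parameter arrays: per-window depthwise kernels
#'   (w x D), pointwise kernels (D x F) and biases (F), dense weights
#'   \code{W1}/\code{b1} and output weights \code{W2}/\code{b2}.
#' @slot trained logical.
#' @slot history data.frame of per-epoch loss and accuracy.
#' @seealso [buildMSCNN()], [trainMSCNN()], [predictMSCNN()]
#' @exportClass MSCNNModel
setClass("MSCNNModel", representation(
  config = "MSCNNConfig", weights = "list", trained = "logical",
  history = "data.frame"))
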