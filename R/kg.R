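nodeId <- function(type, name) {
  prefix <- c(Epitope = "epitope", Molecule = "molecule",
              MoleculeParent = "parent", Organism = "organism")[[type]]
  paste0(prefix, ":", trimws(name))
}

#' Build a knowledge graph from peptide records
#'
#' Creates one Epitope node per record (attributes: id, sequence, host,
#' label) and deduplicated Molecule / MoleculeParent / Organism nodes
#' named by their trimmed metadata value, connected by
#' Epitope-DERIVED_FROM-Molecule, Epitope-ORIGINATES_FROM-Organism and
#' Molecule-BELONGS_TO-MoleculeParent edges.  Absent metadata simply
#' produces no node/edge.  Name matching is exact and case-sensitive
#' after trimming surrounding whitespace.
#'
#' The IFN-gamma label is stored as a node attribute but is never used
#' by [contextWeights()] unless explicitly opted in, so label
#' information cannot leak into the weighting.
#'
#' @param x a [PeptideSet-class].
#' @return a [KnowledgeGraph-class].
#' @examples
#' ps <- PeptideSet(c("e1", "e2"), c("LPRQRAYL", "ACDEFGHIKL"),
#'                  host = "human", source_molecule = "gag")
#' kg <- buildKG(ps)
#' epitopeProperties(kg, "e1")
#' @export
buildKG <- function(x) {
  stopifnot(is(x, "PeptideSet"))
  df <- x@records
  nodes <- data.frame(node_id = character(0), node_type = character(0),
                      name = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(subject = character(0), relation = character(0),
                      object = character(0), stringsAsFactors = FALSE)
  addNodes <- function(type, names) {
    names <- unique(trimws(names[!is.na(names)]))
    if (!length(names)) return()
    ids <- vapply(names, function(nm) nodeId(type, nm), character(1))
    newn <- !(ids %in% nodes$node_id)
    nodes <<- rbind(nodes, data.frame(node_id = ids[newn],
                                      node_type = type, name = names[newn],
                                      stringsAsFactors = FALSE))
  }
  addNodes("Epitope", df$epitope_id)
  addNodes("Molecule", df$source_molecule)
  addNodes("MoleculeParent", df$molecule_parent)
  addNodes("Organism", df$source_organism)
  addEdge <- function(s, rel, o) {
    edges <<- rbind(edges, data.frame(subject = s, relation = rel,
                                      object = o, stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(df))) {
    eid <- nodeId("Epitope", df$epitope_id[i])
    if (!is.na(df$source_molecule[i]))
      addEdge(eid, "DERIVED_FROM", nodeId("Molecule", df$source_molecule[i]))
    if (!is.na(df$source_organism[i]))
      addEdge(eid, "ORIGINATES_FROM",
              nodeId("Organism", df$source_organism[i]))
    if (!is.na(df$molecule_parent[i]) && !is.na(df$source_molecule[i]))
      addEdge(nodeId("Molecule", df$source_molecule[i]), "BELONGS_TO",
              nodeId("MoleculeParent", df$molecule_parent[i]))
  }
  edges <- unique(edges)
  attrs <- data.frame(
    node_id = vapply(df$epitope_id, function(nm) nodeId("Epitope", nm),
                     character(1)),
    epitope_id = df$epitope_id, sequence = df$sequence, host = df$host,
    label = df$label, molecule_parent = df$molecule_parent,
    stringsAsFactors = FALSE, row.names = NULL)
  new("KnowledgeGraph", nodes = nodes, edges = edges, epitopeAttrs = attrs)
}

#' @rdname epitopeIds
#' @export
setMethod("epitopeIds", "KnowledgeGraph",
          function(x) x@epitopeAttrs$epitope_id)

setMethod("show", "KnowledgeGraph", function(object) {
  cat("KnowledgeGraph with", nrow(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (nrow(object@nodes)) {
    tab <- table(object@nodes$node_type)
    cat("  nodes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  if (nrow(object@edges)) {
    tab <- table(object@edges$relation)
    cat("  edges:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})

#' Number of triples (edges) in a knowledge graph
#' @param x a [KnowledgeGraph-class].
#' @export
setMethod("length", "KnowledgeGraph", function(x) nrow(x@edges))

#' Query the four contextual properties of an epitope
#'
#' Resolves host (node attribute), source molecule (DERIVED_FROM edge),
#' source organism (ORIGINATES_FROM edge) and molecule parent (direct
#' attribute when recorded, otherwise traversal
#' Epitope-DERIVED_FROM-Molecule-BELONGS_TO-MoleculeParent).  Absent
#' relations yield \code{NA}, never empty strings.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param epitope_id id of an epitope present in the graph.
#' @return named list with elements \code{host},
#'   \code{source_molecule}, \code{molecule_parent},
#'   \code{source_organism}.
#' @export
epitopeProperties <- function(kg, epitope_id) {
  stopifnot(is(kg, "KnowledgeGraph"))
  row <- which(kg@epitopeAttrs$epitope_id == epitope_id)
  if (length(row) != 1)
    stop("unknown epitope_id: ", epitope_id, call. = FALSE)
  nid <- kg@epitopeAttrs$node_id[row]
  edgeTarget <- function(subject, rel) {
    hit <- kg@edges$object[kg@edges$subject == subject &
                             kg@edges$relation == rel]
    if (length(hit) != 1) return(NA_character_)
    kg@nodes$name[match(hit, kg@nodes$node_id)]
  }
  mol <- edgeTarget(nid, "DERIVED_FROM")
  parent <- kg@epitopeAttrs$molecule_parent[row]
  if (is.na(parent) && !is.na(mol))
    parent <- edgeTarget(nodeId("Molecule", mol), "BELONGS_TO")
  list(host = kg@epitopeAttrs$host[row],
       source_molecule = mol,
       molecule_parent = parent,
       source_organism = edgeTarget(nid, "ORIGINATES_FROM"))
}

#' Export / import a knowledge graph as TSV triples
#'
#' Writes one row per edge (\code{subject_id}, \code{relation},
#' \code{object_id}) to \code{path} plus a companion node/attribute
#' table to \code{nodesPath}; re-import reproduces an isomorphic graph.
#' The TSV pair can be loaded into any graph database tooling.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param path triples TSV path.
#' @param nodesPath companion node table path (default
#'   \code{<path>.nodes.tsv}).
#' @return \code{exportTriples} returns \code{path} invisibly;
#'   \code{importTriples} returns a [KnowledgeGraph-class].
#' @export
exportTriples <- function(kg, path, nodesPath = paste0(path, ".nodes.tsv")) {
  stopifnot(is(kg, "KnowledgeGraph"))
  ed <- kg@edges
  names(ed) <- c("subject_id", "relation", "object_id")
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nd <- merge(kg@nodes, kg@epitopeAttrs, by = "node_id", all.x = TRUE,
              sort = FALSE)
  utils::write.table(nd, nodesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname exportTriples
#' @export
importTriples <- function(path, nodesPath = paste0(path, ".nodes.tsv")) {
  ed <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  nd <- utils::read.delim(nodesPath, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  nodes <- data.frame(node_id = as.character(nd$node_id),
                      node_type = as.character(nd$node_type),
                      name = as.character(nd$name),
                      stringsAsFactors = FALSE)
  if (nrow(ed)) {
    edges <- data.frame(subject = ed$subject_id, relation = ed$relation,
                        object = ed$object_id, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(subject = character(0), relation = character(0),
                        object = character(0), stringsAsFactors = FALSE)
  }
  isEpi <- nodes$node_type == "Epitope"
  attrs <- data.frame(
    node_id = nodes$node_id[isEpi],
    epitope_id = as.character(nd$epitope_id[isEpi]),
    sequence = as.character(nd$sequence[isEpi]),
    host = as.character(nd$host[isEpi]),
    label = suppressWarnings(as.numeric(nd$label[isEpi])),
    molecule_parent = as.character(nd$molecule_parent[isEpi]),
    stringsAsFactors = FALSE)
  new("KnowledgeGraph", nodes = nodes, edges = edges, epitopeAttrs = attrs)
}
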