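#' Epitope identifiers
#'
#' @param x a [PeptideSet-class], [EmbeddingSet-class] or
#'   [KnowledgeGraph-class].
#' @return character vector of epitope ids.
#' @export
setGeneric("epitopeIds", function(x) standardGeneric("epitopeIds"))
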