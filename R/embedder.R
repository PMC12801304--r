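#' Deterministic synthetic per-residue embedder
#'
#' Produces an L x D matrix for a peptide where row i is a fixed base
#' vector for the residue letter at position i plus a small positional
#' perturbation; both terms are deterministic functions of (letter,
#' position, seed), so identical letters at identical positions under
#' the same seed always map to the same row.  The 20 per-letter base
#' vectors are pairwise distinct.  This embedder is a test-scale
#' stand-in with none of a trained protein language model's geometry;
#' it exists so the retrieval/fusion/classifier stack can be exercised
#' deterministically at any dimension.
#'
#' @param sequence peptide string over the canonical alphabet.
#' @param dimension embedding dimension D (>= 4).
#' @param seed integer seed selecting the base-vector table.
#' @return an L x D numeric matrix, L = nchar(sequence).
#' @examples
#' m <- syntheticEmbed("LPRQRAYL", 16, seed = 1)
#' dim(m)
#' @export
syntheticEmbed <- function(sequence, dimension = 32L, seed = 1L) {
  dimension <- assertCount(dimension, "dimension", min = 4L)
  sequence <- toupper(sequence)
  letters20 <- strsplit(sequence, "")[[1]]
  if (!all(letters20 %in% AA_ALPHABET_20))
    stop("sequence contains non-canonical residues", call. = FALSE)
  base <- letterBaseVectors(dimension, seed)
  L <- length(letters20)
  out <- matrix(0, L, dimension)
  for (i in seq_len(L)) {
    pos <- withLocalSeed(deriveSeed(seed, paste0("pos", i, "d", dimension)),
                         rnorm(dimension, sd = 0.15))
    out[i, ] <- base[[letters20[i]]] + pos
  }
  out
}

# Per-letter base vectors, cached per (dimension, seed).
letterBaseVectorCache <- new.env(parent = emptyenv())

letterBaseVectors <- function(dimension, seed) {
  key <- paste0("d", dimension, "s", seed)
  if (!is.null(letterBaseVectorCache[[key]]))
    return(letterBaseVectorCache[[key]])
  base <- lapply(AA_ALPHABET_20, function(l) {
    withLocalSeed(deriveSeed(seed, paste0("letter", l, "d", dimension)),
                  rnorm(dimension))
  })
  names(base) <- AA_ALPHABET_20
  letterBaseVectorCache[[key]] <- base
  base
}

#' Embed peptides with a pluggable backend
#'
#' Converts each peptide sequence to an L x D per-residue embedding
#' matrix.  The \code{"synthetic"} backend uses [syntheticEmbed()] and
#' needs nothing beyond this package.  The \code{"plm"} backend is an
#' adapter slot for a pretrained protein language model (e.g. a
#' 1280-dimensional per-residue transformer): supply \code{embedFun}, a
#' \code{function(sequence)} returning the L x D matrix with special
#' token rows already dropped; without it a capability error points to
#' the synthetic backend.
#'
#' @param x a [PeptideSet-class].
#' @param backend \code{"synthetic"} or \code{"plm"}.
#' @param dimension embedding dimension for the synthetic backend.
#' @param seed synthetic backend seed.
#' @param embedFun external embedding function for \code{"plm"}.
#' @return an [EmbeddingSet-class] with one matrix per record, row
#'   count equal to each sequence length (standardize afterwards with
#'   [standardizeLength()]).
#' @export
embedPeptides <- function(x, backend = c("synthetic", "plm"),
                          dimension = 32L, seed = 1L, embedFun = NULL) {
  stopifnot(is(x, "PeptideSet"))
  backend <- match.arg(backend)
  if (backend == "plm") {
    if (is.null(embedFun))
      stop("no pretrained language model backend is configured; pass ",
           "embedFun or use backend = 'synthetic'", call. = FALSE)
    mats <- lapply(x@records$sequence, embedFun)
  } else {
    mats <- lapply(x@records$sequence, syntheticEmbed,
                   dimension = dimension, seed = seed)
  }
  names(mats) <- x@records$epitope_id
  EmbeddingSet(mats)
}
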