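#' Construct an EmbeddingSet
#'
#' @param matrices named list of L x D numeric matrices (names are
#'   epitope ids; column count must agree across the list).
#' @return an [EmbeddingSet-class].
#' @examples
#' es <- EmbeddingSet(list(e1 = matrix(rnorm(8 * 4), 8, 4)))
#' embeddingDim(es)
#' @export
EmbeddingSet <- function(matrices = list()) {
  if (length(matrices)) {
    matrices <- lapply(matrices, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      m
    })
    d <- unique(vapply(matrices, ncol, integer(1)))
    if (length(d) != 1)
      stop("all matrices must share one embedding dimension, found: ",
           paste(d, collapse = ", "), call. = FALSE)
  } else d <- 0L
  new("EmbeddingSet", matrices = matrices, dim = as.integer(d))
}

#' @describeIn EmbeddingSet number of embeddings.
#' @param x an EmbeddingSet.
#' @export
setMethod("length", "EmbeddingSet", function(x) length(x@matrices))

#' @rdname epitopeIds
#' @export
setMethod("epitopeIds", "EmbeddingSet", function(x) names(x@matrices))

#' Embedding dimension D of a set
#' @param x an [EmbeddingSet-class].
#' @return integer column count shared by all matrices.
#' @export
embeddingDim <- function(x) {
  stopifnot(is(x, "EmbeddingSet"))
  x@dim
}

#' Extract embedding matrices
#' @param x an [EmbeddingSet-class].
#' @param i id or index (\code{[[} returns one matrix, \code{[} a
#'   subset EmbeddingSet).
#' @param j,...,drop ignored.
#' @export
setMethod("[[", "EmbeddingSet", function(x, i, j, ...) x@matrices[[i]])

#' @rdname sub-sub-EmbeddingSet-ANY-ANY-method
#' @export
setMethod("[", "EmbeddingSet", function(x, i, j, ..., drop = TRUE) {
  new("EmbeddingSet", matrices = x@matrices[i], dim = x@dim)
})

setMethod("show", "EmbeddingSet", function(object) {
  L <- unique(vapply(object@matrices, nrow, integer(1)))
  cat("EmbeddingSet with", length(object@matrices), "matrices,",
      "dim", object@dim, "\n")
  if (length(object@matrices))
    cat("  row counts:", paste(sort(L), collapse = ", "), "\n")
})

#' Plain list of matrices from an EmbeddingSet
#' @param x an [EmbeddingSet-class].
#' @return the named list of matrices.
#' @export
embeddingList <- function(x) {
  stopifnot(is(x, "EmbeddingSet"))
  x@matrices
}

#' Standardize embeddings to a fixed row count
#'
#' Pads or truncates each L x D matrix to exactly \code{targetLen} rows
#' so the classifier sees constant-shape inputs.  Shorter matrices are
#' padded with all-zero rows appended after the last residue row
#' (C-terminal padding); longer matrices keep their first
#' \code{targetLen} rows (N-terminal retention).  Idempotent at the
#' target length.
#'
#' @param x an [EmbeddingSet-class] or a single numeric matrix.
#' @param targetLen target row count (default 20, the standard fixed
#'   peptide length).
#' @return same type as \code{x}, every matrix with \code{targetLen}
#'   rows.
#' @export
standardizeLength <- function(x, targetLen = 20L) {
  targetLen <- assertCount(targetLen, "targetLen")
  padOne <- function(m) {
    if (nrow(m) == 0) stop("embedding must have at least one row",
                           call. = FALSE)
    if (nrow(m) >= targetLen) return(m[seq_len(targetLen), , drop = FALSE])
    rbind(m, matrix(0, targetLen - nrow(m), ncol(m)))
  }
  if (is.matrix(x)) return(padOne(x))
  stopifnot(is(x, "EmbeddingSet"))
  new("EmbeddingSet", matrices = lapply(x@matrices, padOne), dim = x@dim)
}

#' Save / load an embedding set as a plain-text container
#'
#' The container is a TSV with columns \code{epitope_id},
#' \code{position}, \code{V1..VD}; values are written with 17
#' significant digits so that doubles round-trip bit-exactly.  All
#' matrices in one container must share both L and D.
#'
#' @param x an [EmbeddingSet-class] whose matrices share a common row
#'   count.
#' @param path output/input file path.
#' @return \code{saveEmbeddings} returns \code{path} invisibly;
#'   \code{loadEmbeddings} returns an [EmbeddingSet-class] preserving
#'   the stored id order.
#' @examples
#' es <- EmbeddingSet(list(a = matrix(1:6, 2, 3), b = matrix(7:12, 2, 3)))
#' f <- tempfile(fileext = ".tsv")
#' saveEmbeddings(es, f)
#' identical(embeddingList(loadEmbeddings(f)), embeddingList(es))
#' @export
saveEmbeddings <- function(x, path) {
  stopifnot(is(x, "EmbeddingSet"))
  L <- unique(vapply(x@matrices, nrow, integer(1)))
  if (length(L) > 1)
    stop("all matrices must share one row count before saving; found: ",
         paste(L, collapse = ", "), call. = FALSE)
  D <- x@dim
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("epitope_id", "position", paste0("V", seq_len(D))),
                   collapse = "\t"), con)
  for (id in names(x@matrices)) {
    m <- x@matrices[[id]]
    vals <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    writeLines(paste(id, seq_len(nrow(m)),
                     apply(vals, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname saveEmbeddings
#' @export
loadEmbeddings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(EmbeddingSet())
  valCols <- grep("^V[0-9]+$", names(df), value = TRUE)
  if (!all(c("epitope_id", "position") %in% names(df)) || !length(valCols))
    stop("not an embedding container: ", path, call. = FALSE)
  if (anyNA(df[valCols]))
    stop("corrupt embedding container (non-numeric or missing values)",
         call. = FALSE)
  ids <- unique(df$epitope_id)
  mats <- lapply(ids, function(id) {
    sub <- df[df$epitope_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    as.matrix(sub[valCols])
  })
  names(mats) <- ids
  L <- unique(vapply(mats, nrow, integer(1)))
  if (length(L) > 1)
    stop("container holds matrices with mixed row counts", call. = FALSE)
  EmbeddingSet(mats)
}
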