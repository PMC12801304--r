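#' Construct a PeptideSet
#'
#' @param epitope_id character vector of unique ids.
#' @param sequence character vector of peptide sequences over the 20
#'   canonical amino-acid letters.
#' @param host,source_molecule,molecule_parent,source_organism optional
#'   character metadata; \code{NA} marks absence.
#' @param label optional numeric vector of 0/1 class labels
#'   (1 = IFN-gamma inducing).
#' @return a [PeptideSet-class].
#' @examples
#' ps <- PeptideSet(c("e1", "e2"), c("LPRQRAYL", "ACDEFGHIKL"),
#'                  host = c("human", "mouse"), label = c(1, 0))
#' length(ps)
#' @export
PeptideSet <- function(epitope_id, sequence, host = NA_character_,
                       label = NA_real_, source_molecule = NA_character_,
                       molecule_parent = NA_character_,
                       source_organism = NA_character_) {
  n <- length(epitope_id)
  df <- data.frame(
    epitope_id = as.character(epitope_id),
    sequence = toupper(as.character(sequence)),
    host = rep_len(as.character(host), n),
    label = rep_len(as.numeric(label), n),
    source_molecule = rep_len(as.character(source_molecule), n),
    molecule_parent = rep_len(as.character(molecule_parent), n),
    source_organism = rep_len(as.character(source_organism), n),
    stringsAsFactors = FALSE)
  for (col in c("host", "source_molecule", "molecule_parent",
                "source_organism")) {
    v <- trimws(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[col]] <- v
  }
  new("PeptideSet", records = df)
}

emptyPeptideSet <- function() {
  PeptideSet(character(0), character(0))
}

#' @describeIn PeptideSet number of records.
#' @param x a PeptideSet.
#' @export
setMethod("length", "PeptideSet", function(x) nrow(x@records))

#' @rdname epitopeIds
#' @export
setMethod("epitopeIds", "PeptideSet", function(x) x@records$epitope_id)

#' Peptide sequences as an AAStringSet
#' @param x a [PeptideSet-class].
#' @return a [Biostrings::AAStringSet] named by epitope id.
#' @export
sequences <- function(x) {
  stopifnot(is(x, "PeptideSet"))
  out <- Biostrings::AAStringSet(x@records$sequence)
  names(out) <- x@records$epitope_id
  out
}

#' Class labels of a PeptideSet
#' @param x a [PeptideSet-class].
#' @return numeric vector of 0/1 labels (NA when unlabelled), named by
#'   epitope id.
#' @export
peptideLabels <- function(x) {
  stopifnot(is(x, "PeptideSet"))
  stats::setNames(x@records$label, x@records$epitope_id)
}

#' Metadata table of a PeptideSet
#' @param x a [PeptideSet-class].
#' @return the underlying data.frame of records.
#' @export
peptideRecords <- function(x) {
  stopifnot(is(x, "PeptideSet"))
  x@records
}

#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@records$epitope_id)
  new("PeptideSet", records = x@records[i, , drop = FALSE])
})

setMethod("show", "PeptideSet", function(object) {
  df <- object@records
  nlab <- sum(!is.na(df$label))
  cat("PeptideSet with", nrow(df), "records",
      sprintf("(%d labelled, %d inducing)\n", nlab,
              sum(df$label == 1, na.rm = TRUE)))
  if (nrow(df)) {
    cat("  length range:", paste(range(nchar(df$sequence)), collapse = "-"),
        "residues\n")
    cat("  hosts:", paste(unique(stats::na.omit(df$host)), collapse = ", "),
        "\n")
  }
})

parseLabels <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop("labels must be 0/1 or inducing/noninducing",
                       call. = FALSE)
    return(as.numeric(x))
  }
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[x %in% c("1", "inducing")] <- 1
  out[x %in% c("0", "noninducing")] <- 0
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad))
    stop("unrecognized label value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Read peptides from FASTA or a delimited table
#'
#' FASTA entries become records with the header word as
#' \code{epitope_id}; tables (CSV/TSV auto-detected by extension) must
#' carry \code{epitope_id} and \code{sequence} columns and may carry the
#' metadata columns \code{host}, \code{label}, \code{source_molecule},
#' \code{molecule_parent}, \code{source_organism}.  Labels may be 0/1 or
#' the case-insensitive words inducing/noninducing.  Records containing
#' non-canonical residues are dropped with a message reporting the
#' count; duplicated ids are an error.
#'
#' @param path file path.
#' @param format "fasta" or "table"; default guesses from the extension.
#' @return a [PeptideSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">e1", "LPRQRAYL"), fa)
#' readPeptides(fa)
#' @export
readPeptides <- function(path, format = c("auto", "fasta", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta" else "table"
  }
  if (format == "fasta") {
    if (file.size(path) == 0) return(emptyPeptideSet())
    aa <- Biostrings::readBStringSet(path)  # BString: validate ourselves
    if (length(aa) == 0) return(emptyPeptideSet())
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    df <- data.frame(epitope_id = ids,
                     sequence = toupper(as.character(aa)),
                     stringsAsFactors = FALSE)
  } else {
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt"))
      "\t" else ","
    df <- utils::read.delim(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = "character",
                            fileEncoding = "UTF-8")
    if (!all(c("epitope_id", "sequence") %in% names(df)))
      stop("table must have columns epitope_id and sequence",
           call. = FALSE)
    if (nrow(df) == 0) return(emptyPeptideSet())
    df$sequence <- toupper(df$sequence)
  }
  if (anyDuplicated(df$epitope_id))
    stop("duplicate epitope_id values in ", path, call. = FALSE)
  keep <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET_20, collapse = "")),
                 df$sequence) & nchar(df$sequence) > 0
  if (any(!keep))
    message("Rejected ", sum(!keep),
            " record(s) with non-canonical residues")
  df <- df[keep, , drop = FALSE]
  getcol <- function(col) {
    if (col %in% names(df)) df[[col]] else NA_character_
  }
  lab <- if ("label" %in% names(df)) parseLabels(df$label) else NA_real_
  PeptideSet(df$epitope_id, df$sequence, host = getcol("host"),
             label = lab, source_molecule = getcol("source_molecule"),
             molecule_parent = getcol("molecule_parent"),
             source_organism = getcol("source_organism"))
}

#' Write peptides to FASTA or CSV
#'
#' @param x a [PeptideSet-class].
#' @param path output path.
#' @param format "fasta" (sequences only) or "table" (all metadata,
#'   CSV).
#' @return \code{path}, invisibly.
#' @export
writePeptides <- function(x, path, format = c("table", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(sequences(x), path)
  } else {
    utils::write.csv(x@records, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Filter peptides by sequence length
#'
#' Retains exactly the records whose sequence length lies in
#' \code{[minLen, maxLen]} (defaults 8-20, the range spanning MHC
#' class I 8-11-mers and class II 13-20-mers), preserving order.
#' Idempotent.
#'
#' @param x a [PeptideSet-class].
#' @param minLen,maxLen inclusive length bounds.
#' @return the filtered [PeptideSet-class].
#' @export
filterByLength <- function(x, minLen = 8L, maxLen = 20L) {
  stopifnot(is(x, "PeptideSet"))
  if (minLen > maxLen) stop("minLen must be <= maxLen", call. = FALSE)
  len <- nchar(x@records$sequence)
  x[which(len >= minLen & len <= maxLen)]
}
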