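#' @import methods
#' @importFrom stats rnorm runif sd
#' @importFrom utils head read.delim write.table
NULL

AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so library code never clobbers the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit sub-seed from a parent seed and a string tag.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# NA-safe trimmed string equality used for KG property matching.
propEqual <- function(a, b) {
  !is.na(a) && !is.na(b) && trimws(a) == trimws(b)
}

assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(what, " must be TRUE or FALSE", call. = FALSE)
}

assertCount <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(what, " must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}
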