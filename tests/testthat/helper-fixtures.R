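# Shared fixture builders; everything generated in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomPeptides <- function(n, lengths = 8:20, seed = 1, prefix = "p",
                           withMeta = TRUE) {
  set.seed(seed)
  seqs <- vapply(sample(lengths, n, replace = TRUE), function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  if (withMeta) {
    PeptideSet(paste0(prefix, seq_len(n)), seqs,
               host = sample(c("human", "mouse", NA), n, replace = TRUE),
               label = sample(c(0, 1), n, replace = TRUE),
               source_molecule = sample(c(paste0("mol", 1:4), NA), n,
                                        replace = TRUE),
               molecule_parent = sample(c(paste0("par", 1:2), NA), n,
                                        replace = TRUE),
               source_organism = sample(c(paste0("org", 1:3), NA), n,
                                        replace = TRUE))
  } else {
    PeptideSet(paste0(prefix, seq_len(n)), seqs)
  }
}

randomEmbeddingSet <- function(n, L = 20, D = 8, seed = 1, prefix = "e") {
  set.seed(seed)
  mats <- lapply(seq_len(n), function(i) matrix(rnorm(L * D), L, D))
  names(mats) <- paste0(prefix, seq_len(n))
  EmbeddingSet(mats)
}

# Five-epitope neighbourhood where e1 and e2 share host + molecule and
# e3..e5 share nothing (distinct values everywhere).
workedExampleKG <- function() {
  ps <- PeptideSet(paste0("e", 1:5), rep("ACDEFGHK", 5),
                   host = c("human", "human", "h3", "h4", "h5"),
                   source_molecule = c("gag", "gag", "m3", "m4", "m5"),
                   source_organism = paste0("o", 1:5),
                   molecule_parent = paste0("mp", 1:5))
  buildKG(ps)
}

# Independent nested-loop oracle for the separable convolution:
# depthwise sum over the window per channel, then 1x1 pointwise mixing.
loopSepConv <- function(x, K, Wp, b) {
  L <- nrow(x); D <- ncol(x); w <- nrow(K)
  P <- L - w + 1; F_ <- ncol(Wp)
  z <- matrix(0, P, D)
  for (p in 1:P) for (d in 1:D) {
    acc <- 0
    for (j in 1:w) acc <- acc + K[j, d] * x[p + j - 1, d]
    z[p, d] <- acc
  }
  y <- matrix(0, P, F_)
  for (p in 1:P) for (f in 1:F_) {
    acc <- b[f]
    for (d in 1:D) acc <- acc + z[p, d] * Wp[d, f]
    y[p, f] <- acc
  }
  y
}

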