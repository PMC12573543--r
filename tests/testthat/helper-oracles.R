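# Independent oracles used by the tests. These deliberately re-derive
# results by brute force and never call the code paths they check.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap local alignment score, written as a direct dynamic
# program (gap of length L costs open + L * ext)
oracle_local_score <- function(a, b, open = 11, ext = 1, S = .blosum62) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + S[a[i], b[j]])
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# exhaustive window scan for exact motif presence
oracle_has_all_motifs <- function(seq, patterns) {
  chars <- strsplit(seq, "")[[1]]
  all(vapply(patterns, function(p) {
    pc <- strsplit(p, "")[[1]]
    w <- length(pc)
    if (length(chars) < w) return(FALSE)
    for (s in seq_len(length(chars) - w + 1)) {
      if (all(chars[s:(s + w - 1)] == pc)) return(TRUE)
    }
    FALSE
  }, logical(1)))
}

oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# additive 5-leaf metric from the tree ((A:2,B:3):1,(C:4,D:5):2,E:6)
additive_5leaf <- function() {
  lv <- c("A", "B", "C", "D", "E")
  D <- matrix(0, 5, 5, dimnames = list(lv, lv))
  D["A","B"] <- 5;  D["A","C"] <- 9;  D["A","D"] <- 10; D["A","E"] <- 9
  D["B","C"] <- 10; D["B","D"] <- 11; D["B","E"] <- 10
  D["C","D"] <- 9;  D["C","E"] <- 12; D["D","E"] <- 13
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

small_corpus <- function(n = 2, rate = 0.05, decoys = 0, seed = 11) {
  generate_reference_corpus(corpus_spec(n, rate, decoys, seed = seed))
}
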