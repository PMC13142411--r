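# Shared fixtures: toy alphabet libraries, a tiny model configuration that
# exercises every architectural component in milliseconds, and a hand-built
# ragged batch for masking checks.

toyLibrary <- function(specs, provenance = "toy") {
  # specs: list of c(method, members)
  AlphabetLibrary(lapply(seq_along(specs), function(i)
    Alphabet(specs[[i]][2], method = specs[[i]][1],
             id = sprintf("a%02d", i))), provenance = provenance)
}

randomLibrary <- function(n, seed) {
  withr::with_seed(seed, {
    specs <- lapply(seq_len(n), function(i) {
      k <- sample(2:12, 1)
      c(sample(c("m1", "m2", "m3"), 1),
        paste(sample(CANONICAL_RESIDUES, k), collapse = ""))
    })
    lib <- lapply(seq_along(specs), function(i)
      Alphabet(specs[[i]][2], method = specs[[i]][1],
               id = sprintf("r%03d", i)))
    key <- paste(vapply(lib, alphabetMethod, character(1)),
                 vapply(lib, alphabetString, character(1)))
    AlphabetLibrary(lib[!duplicated(key)], provenance = "fuzz")
  })
}

tinyModelConfig <- function(dropout = 0) {
  modelConfig(dssp_embed_dim = 6L, type_embed_dim = 3L, lstm_hidden = 5L,
              lstm_layers = 2L, attention_heads = 2L, decoder_dims = c(7L, 6L),
              dropout_rate = dropout)
}

raggedBatch <- function(seed = 42) {
  withr::with_seed(seed, list(
    dssp = matrix(c(0, 3, 8, 2, 5, 1, 4, 9, 9, 9), nrow = 2, byrow = TRUE),
    type = matrix(c(0, 1, 2, 0, 2, 0, 1, 3, 3, 3), nrow = 2, byrow = TRUE),
    labels = matrix(c(0, 5, 19, 3, 7, 2, 11, -1, -1, -1), nrow = 2,
                    byrow = TRUE),
    props = array(rnorm(2 * 5 * 3), dim = c(2, 5, 3)),
    mask = matrix(c(rep(TRUE, 5), TRUE, TRUE, FALSE, FALSE, FALSE),
                  nrow = 2, byrow = TRUE)))
}

randomDssp <- function(len) {
  paste(sample(DSSP_STATES, len, replace = TRUE), collapse = "")
}

# Nested-list path access for parameter trees (paths mix names and indices)
getLeaf <- function(x, path) Reduce(function(acc, k) acc[[k]], path, x)
nudgeLeaf <- function(x, path, i, delta) {
  rec <- function(x, p) {
    if (length(p) == 1L) {
      x[[p[[1]]]][i] <- x[[p[[1]]]][i] + delta
    } else {
      x[[p[[1]]]] <- rec(x[[p[[1]]]], p[-1])
    }
    x
  }
  rec(x, path)
}

# Independent global-alignment oracle (match +1, mismatch 0, gap -1):
# plain Needleman-Wunsch DP returning matches and alignment length.
nwOracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  # traceback for matches / alignment length
  i <- n; j <- m; matches <- 0; len <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1
  }
  list(matches = matches, length = len)
}
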