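# Inference: alphabet-constrained greedy decoding. Disallowed residues get
# the most negative representable logit, so post-softmax mass outside the
# alphabet is exactly zero and the decoded sequence is guaranteed to stay
# inside the alphabet.

.alphabetMembers <- function(alphabet) {
  m <- if (is(alphabet, "Alphabet")) members(alphabet) else {
    if (length(alphabet) == 1L && nchar(alphabet[1]) > 1L)
      alphabet <- strsplit(alphabet, "", fixed = TRUE)[[1]]
    sort(unique(toupper(alphabet)))
  }
  if (length(m) == 0L) stop("empty alphabet")
  if (!all(m %in% CANONICAL_RESIDUES))
    stop("alphabet contains non-canonical residues")
  m
}

#' Mask residue logits to an allowed alphabet
#'
#' Entries for residues outside the alphabet are replaced by the most
#' negative finite double, so that softmax places exactly zero mass on them
#' (the finite stand-in for negative infinity avoids NaN propagation).
#'
#' @param logits Numeric width-20 vector or (L x 20) matrix, columns in
#'   alphabetical residue order.
#' @param alphabet An [Alphabet-class], member string, or character vector.
#' @return Masked logits of the same shape.
#' @export
maskLogits <- function(logits, alphabet) {
  m <- .alphabetMembers(alphabet)
  vec <- is.vector(logits)
  if (vec) logits <- matrix(logits, nrow = 1L)
  stopifnot(ncol(logits) == 20L)
  disallowed <- !CANONICAL_RESIDUES %in% m
  logits[, disallowed] <- -.Machine$double.xmax
  if (vec) logits[1, ] else logits
}

#' Masked softmax over the 20 residues
#'
#' @inheritParams maskLogits
#' @return Probabilities of the same shape; rows sum to 1 over allowed
#'   residues and are exactly 0 elsewhere.
#' @export
maskedSoftmax <- function(logits, alphabet) {
  masked <- maskLogits(logits, alphabet)
  vec <- is.vector(masked)
  if (vec) masked <- matrix(masked, nrow = 1L)
  e <- exp(masked - apply(masked, 1, max))
  p <- e / rowSums(e)
  colnames(p) <- CANONICAL_RESIDUES
  if (vec) p[1, ] else p
}

#' Greedy decode a residue string from per-position distributions
#'
#' Positionwise argmax; exact ties break to the alphabetically first
#' residue.
#'
#' @param probs (L x 20) matrix of per-position distributions (columns in
#'   alphabetical residue order), e.g. from [maskedSoftmax()].
#' @return An amino acid string of length L.
#' @export
greedyDecode <- function(probs) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  stopifnot(ncol(probs) == 20L)
  paste(CANONICAL_RESIDUES[apply(probs, 1, which.max)], collapse = "")
}

#' DesignResult: one designed sequence
#'
#' @slot target_id Target identifier.
#' @slot alphabet_id Alphabet identifier.
#' @slot sequence Designed amino acid string.
#' @slot per_position_probs (L x 20) masked softmax distributions.
#' @slot property_pred (L x 3) predicted property triples (standardized
#'   scale).
#' @export
setClass("DesignResult",
         representation(target_id = "character", alphabet_id = "character",
                        sequence = "character", per_position_probs = "matrix",
                        property_pred = "matrix"))

setValidity("DesignResult", function(object) {
  if (nchar(object@sequence) != nrow(object@per_position_probs))
    return("sequence length must match the probability matrix")
  TRUE
})

#' @rdname DesignResult-class
#' @param object A `DesignResult`.
#' @export
setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult %s|%s: %s\n", object@target_id,
              object@alphabet_id, object@sequence))
})

#' @describeIn DesignResult-class the designed amino acid string
#' @param x A `DesignResult`.
#' @export
setGeneric("designedSequence", function(x) standardGeneric("designedSequence"))
#' @rdname DesignResult-class
#' @export
setMethod("designedSequence", "DesignResult", function(x) x@sequence)

#' Design a sequence for one target under one alphabet
#'
#' Runs the model forward on the tokenized DSSP string and its derived type
#' track, masks the logits to the alphabet, and greedy-decodes. Dropout is
#' disabled. A DSSP length outside the trained length envelope triggers a
#' warning, not an error.
#'
#' @param model A trained [BlstmaModel-class].
#' @param dssp Target DSSP string.
#' @param alphabet An [Alphabet-class] (or member string).
#' @param target_id Identifier recorded in the result.
#' @return A [DesignResult-class].
#' @export
designSequence <- function(model, dssp, alphabet, target_id = "target") {
  ids <- tokenizeDssp(dssp)
  env <- model@meta$trained_lengths
  if (!is.null(env) && (length(ids) < env[1] || length(ids) > env[2]))
    warning(sprintf("target length %d outside trained length envelope [%d, %d]",
                    length(ids), env[1], env[2]))
  out <- forwardModel(model, matrix(ids, nrow = 1L),
                      matrix(typeIdsOf(ids), nrow = 1L))
  .designFromLogits(out, alphabet, target_id)
}

.designFromLogits <- function(out, alphabet, target_id) {
  L <- dim(out$residue_logits)[2]
  logits <- matrix(out$residue_logits[1, , ], nrow = L)
  probs <- maskedSoftmax(logits, alphabet)
  alphabet_id <- if (is(alphabet, "Alphabet")) alphabetId(alphabet)
                 else paste(.alphabetMembers(alphabet), collapse = "")
  new("DesignResult", target_id = target_id, alphabet_id = alphabet_id,
      sequence = greedyDecode(probs), per_position_probs = probs,
      property_pred = matrix(out$property_pred[1, , ], nrow = L,
                             dimnames = list(NULL, c("vdw_volume", "logd",
                                                     "formal_charge"))))
}

#' Batch design over targets x alphabets
#'
#' One model forward per target, reused across all alphabets (masking is
#' applied post hoc), matching the combinatorial design-space layout.
#'
#' @param model A trained [BlstmaModel-class].
#' @param targets Data frame with columns `id` and `dssp`.
#' @param library An [AlphabetLibrary-class] (or list of alphabets).
#' @return List of [DesignResult-class], in targets-major order.
#' @export
designSequences <- function(model, targets, library) {
  abc <- if (is(library, "AlphabetLibrary")) alphabets(library) else library
  results <- vector("list", nrow(targets) * length(abc))
  k <- 0L
  for (i in seq_len(nrow(targets))) {
    ids <- tokenizeDssp(targets$dssp[i])
    out <- forwardModel(model, matrix(ids, nrow = 1L),
                        matrix(typeIdsOf(ids), nrow = 1L))
    for (a in abc) {
      k <- k + 1L
      results[[k]] <- .designFromLogits(out, a, targets$id[i])
    }
  }
  results
}

#' Write design results to FASTA
#'
#' Headers follow `>{target_id}|{alphabet_id}|{alphabet members}`.
#'
#' @param results List of [DesignResult-class].
#' @param path Output FASTA path.
#' @export
writeDesignsFasta <- function(results, path) {
  seqs <- Biostrings::AAStringSet(vapply(results, designedSequence,
                                         character(1)))
  names(seqs) <- vapply(results, function(r) {
    allowed <- colnames(r@per_position_probs)[colSums(r@per_position_probs) > 0]
    paste(r@target_id, r@alphabet_id, paste(allowed, collapse = ""),
          sep = "|")
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Tabular report of design results
#'
#' @param results List of [DesignResult-class].
#' @return Data frame with `target_id`, `alphabet_id`, `sequence`,
#'   `length`, `alphabet_size`.
#' @export
designReport <- function(results) {
  data.frame(
    target_id = vapply(results, function(r) r@target_id, character(1)),
    alphabet_id = vapply(results, function(r) r@alphabet_id, character(1)),
    sequence = vapply(results, designedSequence, character(1)),
    length = vapply(results, function(r) nchar(r@sequence), integer(1)),
    alphabet_size = vapply(results, function(r)
      sum(colSums(r@per_position_probs) > 0), integer(1)),
    stringsAsFactors = FALSE)
}
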