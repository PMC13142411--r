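# Seeded generator of pipeline-shaped data: segmented DSSP strings from a
# run-length grammar, a known DSSP-state -> residue generating rule with
# property-consistent preferences, and complete training datasets. The
# generator targets testability of every other module, not realism of true
# structural statistics.

#' Grammar configuration for synthetic DSSP strings
#'
#' Strings are built from secondary-structure runs: a class is drawn from
#' `class_weights`, the run length is geometric with the class mean, and
#' states within the run are drawn from that class's state weights. Lengths
#' are uniform in `[min_len, max_len]` (the curation bounds).
#'
#' @param min_len,max_len Length bounds (defaults 10 and 300).
#' @param segment_length_mean Named positive means of run lengths per class.
#' @param class_weights Named distribution over helix/sheet/coil.
#' @param state_weights Named list of within-class state distributions.
#' @return A validated grammar config list.
#' @export
grammarConfig <- function(min_len = 10L, max_len = 300L,
                          segment_length_mean = c(helix = 8, sheet = 5,
                                                  coil = 4),
                          class_weights = c(helix = 0.40, sheet = 0.25,
                                            coil = 0.35),
                          state_weights = list(
                            helix = c(H = 0.80, G = 0.15, I = 0.05),
                            sheet = c(E = 0.85, B = 0.15),
                            coil = c(T = 0.30, S = 0.25, P = 0.10, C = 0.35))) {
  stopifnot(min_len >= 1L, max_len >= min_len,
            all(segment_length_mean > 0),
            setequal(names(class_weights), TYPE_CLASSES))
  if (abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must sum to 1")
  for (cl in TYPE_CLASSES) {
    w <- state_weights[[cl]]
    if (abs(sum(w) - 1) > 1e-8)
      stop(sprintf("state_weights[['%s']] must sum to 1", cl))
    if (!all(names(w) %in% DSSP_STATES))
      stop("state weights must be keyed by DSSP states")
  }
  list(min_len = as.integer(min_len), max_len = as.integer(max_len),
       segment_length_mean = segment_length_mean,
       class_weights = class_weights[TYPE_CLASSES],
       state_weights = state_weights)
}

#' Sample segmented DSSP strings from a grammar
#'
#' Draws use the current RNG state; wrap in a seeded stream for
#' reproducibility (as [generateDataset()] does).
#'
#' @param config From [grammarConfig()].
#' @param n Number of strings.
#' @return Character vector of DSSP strings with lengths in
#'   `[min_len, max_len]`.
#' @export
sampleDssp <- function(config, n = 1L) {
  stopifnot(n >= 1L)
  vapply(seq_len(n), function(i) {
    target <- sample(config$min_len:config$max_len, 1L)
    out <- character(0)
    while (length(out) < target) {
      cl <- sample(TYPE_CLASSES, 1L, prob = config$class_weights)
      run <- 1L + rgeom(1L, 1 / config$segment_length_mean[[cl]])
      w <- config$state_weights[[cl]]
      out <- c(out, sample(names(w), run, replace = TRUE, prob = w))
    }
    paste(out[seq_len(target)], collapse = "")
  }, character(1))
}

#' Construct a DSSP-state -> residue generating rule
#'
#' @param probs 9 x 20 matrix of per-state residue distributions (rows in
#'   [DSSP_STATES] order, columns alphabetical residues); each row must sum
#'   to 1 and have a unique mode.
#' @param noise_level Probability of an off-rule draw from the state's
#'   distribution instead of the modal residue.
#' @return A rule-map list (`probs`, `noise_level`, `modal`).
#' @export
ruleMap <- function(probs, noise_level = 0) {
  stopifnot(is.matrix(probs), nrow(probs) == 9L, ncol(probs) == 20L,
            noise_level >= 0, noise_level <= 1)
  if (any(abs(rowSums(probs) - 1) > 1e-8))
    stop("each state's residue distribution must sum to 1")
  modal <- apply(probs, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1L) stop("rule-map rows must have a unique mode")
    CANONICAL_RESIDUES[top]
  })
  rownames(probs) <- DSSP_STATES
  colnames(probs) <- CANONICAL_RESIDUES
  list(probs = probs, noise_level = noise_level,
       modal = setNames(modal, DSSP_STATES))
}

#' Property-consistent default generating rule
#'
#' Helix states prefer A/L/E/K, sheet states prefer V/I/F/Y, coil states
#' prefer G/P/S/N, so the property-regression head receives a learnable
#' physicochemical signal. Each state has a distinct unique mode.
#'
#' @param noise_level Passed to [ruleMap()].
#' @export
defaultRuleMap <- function(noise_level = 0) {
  probs <- matrix(0, 9, 20, dimnames = list(DSSP_STATES, CANONICAL_RESIDUES))
  pref <- list(
    H = c(L = 0.55, A = 0.25, E = 0.10, K = 0.10),
    G = c(A = 0.55, L = 0.20, E = 0.15, K = 0.10),
    I = c(K = 0.55, E = 0.20, A = 0.15, L = 0.10),
    E = c(V = 0.55, I = 0.20, F = 0.15, Y = 0.10),
    B = c(I = 0.55, V = 0.20, F = 0.15, Y = 0.10),
    T = c(G = 0.45, S = 0.25, P = 0.15, N = 0.15),
    S = c(S = 0.45, G = 0.25, N = 0.20, P = 0.10),
    P = c(P = 0.60, G = 0.20, S = 0.10, N = 0.10),
    C = c(N = 0.45, G = 0.30, S = 0.15, P = 0.10))
  for (st in DSSP_STATES) probs[st, names(pref[[st]])] <- pref[[st]]
  ruleMap(probs, noise_level)
}

#' Modal (noiseless) amino acid sequence of a rule for one DSSP string
#'
#' @param dssp A DSSP string.
#' @param rule From [ruleMap()].
#' @export
modalSequence <- function(dssp, rule) {
  chars <- .dsspChars(dssp)
  paste(rule$modal[chars], collapse = "")
}

#' Sample an amino acid sequence from a rule
#'
#' Each position emits the state's modal residue with probability
#' `1 - noise_level` and otherwise draws from the state's full residue
#' distribution. At `noise_level` 0 the output equals [modalSequence()].
#'
#' @param dssp A DSSP string.
#' @param rule From [ruleMap()].
#' @export
ruleSequence <- function(dssp, rule) {
  chars <- .dsspChars(dssp)
  if (rule$noise_level == 0) return(paste(rule$modal[chars], collapse = ""))
  res <- rule$modal[chars]
  noisy <- runif(length(chars)) < rule$noise_level
  if (any(noisy)) {
    res[noisy] <- vapply(which(noisy), function(i)
      sample(CANONICAL_RESIDUES, 1L, prob = rule$probs[chars[i], ]),
      character(1))
  }
  paste(res, collapse = "")
}

#' Generate a complete synthetic training dataset
#'
#' Samples `n` DSSP strings from the grammar, emits rule sequences, and
#' assembles training examples through the standard dataset pipeline (type
#' tracks and raw property targets; standardization happens at training
#' time from the training split). Every example passes [curateRecords()]
#' unchanged by construction.
#'
#' @param n Number of examples (>= 1).
#' @param grammar From [grammarConfig()].
#' @param rule From [ruleMap()].
#' @param seed Root integer seed.
#' @return List with `records` (data frame), `examples` (training-example
#'   list), and `manifest` (seeds and configs).
#' @export
generateDataset <- function(n, grammar = grammarConfig(),
                            rule = defaultRuleMap(), seed = 1L) {
  stopifnot(n >= 1L)
  dssp <- withSeed(deriveSeed(seed, "sampling"), sampleDssp(grammar, n))
  seqs <- withSeed(deriveSeed(seed, "rule"),
                   vapply(dssp, ruleSequence, character(1), rule = rule,
                          USE.NAMES = FALSE))
  records <- .asRecords(data.frame(
    id = sprintf("syn%04d", seq_len(n)), sequence = seqs, dssp = dssp,
    stringsAsFactors = FALSE))
  list(records = records,
       examples = makeTrainingExamples(records),
       manifest = list(n = as.integer(n), seed = as.integer(seed),
                       grammar = grammar[c("min_len", "max_len")],
                       noise_level = rule$noise_level,
                       modal = as.list(rule$modal)))
}
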