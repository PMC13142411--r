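# End-to-end rule-recovery benchmark: the package's core self-test. A
# noiseless DSSP-state -> residue rule whose modal residues lie inside a
# 6-member alphabet is generated, a reduced model (~50K parameters) is
# trained for a few epochs, and greedy designs under that alphabet are
# scored against the modal rule sequences on held-out targets.

#' Reduced model configuration for the recovery benchmark
#'
#' A scaled-down architecture (~50K trainable parameters: 16+8 embeddings,
#' three bidirectional LSTM layers of 24 hidden features, 8-head attention,
#' decoder 48 -> 24 -> 12) that trains in about a minute on one CPU.
#' @export
recoveryModelConfig <- function() {
  modelConfig(dssp_embed_dim = 16L, type_embed_dim = 8L, lstm_hidden = 24L,
              lstm_layers = 3L, attention_heads = 8L,
              decoder_dims = c(24L, 12L), dropout_rate = 0.1)
}

#' The 6-member alphabet and noiseless rule used by the recovery benchmark
#'
#' The rule maps each of the 9 DSSP states deterministically to a residue of
#' the alphabet `AGLPSV` (helix states to L/A, sheet states to V, coil
#' states to G/S/P), so the modal sequence of any target is decodable within
#' the alphabet.
#' @return List with `alphabet` ([Alphabet-class]) and `rule` (rule map).
#' @export
recoveryRule <- function() {
  probs <- matrix(0, 9, 20, dimnames = list(DSSP_STATES, CANONICAL_RESIDUES))
  modal <- c(H = "L", G = "A", I = "A", E = "V", B = "V",
             T = "G", S = "S", P = "P", C = "G")
  for (st in names(modal)) probs[st, modal[st]] <- 1
  list(alphabet = Alphabet("AGLPSV", method = "recovery"),
       rule = ruleMap(probs, noise_level = 0))
}

#' Grammar for the recovery benchmark
#'
#' Short sequences (10-60 residues) with uniform within-class state weights
#' so every one of the 9 states is well represented in a few hundred
#' examples.
#' @export
recoveryGrammar <- function() {
  grammarConfig(min_len = 10L, max_len = 60L,
                state_weights = list(
                  helix = c(H = 1/3, G = 1/3, I = 1/3),
                  sheet = c(E = 0.5, B = 0.5),
                  coil = c(T = 0.25, S = 0.25, P = 0.25, C = 0.25)))
}

#' Run the rule-recovery benchmark for one seed
#'
#' Generates `n_examples` noiseless training examples, trains the reduced
#' model for `epochs` epochs with the standard recipe, designs sequences for
#' `n_heldout` freshly sampled targets under the 6-member alphabet, and
#' returns the mean percent identity against the modal rule sequences.
#'
#' @param seed Integer seed controlling every random stream of the run.
#' @param n_examples Training-set size before the 70/20/10 split.
#' @param epochs Training epochs.
#' @param n_heldout Held-out targets to score.
#' @return List with `mean_pid`, `pids`, `history`, and the trained `model`.
#' @export
recoveryBenchmark <- function(seed, n_examples = 320L, epochs = 10L,
                              n_heldout = 10L) {
  setup <- recoveryRule()
  grammar <- recoveryGrammar()
  ds <- generateDataset(n_examples, grammar, setup$rule, seed = seed)
  split <- splitDataset(ds$examples, seed = seed)
  model <- buildModel(recoveryModelConfig(), seed = seed)
  fit <- trainModel(model, split,
                    trainingConfig(epochs = epochs, batch_size = 8L,
                                   seed = seed))
  held <- withSeed(deriveSeed(seed, "heldout"), sampleDssp(grammar, n_heldout))
  pids <- vapply(held, function(d) {
    des <- designSequence(fit$model, d, setup$alphabet)
    percentIdentitySeq(designedSequence(des), modalSequence(d, setup$rule))
  }, numeric(1), USE.NAMES = FALSE)
  list(mean_pid = mean(pids), pids = pids, history = fit$history,
       model = fit$model)
}

#' Percent identity between two equal-length residue strings
#'
#' The amino-acid analogue of the positionwise branch of
#' [percentIdentity()].
#'
#' @param a,b Equal-length amino acid strings.
#' @return Percentage in [0, 100].
#' @export
percentIdentitySeq <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  if (length(ca) == 0L) stop("empty sequence")
  100 * mean(ca == cb)
}
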