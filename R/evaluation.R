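# Accuracy and complexity metrics for DSSP strings: percent identity,
# the three normalized complexity components (Shannon entropy over the 9
# states, transition frequency, Simpson diversity) and their equally
# weighted composite, tertile complexity binning, and grouped summaries.

.dsspChars <- function(states) {
  chars <- .normalizeDssp(states)
  if (length(chars) == 0L) stop("empty DSSP string")
  bad <- which(!chars %in% DSSP_STATES)
  if (length(bad) > 0L)
    stop(sprintf("invalid DSSP state '%s' at position %d", chars[bad[1]],
                 bad[1]))
  chars
}

#' Percent identity between two DSSP strings
#'
#' Equal lengths: 100 x (matching positions / length). Unequal lengths:
#' end-to-end global alignment (match +1, mismatch 0, gap -1) via
#' `Biostrings::pairwiseAlignment`, with PID = 100 x matches / alignment
#' length.
#'
#' @param predicted,target Valid 9-state DSSP strings (non-empty).
#' @return Percentage in [0, 100].
#' @export
percentIdentity <- function(predicted, target) {
  p <- .dsspChars(predicted)
  t_ <- .dsspChars(target)
  if (length(p) == length(t_))
    return(100 * mean(p == t_))
  sub <- matrix(0L, 9, 9, dimnames = list(DSSP_STATES, DSSP_STATES))
  diag(sub) <- 1L
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(p, collapse = "")),
    Biostrings::AAString(paste(t_, collapse = "")),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 1,
    type = "global")
  alignment_length <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / alignment_length
}

#' Normalized Shannon-entropy component
#'
#' Entropy of the observed 9-state frequencies divided by ln(9), the maximum
#' for 9 states.
#'
#' @param dssp A valid non-empty DSSP string.
#' @return Value in [0, 1].
#' @export
shannonComponent <- function(dssp) {
  p <- table(.dsspChars(dssp))
  p <- p / sum(p)
  h <- -sum(p * log(p))
  min(h / log(9), 1)
}

#' Normalized transition-frequency component
#'
#' Fraction of adjacent position pairs whose state differs, over the 9-state
#' tokens by default (`use_types = TRUE` counts 3-class changes instead).
#' Length-1 strings score 0 by convention.
#'
#' @param dssp A valid non-empty DSSP string.
#' @param use_types Count transitions on the collapsed helix/sheet/coil
#'   track.
#' @return Value in [0, 1].
#' @export
transitionComponent <- function(dssp, use_types = FALSE) {
  chars <- .dsspChars(dssp)
  if (use_types)
    chars <- c("h", "s", "c")[typeIdsOf(match(chars, DSSP_STATES) - 1L) + 1L]
  n <- length(chars)
  if (n < 2L) return(0)
  sum(chars[-1] != chars[-n]) / (n - 1)
}

#' Simpson-diversity component
#'
#' `1 - sum(p^2)` over the observed 9-state frequencies.
#'
#' @param dssp A valid non-empty DSSP string.
#' @return Value in [0, 1].
#' @export
simpsonComponent <- function(dssp) {
  p <- table(.dsspChars(dssp))
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Composite complexity score of a DSSP string
#'
#' The equally weighted mean of the Shannon, transition, and Simpson
#' components, each normalized to [0, 1].
#'
#' @param dssp A valid non-empty DSSP string.
#' @param use_types Passed to [transitionComponent()].
#' @return List with `shannon`, `transition`, `simpson`, `composite`.
#' @export
compositeComplexity <- function(dssp, use_types = FALSE) {
  s <- shannonComponent(dssp)
  t_ <- transitionComponent(dssp, use_types = use_types)
  d <- simpsonComponent(dssp)
  list(shannon = s, transition = t_, simpson = d,
       composite = (s + t_ + d) / 3)
}

#' Tertile complexity classes
#'
#' Assigns `low`/`medium`/`high` labels by the 1/3 and 2/3 empirical
#' quantile boundaries, with ties resolved by stable rank so class sizes
#' differ by at most the tie-group size. Labels are invariant under any
#' order-preserving transform of the scores. An all-identical score vector
#' collapses to `low` with a warning.
#'
#' @param scores Numeric vector of at least 3 complexity scores.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
complexityBins <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("at least 3 scores are required for tertile binning")
  lev <- c("low", "medium", "high")
  if (length(unique(scores)) == 1L) {
    warning("all complexity scores identical: assigning every score to 'low'")
    return(factor(rep("low", n), levels = lev))
  }
  r <- rank(scores, ties.method = "first")
  lab <- ifelse(r <= n / 3, "low", ifelse(r <= 2 * n / 3, "medium", "high"))
  factor(lab, levels = lev)
}

#' Evaluate designs against their targets
#'
#' Computes PID of each externally predicted DSSP string against its target
#' DSSP string, the target's complexity components, and tertile complexity
#' classes over the record set.
#'
#' @param report Data frame with columns `target_id`, `alphabet_id`,
#'   `alphabet_size`, `target_dssp`.
#' @param predicted_dssp Character vector of predicted DSSP strings, one per
#'   report row.
#' @return Data frame of evaluation records (`pid`, `shannon`, `transition`,
#'   `simpson`, `composite`, `complexity_class`, plus the report keys).
#' @export
evaluateDesigns <- function(report, predicted_dssp) {
  stopifnot(nrow(report) == length(predicted_dssp), nrow(report) > 0L)
  pid <- mapply(percentIdentity, predicted_dssp, report$target_dssp,
                USE.NAMES = FALSE)
  comp <- lapply(report$target_dssp, compositeComplexity)
  out <- data.frame(
    target_id = report$target_id, alphabet_id = report$alphabet_id,
    alphabet_size = report$alphabet_size, pid = pid,
    shannon = vapply(comp, `[[`, numeric(1), "shannon"),
    transition = vapply(comp, `[[`, numeric(1), "transition"),
    simpson = vapply(comp, `[[`, numeric(1), "simpson"),
    composite = vapply(comp, `[[`, numeric(1), "composite"),
    stringsAsFactors = FALSE)
  out$complexity_class <- if (nrow(out) >= 3L) complexityBins(out$composite)
                          else factor(rep(NA, nrow(out)),
                                      levels = c("low", "medium", "high"))
  out
}

#' Grouped summaries of evaluation records
#'
#' @param records Data frame from [evaluateDesigns()] (needs `pid`,
#'   `alphabet_size`, `complexity_class`).
#' @return List of two data frames: `by_size` and `by_complexity`, each with
#'   `n`, `mean_pid`, `max_pid`.
#' @export
summarizeEvaluations <- function(records) {
  if (nrow(records) == 0L) stop("no evaluation records to summarize")
  grp <- function(key) {
    split_pid <- split(records$pid, records[[key]], drop = TRUE)
    data.frame(group = names(split_pid),
               n = vapply(split_pid, length, integer(1)),
               mean_pid = vapply(split_pid, mean, numeric(1)),
               max_pid = vapply(split_pid, max, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(by_size = grp("alphabet_size"), by_complexity = grp("complexity_class"))
}

#' Write evaluation records to JSONL
#' @param records Data frame from [evaluateDesigns()].
#' @param path Output path.
#' @export
writeEvalRecords <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    r <- as.list(records[i, ])
    r$complexity_class <- as.character(r$complexity_class)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
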