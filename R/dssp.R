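#' The 9 DSSP content states, in token order
#'
#' H (alpha-helix), G (3-10 helix), I (pi-helix), E (beta-strand), B (bridge),
#' T (turn), S (bend), P (polyproline II), C (coil). Token ids are 0-based in
#' this order; the padding id ([DSSP_PAD_ID]) sits outside the 9-state
#' vocabulary.
#' @export
DSSP_STATES <- c("H", "G", "I", "E", "B", "T", "S", "P", "C")

#' Padding token id for DSSP tracks (outside the 9-state vocabulary)
#' @export
DSSP_PAD_ID <- 9L

#' The 3 secondary-structure type classes, in token order
#' @export
TYPE_CLASSES <- c("helix", "sheet", "coil")

#' Padding token id for the type track
#' @export
TYPE_PAD_ID <- 3L

# mkdssp-style synonyms mapped onto coil
.DSSP_SYNONYMS <- c("-" = "C", " " = "C", "~" = "C")

.normalizeDssp <- function(states) {
  chars <- strsplit(states, "", fixed = TRUE)[[1]]
  syn <- match(chars, names(.DSSP_SYNONYMS))
  chars[!is.na(syn)] <- .DSSP_SYNONYMS[syn[!is.na(syn)]]
  chars
}

#' Tokenize a DSSP string into 0-based integer ids
#'
#' The vocabulary has exactly 9 content states (see [DSSP_STATES]); the
#' characters `-`, space, and `~` are accepted as coil synonyms. Padding is
#' handled separately via [DSSP_PAD_ID].
#'
#' @param states A DSSP string.
#' @return Integer vector of ids in 0..8.
#' @export
tokenizeDssp <- function(states) {
  stopifnot(is.character(states), length(states) == 1L)
  chars <- .normalizeDssp(states)
  ids <- match(chars, DSSP_STATES) - 1L
  bad <- which(is.na(ids))
  if (length(bad) > 0L)
    stop(sprintf("invalid DSSP state '%s' at position %d",
                 chars[bad[1]], bad[1]))
  ids
}

#' Inverse of [tokenizeDssp()]
#'
#' @param ids Integer vector of token ids in 0..8.
#' @return A DSSP string.
#' @export
detokenizeDssp <- function(ids) {
  if (length(ids) == 0L) return("")
  if (any(ids < 0L | ids > 8L)) stop("token id outside the 9-state vocabulary")
  paste(DSSP_STATES[ids + 1L], collapse = "")
}

#' Collapse a 9-state DSSP string to the 3-class type track
#'
#' Positionwise map: helix = \{H, G, I\}, sheet = \{E, B\},
#' coil = \{T, S, P, C\}.
#'
#' @param states A DSSP string.
#' @return A string over `h`/`s`/`c` (one character per class, same length).
#' @export
typeTrackOf <- function(states) {
  ids <- tokenizeDssp(states)
  if (length(ids) == 0L) return("")
  paste(c("h", "s", "c")[typeIdsOf(ids) + 1L], collapse = "")
}

# 0-based 3-class ids from 0-based 9-state ids: helix=0, sheet=1, coil=2
typeIdsOf <- function(dssp_ids) {
  map <- c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L)  # H G I E B T S P C
  map[dssp_ids + 1L]
}

#' Validate a DSSP string
#'
#' @param states Candidate string.
#' @return `TRUE` invisibly, or an error naming the first offending position.
#' @export
validateDssp <- function(states) {
  tokenizeDssp(states)
  invisible(TRUE)
}
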