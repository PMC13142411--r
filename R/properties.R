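#' @importFrom methods new validObject is setClass setGeneric setMethod show
#' @importFrom stats quantile rnorm runif sd setNames rgeom
#' @importFrom utils head read.csv write.csv modifyList
NULL

#' The 20 canonical amino acid one-letter codes, alphabetical
#' @export
CANONICAL_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Per-residue physicochemical descriptors at pH 7.0: van der Waals volume
# (A^3), octanol/water logD, and formal charge. Values are fixed package
# constants (computed originally with ChemAxon JChem); they are looked up,
# never recomputed.
.RESIDUE_PROPERTIES <- data.frame(
  residue = CANONICAL_RESIDUES,
  vdw_volume = c(86.4, 104.9, 118.6, 135.9, 159.0, 69.1, 131.7, 138.3, 149.3,
                 138.3, 139.5, 120.8, 108.6, 138.1, 168.6, 95.2, 112.5, 121.0,
                 178.7, 167.8),
  logd = c(-1.34, -1.29, -1.98, 1.70, 0.31, -1.91, -2.11, -0.01, -1.48,
           -0.09, -0.69, -2.79, -1.07, -2.50, -2.54, -2.39, -1.97, -0.46,
           0.41, 0.01),
  formal_charge = c(0L, 0L, -1L, -1L, 0L, 0L, 0L, 0L, 1L,
                    0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
  stringsAsFactors = FALSE
)
rownames(.RESIDUE_PROPERTIES) <- .RESIDUE_PROPERTIES$residue

#' Residue physicochemical property table
#'
#' Returns the full 20-row table of per-residue descriptors used as
#' regression targets by the model: van der Waals volume (\eqn{\text{\AA}^3}),
#' logD at pH 7.0, and formal charge at pH 7.0.
#'
#' @return A data.frame with columns `residue`, `vdw_volume`, `logd`,
#'   `formal_charge`, one row per canonical residue.
#' @export
residuePropertyTable <- function() {
  df <- .RESIDUE_PROPERTIES
  rownames(df) <- NULL
  df
}

#' Look up the property triple for one residue
#'
#' @param residue A single canonical one-letter residue code.
#' @return A list with elements `residue`, `vdw_volume`, `logd`,
#'   `formal_charge`.
#' @examples
#' lookupProperties("G")  # 69.1 A^3, logD -1.91, charge 0
#' @export
lookupProperties <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L)
    stop("`residue` must be a single one-letter code")
  if (!residue %in% CANONICAL_RESIDUES)
    stop(sprintf("unknown residue code '%s': not one of the 20 canonical residues",
                 residue))
  row <- .RESIDUE_PROPERTIES[residue, ]
  list(residue = row$residue, vdw_volume = row$vdw_volume,
       logd = row$logd, formal_charge = row$formal_charge)
}

#' Per-position property profile of an amino acid sequence
#'
#' Maps each residue of `sequence` to its (volume, logD, charge) triple.
#'
#' @param sequence Amino acid string over the canonical 20-letter alphabet.
#' @return A numeric matrix with `nchar(sequence)` rows and columns
#'   `vdw_volume`, `logd`, `formal_charge` (zero rows for the empty string).
#' @export
propertyProfile <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% CANONICAL_RESIDUES)
  if (length(bad) > 0L)
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad[1]],
                 bad[1]))
  m <- as.matrix(.RESIDUE_PROPERTIES[chars,
                                     c("vdw_volume", "logd", "formal_charge"),
                                     drop = FALSE])
  if (length(chars) == 0L)
    m <- matrix(numeric(0), nrow = 0L, ncol = 3L,
                dimnames = list(NULL, c("vdw_volume", "logd", "formal_charge")))
  rownames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write the property table to CSV
#'
#' @param path Output file path.
#' @export
writePropertyTable <- function(path) {
  write.csv(residuePropertyTable(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
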