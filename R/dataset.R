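# Dataset assembly: curation of (sequence, DSSP) records, training-example
# construction with property targets, reproducible splits, padded batches.
# Records travel as a plain data.frame with columns id, sequence, dssp and
# optional cluster_id, cluster_size, representative.

.emptyRecords <- function() {
  data.frame(id = character(0), sequence = character(0), dssp = character(0),
             cluster_id = character(0), cluster_size = integer(0),
             representative = logical(0), stringsAsFactors = FALSE)
}

.asRecords <- function(df) {
  stopifnot(all(c("id", "sequence", "dssp") %in% names(df)))
  if (!"cluster_id" %in% names(df)) df$cluster_id <- NA_character_
  if (!"cluster_size" %in% names(df)) df$cluster_size <- NA_integer_
  if (!"representative" %in% names(df)) df$representative <- NA
  df$id <- as.character(df$id)
  df$cluster_size <- as.integer(df$cluster_size)
  df$representative <- as.logical(df$representative)
  rownames(df) <- NULL
  df[, c("id", "sequence", "dssp", "cluster_id", "cluster_size",
         "representative")]
}

#' Read (sequence, DSSP) records from JSONL or TSV
#'
#' JSONL: one object per line with fields `id`, `sequence`, `dssp` and
#' optional `cluster_id`, `cluster_size`, `representative`. TSV: the same
#' columns with a header.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"jsonl"`, or `"tsv"`.
#' @return A records data.frame.
#' @export
readDsspRecords <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(rows, function(r) {
      data.frame(id = r$id, sequence = r$sequence, dssp = r$dssp,
                 cluster_id = if (is.null(r$cluster_id)) NA_character_ else r$cluster_id,
                 cluster_size = if (is.null(r$cluster_size)) NA_integer_ else r$cluster_size,
                 representative = if (is.null(r$representative)) NA else r$representative,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- .emptyRecords()
  }
  .asRecords(df)
}

#' Write records to JSONL
#'
#' @param records A records data.frame.
#' @param path Output path.
#' @export
writeDsspRecords <- function(records, path) {
  records <- .asRecords(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    r <- as.list(records[i, ])
    r <- r[!vapply(r, function(x) is.na(x), logical(1))]
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read sequences from FASTA plus a parallel DSSP text file
#'
#' The DSSP file holds one line per FASTA record, in the same order.
#'
#' @param fasta_path FASTA file of amino acid sequences.
#' @param dssp_path Plain-text file of DSSP strings, one per line.
#' @return A records data.frame.
#' @export
readFastaWithDssp <- function(fasta_path, dssp_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  dssp <- readLines(dssp_path, warn = FALSE)
  dssp <- dssp[nzchar(trimws(dssp))]
  if (length(aa) != length(dssp))
    stop(sprintf("FASTA has %d records but DSSP file has %d lines",
                 length(aa), length(dssp)))
  .asRecords(data.frame(id = sub("\\s.*$", "", names(aa)),
                        sequence = as.character(aa), dssp = trimws(dssp),
                        stringsAsFactors = FALSE))
}

#' Curate records with the length, cluster, and canonical-residue filters
#'
#' Keeps records whose length is within `[min_len, max_len]`; when cluster
#' annotations are present, keeps only the designated representatives of
#' clusters with at least `min_cluster` members; drops records with
#' non-canonical residues or a sequence/DSSP length mismatch (counts are
#' reported via `message()`).
#'
#' @param records A records data.frame.
#' @param min_len,max_len Length bounds (defaults 10 and 300).
#' @param min_cluster Minimum cluster size (default 10).
#' @return The curated records data.frame (possibly empty).
#' @export
curateRecords <- function(records, min_len = 10L, max_len = 300L,
                          min_cluster = 10L) {
  records <- .asRecords(records)
  n0 <- nrow(records)
  len <- nchar(records$sequence)
  mismatch <- len != nchar(records$dssp)
  noncanon <- !grepl(sprintf("^[%s]*$", paste(CANONICAL_RESIDUES, collapse = "")),
                     records$sequence)
  drop_bad <- mismatch | noncanon
  if (any(drop_bad))
    message(sprintf("curate: dropping %d record(s) with non-canonical residues or track length mismatch",
                    sum(drop_bad)))
  records <- records[!drop_bad, , drop = FALSE]
  len <- nchar(records$sequence)
  records <- records[len >= min_len & len <= max_len, , drop = FALSE]
  has_cluster <- !is.na(records$cluster_size) & !is.na(records$representative)
  keep <- !has_cluster |
    (records$representative %in% TRUE & records$cluster_size >= min_cluster)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) message("curate: no records survived curation")
  rownames(records) <- NULL
  records
}

#' Build training examples from curated records
#'
#' Each example carries the tokenized DSSP track, the derived 3-class type
#' track, 0-based residue labels over the alphabetically ordered 20-residue
#' vocabulary, and the raw per-position property triples from the residue
#' property table. Standardization (z-scoring) is applied later, from
#' training-split statistics, via [standardizeExamples()].
#'
#' @param records Curated records data.frame.
#' @return A list of examples, each a list with `id`, `dssp`, `dssp_ids`,
#'   `type_ids`, `residue_ids`, `property_raw` (L x 3 matrix).
#' @export
makeTrainingExamples <- function(records) {
  records <- .asRecords(records)
  lapply(seq_len(nrow(records)), function(i) {
    dssp_ids <- tokenizeDssp(records$dssp[i])
    chars <- strsplit(records$sequence[i], "", fixed = TRUE)[[1]]
    list(id = records$id[i],
         dssp = records$dssp[i],
         sequence = records$sequence[i],
         dssp_ids = dssp_ids,
         type_ids = typeIdsOf(dssp_ids),
         residue_ids = match(chars, CANONICAL_RESIDUES) - 1L,
         property_raw = propertyProfile(records$sequence[i]))
  })
}

#' Compute a per-property standardizer (mean/sd) over a set of examples
#'
#' @param examples List of examples (typically the training split).
#' @return List with numeric `mean` and `sd` of length 3.
#' @export
computeStandardizer <- function(examples) {
  stopifnot(length(examples) > 0L)
  all_props <- do.call(rbind, lapply(examples, `[[`, "property_raw"))
  mu <- colMeans(all_props)
  sdev <- apply(all_props, 2, sd)
  sdev[sdev == 0] <- 1
  list(mean = as.numeric(mu), sd = as.numeric(sdev))
}

#' Apply a standardizer, attaching z-scored `property_targets`
#'
#' @param examples List of examples.
#' @param standardizer From [computeStandardizer()].
#' @return The examples with an added `property_targets` matrix each.
#' @export
standardizeExamples <- function(examples, standardizer) {
  lapply(examples, function(ex) {
    ex$property_targets <- sweep(sweep(ex$property_raw, 2, standardizer$mean),
                                 2, standardizer$sd, "/")
    ex
  })
}

#' Random 70/20/10 split of a dataset
#'
#' Counts use a floor-then-remainder rule: each split gets
#' `floor(fraction * n)` examples and any remainder goes to the training
#' split, so the split is exhaustive and deterministic.
#'
#' @param examples List of examples.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test`, `seed`, and `manifest`
#'   (ids per split).
#' @export
splitDataset <- function(examples, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  n <- length(examples)
  counts <- floor(fractions * n)
  counts[1] <- counts[1] + (n - sum(counts))
  perm <- withSeed(deriveSeed(seed, "split"), sample.int(n))
  idx <- list(train = perm[seq_len(counts[1])],
              validation = perm[counts[1] + seq_len(counts[2])],
              test = perm[counts[1] + counts[2] + seq_len(counts[3])])
  ids <- function(i) vapply(examples[i], `[[`, character(1), "id")
  list(train = examples[idx$train], validation = examples[idx$validation],
       test = examples[idx$test], seed = as.integer(seed),
       manifest = list(seed = as.integer(seed), fractions = fractions,
                       train = ids(idx$train), validation = ids(idx$validation),
                       test = ids(idx$test)))
}

#' Write a split manifest (ids per split + seed) as JSON
#' @param split Result of [splitDataset()].
#' @param path Output path.
#' @export
writeSplitManifest <- function(split, path) {
  jsonlite::write_json(split$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble padded batches from a list of examples
#'
#' Each batch is padded to its own maximum length with the out-of-vocabulary
#' padding ids; `mask` marks real positions. Every example appears exactly
#' once per epoch.
#'
#' @param examples List of standardized examples.
#' @param batch_size Batch size (default 8).
#' @param shuffle_seed Optional seed; `NULL` keeps input order.
#' @return List of batches; each has `dssp` (B x L integer, pad
#'   [DSSP_PAD_ID]), `type` (pad [TYPE_PAD_ID]), `labels` (pad -1), `props`
#'   (B x L x 3), `mask` (B x L logical), `ids`, `lengths`.
#' @export
makeBatches <- function(examples, batch_size = 8L, shuffle_seed = NULL) {
  stopifnot(batch_size >= 1L)
  n <- length(examples)
  ord <- seq_len(n)
  if (!is.null(shuffle_seed))
    ord <- withSeed(as.integer(shuffle_seed), sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    ex <- examples[ord[s:min(s + batch_size - 1L, n)]]
    B <- length(ex)
    lens <- vapply(ex, function(e) length(e$dssp_ids), integer(1))
    L <- max(lens)
    dssp <- matrix(DSSP_PAD_ID, B, L)
    type <- matrix(TYPE_PAD_ID, B, L)
    labels <- matrix(-1L, B, L)
    props <- array(0, dim = c(B, L, 3))
    mask <- matrix(FALSE, B, L)
    for (b in seq_len(B)) {
      l <- lens[b]
      dssp[b, seq_len(l)] <- ex[[b]]$dssp_ids
      type[b, seq_len(l)] <- ex[[b]]$type_ids
      if (!is.null(ex[[b]]$residue_ids))
        labels[b, seq_len(l)] <- ex[[b]]$residue_ids
      tgt <- if (!is.null(ex[[b]]$property_targets)) ex[[b]]$property_targets
             else ex[[b]]$property_raw
      if (!is.null(tgt)) props[b, seq_len(l), ] <- tgt
      mask[b, seq_len(l)] <- TRUE
    }
    list(dssp = dssp, type = type, labels = labels, props = props,
         mask = mask, ids = vapply(ex, `[[`, character(1), "id"),
         lengths = lens)
  })
}
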