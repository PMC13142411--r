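mkRecords <- function(seqs, dssp = NULL, ...) {
  if (is.null(dssp))
    dssp <- vapply(nchar(seqs), function(n)
      paste(rep("H", n), collapse = ""), character(1))
  data.frame(id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
             dssp = dssp, ..., stringsAsFactors = FALSE)
}

test_that("curation applies the length window [10, 300]", {
  seqs <- vapply(c(5, 10, 300, 301), function(n)
    paste(rep("A", n), collapse = ""), character(1))
  out <- curateRecords(mkRecords(seqs))
  expect_equal(sort(nchar(out$sequence)), c(10L, 300L))
})

test_that("cluster filtering keeps representatives of clusters >= 10 members", {
  seqs <- rep(paste(rep("A", 20), collapse = ""), 4)
  rec <- mkRecords(seqs,
                   cluster_id = c("c1", "c2", "c3", "c3"),
                   cluster_size = c(9L, 12L, 12L, 12L),
                   representative = c(TRUE, FALSE, TRUE, FALSE))
  out <- curateRecords(rec)
  expect_identical(out$id, "r3")  # 9-member rep and non-reps all dropped
})

test_that("records with non-canonical residues are dropped with a count", {
  rec <- mkRecords(c(paste(rep("A", 12), collapse = ""),
                     paste(c(rep("A", 11), "X"), collapse = "")))
  expect_message(out <- curateRecords(rec), "1 record")
  expect_equal(nrow(out), 1L)
})

test_that("curation is idempotent", {
  withr::with_seed(5, {
    ds <- generateDataset(20, grammarConfig(min_len = 10, max_len = 40),
                          defaultRuleMap(0.2), seed = 5)
    once <- curateRecords(ds$records)
    twice <- curateRecords(once)
    expect_identical(once, twice)
  })
})

test_that("training examples carry labels and raw property targets from the table", {
  ex <- makeTrainingExamples(mkRecords("AG", dssp = "HC"))[[1]]
  expect_identical(ex$residue_ids,
                   c(match("A", CANONICAL_RESIDUES), match("G", CANONICAL_RESIDUES)) - 1L)
  expect_equal(unname(ex$property_raw[1, ]), c(86.4, -1.34, 0))
  expect_equal(unname(ex$property_raw[2, ]), c(69.1, -1.91, 0))
  expect_identical(ex$type_ids, c(0L, 2L))
})

test_that("standardized targets have mean 0 and sd 1 per property", {
  ds <- generateDataset(30, grammarConfig(min_len = 10, max_len = 30),
                        defaultRuleMap(0.3), seed = 9)
  std <- computeStandardizer(ds$examples)
  ex <- standardizeExamples(ds$examples, std)
  all_t <- do.call(rbind, lapply(ex, `[[`, "property_targets"))
  expect_equal(unname(colMeans(all_t)), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(all_t, 2, sd)), c(1, 1, 1), tolerance = 1e-10)
  # raw targets correspond to the labelled residue via the property table
  e1 <- ds$examples[[1]]
  expect_equal(e1$property_raw,
               propertyProfile(paste(CANONICAL_RESIDUES[e1$residue_ids + 1L],
                                     collapse = "")))
})

test_that("splits are exact, disjoint, exhaustive, and seeded", {
  mkEx <- function(n) lapply(seq_len(n), function(i)
    list(id = sprintf("e%d", i), dssp_ids = c(0L, 3L)))
  s100 <- splitDataset(mkEx(100), seed = 3)
  expect_equal(lengths(s100[c("train", "validation", "test")]),
               c(train = 70L, validation = 20L, test = 10L))
  s101 <- splitDataset(mkEx(101), seed = 3)
  expect_equal(lengths(s101[c("train", "validation", "test")]),
               c(train = 71L, validation = 20L, test = 10L))
  ids <- function(s) unlist(lapply(s[c("train", "validation", "test")],
                                   vapply, `[[`, character(1), "id"))
  expect_setequal(ids(s101), sprintf("e%d", 1:101))
  expect_equal(length(ids(s101)), 101L)  # pairwise disjoint + exhaustive
  again <- splitDataset(mkEx(101), seed = 3)
  expect_identical(again$manifest$train, s101$manifest$train)
  other <- splitDataset(mkEx(101), seed = 4)
  expect_false(identical(other$manifest$train, s101$manifest$train))
  expect_error(splitDataset(mkEx(10), fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  # manifest JSON round-trips the membership and seed
  path <- withr::local_tempfile(fileext = ".json")
  writeSplitManifest(s101, path)
  mf <- jsonlite::fromJSON(path)
  expect_equal(mf$seed, 3L)
  expect_identical(mf$train, s101$manifest$train)
})

test_that("batches pad to their own max length and conserve every example", {
  ds <- generateDataset(20, grammarConfig(min_len = 10, max_len = 25),
                        defaultRuleMap(), seed = 11)
  std <- standardizeExamples(ds$examples, computeStandardizer(ds$examples))
  batches <- makeBatches(std, batch_size = 8L, shuffle_seed = 2L)
  expect_equal(vapply(batches, function(b) nrow(b$dssp), integer(1)),
               c(8L, 8L, 4L))
  total_residues <- sum(vapply(std, function(e) length(e$dssp_ids), integer(1)))
  expect_equal(sum(vapply(batches, function(b) sum(b$mask), numeric(1))),
               total_residues)
  # concatenated unpadded examples are a permutation of the dataset
  seen <- unlist(lapply(batches, function(b) b$ids))
  expect_setequal(seen, vapply(std, `[[`, character(1), "id"))
  # padded cells hold the out-of-vocabulary ids
  b1 <- batches[[1]]
  expect_true(all(b1$dssp[!b1$mask] == DSSP_PAD_ID))
  expect_true(all(b1$type[!b1$mask] == TYPE_PAD_ID))
  expect_true(all(b1$labels[!b1$mask] == -1L))
})

test_that("JSONL and TSV record files round-trip", {
  rec <- mkRecords(c("ACDEFGHIKLMN", "GGGGGGGGGGGG"),
                   dssp = c("HHHHHHHHTTTT", "EEEEEEEEEEEE"))
  rec$cluster_id <- c("c1", NA)
  rec$cluster_size <- c(12L, NA)
  rec$representative <- c(TRUE, NA)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeDsspRecords(rec, path)
  back <- readDsspRecords(path)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$dssp, rec$dssp)
  expect_identical(back$cluster_size, rec$cluster_size)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- readDsspRecords(tsv)
  expect_identical(back2$sequence, rec$sequence)
})

test_that("FASTA plus parallel DSSP text reads into records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1 desc", "ACDEFGHIKL", ">t2", "GGGGGGGGGG"), fa)
  dt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("HHHHHHHHHH", "EEEEEEEEEE"), dt)
  rec <- readFastaWithDssp(fa, dt)
  expect_identical(rec$id, c("t1", "t2"))
  expect_identical(rec$dssp, c("HHHHHHHHHH", "EEEEEEEEEE"))
  writeLines("HHHH", dt)
  expect_error(readFastaWithDssp(fa, dt), "2 records")
})
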