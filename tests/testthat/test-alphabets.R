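test_that("alphabets canonicalize to sorted unique uppercase members", {
  a <- Alphabet("dcaa")
  expect_identical(members(a), c("A", "C", "D"))
  expect_identical(alphabetString(a), "ACD")
  expect_identical(alphabetSize(a), 3L)
  g <- Alphabet("LVIM-AG-ST", method = "grouped", groups = TRUE)
  expect_identical(alphabetString(g), "AGILMSTV")
  expect_error(Alphabet("AXZ"), "non-canonical")
  expect_error(Alphabet(character(0)), "at least one")
})

test_that("library CSV round-trip preserves membership, method, and order", {
  lib <- toyLibrary(list(c("m1", "ACD"), c("m2", "GILV"), c("m1", "AEK")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeAlphabetLibrary(lib, path)
  back <- readAlphabetLibrary(path)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_identical(members(back[[i]]), members(lib[[i]]))
    expect_identical(alphabetMethod(back[[i]]), alphabetMethod(lib[[i]]))
    expect_identical(alphabetId(back[[i]]), alphabetId(lib[[i]]))
  }
})

test_that("duplicate (method, members) pairs are dropped on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("method,alphabet", "m1,ACD", "m1,DCA", "m2,ACD"), path)
  expect_message(lib <- readAlphabetLibrary(path), "duplicate")
  expect_equal(length(lib), 2L)
})

test_that("stratified sampling keeps exactly one alphabet per (size, method) group", {
  lib <- toyLibrary(list(c("m1", "ACD"), c("m1", "ACDEFG"), c("m1", "ACDEFH"),
                         c("m2", "ACDEFG")))
  out <- filterAndSample(lib, min_size = 6L, seed = 7L)
  expect_equal(length(out), 2L)
  got_m1 <- Filter(function(a) alphabetMethod(a) == "m1", alphabets(out))
  expect_length(got_m1, 1L)
  expect_true(alphabetString(got_m1[[1]]) %in% c("ACDEFG", "ACDEFH"))
  expect_equal(alphabetString(Filter(function(a) alphabetMethod(a) == "m2",
                                     alphabets(out))[[1]]), "ACDEFG")
  # same seed -> identical selection
  out2 <- filterAndSample(lib, min_size = 6L, seed = 7L)
  expect_identical(vapply(alphabets(out), alphabetId, character(1)),
                   vapply(alphabets(out2), alphabetId, character(1)))
  # everything filtered -> explicit error
  small <- toyLibrary(list(c("m1", "ACD"), c("m2", "AC")))
  expect_error(filterAndSample(small, min_size = 6L), "no alphabets")
})

test_that("stratified sampling invariants hold on fuzzed libraries", {
  for (seed in 1:5) {
    lib <- randomLibrary(40, seed)
    out <- filterAndSample(lib, min_size = 4L, seed = seed)
    sz <- vapply(alphabets(out), alphabetSize, integer(1))
    mt <- vapply(alphabets(out), alphabetMethod, character(1))
    expect_true(all(sz >= 4L))
    expect_false(anyDuplicated(paste(sz, mt)) > 0)
    # one per surviving group, verified by brute-force enumeration
    all_sz <- vapply(alphabets(lib), alphabetSize, integer(1))
    all_mt <- vapply(alphabets(lib), alphabetMethod, character(1))
    surviving <- unique(paste(all_sz, all_mt)[all_sz >= 4L])
    expect_setequal(paste(sz, mt), surviving)
  }
})

test_that("size statistics use the sample (n-1) standard deviation", {
  lib <- toyLibrary(list(c("m1", "ACDEFG"), c("m1", "ACDEFGHIKL"),
                         c("m1", "ACDEFGHIKLMNPQ")))
  st <- sizeStatistics(lib)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 4)
  expect_equal(st$min, 6L)
  expect_equal(st$max, 14L)
  expect_equal(unname(st$histogram[c("6", "10", "14")]), c(1L, 1L, 1L))
  single <- toyLibrary(list(c("m1", "ACDEFGH")))
  expect_warning(st1 <- sizeStatistics(single), "degenerate")
  expect_equal(st1$mean, 7)
  expect_equal(st1$sd, 0)
  expect_error(sizeStatistics(AlphabetLibrary(list())), "empty")
})

test_that("composition frequencies count the fraction of alphabets with each residue", {
  lib <- toyLibrary(list(c("m1", "AC"), c("m1", "AD")))
  f <- compositionFrequencies(lib)
  expect_equal(unname(f["A"]), 1.0)
  expect_equal(unname(f["C"]), 0.5)
  expect_equal(unname(f["D"]), 0.5)
  expect_true(all(f[setdiff(CANONICAL_RESIDUES, c("A", "C", "D"))] == 0))
  full <- toyLibrary(list(c("m1", paste(CANONICAL_RESIDUES, collapse = ""))))
  expect_true(all(compositionFrequencies(full) == 1.0))
  # letters mode shares out the total member count
  fl <- compositionFrequencies(lib, mode = "letters")
  expect_equal(unname(fl["A"]), 0.5)
  expect_equal(sum(fl), 1.0)
  expect_error(compositionFrequencies(AlphabetLibrary(list())), "empty")
})

test_that("co-occurrence matrix matches brute force and is symmetric", {
  lib <- toyLibrary(list(c("m1", "AC"), c("m1", "AD")))
  m <- cooccurrenceMatrix(lib)
  expect_equal(m["A", "C"], 1L)
  expect_equal(m["A", "D"], 1L)
  expect_equal(m["C", "D"], 0L)
  expect_equal(m["A", "A"], 2L)
  expect_equal(m["C", "C"], 1L)
  single <- toyLibrary(list(c("m1", "ACD")))
  ms <- cooccurrenceMatrix(single)
  expect_true(all(ms[c("A", "C", "D"), c("A", "C", "D")] == 1L))
  for (seed in 1:3) {
    lib <- randomLibrary(15, seed + 100)
    m <- cooccurrenceMatrix(lib)
    expect_identical(m, t(m))
    # diagonal equals membership counts (frequency x library size)
    counts <- compositionFrequencies(lib) * length(lib)
    expect_equal(unname(diag(m)), unname(counts))
    # brute-force pair counts
    memb <- lapply(alphabets(lib), members)
    for (pair in list(c("A", "G"), c("C", "W"), c("K", "R"))) {
      expected <- sum(vapply(memb, function(mm) all(pair %in% mm), logical(1)))
      expect_equal(m[pair[1], pair[2]], expected)
    }
  }
})
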