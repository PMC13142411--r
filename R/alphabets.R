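#' Alphabet: a reduced amino acid alphabet
#'
#' An `Alphabet` is a subset of the 20 canonical residues together with a
#' free-text label for the reduction method that produced it and a stable id.
#' The canonical serialization is the sorted one-letter member string
#' (e.g. `"ACDE"`).
#'
#' @slot members Character vector of one-letter codes, sorted, unique.
#' @slot method Character scalar, reduction-method label.
#' @slot id Character scalar, stable identifier.
#' @export
setClass("Alphabet",
         representation(members = "character", method = "character",
                        id = "character"))

setValidity("Alphabet", function(object) {
  m <- object@members
  if (length(m) < 1L) return("alphabet must have at least one member")
  if (anyDuplicated(m)) return("duplicate members")
  if (!all(m %in% CANONICAL_RESIDUES))
    return(sprintf("non-canonical member(s): %s",
                   paste(setdiff(m, CANONICAL_RESIDUES), collapse = ",")))
  if (is.unsorted(m)) return("members must be sorted")
  if (length(object@method) != 1L || length(object@id) != 1L)
    return("method and id must be scalars")
  TRUE
})

#' Construct an Alphabet
#'
#' @param members Either a single string of one-letter codes (`"ACDE"`,
#'   possibly unsorted, or group notation like `"LVIM-AG"` when
#'   `groups = TRUE`) or a character vector of codes.
#' @param method Reduction-method label.
#' @param id Stable identifier; defaults to `<method>:<canonical string>`.
#' @param groups If `TRUE`, treat `-`/`|`/`,`-separated groups as one member
#'   set by unioning them (Liang-style grouping notation).
#' @return An [Alphabet-class] object.
#' @export
Alphabet <- function(members, method = "unknown", id = NULL, groups = FALSE) {
  if (length(members) == 1L && nchar(members[1]) > 1L) {
    s <- members
    if (groups) s <- gsub("[-|, ]", "", s)
    members <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  }
  members <- sort(unique(toupper(members)))
  if (is.null(id)) id <- paste0(method, ":", paste(members, collapse = ""))
  new("Alphabet", members = members, method = method, id = id)
}

#' @describeIn Alphabet-class member residues
#' @param x,object An `Alphabet`.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname Alphabet-class
#' @export
setMethod("members", "Alphabet", function(x) x@members)

#' @describeIn Alphabet-class number of members
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))
#' @rdname Alphabet-class
#' @export
setMethod("alphabetSize", "Alphabet", function(x) length(x@members))

#' @describeIn Alphabet-class canonical serialization (sorted member string)
#' @export
setGeneric("alphabetString", function(x) standardGeneric("alphabetString"))
#' @rdname Alphabet-class
#' @export
setMethod("alphabetString", "Alphabet",
          function(x) paste(x@members, collapse = ""))

#' @describeIn Alphabet-class reduction-method label
#' @export
setGeneric("alphabetMethod", function(x) standardGeneric("alphabetMethod"))
#' @rdname Alphabet-class
#' @export
setMethod("alphabetMethod", "Alphabet", function(x) x@method)

#' @describeIn Alphabet-class stable identifier
#' @export
setGeneric("alphabetId", function(x) standardGeneric("alphabetId"))
#' @rdname Alphabet-class
#' @export
setMethod("alphabetId", "Alphabet", function(x) x@id)

#' @rdname Alphabet-class
#' @export
setMethod("show", "Alphabet", function(object) {
  cat(sprintf("Alphabet '%s' (method %s): %s [size %d]\n", object@id,
              object@method, alphabetString(object), alphabetSize(object)))
})

#' AlphabetLibrary: an ordered collection of reduced alphabets
#'
#' @slot alphabets List of [Alphabet-class] objects with unique ids,
#'   deduplicated on canonical serialization within a method.
#' @slot provenance Character scalar describing the source.
#' @export
setClass("AlphabetLibrary",
         representation(alphabets = "list", provenance = "character"))

setValidity("AlphabetLibrary", function(object) {
  if (!all(vapply(object@alphabets, is, logical(1), "Alphabet")))
    return("all elements must be Alphabet objects")
  ids <- vapply(object@alphabets, alphabetId, character(1))
  if (anyDuplicated(ids)) return("alphabet ids must be unique")
  key <- paste(vapply(object@alphabets, alphabetMethod, character(1)),
               vapply(object@alphabets, alphabetString, character(1)))
  if (anyDuplicated(key))
    return("duplicate (method, members) pair in library")
  TRUE
})

#' Construct an AlphabetLibrary
#'
#' @param alphabets List of [Alphabet-class] objects.
#' @param provenance Free-text source description.
#' @export
AlphabetLibrary <- function(alphabets, provenance = "in-memory") {
  new("AlphabetLibrary", alphabets = alphabets, provenance = provenance)
}

#' @describeIn AlphabetLibrary-class list of member alphabets
#' @param x,object An `AlphabetLibrary`.
#' @export
setGeneric("alphabets", function(x) standardGeneric("alphabets"))
#' @rdname AlphabetLibrary-class
#' @export
setMethod("alphabets", "AlphabetLibrary", function(x) x@alphabets)

#' @rdname AlphabetLibrary-class
#' @export
setMethod("length", "AlphabetLibrary", function(x) length(x@alphabets))

#' @rdname AlphabetLibrary-class
#' @param i Index.
#' @export
setMethod("[[", "AlphabetLibrary", function(x, i) x@alphabets[[i]])

#' @rdname AlphabetLibrary-class
#' @export
setMethod("show", "AlphabetLibrary", function(object) {
  sz <- vapply(object@alphabets, alphabetSize, integer(1))
  cat(sprintf("AlphabetLibrary with %d alphabets (sizes %s-%s), provenance: %s\n",
              length(object@alphabets),
              if (length(sz)) min(sz) else NA, if (length(sz)) max(sz) else NA,
              object@provenance))
})

#' Read an alphabet library from CSV
#'
#' Expected columns: `method`, `alphabet` (flat one-letter member string),
#' optional `id`. Duplicated (method, members) pairs are dropped with a
#' message.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param groups Passed to [Alphabet()]: union group-notation strings.
#' @return An [AlphabetLibrary-class].
#' @export
readAlphabetLibrary <- function(path, groups = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("method", "alphabet") %in% names(df)))
    stop("alphabet CSV must have columns 'method' and 'alphabet'")
  ids <- if ("id" %in% names(df)) as.character(df$id) else rep(NA_character_,
                                                               nrow(df))
  abc <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    abc[[i]] <- Alphabet(df$alphabet[i], method = df$method[i],
                         id = if (is.na(ids[i])) NULL else ids[i],
                         groups = groups)
  }
  key <- paste(vapply(abc, alphabetMethod, character(1)),
               vapply(abc, alphabetString, character(1)))
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("dropping %d duplicate alphabet(s)", sum(dup)))
    abc <- abc[!dup]
  }
  AlphabetLibrary(abc, provenance = path)
}

#' Write an alphabet library to CSV
#'
#' @param library An [AlphabetLibrary-class].
#' @param path Output CSV path.
#' @export
writeAlphabetLibrary <- function(library, path) {
  df <- data.frame(
    method = vapply(alphabets(library), alphabetMethod, character(1)),
    alphabet = vapply(alphabets(library), alphabetString, character(1)),
    id = vapply(alphabets(library), alphabetId, character(1)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified down-selection of an alphabet library
#'
#' Removes alphabets smaller than `min_size`, groups the survivors by
#' (size, method), and selects one alphabet uniformly at random per group.
#' Group iteration order is lexicographic on (size, method) so the selection
#' is platform-stable for a given seed.
#'
#' @param library An [AlphabetLibrary-class].
#' @param min_size Minimum retained alphabet size (default 6, i.e. drop
#'   size 5 and smaller).
#' @param seed Integer seed for the selection.
#' @return A filtered [AlphabetLibrary-class] with one alphabet per
#'   (size, method) group.
#' @export
filterAndSample <- function(library, min_size = 6L, seed = 1L) {
  stopifnot(min_size >= 1L)
  abc <- alphabets(library)
  sz <- vapply(abc, alphabetSize, integer(1))
  abc <- abc[sz >= min_size]
  if (length(abc) == 0L)
    stop(sprintf("no alphabets of size >= %d in library", min_size))
  sz <- vapply(abc, alphabetSize, integer(1))
  mt <- vapply(abc, alphabetMethod, character(1))
  key <- sprintf("%03d|%s", sz, mt)
  groups <- split(seq_along(abc), key)
  groups <- groups[order(names(groups))]
  picked <- integer(length(groups))
  withSeed(seed, {
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      picked[g] <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }
  })
  AlphabetLibrary(abc[sort(picked)],
                  provenance = sprintf("%s [filtered min_size=%d seed=%d]",
                                       library@provenance, min_size, seed))
}

#' Alphabet-size statistics of a library
#'
#' @param library An [AlphabetLibrary-class].
#' @return A list with `mean`, `sd` (sample, n-1 denominator; 0 with a
#'   warning for a single alphabet), `min`, `max`, and `histogram` (named
#'   integer vector keyed by size).
#' @export
sizeStatistics <- function(library) {
  if (length(library) == 0L) stop("empty alphabet library")
  sz <- vapply(alphabets(library), alphabetSize, integer(1))
  s <- if (length(sz) == 1L) {
    warning("single-alphabet library: standard deviation is degenerate, reporting 0")
    0
  } else sd(sz)
  h <- table(factor(sz, levels = seq(min(sz), max(sz))))
  list(mean = mean(sz), sd = s, min = min(sz), max = max(sz),
       histogram = setNames(as.integer(h), names(h)))
}

#' Per-residue composition frequencies of a library
#'
#' For each of the 20 residues, the fraction of alphabets that contain it
#' (`mode = "membership"`, default) or its share of all member letters
#' (`mode = "letters"`).
#'
#' @param library An [AlphabetLibrary-class].
#' @param mode `"membership"` or `"letters"`.
#' @return Named numeric vector of length 20, values in [0, 1].
#' @export
compositionFrequencies <- function(library,
                                   mode = c("membership", "letters")) {
  mode <- match.arg(mode)
  if (length(library) == 0L) stop("empty alphabet library")
  counts <- setNames(numeric(20), CANONICAL_RESIDUES)
  total_letters <- 0
  for (a in alphabets(library)) {
    counts[members(a)] <- counts[members(a)] + 1
    total_letters <- total_letters + alphabetSize(a)
  }
  if (mode == "membership") counts / length(library)
  else counts / total_letters
}

#' Residue co-occurrence matrix of a library
#'
#' Entry (i, j) with i != j counts alphabets containing both residues; the
#' diagonal counts alphabets containing residue i.
#'
#' @param library An [AlphabetLibrary-class].
#' @return A symmetric 20 x 20 integer matrix with residue dimnames.
#' @export
cooccurrenceMatrix <- function(library) {
  if (length(library) == 0L) stop("empty alphabet library")
  m <- matrix(0L, 20, 20, dimnames = list(CANONICAL_RESIDUES,
                                          CANONICAL_RESIDUES))
  for (a in alphabets(library)) {
    idx <- match(members(a), CANONICAL_RESIDUES)
    m[idx, idx] <- m[idx, idx] + 1L
  }
  m
}
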