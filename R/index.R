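# Reference library and permuted sorted indexes.

#' Build the reference M-mer library
#'
#' Enumerates the start positions of all N-free contiguous length-\code{m}
#' substrings of the reference (there are at most \code{N - M + 1} of them;
#' any M-mer overlapping an N-masked base is excluded).
#'
#' @param w reference sequence: character scalar, \code{DNAString}, or a list
#'   as returned by \code{\link{readReferenceFasta}} (sequence plus
#'   coordinate map).
#' @param m M-mer length; reads aligned against the library must have this
#'   length (longer reads go through \code{\link{slidingWindowSearch}}).
#' @param refMap optional data.frame mapping concatenated coordinates back to
#'   input sequences (columns \code{name}, \code{length}, \code{offset}).
#' @return A \linkS4class{ReferenceLibrary}.
#' @examples
#' lib <- buildLibrary(generateGenome(200, seed = 1), m = 15)
#' lib
#' @export
buildLibrary <- function(w, m, refMap = NULL) {
    if (is.list(w) && !is.null(w$sequence)) {
        if (is.null(refMap)) refMap <- w$map
        w <- w$sequence
    }
    w <- normalizeDna(w)
    m <- as.integer(m)
    if (length(w) != 1L) stop("'w' must be a single sequence")
    if (m < 1L) stop("'m' must be >= 1")
    if (nchar(w) < m) stop("reference shorter than m")
    if (is.null(refMap))
        refMap <- data.frame(name = "ref", length = nchar(w), offset = 0L)
    new("ReferenceLibrary", sequence = w, m = m,
        positions = cpp_valid_mmer_starts(w, m), refMap = refMap)
}

#' Extract the M-mer at a library position
#'
#' @param lib a \linkS4class{ReferenceLibrary} (or \linkS4class{PermutedIndex}).
#' @param pos 0-based genome start position(s).
#' @return Character vector of M-mers.
#' @export
libraryMmer <- function(lib, pos) {
    if (is(lib, "PermutedIndex")) lib <- lib@library
    substring(lib@sequence, pos + 1L, pos + lib@m)
}

#' Build one permuted sorted index
#'
#' Sorts the library positions by their permuted M-mers (lexicographically,
#' ties by ascending genome position). Only the position order is stored;
#' permuted strings are re-derived from the reference and the permutation
#' whenever a comparison needs them.
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param perm a \linkS4class{Permutation} with \code{permSize(perm) == mmerLength(lib)}.
#' @param seed integer recorded for provenance (NA if the permutation was not
#'   drawn from a seed).
#' @return A \linkS4class{PermutedIndex}. The number of M-mer comparisons the
#'   sort performed is available as \code{attr(indexOrder(x), "comparisons")}.
#' @export
buildIndex <- function(lib, perm, seed = NA_integer_) {
    stopifnot(is(lib, "ReferenceLibrary"), is(perm, "Permutation"))
    if (perm@m != lib@m)
        stop("permutation length (", perm@m, ") must equal M-mer length (",
             lib@m, ")")
    ord <- cpp_sort_index(lib@sequence, lib@positions, perm@order - 1L)
    new("PermutedIndex", permutation = perm, library = lib, order = ord,
        seed = as.integer(seed))
}

#' Build a collection of independent permuted indexes
#'
#' Draws \code{j} independent uniform permutations from per-index seeds
#' derived deterministically from \code{seed} and builds one sorted index for
#' each. The whole collection is used for every read (using all of J
#' identically-distributed indexes is equivalent to the random choice of J
#' permutations from a larger pool).
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param j number of indexes.
#' @param seed integer master seed.
#' @return List of \linkS4class{PermutedIndex} objects.
#' @export
buildIndexes <- function(lib, j, seed = 1L) {
    seeds <- with_seed(seed, sample.int(.Machine$integer.max, j))
    lapply(seeds, function(s) buildIndex(lib, randomPermutation(lib@m, s), s))
}

#' Lexicographical position of a permuted query
#'
#' Leftmost insertion point of the (already permuted) query in the sorted
#' index: the number of entries whose permuted M-mer is strictly smaller.
#' Binary search, O(log N) M-mer comparisons; the count actually spent is
#' attached as attribute \code{comparisons}.
#'
#' @param index a \linkS4class{PermutedIndex}.
#' @param q character scalar of length m, \emph{already} permuted with the
#'   index's permutation.
#' @return Integer rank in \code{0..length(indexOrder(index))}.
#' @export
lexicographicPosition <- function(index, q) {
    stopifnot(is(index, "PermutedIndex"))
    if (!is.character(q)) q <- as.character(q)
    if (nchar(q) != index@permutation@m)
        stop("query length must equal m")
    r <- cpp_lex_position(index@library@sequence, index@order,
                          index@permutation@order - 1L, q)
    structure(r$rank, comparisons = r$comparisons)
}

#' Sorted-array neighborhood
#'
#' The genome positions stored at array indices \code{rank - k} to
#' \code{rank + k} of the sorted index (at most \code{2k + 1} entries,
#' clamped at the array boundaries rather than wrapped).
#'
#' @param index a \linkS4class{PermutedIndex}.
#' @param rank integer in \code{0..length(indexOrder(index))}, usually from
#'   \code{\link{lexicographicPosition}}.
#' @param k neighborhood half-width K.
#' @return Integer vector of 0-based genome positions.
#' @export
neighborhood <- function(index, rank, k) {
    stopifnot(is(index, "PermutedIndex"))
    n <- length(index@order)
    if (rank < 0L || rank > n) stop("rank out of range")
    if (k < 0L) stop("k must be >= 0")
    lo <- max(0L, rank - k)
    hi <- min(n - 1L, rank + k)
    if (lo > hi) return(integer(0))
    index@order[(lo + 1L):(hi + 1L)]
}

#' Prefix neighborhood
#'
#' All index entries whose permuted M-mer shares the first \code{l} characters
#' of the permuted query; found with two binary searches over the sorted
#' array.
#'
#' @param index a \linkS4class{PermutedIndex}.
#' @param q permuted query (character scalar of length m).
#' @param l prefix length in \code{0..m}; \code{l = 0} matches the whole
#'   library.
#' @return Integer vector of 0-based genome positions.
#' @export
prefixNeighborhood <- function(index, q, l) {
    stopifnot(is(index, "PermutedIndex"))
    if (!is.character(q)) q <- as.character(q)
    m <- index@permutation@m
    if (l < 0L || l > m) stop("'l' must lie in 0..m")
    if (nchar(q) != m) stop("query length must equal m")
    rng <- cpp_prefix_range(index@library@sequence, index@order,
                            index@permutation@order - 1L, q, l)
    if (rng[1L] >= rng[2L]) return(integer(0))
    index@order[(rng[1L] + 1L):rng[2L]]
}

#' Resolution length of a library entry
#'
#' The smallest prefix length L at which the permuted M-mer starting at
#' genome position \code{i} is shared by at most \code{k} library entries
#' (itself included). When even the full M-mer is shared by more than
#' \code{k} entries (duplicated M-mers), the sentinel \code{m + 1} is
#' returned: no prefix can separate identical strings.
#'
#' @param index a \linkS4class{PermutedIndex}.
#' @param i 0-based library position.
#' @param k neighborhood size K (>= 1).
#' @return Integer L in \code{0..m}, or \code{m + 1}.
#' @export
resolutionLength <- function(index, i, k) {
    stopifnot(is(index, "PermutedIndex"))
    if (k < 1L) stop("'k' must be >= 1")
    if (!(i %in% index@library@positions)) stop("'i' is not a library position")
    m <- index@permutation@m
    q <- applyPermutation(index@permutation, libraryMmer(index, i))
    sizeAt <- function(l) {
        rng <- cpp_prefix_range(index@library@sequence, index@order,
                                index@permutation@order - 1L, q, l)
        rng[2L] - rng[1L]
    }
    if (sizeAt(m) > k) return(m + 1L)
    # prefix-neighborhood size is nonincreasing in l: binary search minimal L
    lo <- 0L; hi <- m
    while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (sizeAt(mid) <= k) hi <- mid else lo <- mid + 1L
    }
    lo
}

#' Persist and reload a permuted index
#'
#' Plain-text container honoring the memory contract: only the header
#' (format version, m, seed, reference length and checksum, permutation in
#' manifest form) and the order array are stored - never the permuted
#' strings. \code{readIndex} verifies the checksum against the supplied
#' library before accepting the order array.
#'
#' @param index a \linkS4class{PermutedIndex}.
#' @param path file path.
#' @param lib the \linkS4class{ReferenceLibrary} the index was built from.
#' @return \code{readIndex} returns the reconstructed
#'   \linkS4class{PermutedIndex}.
#' @export
writeIndex <- function(index, path) {
    stopifnot(is(index, "PermutedIndex"))
    lib <- index@library
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("permalign-index 1",
                 sprintf("m=%d seed=%s n=%d checksum=%s",
                         lib@m, ifelse(is.na(index@seed), "NA", index@seed),
                         nchar(lib@sequence), cpp_string_hash(lib@sequence)),
                 paste(index@permutation@order, collapse = ","),
                 paste(index@order, collapse = ",")), con)
    invisible(path)
}

#' @rdname writeIndex
#' @export
readIndex <- function(path, lib) {
    stopifnot(is(lib, "ReferenceLibrary"))
    lines <- readLines(path)
    if (length(lines) < 4L || lines[1L] != "permalign-index 1")
        stop("not a permalign index file")
    hdr <- regmatches(lines[2L], regexec(
        "^m=(\\d+) seed=(NA|-?\\d+) n=(\\d+) checksum=([0-9a-f]+)$",
        lines[2L]))[[1L]]
    if (length(hdr) != 5L) stop("malformed index header")
    if (as.integer(hdr[2L]) != lib@m)
        stop("index m disagrees with library m")
    if (hdr[5L] != cpp_string_hash(lib@sequence))
        stop("reference checksum mismatch: index built from another genome")
    perm <- asPermutation(as.integer(strsplit(lines[3L], ",")[[1L]]))
    ord <- as.integer(strsplit(lines[4L], ",")[[1L]])
    new("PermutedIndex", permutation = perm, library = lib, order = ord,
        seed = suppressWarnings(as.integer(hdr[3L])))
}
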