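# DNA string primitives and position permutations.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. seed = NULL uses (and advances) the current
# stream.
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Normalize a DNA string
#'
#' Case-folds to upper case and maps every character outside A, C, G, T to N.
#' Accepts plain character vectors as well as Biostrings XString/XStringSet
#' objects (converted with \code{as.character}).
#'
#' @param x character vector, \code{DNAString} or \code{DNAStringSet}.
#' @return An upper-case character vector over the alphabet \{A,C,G,T,N\}.
#' @export
normalizeDna <- function(x) {
    if (!is.character(x)) x <- as.character(x)
    x <- toupper(x)
    gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' Construct a permutation
#'
#' \code{asPermutation} wraps a 1-based order vector (the printed form used in
#' permutation manifests); \code{identityPermutation} and
#' \code{randomPermutation} are the common constructors. Random permutations
#' are drawn uniformly from all \code{m!} possibilities (Fisher-Yates, via
#' \code{sample.int}); the same seed always yields the same permutation.
#'
#' @param order integer vector of 1-based source positions.
#' @param m positive integer, length of the strings the permutation acts on.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return A \linkS4class{Permutation}.
#' @examples
#' randomPermutation(15, seed = 1)
#' @export
asPermutation <- function(order) {
    new("Permutation", m = length(order), order = as.integer(order))
}

#' @rdname asPermutation
#' @export
identityPermutation <- function(m) asPermutation(seq_len(m))

#' @rdname asPermutation
#' @export
randomPermutation <- function(m, seed = NULL) {
    if (length(m) != 1L || is.na(m) || m < 1) stop("'m' must be >= 1")
    asPermutation(with_seed(seed, sample.int(m)))
}

#' Invert a permutation
#'
#' @param perm a \linkS4class{Permutation}.
#' @return The inverse \linkS4class{Permutation}:
#'   \code{applyPermutation(invertPermutation(p), applyPermutation(p, s))}
#'   recovers \code{s}.
#' @export
invertPermutation <- function(perm) {
    stopifnot(is(perm, "Permutation"))
    asPermutation(order(perm@order))
}

#' Apply a permutation to a string
#'
#' Gather convention: output position \code{j} holds the input character at
#' \code{permOrder(perm)[j]}. Reordering characters preserves the Hamming
#' distance between any two equal-length strings, which is what makes the
#' permuted sorted indexes searchable.
#'
#' @param perm a \linkS4class{Permutation}.
#' @param s character scalar (or \code{DNAString}) of length \code{permSize(perm)}.
#' @return The permuted string (character scalar).
#' @examples
#' p <- asPermutation(c(11, 2, 7, 13, 9, 15, 4, 5, 1, 12, 10, 14, 3, 8, 6))
#' applyPermutation(p, "CTTGCCAAAGCCATG")
#' @export
applyPermutation <- function(perm, s) {
    stopifnot(is(perm, "Permutation"))
    if (!is.character(s)) s <- as.character(s)
    if (nchar(s) != perm@m)
        stop("string length (", nchar(s), ") must equal permutation length (",
             perm@m, ")")
    cpp_apply_perm(s, perm@order - 1L)
}

#' Where does an input position land?
#'
#' Returns the output position to which a character at 1-based input position
#' \code{pos} is moved by \code{applyPermutation}; a mismatch at \code{pos}
#' ends up at \code{permutePosition(perm, pos)} in the permuted string.
#'
#' @param perm a \linkS4class{Permutation}.
#' @param pos 1-based input position(s).
#' @return The 1-based output position(s).
#' @export
permutePosition <- function(perm, pos) {
    stopifnot(is(perm, "Permutation"))
    if (any(pos < 1L) || any(pos > perm@m)) stop("position out of range")
    match(pos, perm@order)
}

#' Hamming distance between equal-length strings
#'
#' Counts mismatching positions. \code{N} is treated conservatively: it
#' mismatches every character, including another \code{N}, so masked regions
#' never look similar to anything.
#'
#' @param a,b character scalars (or \code{DNAString}s) of equal length.
#' @return Non-negative integer mismatch count.
#' @export
hammingDistance <- function(a, b) {
    if (!is.character(a)) a <- as.character(a)
    if (!is.character(b)) b <- as.character(b)
    if (nchar(a) != nchar(b)) stop("strings must have equal length")
    cpp_hamming(a, b)
}

#' @describeIn reverseComplement-character Reverse complement of plain
#'   character vectors; \code{N} maps to \code{N}.
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
    cpp_revcomp(normalizeDna(x))
})

#' Reverse complement for character vectors
#'
#' A character method for the \code{Biostrings} generic so that the aligner's
#' plain-string reads can be flipped without manual conversion.
#'
#' @param x character vector of DNA strings.
#' @param ... ignored.
#' @return Character vector of reverse complements.
#' @name reverseComplement-character
NULL

#' Read and write permutation manifests
#'
#' Plain-text record of a permutation collection: a header line
#' \code{# m=<m> seed=<seed>} followed by one permutation per line as
#' comma-separated 1-based source positions. Rebuilding indexes from the
#' reference plus a manifest reproduces the sorted arrays bit for bit.
#'
#' @param perms list of \linkS4class{Permutation} objects.
#' @param path file path.
#' @param seed integer master seed recorded in the header (NA if unknown).
#' @return \code{readPermutationManifest} returns the list of permutations,
#'   with the header fields in attributes \code{m} and \code{seed}.
#' @export
writePermutationManifest <- function(perms, path, seed = NA_integer_) {
    if (is(perms, "Permutation")) perms <- list(perms)
    m <- unique(vapply(perms, permSize, integer(1)))
    if (length(m) != 1L) stop("all permutations must share one length")
    lines <- c(sprintf("# m=%d seed=%s", m, ifelse(is.na(seed), "NA", seed)),
               vapply(perms, function(p) paste(p@order, collapse = ","), ""))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writePermutationManifest
#' @export
readPermutationManifest <- function(path) {
    lines <- readLines(path)
    if (!length(lines) || !grepl("^# m=", lines[1L]))
        stop("not a permutation manifest: missing '# m=' header")
    hdr <- regmatches(lines[1L],
                      regexec("^# m=(\\d+) seed=(NA|-?\\d+)$", lines[1L]))[[1L]]
    if (length(hdr) != 3L) stop("malformed manifest header: ", lines[1L])
    m <- as.integer(hdr[2L])
    perms <- lapply(lines[-1L], function(l) {
        ord <- as.integer(strsplit(l, ",", fixed = TRUE)[[1L]])
        if (length(ord) != m) stop("manifest row length disagrees with header")
        asPermutation(ord)
    })
    attr(perms, "m") <- m
    attr(perms, "seed") <- suppressWarnings(as.integer(hdr[3L]))
    perms
}
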