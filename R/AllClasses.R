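#' @useDynLib permalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new is setClass setGeneric setMethod setValidity show
#'   validObject slot
#' @importFrom stats rbinom rnorm runif quantile setNames
#' @importFrom utils read.table write.table head
NULL

#' Permutation of string positions
#'
#' A bijection on the positions \code{1..m} of a string, the randomization
#' primitive of the aligner. The \code{order} slot follows the gather
#' convention: output position \code{j} receives the input character at
#' \code{order[j]}.
#'
#' @slot m integer, length of the strings the permutation acts on.
#' @slot order integer vector of 1-based source positions, a bijection on
#'   \code{1..m}.
#' @exportClass Permutation
setClass("Permutation", representation(m = "integer", order = "integer"))

setValidity("Permutation", function(object) {
    if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
        return("'m' must be a single positive integer")
    if (length(object@order) != object@m)
        return("'order' must have length m")
    if (!identical(sort(object@order), seq_len(object@m)))
        return("'order' must be a bijection on 1..m")
    TRUE
})

#' Reference M-mer library
#'
#' The reference genome together with the start positions of all its N-free
#' contiguous substrings of length \code{m} (the M-mers \eqn{X_i}). Positions
#' are 0-based internally; user-facing output (SAM, manifests) is 1-based.
#'
#' @slot sequence character scalar, the (possibly concatenated) reference.
#' @slot m integer M-mer length.
#' @slot positions integer vector of valid 0-based M-mer start positions.
#' @slot refMap data.frame with columns \code{name}, \code{length},
#'   \code{offset} mapping concatenated coordinates back to input sequences.
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
    representation(sequence = "character", m = "integer",
                   positions = "integer", refMap = "data.frame"))

setValidity("ReferenceLibrary", function(object) {
    n <- nchar(object@sequence)
    if (length(object@sequence) != 1L) return("'sequence' must be a scalar")
    if (object@m < 1L || n < object@m) return("need length(sequence) >= m >= 1")
    if (length(object@positions) &&
        (min(object@positions) < 0L || max(object@positions) > n - object@m))
        return("positions out of range")
    if (is.unsorted(object@positions, strictly = TRUE))
        return("positions must be strictly increasing")
    TRUE
})

#' Sorted permuted index
#'
#' One random permutation plus the library positions sorted by permuted M-mer
#' (lexicographically, ties broken by ascending genome position). The permuted
#' strings themselves are never stored; they are re-derived from the reference
#' and the permutation on demand.
#'
#' @slot permutation a \linkS4class{Permutation}.
#' @slot library the \linkS4class{ReferenceLibrary} the index was built from.
#' @slot order integer vector: library positions in permuted-lexicographic
#'   order.
#' @slot seed integer seed the permutation was drawn from (NA if unknown).
#' @exportClass PermutedIndex
setClass("PermutedIndex",
    representation(permutation = "Permutation", library = "ReferenceLibrary",
                   order = "integer", seed = "integer"))

setValidity("PermutedIndex", function(object) {
    if (object@permutation@m != object@library@m)
        return("permutation length must equal library M-mer length")
    if (length(object@order) != length(object@library@positions))
        return("order must contain every library position exactly once")
    TRUE
})

#' Search parameters
#'
#' @slot j integer, number of permuted indexes searched per read (J).
#' @slot k integer, neighborhood half-width (K): 2K+1 sorted-array entries are
#'   harvested around the query's lexicographical position.
#' @slot minHits integer, hit-count filtration threshold.
#' @slot maxReport integer, maximum alignments reported per read.
#' @slot strandMode "both" or "forward".
#' @exportClass SearchParams
setClass("SearchParams",
    representation(j = "integer", k = "integer", minHits = "integer",
                   maxReport = "integer", strandMode = "character"))

setValidity("SearchParams", function(object) {
    if (object@j < 0L) return("j must be >= 0")
    if (object@k < 0L) return("k must be >= 0")
    if (object@minHits < 1L) return("minHits must be >= 1")
    if (object@maxReport < 1L) return("maxReport must be >= 1")
    if (!object@strandMode %in% c("both", "forward"))
        return("strandMode must be 'both' or 'forward'")
    TRUE
})

#' Candidate alignment positions with hit counts
#'
#' @slot pos integer vector of 0-based genome positions.
#' @slot strand character vector ("+"/"-") parallel to \code{pos}.
#' @slot hits integer vector of hit counts (number of index searches whose
#'   neighborhood proposed the position).
#' @slot comparisons numeric, M-mer comparisons spent collecting the set.
#' @exportClass CandidateSet
setClass("CandidateSet",
    representation(pos = "integer", strand = "character", hits = "integer",
                   comparisons = "numeric"))

setValidity("CandidateSet", function(object) {
    if (length(object@pos) != length(object@strand) ||
        length(object@pos) != length(object@hits))
        return("pos, strand and hits must be parallel")
    if (length(object@hits) && min(object@hits) < 1L)
        return("hit counts must be >= 1")
    TRUE
})

#' Single-read alignment result
#'
#' @slot readId character read identifier.
#' @slot status "aligned" or "unaligned".
#' @slot reported data.frame with columns \code{pos} (0-based), \code{strand},
#'   \code{distance}, \code{hits}, sorted by (distance, -hits, pos), truncated
#'   to \code{maxReport}.
#' @slot ties data.frame (\code{pos}, \code{strand}) of all candidates sharing
#'   the best distance.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
    representation(readId = "character", status = "character",
                   reported = "data.frame", ties = "data.frame"))

#' Paired-end parameters
#'
#' @slot insertMin,insertMax integer bounds on the outer fragment span
#'   (leftmost mate start to rightmost mate end) for a concordant pair.
#' @slot orientation expected relative orientation; only "fr"
#'   (forward/reverse, Illumina convention) is implemented.
#' @slot rescueBand integer band half-width for the banded edit-distance
#'   verification during mate rescue (the indel budget).
#' @slot maxRescueDistance integer, maximum accepted edit distance for a
#'   rescued mate.
#' @slot seedLength integer length of exact-match seeds used to narrow the
#'   rescue scan (NA: half the index M-mer length).
#' @slot maxAnchorMismatchFrac numeric, an anchor candidate is "reasonable"
#'   when its Hamming distance is at most \code{ceil(frac * read length)}.
#' @slot exhaustiveRescue logical, always scan the whole rescue window instead
#'   of stopping at the first acceptable seeded hit.
#' @exportClass PairedParams
setClass("PairedParams",
    representation(insertMin = "integer", insertMax = "integer",
                   orientation = "character", rescueBand = "integer",
                   maxRescueDistance = "integer", seedLength = "integer",
                   maxAnchorMismatchFrac = "numeric",
                   exhaustiveRescue = "logical"))

setValidity("PairedParams", function(object) {
    if (object@insertMin < 0L || object@insertMax < object@insertMin)
        return("need 0 <= insertMin <= insertMax")
    if (object@rescueBand < 0L) return("rescueBand must be >= 0")
    if (object@maxRescueDistance < 0L) return("maxRescueDistance must be >= 0")
    if (!identical(object@orientation, "fr"))
        return("only orientation 'fr' is supported")
    TRUE
})

#' Paired-end alignment result
#'
#' @slot first,second per-mate \linkS4class{AlignmentResult}; for a rescued
#'   mate the reported table holds the rescued position and edit distance.
#' @slot status "concordant", "one-rescued", "discordant" or "unaligned".
#' @slot rescue list with elements \code{mate} (1 or 2), \code{pos},
#'   \code{strand}, \code{distance}, \code{cigar}, \code{transcript} when a
#'   mate was rescued; empty list otherwise.
#' @exportClass PairedResult
setClass("PairedResult",
    representation(first = "AlignmentResult", second = "AlignmentResult",
                   status = "character", rescue = "list"))

#' Read-simulation configuration
#'
#' wgsim-style generation parameters: haplotype variants are planted on the
#' reference at \code{mutationRate} per base, a fraction \code{indelFraction}
#' of them being single-base indels, and sequencing mismatches are applied to
#' each sampled read at \code{errorRate} per base.
#'
#' @slot genomeLength,nReads,readLength integer sizes.
#' @slot mutationRate,indelFraction,errorRate numeric rates in [0, 1].
#' @slot insertMean,insertSd numeric insert-size model for pairs.
#' @slot seed integer master seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(genomeLength = "integer", nReads = "integer",
                   readLength = "integer", mutationRate = "numeric",
                   indelFraction = "numeric", errorRate = "numeric",
                   insertMean = "numeric", insertSd = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    rates <- c(object@mutationRate, object@indelFraction, object@errorRate)
    if (any(rates < 0) || any(rates > 1)) return("rates must lie in [0, 1]")
    if (object@genomeLength < 1L || object@nReads < 0L ||
        object@readLength < 1L)
        return("lengths must be positive")
    if (object@readLength > object@genomeLength)
        return("readLength must not exceed genomeLength")
    TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "Permutation", function(object) {
    cat(sprintf("Permutation on %d positions: (%s)\n", object@m,
                paste(object@order, collapse = ", ")))
})

setMethod("show", "ReferenceLibrary", function(object) {
    cat(sprintf("ReferenceLibrary: %d bases, m = %d, %d M-mer positions",
                nchar(object@sequence), object@m, length(object@positions)))
    if (nrow(object@refMap) > 0L)
        cat(sprintf(" (%d sequences)", nrow(object@refMap)))
    cat("\n")
})

setMethod("show", "PermutedIndex", function(object) {
    cat(sprintf("PermutedIndex: m = %d, %d entries, seed = %s\n",
                object@permutation@m, length(object@order),
                ifelse(is.na(object@seed), "NA", object@seed)))
})

setMethod("show", "CandidateSet", function(object) {
    cat(sprintf("CandidateSet: %d candidate position(s)\n", length(object@pos)))
    if (length(object@pos))
        print(head(data.frame(pos = object@pos, strand = object@strand,
                              hits = object@hits), 10L))
})

setMethod("show", "AlignmentResult", function(object) {
    cat(sprintf("AlignmentResult '%s': %s\n", object@readId, object@status))
    if (nrow(object@reported)) print(head(object@reported, 5L))
})

setMethod("show", "PairedResult", function(object) {
    cat(sprintf("PairedResult [%s]\n", object@status))
    cat("  first:  "); show(object@first)
    cat("  second: "); show(object@second)
})

## ---- accessors -------------------------------------------------------------

#' Accessors for permalign objects
#'
#' Small read-only accessors for the S4 containers; slot access is internal.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases permSize permOrder refSequence mmerLength libPositions refMap
#'   indexOrder indexPermutation candidateTable readId alignmentStatus
#'   reported bestPosition bestStrand bestDistance
NULL

#' @rdname accessors
#' @export
permSize <- function(x) { stopifnot(is(x, "Permutation")); x@m }

#' @rdname accessors
#' @export
permOrder <- function(x) { stopifnot(is(x, "Permutation")); x@order }

#' @rdname accessors
#' @export
refSequence <- function(x) {
    if (is(x, "PermutedIndex")) x <- x@library
    stopifnot(is(x, "ReferenceLibrary"))
    x@sequence
}

#' @rdname accessors
#' @export
mmerLength <- function(x) {
    if (is(x, "PermutedIndex")) x <- x@library
    stopifnot(is(x, "ReferenceLibrary"))
    x@m
}

#' @rdname accessors
#' @export
libPositions <- function(x) {
    if (is(x, "PermutedIndex")) x <- x@library
    stopifnot(is(x, "ReferenceLibrary"))
    x@positions
}

#' @rdname accessors
#' @export
refMap <- function(x) {
    if (is(x, "PermutedIndex")) x <- x@library
    stopifnot(is(x, "ReferenceLibrary"))
    x@refMap
}

#' @rdname accessors
#' @export
indexOrder <- function(x) { stopifnot(is(x, "PermutedIndex")); x@order }

#' @rdname accessors
#' @export
indexPermutation <- function(x) { stopifnot(is(x, "PermutedIndex")); x@permutation }

#' @rdname accessors
#' @export
candidateTable <- function(x) {
    stopifnot(is(x, "CandidateSet"))
    data.frame(pos = x@pos, strand = x@strand, hits = x@hits)
}

#' @rdname accessors
#' @export
readId <- function(x) { stopifnot(is(x, "AlignmentResult")); x@readId }

#' @rdname accessors
#' @export
alignmentStatus <- function(x) {
    if (is(x, "PairedResult")) return(x@status)
    stopifnot(is(x, "AlignmentResult"))
    x@status
}

#' @rdname accessors
#' @export
reported <- function(x) { stopifnot(is(x, "AlignmentResult")); x@reported }

#' @rdname accessors
#' @export
bestPosition <- function(x) {
    stopifnot(is(x, "AlignmentResult"))
    if (nrow(x@reported) == 0L) NA_integer_ else x@reported$pos[1L]
}

#' @rdname accessors
#' @export
bestStrand <- function(x) {
    stopifnot(is(x, "AlignmentResult"))
    if (nrow(x@reported) == 0L) NA_character_ else x@reported$strand[1L]
}

#' @rdname accessors
#' @export
bestDistance <- function(x) {
    stopifnot(is(x, "AlignmentResult"))
    if (nrow(x@reported) == 0L) NA_integer_ else x@reported$distance[1L]
}
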