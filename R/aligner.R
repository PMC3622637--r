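# Candidate collection over J permuted indexes, hit-count filtration and
# Hamming ranking.

#' Construct search parameters
#'
#' @param j number of permuted indexes searched per read (J). Each index
#'   contributes one sorted-array neighborhood per strand.
#' @param k neighborhood half-width (K).
#' @param minHits hit-count filtration threshold: a candidate must be proposed
#'   by at least this many searches to be evaluated.
#' @param maxReport maximum number of alignments reported per read.
#' @param strandMode \code{"both"} (search the read and its reverse
#'   complement) or \code{"forward"}.
#' @return A \linkS4class{SearchParams}.
#' @export
searchParams <- function(j = 8L, k = 20L, minHits = 1L, maxReport = 5L,
                         strandMode = c("both", "forward")) {
    new("SearchParams", j = as.integer(j), k = as.integer(k),
        minHits = as.integer(minHits), maxReport = as.integer(maxReport),
        strandMode = match.arg(strandMode))
}

# Aggregate raw (pos, strand) proposals into a CandidateSet with hit counts.
.tallyCandidates <- function(pos, strand, ncmp) {
    if (!length(pos))
        return(new2("CandidateSet", pos = integer(0), strand = character(0),
                    hits = integer(0), comparisons = as.numeric(ncmp),
                    check = FALSE))
    key <- 2 * as.numeric(pos) + (strand == "-")
    u <- which(!duplicated(key))
    hits <- tabulate(match(key, key[u]), nbins = length(u))
    o <- u[order(key[u])]
    new2("CandidateSet", pos = as.integer(pos[o]), strand = strand[o],
         hits = as.integer(hits[order(key[u])]),
         comparisons = as.numeric(ncmp), check = FALSE)
}

# data.frame without the construction overhead (columns are same-length
# atomic vectors by construction)
.fastDF <- function(...) {
    x <- list(...)
    attr(x, "row.names") <- .set_row_names(length(x[[1L]]))
    class(x) <- "data.frame"
    x
}

#' Collect candidate loci for a read
#'
#' One search per index (and per strand): the read is permuted with the
#' index's permutation, its lexicographical position is found by binary
#' search, and the \code{2k + 1} neighborhood entries are added to the
#' candidate set, incrementing each position's hit count.
#'
#' @param read character scalar of length \code{mmerLength(lib)}.
#' @param indexes list of \linkS4class{PermutedIndex} objects; the first
#'   \code{params@j} are used.
#' @param params a \linkS4class{SearchParams}.
#' @return A \linkS4class{CandidateSet}; reverse-strand candidates record the
#'   position where the reverse complement of the read matches the forward
#'   reference.
#' @export
collectCandidates <- function(read, indexes, params = searchParams()) {
    if (is(indexes, "PermutedIndex")) indexes <- list(indexes)
    if (params@j > length(indexes))
        stop("params@j exceeds the number of available indexes")
    if (params@j == 0L) return(.tallyCandidates(integer(0), character(0), 0))
    read <- normalizeDna(read)
    m <- indexes[[1L]]@permutation@m
    if (nchar(read) != m)
        stop("read length (", nchar(read), ") must equal m (", m,
             "); use slidingWindowSearch for longer reads")
    strands <- if (params@strandMode == "both") c("+", "-") else "+"
    queries <- if (params@strandMode == "both")
        c("+" = read, "-" = cpp_revcomp(read)) else c("+" = read)
    pos <- vector("list", params@j * length(strands))
    str <- vector("list", params@j * length(strands))
    ncmp <- 0
    slot <- 0L
    for (jj in seq_len(params@j)) {
        idx <- indexes[[jj]]
        for (s in strands) {
            qp <- applyPermutation(idx@permutation, queries[[s]])
            rank <- lexicographicPosition(idx, qp)
            ncmp <- ncmp + attr(rank, "comparisons")
            nb <- neighborhood(idx, as.integer(rank), params@k)
            slot <- slot + 1L
            pos[[slot]] <- nb
            str[[slot]] <- rep(s, length(nb))
        }
    }
    .tallyCandidates(unlist(pos), unlist(str), ncmp)
}

#' Coarse hit-count filtration
#'
#' Retains candidates proposed by at least \code{minHits} independent
#' searches. With \code{minHits = 1} the set is unchanged.
#'
#' @param cands a \linkS4class{CandidateSet}.
#' @param minHits integer threshold (>= 1).
#' @return The filtered \linkS4class{CandidateSet}.
#' @export
filterByHits <- function(cands, minHits) {
    stopifnot(is(cands, "CandidateSet"))
    if (minHits < 1L) stop("minHits must be >= 1")
    if (minHits == 1L) return(cands)
    keep <- cands@hits >= minHits
    new2("CandidateSet", pos = cands@pos[keep], strand = cands@strand[keep],
         hits = cands@hits[keep], comparisons = cands@comparisons,
         check = FALSE)
}

#' Rank candidates by Hamming distance
#'
#' Evaluates the strand-appropriate read against every candidate M-mer and
#' reports the closest ones: the reported table is sorted by (distance
#' ascending, hit count descending, position ascending, forward strand
#' first) and truncated to \code{maxReport}; all candidates sharing the best
#' distance are kept in the \code{ties} slot.
#'
#' @param read character scalar of length m (as given, forward orientation).
#' @param cands a \linkS4class{CandidateSet}.
#' @param lib the \linkS4class{ReferenceLibrary}.
#' @param params a \linkS4class{SearchParams}.
#' @param id read identifier stored in the result.
#' @return An \linkS4class{AlignmentResult}; an empty candidate set yields
#'   status \code{"unaligned"}.
#' @export
rankCandidates <- function(read, cands, lib, params = searchParams(),
                           id = "read") {
    stopifnot(is(cands, "CandidateSet"), is(lib, "ReferenceLibrary"))
    read <- normalizeDna(read)
    if (!length(cands@pos)) {
        empty <- .fastDF(pos = integer(0), strand = character(0),
                         distance = integer(0), hits = integer(0))
        return(new2("AlignmentResult", readId = id, status = "unaligned",
                    reported = empty, ties = empty[c("pos", "strand")],
                    check = FALSE))
    }
    dist <- integer(length(cands@pos))
    fwd <- cands@strand == "+"
    if (any(fwd))
        dist[fwd] <- cpp_hamming_at(lib@sequence, cands@pos[fwd], read)
    if (!all(fwd))
        dist[!fwd] <- cpp_hamming_at(lib@sequence, cands@pos[!fwd],
                                     cpp_revcomp(read))
    o <- order(dist, -cands@hits, cands@pos, cands@strand != "+")
    tab <- .fastDF(pos = cands@pos[o], strand = cands@strand[o],
                   distance = dist[o], hits = cands@hits[o])
    best <- tab$distance[1L]
    isTie <- tab$distance == best
    ties <- .fastDF(pos = tab$pos[isTie], strand = tab$strand[isTie])
    n <- min(nrow(tab), params@maxReport)
    new2("AlignmentResult", readId = id, status = "aligned",
         reported = tab[seq_len(n), , drop = FALSE], ties = ties,
         check = FALSE)
}

#' Align a single read
#'
#' The full per-read pipeline: candidate collection over the permuted
#' indexes, hit-count filtration, then Hamming ranking of the survivors.
#'
#' @inheritParams collectCandidates
#' @inheritParams rankCandidates
#' @param lib the \linkS4class{ReferenceLibrary} the indexes were built from.
#' @return An \linkS4class{AlignmentResult}. The total number of M-mer
#'   comparisons spent searching is attached as attribute
#'   \code{comparisons}.
#' @examples
#' g <- generateGenome(2000, seed = 7)
#' lib <- buildLibrary(g, 15)
#' idx <- buildIndexes(lib, j = 4, seed = 7)
#' alignRead(substring(g, 501, 515), idx, lib, searchParams(j = 4, k = 5))
#' @export
alignRead <- function(read, indexes, lib, params = searchParams(),
                      id = "read") {
    cands <- collectCandidates(read, indexes, params)
    res <- rankCandidates(read, filterByHits(cands, params@minHits), lib,
                          params, id = id)
    attr(res, "comparisons") <- cands@comparisons
    res
}

#' Align a batch of reads
#'
#' @param reads named character vector (or \code{DNAStringSet}); names become
#'   read identifiers.
#' @inheritParams alignRead
#' @return List of \linkS4class{AlignmentResult} objects, one per read, in
#'   input order.
#' @export
alignReads <- function(reads, indexes, lib, params = searchParams()) {
    if (!is.character(reads)) {
        nm <- names(reads)
        reads <- as.character(reads)
        names(reads) <- nm
    }
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    res <- vector("list", length(reads))
    for (i in seq_along(reads))
        res[[i]] <- alignRead(reads[[i]], indexes, lib, params, id = ids[[i]])
    names(res) <- ids
    res
}

#' Tabulate alignment results
#'
#' Flattens a list of \linkS4class{AlignmentResult} objects into one
#' data.frame of reported alignments (one row per reported candidate, primary
#' first).
#'
#' @param results list of \linkS4class{AlignmentResult}.
#' @return data.frame with columns \code{id}, \code{rank}, \code{pos}
#'   (0-based), \code{strand}, \code{distance}, \code{hits}; unaligned reads
#'   contribute one row with NA position.
#' @export
resultsTable <- function(results) {
    if (is(results, "AlignmentResult")) results <- list(results)
    n <- vapply(results, function(r) max(1L, nrow(r@reported)), integer(1))
    grab <- function(f, empty) unlist(lapply(results, function(r)
        if (nrow(r@reported) == 0L) empty else f(r@reported)))
    data.frame(
        id = rep(vapply(results, function(r) r@readId, ""), n),
        rank = grab(function(t) seq_len(nrow(t)), NA_integer_),
        pos = grab(function(t) t$pos, NA_integer_),
        strand = grab(function(t) t$strand, NA_character_),
        distance = grab(function(t) t$distance, NA_integer_),
        hits = grab(function(t) t$hits, NA_integer_))
}

#' Brute-force nearest-neighbour scan
#'
#' Computes the exact minimum Hamming distance of a read over \emph{every}
#' library M-mer by linear scan, with all argmin positions. O(N M) per read,
#' so only sensible on small references; used as the exhaustive reference
#' answer that the randomized index search approximates.
#'
#' @param lib a \linkS4class{ReferenceLibrary}.
#' @param read character scalar of length \code{mmerLength(lib)}.
#' @return List with \code{distance} and \code{positions} (all 0-based
#'   argmin positions).
#' @export
scanNearest <- function(lib, read) {
    stopifnot(is(lib, "ReferenceLibrary"))
    read <- normalizeDna(read)
    if (nchar(read) != lib@m) stop("read length must equal m")
    cpp_min_hamming(lib@sequence, lib@positions, read)
}

#' Sliding-window search of a long read in a single index
#'
#' Reuses one sorted index almost as if it were several: contiguous
#' length-m windows of the read (offsets \code{0, stride, 2 stride, ...},
#' the last window clamped to end at the read's final character) are each
#' permuted and searched, and every neighborhood hit votes for the read
#' start position implied by its window offset. Hit counts therefore
#' accumulate across windows.
#'
#' @param read character scalar with \code{nchar(read) >= m}.
#' @param index a single \linkS4class{PermutedIndex}.
#' @param params a \linkS4class{SearchParams} (only \code{k} and
#'   \code{strandMode} are used).
#' @param stride window step in positions; default \code{floor(m / 2)}.
#' @return A \linkS4class{CandidateSet} of candidate \emph{read start}
#'   positions (0-based).
#' @export
slidingWindowSearch <- function(read, index, params = searchParams(),
                                stride = NULL) {
    stopifnot(is(index, "PermutedIndex"))
    read <- normalizeDna(read)
    m <- index@permutation@m
    len <- nchar(read)
    if (len < m) stop("read shorter than m")
    if (is.null(stride)) stride <- max(1L, m %/% 2L)
    if (stride < 1L) stop("stride must be >= 1")
    offs <- unique(c(seq.int(0L, len - m, by = stride), len - m))
    one <- searchParams(j = 1L, k = params@k, strandMode = params@strandMode)
    pos <- list(); str <- list(); ncmp <- 0
    for (o in offs) {
        win <- substring(read, o + 1L, o + m)
        cs <- collectCandidates(win, list(index), one)
        ncmp <- ncmp + cs@comparisons
        # a window hit at genome position h implies read start h - o on the
        # forward strand and h + o + m - len on the reverse strand
        adj <- ifelse(cs@strand == "+", cs@pos - o, cs@pos + o + m - len)
        keep <- adj >= 0L & adj <= nchar(index@library@sequence) - len
        pos[[length(pos) + 1L]] <- rep(as.integer(adj[keep]), cs@hits[keep])
        str[[length(str) + 1L]] <- rep(cs@strand[keep], cs@hits[keep])
    }
    .tallyCandidates(unlist(pos), unlist(str), ncmp)
}
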