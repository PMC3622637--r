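# Paired-end alignment with indel-tolerant mate rescue.

#' Construct paired-end parameters
#'
#' @param insertMin,insertMax bounds on the outer fragment span (leftmost
#'   mate start to rightmost mate end) for a concordant pair.
#' @param rescueBand band half-width for the banded edit-distance
#'   verification (the indel budget of a rescue).
#' @param maxRescueDistance maximum accepted edit distance for a rescued
#'   mate.
#' @param seedLength exact-seed length used to narrow the rescue scan (NA:
#'   half the index M-mer length).
#' @param maxAnchorMismatchFrac fraction of the read length tolerated as
#'   Hamming distance for an anchor candidate to be considered "reasonable".
#' @param exhaustiveRescue always scan the whole window, even when a seeded
#'   hit is already acceptable.
#' @param orientation expected relative orientation ("fr").
#' @return A \linkS4class{PairedParams}.
#' @export
pairedParams <- function(insertMin = 100L, insertMax = 500L, rescueBand = 5L,
                         maxRescueDistance = 10L, seedLength = NA_integer_,
                         maxAnchorMismatchFrac = 0.1,
                         exhaustiveRescue = FALSE, orientation = "fr") {
    new("PairedParams", insertMin = as.integer(insertMin),
        insertMax = as.integer(insertMax), orientation = orientation,
        rescueBand = as.integer(rescueBand),
        maxRescueDistance = as.integer(maxRescueDistance),
        seedLength = as.integer(seedLength),
        maxAnchorMismatchFrac = maxAnchorMismatchFrac,
        exhaustiveRescue = exhaustiveRescue)
}

#' Banded global edit distance with transcript
#'
#' Unit-cost dynamic programming restricted to a diagonal band; exact
#' whenever the true edit distance is within \code{band} (the band is widened
#' to the length difference so the alignment always completes). The
#' transcript uses \code{M} (match), \code{X} (mismatch), \code{I} (read
#' insertion) and \code{D} (deletion); the CIGAR folds \code{X} into
#' \code{M}.
#'
#' @param a,b character scalars (read and reference window, conventionally).
#' @param band band half-width (>= 0).
#' @return List with \code{distance}, \code{transcript}, \code{cigar}.
#' @examples
#' boundedEditDistance("ACGTACGT", "ACGACGT", band = 2)
#' @export
boundedEditDistance <- function(a, b, band) {
    if (band < 0L) stop("band must be >= 0")
    if (!is.character(a)) a <- as.character(a)
    if (!is.character(b)) b <- as.character(b)
    cpp_banded_edit(a, b, as.integer(band))
}

# Genomic window of plausible mate start offsets for an anchor alignment
# under FR orientation. Returns c(lo, hi) of 0-based start offsets
# (inclusive), or NULL when empty. mateLen is the mate's length; anchorLen
# the anchor read's length.
.rescueWindow <- function(anchorPos, anchorStrand, anchorLen, mateLen,
                          params, genomeLength) {
    band <- params@rescueBand
    if (anchorStrand == "+") {
        # mate is downstream, reverse: fragment [anchorPos, anchorPos + insert)
        lo <- anchorPos + params@insertMin - mateLen - band
        hi <- anchorPos + params@insertMax - mateLen + band
    } else {
        # anchor reverse: fragment ends at anchorPos + anchorLen; mate forward
        lo <- anchorPos + anchorLen - params@insertMax - band
        hi <- anchorPos + anchorLen - params@insertMin + band
    }
    lo <- max(0L, as.integer(lo))
    hi <- min(genomeLength - mateLen, as.integer(hi))
    if (lo > hi) return(NULL)
    c(lo, hi)
}

#' Rescue a mate around an anchored alignment
#'
#' Scans the reference window implied by the anchor position, the insert
#' bounds and the FR orientation for the offset minimizing the banded edit
#' distance of the (strand-oriented) mate. The scan is narrowed by exact
#' matches of mate substrings of length \code{seedLength} (prefix and suffix
#' halves, so a single indel leaves at least one seed intact); when no
#' seeded offset is acceptable the whole window is scanned by dynamic
#' programming. A rescue is accepted when the distance is at most
#' \code{maxRescueDistance}.
#'
#' @param anchorPos 0-based genome position of the anchored mate.
#' @param anchorStrand strand of the anchored mate ("+" or "-").
#' @param mate character scalar, the unanchored mate as sequenced.
#' @param lib the \linkS4class{ReferenceLibrary}.
#' @param params a \linkS4class{PairedParams}.
#' @param anchorLen length of the anchor read (default: length of
#'   \code{mate}).
#' @return List with \code{rescued} (logical), and when successful
#'   \code{pos} (0-based), \code{strand}, \code{distance}, \code{cigar},
#'   \code{transcript}.
#' @export
rescueMate <- function(anchorPos, anchorStrand, mate, lib, params,
                       anchorLen = NULL) {
    stopifnot(is(lib, "ReferenceLibrary"))
    mate <- normalizeDna(mate)
    len <- nchar(mate)
    if (is.null(anchorLen)) anchorLen <- len
    n <- nchar(lib@sequence)
    win <- .rescueWindow(anchorPos, anchorStrand, anchorLen, len, params, n)
    fail <- list(rescued = FALSE, pos = NA_integer_, strand = NA_character_,
                 distance = NA_integer_, cigar = NA_character_,
                 transcript = NA_character_)
    if (is.null(win)) return(fail)
    mateStrand <- if (anchorStrand == "+") "-" else "+"
    oriented <- if (mateStrand == "-") cpp_revcomp(mate) else mate
    band <- params@rescueBand

    evalOffsets <- function(offs) {
        if (!length(offs)) return(NULL)
        d <- cpp_band_dist_multi(lib@sequence, offs, oriented, band)
        ok <- !is.na(d)
        if (!any(ok)) return(NULL)
        best <- min(d[ok])
        list(pos = min(offs[ok][d[ok] == best]), distance = best)
    }

    ms <- params@seedLength
    if (is.na(ms)) ms <- max(4L, lib@m %/% 2L)
    ms <- min(ms, len)
    hit <- NULL
    if (!params@exhaustiveRescue && ms >= 4L) {
        # seed with the prefix and suffix halves of the oriented mate
        winSeq <- substring(lib@sequence, win[1L] + 1L, win[2L] + len)
        seeds <- list(c(seq = substring(oriented, 1L, ms), shift = 0L),
                      c(seq = substring(oriented, len - ms + 1L, len),
                        shift = len - ms))
        offs <- integer(0)
        for (sd in seeds) {
            mp <- Biostrings::matchPattern(sd[["seq"]],
                                           Biostrings::DNAString(winSeq))
            st <- IRanges::start(mp)
            offs <- c(offs, win[1L] + st - 1L - as.integer(sd[["shift"]]))
        }
        offs <- sort(unique(offs[offs >= win[1L] & offs <= win[2L]]))
        cand <- evalOffsets(offs)
        if (!is.null(cand) && cand$distance <= params@maxRescueDistance)
            hit <- cand
    }
    if (is.null(hit)) {
        cand <- evalOffsets(win[1L]:win[2L])
        if (!is.null(cand) && cand$distance <= params@maxRescueDistance)
            hit <- cand
    }
    if (is.null(hit)) return(fail)
    ref <- substring(lib@sequence, hit$pos + 1L, hit$pos + len)
    dp <- cpp_banded_edit(oriented, ref, band)
    list(rescued = TRUE, pos = as.integer(hit$pos), strand = mateStrand,
         distance = dp$distance, cigar = dp$cigar,
         transcript = dp$transcript)
}

# all concordant (FR, insert within bounds) combinations of two reported
# tables; returns the best by summed distance or NULL. Only "reasonable"
# candidates (Hamming distance <= ceil(frac * read length)) may form a
# concordant pair, so that an indel-bearing mate's garbage Hamming hits do
# not mask the rescue path.
.bestConcordant <- function(t1, t2, len1, len2, params) {
    keep1 <- which(t1$distance <= ceiling(params@maxAnchorMismatchFrac * len1))
    keep2 <- which(t2$distance <= ceiling(params@maxAnchorMismatchFrac * len2))
    if (!length(keep1) || !length(keep2)) return(NULL)
    cross <- expand.grid(i = keep1, j = keep2)
    a <- t1[cross$i, ]; b <- t2[cross$j, ]
    # forward mate must be leftmost; insert = reverse-mate end - forward start
    fwd1 <- a$strand == "+" & b$strand == "-"
    fwd2 <- b$strand == "+" & a$strand == "-"
    insert <- ifelse(fwd1, b$pos + len2 - a$pos,
              ifelse(fwd2, a$pos + len1 - b$pos, NA_integer_))
    ok <- !is.na(insert) & insert >= params@insertMin &
          insert <= params@insertMax &
          ifelse(fwd1, b$pos >= a$pos, a$pos >= b$pos)
    if (!any(ok)) return(NULL)
    sumd <- a$distance + b$distance
    pick <- which(ok)[order(sumd[ok], pmin(a$pos, b$pos)[ok])][1L]
    list(i = cross$i[pick], j = cross$j[pick],
         insert = as.integer(insert[pick]))
}

# single-row AlignmentResult for a rescued mate
.rescuedResult <- function(id, rescue) {
    tab <- data.frame(pos = rescue$pos, strand = rescue$strand,
                      distance = rescue$distance, hits = NA_integer_)
    new("AlignmentResult", readId = id, status = "aligned", reported = tab,
        ties = tab[c("pos", "strand")])
}

#' Align a read pair
#'
#' Both mates are first aligned independently. If some combination of their
#' "reasonable" reported candidates (Hamming distance at most
#' \code{ceil(maxAnchorMismatchFrac * read length)}) is concordant (FR
#' orientation, outer span within the insert bounds), the combination with
#' the smallest summed Hamming distance is reported; implausibly distant
#' candidates may not form a concordant pair, so an indel-bearing mate falls
#' through to rescue instead of pairing with a garbage Hamming hit. Otherwise the better-aligned mate anchors a rescue: its
#' "reasonable" candidates (hit-filtered, Hamming distance at most
#' \code{ceil(maxAnchorMismatchFrac * read length)}) are processed by
#' ascending distance and \code{\link{rescueMate}} is attempted around each;
#' the first acceptable rescue wins.
#'
#' @param r1,r2 character scalars, the two mates as sequenced.
#' @param indexes list of \linkS4class{PermutedIndex} objects.
#' @param lib the \linkS4class{ReferenceLibrary}.
#' @param params a \linkS4class{SearchParams}.
#' @param pairParams a \linkS4class{PairedParams}.
#' @param id pair identifier.
#' @return A \linkS4class{PairedResult} with status \code{"concordant"},
#'   \code{"one-rescued"}, \code{"discordant"} (at least one mate aligned,
#'   no concordant combination, rescue failed or disabled) or
#'   \code{"unaligned"}.
#' @export
alignPair <- function(r1, r2, indexes, lib, params = searchParams(),
                      pairParams = pairedParams(), id = "pair") {
    res1 <- alignRead(r1, indexes, lib, params, id = paste0(id, "/1"))
    res2 <- alignRead(r2, indexes, lib, params, id = paste0(id, "/2"))
    len1 <- nchar(r1); len2 <- nchar(r2)
    conc <- .bestConcordant(res1@reported, res2@reported, len1, len2,
                            pairParams)
    if (!is.null(conc)) {
        # promote the concordant combination to the primary reported rows
        res1@reported <- rbind(res1@reported[conc$i, ],
                               res1@reported[-conc$i, ])
        res2@reported <- rbind(res2@reported[conc$j, ],
                               res2@reported[-conc$j, ])
        rownames(res1@reported) <- rownames(res2@reported) <- NULL
        return(new("PairedResult", first = res1, second = res2,
                   status = "concordant", rescue = list()))
    }
    # rescue around the better-aligned mate
    d1 <- bestDistance(res1); d2 <- bestDistance(res2)
    anchorFirst <- !is.na(d1) && (is.na(d2) || d1 <= d2)
    anchors <- if (anchorFirst) res1 else res2
    mate <- if (anchorFirst) r2 else r1
    anchorLen <- if (anchorFirst) len1 else len2
    maxAnchor <- ceiling(pairParams@maxAnchorMismatchFrac * anchorLen)
    tab <- anchors@reported
    tab <- tab[tab$distance <= maxAnchor, , drop = FALSE]
    if (nrow(tab)) {
        for (r in seq_len(nrow(tab))) {
            resc <- rescueMate(tab$pos[r], tab$strand[r], mate, lib,
                               pairParams, anchorLen = anchorLen)
            if (resc$rescued) {
                resc$mate <- if (anchorFirst) 2L else 1L
                rr <- .rescuedResult(
                    paste0(id, if (anchorFirst) "/2" else "/1"), resc)
                if (anchorFirst) res2 <- rr else res1 <- rr
                return(new("PairedResult", first = res1, second = res2,
                           status = "one-rescued", rescue = resc))
            }
        }
    }
    status <- if (is.na(d1) && is.na(d2)) "unaligned" else "discordant"
    new("PairedResult", first = res1, second = res2, status = status,
        rescue = list())
}

#' Align a batch of read pairs
#'
#' @param reads1,reads2 named character vectors of mates, in lockstep order.
#' @inheritParams alignPair
#' @return List of \linkS4class{PairedResult} objects.
#' @export
alignPairs <- function(reads1, reads2, indexes, lib,
                       params = searchParams(),
                       pairParams = pairedParams()) {
    if (length(reads1) != length(reads2))
        stop("mate files have different numbers of reads")
    ids <- names(reads1)
    if (is.null(ids)) ids <- sprintf("pair%d", seq_along(reads1))
    res <- vector("list", length(reads1))
    for (i in seq_along(reads1))
        res[[i]] <- alignPair(reads1[[i]], reads2[[i]], indexes, lib,
                              params, pairParams, id = ids[[i]])
    names(res) <- ids
    res
}
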