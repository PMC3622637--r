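# wgsim-style synthetic genomes, haplotypes and reads with ground truth.

#' Construct a simulation configuration
#'
#' @param genomeLength reference length in bases.
#' @param nReads number of reads (or pairs) to sample.
#' @param readLength read length in bases.
#' @param mutationRate per-base probability that a haplotype position carries
#'   a planted variant.
#' @param indelFraction fraction of planted variants that are single-base
#'   indels (the rest are substitutions).
#' @param errorRate per-base sequencing mismatch probability applied to each
#'   sampled read.
#' @param insertMean,insertSd insert-size (outer fragment span) model for
#'   paired reads, truncated below at \code{readLength}.
#' @param seed integer master seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(genomeLength, nReads, readLength,
                             mutationRate = 0.001, indelFraction = 0.15,
                             errorRate = 0.02, insertMean = 300,
                             insertSd = 30, seed = 1L) {
    new("SimulationConfig", genomeLength = as.integer(genomeLength),
        nReads = as.integer(nReads), readLength = as.integer(readLength),
        mutationRate = mutationRate, indelFraction = indelFraction,
        errorRate = errorRate, insertMean = insertMean, insertSd = insertSd,
        seed = as.integer(seed))
}

#' Generate a uniform random genome
#'
#' i.i.d. uniform bases over A, C, G, T; fully reproducible from the seed.
#'
#' @param n genome length.
#' @param seed integer seed (NULL: current RNG stream).
#' @return Character scalar of length \code{n}.
#' @export
generateGenome <- function(n, seed = NULL) {
    if (n < 1L) stop("'n' must be >= 1")
    with_seed(seed,
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
              collapse = ""))
}

#' Plant variants on a haplotype
#'
#' Each reference base is independently selected as a variant site with
#' probability \code{mutationRate}; a selected site becomes a substitution
#' with probability \code{1 - indelFraction}, otherwise a single-base
#' insertion or deletion with equal odds. Insertions add one uniform base
#' immediately after the site.
#'
#' @param genome character scalar reference.
#' @param mutationRate,indelFraction rates in [0, 1].
#' @param seed integer seed.
#' @return List with elements \code{haplotype} (character scalar),
#'   \code{variants} (data.frame: \code{refPos} 0-based, \code{type} in
#'   sub/ins/del, \code{ref}, \code{alt}) and \code{refMap} (integer vector:
#'   0-based reference coordinate of every haplotype base; an inserted base
#'   inherits the coordinate of the base it follows).
#' @export
mutateHaplotype <- function(genome, mutationRate, indelFraction,
                            seed = NULL) {
    if (mutationRate < 0 || mutationRate > 1 ||
        indelFraction < 0 || indelFraction > 1)
        stop("rates must lie in [0, 1]")
    genome <- normalizeDna(genome)
    with_seed(seed, {
        n <- nchar(genome)
        bases <- strsplit(genome, "", fixed = TRUE)[[1L]]
        pieces <- bases
        site <- which(runif(n) < mutationRate)
        nv <- length(site)
        type <- character(nv)
        alt <- character(nv)
        if (nv) {
            u <- runif(nv)
            isIndel <- u < indelFraction
            # split the indel mass evenly between insertions and deletions
            type <- ifelse(isIndel, ifelse(u < indelFraction / 2, "ins", "del"),
                           "sub")
            for (v in seq_len(nv)) {
                i <- site[v]
                if (type[v] == "sub") {
                    alt[v] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]),
                                     1L)
                    pieces[i] <- alt[v]
                } else if (type[v] == "ins") {
                    alt[v] <- sample(c("A", "C", "G", "T"), 1L)
                    pieces[i] <- paste0(bases[i], alt[v])
                } else {
                    alt[v] <- ""
                    pieces[i] <- ""
                }
            }
        }
        lens <- nchar(pieces)
        refMap <- rep.int(0:(n - 1L), lens)
        list(haplotype = paste(pieces, collapse = ""),
             variants = data.frame(refPos = site - 1L, type = type,
                                   ref = bases[site], alt = alt),
             refMap = as.integer(refMap))
    })
}

# substitute a different base at each given 1-based position of read s
.plantErrors <- function(s, at) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (i in at)
        v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste(v, collapse = "")
}

#' Sample single-end reads with ground truth
#'
#' Uniform start positions and strands on the haplotype; per-base sequencing
#' mismatches at \code{errorRate}. Truth records carry the 0-based
#' \emph{reference}-coordinate start (mapped through the variant list when a
#' haplotype map is supplied), the strand, and the planted error count.
#'
#' @param haplotype character scalar to sample from (a haplotype from
#'   \code{\link{mutateHaplotype}}, or the reference itself).
#' @param n number of reads.
#' @param readLength read length.
#' @param errorRate per-base sequencing mismatch probability.
#' @param seed integer seed.
#' @param refMap optional integer vector mapping haplotype to reference
#'   coordinates (the \code{refMap} element of \code{\link{mutateHaplotype}}).
#' @return List with \code{reads} (named character vector) and \code{truth}
#'   (data.frame: \code{id}, \code{pos} 0-based reference start,
#'   \code{strand}, \code{errors}).
#' @export
sampleReads <- function(haplotype, n, readLength, errorRate = 0,
                        seed = NULL, refMap = NULL) {
    nh <- nchar(haplotype)
    if (readLength > nh) stop("readLength exceeds haplotype length")
    if (errorRate < 0 || errorRate > 1) stop("errorRate must lie in [0, 1]")
    with_seed(seed, {
        start0 <- sample.int(nh - readLength + 1L, n, replace = TRUE) - 1L
        strand <- sample(c("+", "-"), n, replace = TRUE)
        seqs <- substring(haplotype, start0 + 1L, start0 + readLength)
        seqs[strand == "-"] <- cpp_revcomp(seqs[strand == "-"])
        nerr <- rbinom(n, readLength, errorRate)
        for (i in which(nerr > 0L))
            seqs[i] <- .plantErrors(seqs[i],
                                    sample.int(readLength, nerr[i]))
        ids <- sprintf("read%d", seq_len(n))
        names(seqs) <- ids
        pos <- if (is.null(refMap)) start0 else refMap[start0 + 1L]
        list(reads = seqs,
             truth = data.frame(id = ids, pos = as.integer(pos),
                                strand = strand, errors = nerr))
    })
}

#' Sample paired-end reads with ground truth
#'
#' Fragments of length \code{insert ~ round(Normal(insertMean, insertSd))}
#' (truncated to \code{[readLength, nchar(haplotype)]}) are placed uniformly;
#' the two mates are the fragment's ends in forward/reverse orientation.
#' Which physical end becomes mate 1 is flipped with probability 1/2, as in
#' wgsim. Sequencing errors are planted per mate at \code{errorRate}.
#'
#' @inheritParams sampleReads
#' @param n number of pairs.
#' @param insertMean,insertSd insert-size model (outer span).
#' @return List with \code{reads1}, \code{reads2} (named character vectors)
#'   and \code{truth} (data.frame: \code{id}, \code{pos1}, \code{strand1},
#'   \code{pos2}, \code{strand2}, \code{insert}, \code{errors1},
#'   \code{errors2}; positions are 0-based reference starts).
#' @export
samplePairs <- function(haplotype, n, readLength, insertMean = 300,
                        insertSd = 30, errorRate = 0, seed = NULL,
                        refMap = NULL) {
    nh <- nchar(haplotype)
    if (readLength > nh) stop("readLength exceeds haplotype length")
    with_seed(seed, {
        insert <- as.integer(pmin(pmax(round(rnorm(n, insertMean, insertSd)),
                                       readLength), nh))
        frag0 <- as.integer(floor(runif(n) * (nh - insert + 1L)))
        leftStart <- frag0
        rightStart <- frag0 + insert - readLength
        left <- substring(haplotype, leftStart + 1L, leftStart + readLength)
        right <- cpp_revcomp(
            substring(haplotype, rightStart + 1L, rightStart + readLength))
        flip <- runif(n) < 0.5
        r1 <- ifelse(flip, right, left)
        r2 <- ifelse(flip, left, right)
        s1 <- ifelse(flip, "-", "+")
        s2 <- ifelse(flip, "+", "-")
        p1 <- ifelse(flip, rightStart, leftStart)
        p2 <- ifelse(flip, leftStart, rightStart)
        e1 <- rbinom(n, readLength, errorRate)
        e2 <- rbinom(n, readLength, errorRate)
        for (i in which(e1 > 0L))
            r1[i] <- .plantErrors(r1[i], sample.int(readLength, e1[i]))
        for (i in which(e2 > 0L))
            r2[i] <- .plantErrors(r2[i], sample.int(readLength, e2[i]))
        ids <- sprintf("pair%d", seq_len(n))
        names(r1) <- ids; names(r2) <- ids
        toRef <- function(x) if (is.null(refMap)) x else refMap[x + 1L]
        list(reads1 = r1, reads2 = r2,
             truth = data.frame(id = ids,
                                pos1 = as.integer(toRef(p1)), strand1 = s1,
                                pos2 = as.integer(toRef(p2)), strand2 = s2,
                                insert = insert, errors1 = e1, errors2 = e2))
    })
}

# normalize alignment output (list of AlignmentResult or long data.frame)
# into a per-id list of data.frames with pos/strand
.reportedById <- function(results) {
    if (is(results, "AlignmentResult")) results <- list(results)
    if (is.data.frame(results)) {
        if (!all(c("id", "pos", "strand") %in% names(results)))
            stop("results data.frame needs columns id, pos, strand")
        return(split(results[c("pos", "strand")], results$id))
    }
    tabs <- lapply(results, function(r) r@reported[c("pos", "strand")])
    names(tabs) <- vapply(results, readId, "")
    tabs
}

#' Evaluate recovery of the correct original location
#'
#' A read counts as correct when at least one of its reported alignments lies
#' on the truth strand within \code{tolerance} positions of the truth start
#' (indels shift coordinates slightly, hence the tolerance). Reads whose
#' truth window overlaps an N-masked stretch of the reference are excluded
#' from the denominator when the reference library is supplied.
#'
#' @param results list of \linkS4class{AlignmentResult} objects, or a long
#'   data.frame with columns \code{id}, \code{pos} (0-based), \code{strand}.
#' @param truth data.frame with columns \code{id}, \code{pos} (0-based),
#'   \code{strand}, as produced by \code{\link{sampleReads}}.
#' @param tolerance maximum absolute start-position error, in positions.
#' @param lib optional \linkS4class{ReferenceLibrary}; when given, truth
#'   windows containing N are excluded.
#' @param readLength read length used for the N-mask exclusion window.
#' @return List with \code{percent} (percentage correct among evaluated
#'   reads), \code{n}, \code{nExcluded}, and \code{counts} (correct /
#'   incorrect / unaligned).
#' @export
evaluateAlignments <- function(results, truth, tolerance = 5L, lib = NULL,
                               readLength = NULL) {
    tabs <- .reportedById(results)
    if (!all(truth$id %in% names(tabs)))
        stop("results are missing ids present in truth")
    excluded <- rep(FALSE, nrow(truth))
    if (!is.null(lib)) {
        if (is.null(readLength)) readLength <- lib@m
        win <- substring(lib@sequence, truth$pos + 1L,
                         truth$pos + readLength)
        excluded <- grepl("N", win, fixed = TRUE)
    }
    correct <- logical(nrow(truth))
    unaligned <- logical(nrow(truth))
    for (i in seq_len(nrow(truth))) {
        tab <- tabs[[truth$id[i]]]
        tab <- tab[!is.na(tab$pos), , drop = FALSE]
        if (nrow(tab) == 0L) { unaligned[i] <- TRUE; next }
        correct[i] <- any(tab$strand == truth$strand[i] &
                          abs(tab$pos - truth$pos[i]) <= tolerance)
    }
    keep <- !excluded
    nEval <- sum(keep)
    list(percent = if (nEval) 100 * sum(correct[keep]) / nEval else NA_real_,
         n = nEval, nExcluded = sum(excluded),
         counts = c(correct = sum(correct[keep]),
                    incorrect = sum(keep & !correct & !unaligned),
                    unaligned = sum(unaligned[keep])))
}
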