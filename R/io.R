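# Standard-format I/O: FASTA references, FASTQ reads, SAM output, truth
# tables.

#' Read a reference FASTA into concatenated coordinates
#'
#' Multi-sequence references are concatenated into the single internal
#' reference string, separated by runs of N at least as long as any M-mer,
#' so no M-mer ever spans two sequences; the returned coordinate map takes
#' concatenated positions back to (sequence name, offset). Sequences are
#' case-folded and non-ACGTN characters become N.
#'
#' @param path FASTA file (plain or gzip; parsed by Biostrings).
#' @param spacer length of the N spacer between sequences; must be at least
#'   the M-mer length used downstream.
#' @return List with \code{sequence} (character scalar) and \code{map}
#'   (data.frame: \code{name}, \code{length}, \code{offset} 0-based).
#' @export
readReferenceFasta <- function(path, spacer = 100L) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop("no sequences in ", path)
    seqs <- normalizeDna(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    lens <- nchar(seqs)
    offsets <- cumsum(c(0L, head(lens + spacer, -1L)))
    list(sequence = paste(seqs, collapse = strrep("N", spacer)),
         map = data.frame(name = names(seqs), length = as.integer(lens),
                          offset = as.integer(offsets)))
}

#' Write a genome FASTA
#'
#' @param sequence character scalar (or named character vector of
#'   sequences).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGenomeFasta <- function(sequence, path) {
    if (is.null(names(sequence)))
        names(sequence) <- sprintf("seq%d", seq_along(sequence))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequence), path)
    invisible(path)
}

#' Read FASTQ reads
#'
#' Order-preserving; identifiers are the first whitespace-delimited token.
#' Base qualities are not used by the aligner and are dropped.
#'
#' @param path FASTQ file (plain or gzip).
#' @return Named character vector of normalized read sequences.
#' @export
readFastqReads <- function(path) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    reads <- normalizeDna(as.character(ss))
    names(reads) <- sub("\\s.*$", "", names(ss))
    reads
}

#' Read a FASTQ pair in lockstep
#'
#' @param path1,path2 mate FASTQ files.
#' @return List with \code{reads1}, \code{reads2}; identifiers (after
#'   stripping a trailing \code{/1} or \code{/2}) must agree pairwise.
#' @export
readFastqPairs <- function(path1, path2) {
    r1 <- readFastqReads(path1)
    r2 <- readFastqReads(path2)
    if (length(r1) != length(r2))
        stop("mate files differ in read count")
    core <- function(x) sub("/[12]$", "", names(x))
    bad <- which(core(r1) != core(r2))
    if (length(bad))
        stop("mate id mismatch at record ", bad[1L], ": '",
             names(r1)[bad[1L]], "' vs '", names(r2)[bad[1L]], "'")
    list(reads1 = r1, reads2 = r2)
}

#' Write reads as FASTQ
#'
#' @param reads named character vector.
#' @param path output path.
#' @param quality single quality character used for every base (placeholder;
#'   the simulator does not model qualities).
#' @return The path, invisibly.
#' @export
writeReadsFastq <- function(reads, path, quality = "I") {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    lines <- character(4L * length(reads))
    lines[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", ids)
    lines[seq(2L, by = 4L, length.out = length(reads))] <- unname(reads)
    lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
    lines[seq(4L, by = 4L, length.out = length(reads))] <-
        strrep(quality, nchar(reads))
    writeLines(lines, path)
    invisible(path)
}

#' Write and read ground-truth tables
#'
#' Tab-separated truth records with user-facing 1-based positions:
#' columns \code{id}, \code{chrom}, \code{pos}, \code{strand} plus any extra
#' columns present. \code{readTruthTable} converts positions back to the
#' package's internal 0-based convention.
#'
#' @param truth data.frame as produced by \code{\link{sampleReads}} (0-based
#'   \code{pos}).
#' @param path file path.
#' @param chrom chromosome name recorded for every row.
#' @return \code{readTruthTable} returns the data.frame with 0-based
#'   \code{pos}.
#' @export
writeTruthTable <- function(truth, path, chrom = "ref") {
    out <- truth
    out$chrom <- chrom
    out$pos <- out$pos + 1L
    front <- intersect(c("id", "chrom", "pos", "strand"), names(out))
    out <- out[c(front, setdiff(names(out), front))]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
    out <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    out$pos <- as.integer(out$pos) - 1L
    out
}

# concatenated 0-based position -> list(rname, pos1) via the reference map
.mapCoord <- function(pos, map) {
    i <- findInterval(pos, map$offset)
    list(rname = map$name[i], pos1 = pos - map$offset[i] + 1L)
}

.samHeader <- function(map, extra = NULL) {
    c("@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", map$name, map$length),
      paste0("@PG\tID:permalign\tPN:permalign\tVN:",
             as.character(utils::packageVersion("permalign")),
             if (!is.null(extra)) paste0("\tCL:", extra)))
}

# one SAM line
.samLine <- function(qname, flag, rname, pos1, mapq, cigar, rnext, pnext,
                     tlen, seq, qual, nm) {
    base <- paste(qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen,
                  seq, qual, sep = "\t")
    if (is.na(nm)) base else paste0(base, "\tNM:i:", nm)
}

# records for one AlignmentResult (single-end); seq given in sequencing
# orientation
.samRecordsSingle <- function(res, seq, map, flagBase = 0L, mateInfo = NULL) {
    tab <- res@reported
    if (nrow(tab) == 0L) {
        flag <- bitwOr(flagBase, 4L)
        return(.samLine(res@readId, flag, "*", 0L, 0L, "*", "*", 0L, 0L,
                        seq, "*", NA_integer_))
    }
    out <- character(nrow(tab))
    for (r in seq_len(nrow(tab))) {
        flag <- flagBase
        if (tab$strand[r] == "-") flag <- bitwOr(flag, 16L)
        if (r > 1L) flag <- bitwOr(flag, 256L)
        cc <- .mapCoord(tab$pos[r], map)
        cigar <- if (!is.null(tab$cigar) && !is.na(tab$cigar[r]))
            tab$cigar[r] else paste0(nchar(seq), "M")
        sq <- if (r > 1L) "*"
              else if (tab$strand[r] == "-") reverseComplement(seq) else seq
        rnext <- "*"; pnext <- 0L; tlen <- 0L
        if (!is.null(mateInfo) && r == 1L) {
            rnext <- mateInfo$rnext; pnext <- mateInfo$pnext
            tlen <- mateInfo$tlen
        }
        out[r] <- .samLine(res@readId, flag, cc$rname, cc$pos1, 255L, cigar,
                           rnext, pnext, tlen, sq, if (sq == "*") "*" else
                           strrep("I", nchar(sq)), tab$distance[r])
    }
    out
}

#' Write single-end alignments as SAM
#'
#' Emits a valid SAM file: @HD/@SQ/@PG header, 1-based positions through the
#' reference map, strand and secondary-alignment flags, full-length-match
#' CIGARs for Hamming alignments and the \code{NM} tag carrying the
#' distance. Up to \code{maxReport - 1} non-primary candidates per read are
#' written as secondary records.
#'
#' @param results list of \linkS4class{AlignmentResult}.
#' @param reads named character vector of the read sequences (sequencing
#'   orientation), aligned-orientation SEQ is derived per record.
#' @param map reference map data.frame (\code{name}, \code{length},
#'   \code{offset}).
#' @param path output path.
#' @param commandLine optional string recorded in the @PG line.
#' @return The path, invisibly.
#' @export
writeSam <- function(results, reads, map, path, commandLine = NULL) {
    if (is(results, "AlignmentResult")) results <- list(results)
    lines <- vector("list", length(results))
    for (i in seq_along(results)) {
        res <- results[[i]]
        lines[[i]] <- .samRecordsSingle(res, unname(reads[[res@readId]]), map)
    }
    writeLines(c(.samHeader(map, commandLine), unlist(lines)), path)
    invisible(path)
}

#' Write paired-end alignments as SAM
#'
#' As \code{\link{writeSam}}, with paired flags: first/second-in-pair,
#' mate strand and position fields, proper-pair for concordant and rescued
#' pairs, and signed TLEN (outer span). A rescued mate's CIGAR is the edit
#' transcript of the rescue.
#'
#' @param results list of \linkS4class{PairedResult}.
#' @param reads1,reads2 named character vectors of mate sequences.
#' @inheritParams writeSam
#' @return The path, invisibly.
#' @export
writeSamPaired <- function(results, reads1, reads2, map, path,
                           commandLine = NULL) {
    if (is(results, "PairedResult")) results <- list(results)
    out <- vector("list", length(results))
    for (i in seq_along(results)) {
        pr <- results[[i]]
        proper <- pr@status %in% c("concordant", "one-rescued")
        # attach rescue CIGAR to the rescued mate's reported table
        if (length(pr@rescue) && isTRUE(pr@rescue$rescued)) {
            if (pr@rescue$mate == 1L)
                pr@first@reported$cigar <- pr@rescue$cigar
            else
                pr@second@reported$cigar <- pr@rescue$cigar
        }
        mates <- list(pr@first, pr@second)
        seqs <- c(reads1[[i]], reads2[[i]])
        flagBase <- c(bitwOr(1L, 64L), bitwOr(1L, 128L))
        recs <- character(0)
        for (w in 1:2) {
            me <- mates[[w]]; other <- mates[[3L - w]]
            fb <- flagBase[[w]]
            if (proper) fb <- bitwOr(fb, 2L)
            mi <- NULL
            if (nrow(other@reported)) {
                oc <- .mapCoord(other@reported$pos[1L], map)
                if (other@reported$strand[1L] == "-")
                    fb <- bitwOr(fb, 32L)
                tlen <- 0L
                if (nrow(me@reported) && nrow(other@reported)) {
                    myPos <- me@reported$pos[1L]
                    otPos <- other@reported$pos[1L]
                    lens <- nchar(seqs)
                    left <- min(myPos, otPos)
                    right <- max(myPos + lens[w], otPos + lens[3L - w])
                    tlen <- if (myPos <= otPos) right - left
                            else -(right - left)
                }
                mi <- list(rnext = "=", pnext = oc$pos1, tlen = tlen)
            } else {
                fb <- bitwOr(fb, 8L)
            }
            recs <- c(recs, .samRecordsSingle(me, seqs[[w]], map, fb, mi))
        }
        out[[i]] <- recs
    }
    writeLines(c(.samHeader(map, commandLine), unlist(out)), path)
    invisible(path)
}

#' Parse a SAM file back into an alignment table
#'
#' Conversion and parsing go through Rsamtools (htslib), so reading also
#' validates the file against an independent SAM implementation.
#'
#' @param path SAM file.
#' @param map optional reference map; when given, positions are returned in
#'   concatenated 0-based coordinates (matching the aligner's internal
#'   convention), otherwise per-sequence 0-based positions.
#' @return data.frame with columns \code{id}, \code{rname}, \code{pos}
#'   (0-based), \code{strand}, \code{distance} (NM tag), \code{flag},
#'   \code{primary}; unmapped records carry NA position.
#' @export
readSamResults <- function(path, map = NULL) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "strand"), tag = "NM",
        flag = Rsamtools::scanBamFlag())
    x <- Rsamtools::scanBam(bam, param = p)[[1L]]
    pos0 <- x$pos - 1L
    rname <- as.character(x$rname)
    if (!is.null(map)) {
        off <- setNames(map$offset, map$name)
        pos0 <- ifelse(is.na(pos0), NA_integer_,
                       pos0 + off[rname])
    }
    data.frame(id = x$qname, rname = rname,
               pos = as.integer(pos0),
               strand = as.character(x$strand),
               distance = if (is.null(x$tag$NM)) NA_integer_ else x$tag$NM,
               flag = x$flag,
               primary = bitwAnd(x$flag, 256L) == 0L)
}
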