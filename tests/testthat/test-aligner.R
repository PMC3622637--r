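test_that("candidate collection matches a naive re-run of the search", {
    lib <- toy_lib()
    idx <- toy_idx8()
    set.seed(31)
    sp <- searchParams(j = 4, k = 6)
    for (trial in 1:10) {
        read <- random_dna(15)
        cands <- collectCandidates(read, idx, sp)
        # naive re-execution with the same permutations
        naive <- list()
        for (jj in 1:4) {
            p <- indexPermutation(idx[[jj]])
            pstrs <- vapply(libraryMmer(lib, indexOrder(idx[[jj]])),
                            function(s) applyPermutation(p, s), "",
                            USE.NAMES = FALSE)
            for (s in c("+", "-")) {
                q <- applyPermutation(p, if (s == "+") read
                                         else reverseComplement(read))
                rank <- sum(pstrs < q)
                lo <- max(0L, rank - 6L); hi <- min(length(pstrs) - 1L,
                                                    rank + 6L)
                hits <- indexOrder(idx[[jj]])[(lo + 1L):(hi + 1L)]
                naive[[length(naive) + 1L]] <-
                    data.frame(pos = as.integer(hits), strand = s)
            }
        }
        naive <- do.call(rbind, naive)
        agg <- aggregate(list(hits = rep(1L, nrow(naive))),
                         naive[c("pos", "strand")], sum)
        got <- candidateTable(cands)
        got <- got[order(got$pos, got$strand), ]
        agg <- agg[order(agg$pos, agg$strand), ]
        expect_equal(got$pos, agg$pos)
        expect_equal(got$strand, agg$strand)
        expect_equal(got$hits, agg$hits)
    }
})

test_that("an exact copy of a reference M-mer is hit by every iteration", {
    lib <- toy_lib()
    idx <- toy_idx8()
    for (j in c(1L, 4L, 8L)) {
        cands <- collectCandidates(libraryMmer(lib, 5000L), idx,
                                   searchParams(j = j, k = 3))
        tab <- candidateTable(cands)
        expect_identical(tab$hits[tab$pos == 5000L & tab$strand == "+"], j)
        expect_lte(nrow(tab), j * 7L * 2L)     # <= j (2k+1) strands
    }
    empty <- collectCandidates(libraryMmer(lib, 5000L), idx,
                               searchParams(j = 0))
    expect_identical(nrow(candidateTable(empty)), 0L)
    expect_error(collectCandidates("ACGT", idx, searchParams(j = 1)),
                 "length")
})

test_that("hit-count filtration keeps exactly the multi-hit candidates", {
    lib <- toy_lib()
    idx <- toy_idx8()
    read <- libraryMmer(lib, 777L)
    cands <- collectCandidates(read, idx, searchParams(j = 8, k = 10))
    expect_identical(candidateTable(filterByHits(cands, 1L)),
                     candidateTable(cands))
    tab <- candidateTable(cands)
    for (mh in c(2L, 4L)) {
        keep <- candidateTable(filterByHits(cands, mh))
        want <- tab[tab$hits >= mh, ]
        rownames(want) <- NULL
        expect_identical(keep, want)            # recount oracle
    }
    expect_identical(nrow(candidateTable(filterByHits(cands, 9L))), 0L)
    expect_error(filterByHits(cands, 0L), "minHits")
})

test_that("ranking reports the brute-force argmin with deterministic ties", {
    lib <- toy_lib()
    idx <- toy_idx8()
    sp <- searchParams(j = 8, k = 10, maxReport = 4)
    set.seed(32)
    for (trial in 1:10) {
        read <- random_dna(15)
        cands <- collectCandidates(read, idx, sp)
        res <- rankCandidates(read, cands, lib, sp)
        tab <- candidateTable(cands)
        d <- integer(nrow(tab))
        for (r in seq_len(nrow(tab)))
            d[r] <- hammingDistance(if (tab$strand[r] == "+") read
                                    else reverseComplement(read),
                                    libraryMmer(lib, tab$pos[r]))
        expect_identical(bestDistance(res), min(d))       # brute-force min
        expect_identical(nrow(res@ties), sum(d == min(d)))
        expect_lte(nrow(reported(res)), 4L)
        expect_false(is.unsorted(reported(res)$distance))
    }
    emptyRes <- rankCandidates("ACGTACGTACGTACG",
                               collectCandidates("ACGTACGTACGTACG", toy_idx8(),
                                                 searchParams(j = 0)),
                               lib, sp)
    expect_identical(alignmentStatus(emptyRes), "unaligned")
    expect_true(is.na(bestPosition(emptyRes)))
})

test_that("a planted copy aligns to its origin at distance 0", {
    lib <- toy_lib()
    idx <- toy_idx8()
    res <- alignRead(libraryMmer(lib, 12345L), idx, lib,
                     searchParams(j = 2, k = 1), id = "copy")
    expect_identical(alignmentStatus(res), "aligned")
    expect_identical(bestPosition(res), 12345L)
    expect_identical(bestStrand(res), "+")
    expect_identical(bestDistance(res), 0L)
})

test_that("per-read search cost stays within the J (log N + K) budget", {
    lib <- toy_lib()
    idx <- toy_idx8()
    n <- length(libPositions(lib))
    set.seed(33)
    for (j in c(2L, 8L)) {
        res <- alignRead(random_dna(15), idx, lib, searchParams(j = j, k = 4))
        # two strands, each search costing at most ceil(log2 n) + 1
        expect_lte(attr(res, "comparisons"),
                   2 * j * (ceiling(log2(n)) + 1))
    }
})

test_that("candidate sets grow monotonically in J and K", {
    lib <- toy_lib()
    idx <- toy_idx8()
    set.seed(34)
    reads <- replicate(15, random_dna(15))
    keyify <- function(cs) {
        tab <- candidateTable(cs)
        paste(tab$pos, tab$strand)
    }
    for (read in reads) {
        small <- collectCandidates(read, idx, searchParams(j = 3, k = 5))
        bigJ <- collectCandidates(read, idx, searchParams(j = 8, k = 5))
        bigK <- collectCandidates(read, idx, searchParams(j = 3, k = 12))
        expect_true(all(keyify(small) %in% keyify(bigJ)))
        expect_true(all(keyify(small) %in% keyify(bigK)))
    }
})

test_that("alignment is deterministic for fixed seeds and parameters", {
    lib <- toy_lib()
    set.seed(35)
    reads <- setNames(replicate(10, random_dna(15)),
                      sprintf("r%d", 1:10))
    idxA <- buildIndexes(lib, 4, seed = 777)
    idxB <- buildIndexes(lib, 4, seed = 777)
    sp <- searchParams(j = 4, k = 8)
    resA <- alignReads(reads, idxA, lib, sp)
    resB <- alignReads(reads, idxB, lib, sp)
    expect_identical(resultsTable(resA), resultsTable(resB))
})

test_that("sliding windows reuse one index with offset-adjusted votes", {
    lib <- toy_lib()
    idx <- toy_idx8()[[1L]]
    g <- toy_genome()
    sp <- searchParams(j = 1, k = 4)

    # read of length m: identical to a single search in that index
    read15 <- substring(g, 2001, 2015)
    expect_identical(candidateTable(slidingWindowSearch(read15, idx, sp)),
                     candidateTable(collectCandidates(read15, idx, sp)))

    # exact 30-base copy: both windows vote for the same start
    read30 <- substring(g, 4001, 4030)
    cs <- slidingWindowSearch(read30, idx, sp, stride = 15L)
    tab <- candidateTable(cs)
    expect_gte(tab$hits[tab$pos == 4000L & tab$strand == "+"], 2L)

    # naive per-window oracle with offset adjustment, both strands
    set.seed(36)
    for (trial in 1:5) {
        read <- random_dna(40)
        stride <- 7L
        cs <- slidingWindowSearch(read, idx, sp, stride = stride)
        offs <- unique(c(seq(0L, 25L, by = stride), 25L))
        naive <- list()
        for (o in offs) {
            win <- substring(read, o + 1L, o + 15L)
            wtab <- candidateTable(collectCandidates(win, idx, sp))
            adj <- ifelse(wtab$strand == "+", wtab$pos - o,
                          wtab$pos + o + 15L - 40L)
            ok <- adj >= 0 & adj <= nchar(g) - 40L
            naive[[length(naive) + 1L]] <-
                data.frame(pos = as.integer(adj[ok]), strand = wtab$strand[ok])
        }
        naive <- do.call(rbind, naive)
        agg <- aggregate(list(hits = rep(1L, nrow(naive))),
                         naive[c("pos", "strand")], sum)
        agg <- agg[order(agg$pos, agg$strand), ]
        got <- candidateTable(cs)
        expect_equal(got$pos, agg$pos)
        expect_equal(got$hits, agg$hits)
    }
    expect_error(slidingWindowSearch("ACGT", idx, sp), "shorter")
})
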