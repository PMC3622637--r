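test_that("banded edit distance agrees with unbanded DP", {
    r <- boundedEditDistance("ACGTAC", "ACGTAC", band = 2)
    expect_identical(r$distance, 0L)
    expect_identical(r$transcript, "MMMMMM")
    expect_identical(r$cigar, "6M")

    r <- boundedEditDistance("ACGTACGT", "ACGACGT", band = 2)
    expect_identical(r$distance, 1L)
    expect_identical(sum(strsplit(r$transcript, "")[[1L]] == "I"), 1L)

    # full-band agreement with an independent Levenshtein implementation
    set.seed(51)
    for (trial in 1:40) {
        a <- random_dna(sample(5:40, 1))
        b <- random_dna(sample(5:40, 1))
        want <- as.integer(adist(a, b))
        got <- boundedEditDistance(a, b, band = max(nchar(a), nchar(b)))
        expect_identical(got$distance, want)
        # transcript is consistent: ops consume both strings fully and the
        # non-match ops count the distance
        ops <- strsplit(got$transcript, "")[[1L]]
        expect_identical(sum(ops %in% c("M", "X", "I")), nchar(a))
        expect_identical(sum(ops %in% c("M", "X", "D")), nchar(b))
        expect_identical(sum(ops %in% c("X", "I", "D")), got$distance)
    }

    # banded result is exact whenever the true distance fits in the band
    set.seed(52)
    for (trial in 1:20) {
        a <- random_dna(50)
        v <- strsplit(a, "")[[1L]]
        v <- v[-sample.int(50, 1)]              # one deletion
        b <- paste(v, collapse = "")
        want <- as.integer(adist(a, b))
        expect_identical(boundedEditDistance(a, b, band = 3)$distance, want)
    }
    expect_error(boundedEditDistance("A", "A", band = -1), "band")
})

test_that("mate rescue finds planted mates inside the insert window", {
    set.seed(53)
    g <- generateGenome(30000, seed = 54)
    lib <- buildLibrary(g, 100)
    pp <- pairedParams(insertMin = 150, insertMax = 350, rescueBand = 5,
                       maxRescueDistance = 6)
    for (trial in 1:20) {
        anchor <- sample(0:(30000 - 400), 1)
        insert <- sample(160:340, 1)
        mateStart <- anchor + insert - 100L
        mate <- reverseComplement(substring(g, mateStart + 1, mateStart + 100))
        r <- rescueMate(anchor, "+", mate, lib, pp)
        expect_true(r$rescued)
        expect_identical(r$pos, as.integer(mateStart))
        expect_identical(r$strand, "-")
        expect_identical(r$distance, 0L)
        expect_identical(r$cigar, "100M")
        # rescue never reports outside the stated window
        expect_gte(r$pos, anchor + 150 - 100 - 5)
        expect_lte(r$pos, anchor + 350 - 100 + 5)
    }

    # a planted 1-base deletion is recovered at the true locus with the
    # unbanded edit distance
    for (trial in 1:20) {
        anchor <- sample(0:(30000 - 400), 1)
        insert <- sample(160:340, 1)
        mateStart <- anchor + insert - 100L
        win <- substring(g, mateStart + 1, mateStart + 101)
        d <- sample(5:95, 1)
        mateFwd <- paste0(substr(win, 1, d - 1), substr(win, d + 1, 101))
        r <- rescueMate(anchor, "+", reverseComplement(mateFwd), lib, pp)
        expect_true(r$rescued)
        expect_lte(abs(r$pos - mateStart), 5L)
        ref <- substring(g, r$pos + 1, r$pos + 100)
        expect_identical(r$distance, as.integer(adist(mateFwd, ref)))
    }

    # a random string is not rescued at a small distance budget
    r <- rescueMate(1000L, "+", random_dna(100), lib, pp)
    expect_false(r$rescued)

    # empty window (anchor at the extreme end)
    r <- rescueMate(29990L, "+", random_dna(100), lib, pp)
    expect_false(r$rescued)
})

test_that("with band 0 and no indels rescue reduces to Hamming distance", {
    g <- generateGenome(5000, seed = 55)
    lib <- buildLibrary(g, 50)
    pp <- pairedParams(insertMin = 100, insertMax = 200, rescueBand = 0,
                       maxRescueDistance = 10)
    set.seed(56)
    anchor <- 2000L
    mateStart <- 2100L
    v <- strsplit(substring(g, mateStart + 1, mateStart + 50), "")[[1L]]
    at <- sample.int(50, 3)
    for (a in at) v[a] <- sample(setdiff(c("A", "C", "G", "T"), v[a]), 1L)
    mateFwd <- paste(v, collapse = "")
    r <- rescueMate(anchor, "+", reverseComplement(mateFwd), lib,
                    pp, anchorLen = 50L)
    expect_true(r$rescued)
    expect_identical(r$distance,
                     hammingDistance(mateFwd,
                                     substring(g, r$pos + 1, r$pos + 50)))
})

test_that("error-free pairs are concordant at the truth with summed distance 0", {
    g <- generateGenome(30000, seed = 57)
    lib <- buildLibrary(g, 100)
    idx <- buildIndexes(lib, 4, seed = 58)
    sim <- samplePairs(g, 25, 100, insertMean = 250, insertSd = 25,
                       errorRate = 0, seed = 59)
    sp <- searchParams(j = 4, k = 10)
    pp <- pairedParams(insertMin = 150, insertMax = 350)
    res <- alignPairs(sim$reads1, sim$reads2, idx, lib, sp, pp)
    for (i in seq_along(res)) {
        pr <- res[[i]]
        expect_identical(alignmentStatus(pr), "concordant")
        expect_identical(bestPosition(pr@first), sim$truth$pos1[i])
        expect_identical(bestStrand(pr@first), sim$truth$strand1[i])
        expect_identical(bestPosition(pr@second), sim$truth$pos2[i])
        expect_identical(bestDistance(pr@first) + bestDistance(pr@second), 0L)
        # concordance geometry: outer span within bounds, FR orientation
        left <- min(bestPosition(pr@first), bestPosition(pr@second))
        right <- max(bestPosition(pr@first), bestPosition(pr@second)) + 100L
        expect_gte(right - left, 150L)
        expect_lte(right - left, 350L)
    }
})

test_that("concordance selection equals a brute-force cross-product check", {
    fx <- pairs_fixture()
    sim <- samplePairs(fx$genome, 30, 100, insertMean = 250, insertSd = 25,
                       errorRate = 0.02, seed = 61)
    res <- alignPairs(sim$reads1, sim$reads2, fx$idx, fx$lib,
                      fx$sparams, fx$pparams)
    for (i in seq_along(res)) {
        pr <- res[[i]]
        r1 <- alignRead(sim$reads1[[i]], fx$idx, fx$lib, fx$sparams)
        r2 <- alignRead(sim$reads2[[i]], fx$idx, fx$lib, fx$sparams)
        t1 <- reported(r1); t2 <- reported(r2)
        thr <- ceiling(0.1 * 100)
        found <- FALSE
        for (a in seq_len(nrow(t1))) for (b in seq_len(nrow(t2))) {
            if (t1$distance[a] > thr || t2$distance[b] > thr) next
            if (t1$strand[a] == "+" && t2$strand[b] == "-" &&
                t2$pos[b] >= t1$pos[a]) {
                span <- t2$pos[b] + 100 - t1$pos[a]
                if (span >= 150 && span <= 350) found <- TRUE
            }
            if (t2$strand[b] == "+" && t1$strand[a] == "-" &&
                t1$pos[a] >= t2$pos[b]) {
                span <- t1$pos[a] + 100 - t2$pos[b]
                if (span >= 150 && span <= 350) found <- TRUE
            }
        }
        expect_identical(alignmentStatus(pr) == "concordant", found)
    }
})

test_that("wide-open insert bounds degenerate to single-end alignment", {
    g <- generateGenome(20000, seed = 62)
    lib <- buildLibrary(g, 100)
    idx <- buildIndexes(lib, 3, seed = 63)
    sim <- samplePairs(g, 10, 100, errorRate = 0, seed = 64)
    sp <- searchParams(j = 3, k = 10)
    # rescue disabled via a negative reasonableness threshold
    pp <- pairedParams(insertMin = 0, insertMax = nchar(g),
                       maxAnchorMismatchFrac = -1)
    res <- alignPairs(sim$reads1, sim$reads2, idx, lib, sp, pp)
    for (i in seq_along(res)) {
        pr <- res[[i]]
        s1 <- alignRead(sim$reads1[[i]], idx, lib, sp)
        s2 <- alignRead(sim$reads2[[i]], idx, lib, sp)
        expect_identical(bestPosition(pr@first), bestPosition(s1))
        expect_identical(bestDistance(pr@first), bestDistance(s1))
        expect_identical(bestPosition(pr@second), bestPosition(s2))
    }
})
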