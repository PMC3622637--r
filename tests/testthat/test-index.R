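test_that("buildLibrary lists exactly the N-free M-mer starts", {
    lib <- toy_lib()
    expect_identical(length(libPositions(lib)), 19986L)  # N - M + 1
    expect_identical(length(libPositions(buildLibrary("ACGTACG", 7))), 1L)
    expect_error(buildLibrary("ACGT", 5), "shorter")

    # internal N run: compare with a direct per-position scan
    set.seed(11)
    g <- paste0(random_dna(60), "NNN", random_dna(40), "N", random_dna(30))
    m <- 8L
    lib2 <- buildLibrary(g, m)
    scan <- which(!vapply(seq_len(nchar(g) - m + 1L), function(i)
        grepl("N", substring(g, i, i + m - 1L), fixed = TRUE), TRUE)) - 1L
    expect_identical(libPositions(lib2), as.integer(scan))
})

test_that("a permuted index is the lexicographic sort of permuted M-mers", {
    set.seed(12)
    g <- random_dna(200)
    lib <- buildLibrary(g, 10)
    # identity permutation: order equals plain sort of the explicit strings
    idx <- buildIndex(lib, identityPermutation(10))
    strs <- libraryMmer(lib, libPositions(lib))
    expect_identical(as.integer(indexOrder(idx)),
                     libPositions(lib)[order(strs, libPositions(lib),
                                             method = "radix")])
    # random permutation: sort explicitly permuted strings as oracle
    p <- randomPermutation(10, seed = 3)
    idx2 <- buildIndex(lib, p)
    pstrs <- vapply(strs, function(s) applyPermutation(p, s), "")
    expect_identical(as.integer(indexOrder(idx2)),
                     libPositions(lib)[order(pstrs, libPositions(lib),
                                             method = "radix")])
    expect_identical(length(indexOrder(idx2)), length(libPositions(lib)))
    expect_error(buildIndex(lib, identityPermutation(9)), "length")
})

test_that("index construction stays within the sorting comparison budget", {
    set.seed(13)
    g <- random_dna(520)
    lib <- buildLibrary(g, 12)
    idx <- buildIndex(lib, randomPermutation(12, seed = 1))
    n <- length(libPositions(lib))
    ncmp <- attr(indexOrder(idx), "comparisons")
    expect_true(is.numeric(ncmp) && ncmp > 0)
    expect_lt(ncmp, 3 * n * log2(n))
})

test_that("lexicographicPosition matches a linear scan and is O(log N)", {
    lib <- toy_lib()
    p <- randomPermutation(15, seed = 21)
    idx <- buildIndex(lib, p)
    pstrs <- vapply(libraryMmer(lib, indexOrder(idx)),
                    function(s) applyPermutation(p, s), "",
                    USE.NAMES = FALSE)
    expect_false(is.unsorted(pstrs))          # sortedness of the index
    set.seed(22)
    queries <- c(pstrs[1L], pstrs[length(pstrs)], "TTTTTTTTTTTTTTT",
                 replicate(20, random_dna(15)))
    for (q in queries) {
        r <- lexicographicPosition(idx, q)
        expect_identical(as.integer(r), sum(pstrs < q))
        expect_lte(attr(r, "comparisons"),
                   ceiling(log2(length(pstrs))) + 1L)
    }
    expect_identical(as.integer(lexicographicPosition(idx, pstrs[1L])), 0L)
})

test_that("neighborhoods are clamped windows of the sorted array", {
    lib <- toy_lib()
    idx <- toy_idx8()[[1L]]
    ord <- indexOrder(idx)
    n <- length(ord)
    expect_identical(neighborhood(idx, 1000L, 2L), ord[999:1003])  # 2K+1
    expect_identical(neighborhood(idx, 0L, 3L), ord[1:4])          # clamped
    expect_identical(neighborhood(idx, n, 2L), ord[(n - 1):n])
    expect_identical(neighborhood(idx, 5L, 0L), ord[6L])
    expect_error(neighborhood(idx, -1L, 2L), "rank")
})

test_that("prefix neighborhoods equal a full scan over permuted M-mers", {
    set.seed(23)
    g <- random_dna(500)
    lib <- buildLibrary(g, 12)
    p <- randomPermutation(12, seed = 8)
    idx <- buildIndex(lib, p)
    pstrs <- vapply(libraryMmer(lib, libPositions(lib)),
                    function(s) applyPermutation(p, s), "",
                    USE.NAMES = FALSE)
    q <- applyPermutation(p, libraryMmer(lib, libPositions(lib)[37L]))
    expect_setequal(prefixNeighborhood(idx, q, 0L), libPositions(lib))
    for (l in c(2L, 4L, 12L)) {
        want <- libPositions(lib)[substring(pstrs, 1L, l) ==
                                  substring(q, 1L, l)]
        expect_setequal(prefixNeighborhood(idx, q, l), want)
    }
    expect_error(prefixNeighborhood(idx, q, 13L), "0..m")
})

test_that("resolution length is the minimal separating prefix", {
    set.seed(24)
    g <- random_dna(400)
    lib <- buildLibrary(g, 10)
    p <- randomPermutation(10, seed = 2)
    idx <- buildIndex(lib, p)
    pos <- libPositions(lib)
    # K >= library size: the empty prefix already qualifies
    expect_identical(resolutionLength(idx, pos[5L], length(pos)), 0L)
    # minimality: the (L-1)-prefix neighborhood must exceed K
    for (i in pos[seq(1, length(pos), by = 40)]) {
        for (k in c(1L, 3L, 10L)) {
            L <- resolutionLength(idx, i, k)
            q <- applyPermutation(p, libraryMmer(lib, i))
            if (L <= 10L) {
                expect_lte(length(prefixNeighborhood(idx, q, L)), k)
                if (L >= 1L)
                    expect_gt(length(prefixNeighborhood(idx, q, L - 1L)), k)
            } else {
                # sentinel: even the full M-mer is shared by more than k
                expect_gt(length(prefixNeighborhood(idx, q, 10L)), k)
            }
        }
    }
    # duplicated M-mer: no prefix separates identical strings
    core <- random_dna(40)
    dup <- buildLibrary(paste0(core, core), 10)
    dupIdx <- buildIndex(dup, randomPermutation(10, seed = 4))
    expect_identical(resolutionLength(dupIdx, 0L, 1L), 11L)  # sentinel m+1
    expect_error(resolutionLength(idx, 399L, 1L), "library position")
})

test_that("an exact-match read is always located (completeness)", {
    lib <- toy_lib()
    idx <- toy_idx8()[[2L]]
    set.seed(25)
    for (i in sample(libPositions(lib), 50)) {
        q <- applyPermutation(indexPermutation(idx), libraryMmer(lib, i))
        r <- lexicographicPosition(idx, q)
        expect_true(i %in% neighborhood(idx, as.integer(r), 0L))
    }
})

test_that("indexes rebuild bit-for-bit from reference plus manifest", {
    lib <- toy_lib()
    idx <- toy_idx8()[[1L]]
    mpath <- withr::local_tempfile(fileext = ".txt")
    writePermutationManifest(indexPermutation(idx), mpath, seed = idx@seed)
    perm <- readPermutationManifest(mpath)[[1L]]
    rebuilt <- buildIndex(lib, perm)
    expect_identical(as.integer(indexOrder(rebuilt)),
                     as.integer(indexOrder(idx)))

    ipath <- withr::local_tempfile(fileext = ".idx")
    writeIndex(idx, ipath)
    back <- readIndex(ipath, lib)
    expect_identical(as.integer(indexOrder(back)),
                     as.integer(indexOrder(idx)))
    expect_identical(permOrder(indexPermutation(back)),
                     permOrder(indexPermutation(idx)))
    other <- buildLibrary(generateGenome(200, seed = 1), 15)
    expect_error(readIndex(ipath, other), "checksum")
})
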