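# Shared fixtures, built once per test run and cached; everything is
# generated in code from fixed seeds.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
    if (!exists(name, envir = .fx, inherits = FALSE))
        assign(name, force(expr), envir = .fx)
    get(name, envir = .fx, inherits = FALSE)
}

# 20 kb random genome with a 15-mer library: the toy scale used throughout.
toy_genome <- function() fixture("toy_genome", generateGenome(20000, seed = 101))
toy_lib <- function() fixture("toy_lib", buildLibrary(toy_genome(), 15))
toy_idx8 <- function() fixture("toy_idx8", buildIndexes(toy_lib(), 8, seed = 202))

# 500 reads copied from the toy genome with p in {1, 2} planted mismatches.
toy_planted <- function() fixture("toy_planted", {
    lib <- toy_lib()
    set.seed(303)
    n <- 500
    origin <- sample(libPositions(lib), n)
    p <- rep(c(1L, 2L), length.out = n)
    reads <- character(n)
    for (i in seq_len(n)) {
        v <- strsplit(libraryMmer(lib, origin[i]), "")[[1L]]
        at <- sample.int(15L, p[i])
        for (a in at) v[a] <- sample(setdiff(c("A", "C", "G", "T"), v[a]), 1L)
        reads[i] <- paste(v, collapse = "")
    }
    names(reads) <- sprintf("read%d", seq_len(n))
    list(reads = reads, origin = origin, p = p,
         truth = data.frame(id = names(reads), pos = origin, strand = "+"))
})

# Scaled end-to-end simulation: 1 Mb genome, 10^4 length-100 reads,
# sequencing error 2%, mutation rate 0.1% with 15% indels; default J = 8,
# K = 20.
e2e_fixture <- function() fixture("e2e", {
    g <- generateGenome(1e6, seed = 11)
    mh <- mutateHaplotype(g, mutationRate = 0.001, indelFraction = 0.15,
                          seed = 12)
    lib <- buildLibrary(g, 100)
    idx <- buildIndexes(lib, 8, seed = 13)
    sim <- sampleReads(mh$haplotype, 10000, 100, errorRate = 0.02,
                       seed = 14, refMap = mh$refMap)
    res <- alignReads(sim$reads, idx, lib, searchParams(j = 8, k = 20))
    list(genome = g, lib = lib, idx = idx, sim = sim, res = res)
})

# 2000 error-free pairs from a 100 kb genome, insert ~ N(250, 25), with
# exactly one 1-base indel planted in mate 2 of every pair.
pairs_fixture <- function() fixture("pairs", {
    g <- generateGenome(1e5, seed = 515)
    lib <- buildLibrary(g, 100)
    idx <- buildIndexes(lib, 4, seed = 518)
    sim <- samplePairs(g, 2000, 100, insertMean = 250, insertSd = 25,
                       errorRate = 0, seed = 516)
    set.seed(517)
    r2 <- sim$reads2
    for (i in seq_along(r2)) {
        p2 <- sim$truth$pos2[i]
        d <- sample(10:90, 1L)                       # interior edit site
        del <- runif(1) < 0.5 && p2 + 101L <= nchar(g)
        if (del) {
            win <- substring(g, p2 + 1L, p2 + 101L)
            new <- paste0(substr(win, 1L, d - 1L), substr(win, d + 1L, 101L))
        } else {
            win <- substring(g, p2 + 1L, p2 + 99L)
            new <- paste0(substr(win, 1L, d),
                          sample(c("A", "C", "G", "T"), 1L),
                          substr(win, d + 1L, 99L))
        }
        r2[i] <- if (sim$truth$strand2[i] == "-") reverseComplement(new)
                 else new
    }
    sim$reads2 <- r2
    list(genome = g, lib = lib, idx = idx, sim = sim,
         sparams = searchParams(j = 4, k = 20),
         pparams = pairedParams(insertMin = 150, insertMax = 350,
                                rescueBand = 5, maxRescueDistance = 6))
})

pairs_results <- function() fixture("pairs_results", {
    fx <- pairs_fixture()
    alignPairs(fx$sim$reads1, fx$sim$reads2, fx$idx, fx$lib,
               fx$sparams, fx$pparams)
})

# All permutations of 1..m as an m!-row matrix (rows are gather orders).
enumerate_permutations <- function(m) {
    if (m == 1L) return(matrix(1L, 1L, 1L))
    sub <- enumerate_permutations(m - 1L)
    do.call(rbind, lapply(seq_len(m), function(k)
        cbind(k, sub + (sub >= k))))
}

# random ACGT(N) string
random_dna <- function(len, withN = FALSE) {
    ab <- c("A", "C", "G", "T", if (withN) "N")
    paste(sample(ab, len, replace = TRUE), collapse = "")
}
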