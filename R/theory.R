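# Success-probability calculus for planning J and K.

#' Probability that one random permutation is "lucky"
#'
#' For a read with \code{p} mismatches against its true nearest neighbour and
#' resolution length \code{l}, a uniformly random permutation of the \code{m}
#' positions moves every mismatch out of the first \code{l} output positions
#' with probability
#' \deqn{\frac{(m-l)!}{(m-l-p)!}\;\frac{(m-p)!}{m!},}
#' in which case the true nearest neighbour enters the candidate list of that
#' iteration. Evaluated in log-space (\code{lgamma}) so large \code{m} does
#' not overflow; when \code{p > m - l} no placement avoids the prefix and the
#' probability is exactly 0 (pigeonhole).
#'
#' @param p number of mismatches (0..m).
#' @param l resolution length L (0..m).
#' @param m string length M.
#' @return Probability in [0, 1]. Vectorized over \code{p} and \code{l}.
#' @examples
#' prGoodPerm(p = 1, l = 2, m = 5)   # 72 of the 120 permutations
#' @export
prGoodPerm <- function(p, l, m) {
    n <- max(length(p), length(l), length(m))
    p <- rep_len(as.numeric(p), n)
    l <- rep_len(as.numeric(l), n)
    m <- rep_len(as.numeric(m), n)
    if (any(p < 0 | p > m | l < 0 | l > m))
        stop("need 0 <= p <= m and 0 <= l <= m")
    out <- numeric(n)
    ok <- p <= m - l
    out[ok] <- exp(lgamma(m - l + 1) - lgamma(m - l - p + 1) +
                   lgamma(m - p + 1) - lgamma(m + 1))[ok]
    pmin(pmax(out, 0), 1)
}

#' Lower bound on the overall success probability
#'
#' With \code{j} independent uniformly random permutations, the probability
#' that at least one candidate list contains the true nearest neighbour is at
#' least \code{1 - (1 - prGoodPerm(p, l, m))^j}; since every candidate is
#' verified by Hamming distance, this bounds the probability of reporting the
#' correct alignment.
#'
#' @inheritParams prGoodPerm
#' @param j number of iterations/indexes (J >= 0).
#' @return Probability lower bound in [0, 1]. Vectorized.
#' @export
prSuccess <- function(p, l, m, j) {
    q <- prGoodPerm(p, l, m)
    1 - (1 - q)^j
}

#' Smallest J reaching a target success probability
#'
#' @inheritParams prGoodPerm
#' @param target desired success probability, strictly between 0 and 1.
#' @return The smallest integer \code{j} with
#'   \code{prSuccess(p, l, m, j) >= target}.
#' @export
requiredIterations <- function(p, l, m, target) {
    if (target <= 0 || target >= 1) stop("'target' must lie in (0, 1)")
    q <- prGoodPerm(p, l, m)
    if (length(q) != 1L) stop("scalar arguments required")
    if (q == 0)
        stop("unattainable: a read with p > m - l mismatches is never ",
             "captured by a prefix of length l")
    if (q >= target) return(1L)
    j <- as.integer(ceiling(log1p(-target) / log1p(-q)))
    # guard the closed form against floating-point edges
    while (prSuccess(p, l, m, j) < target) j <- j + 1L
    while (j > 1L && prSuccess(p, l, m, j - 1L) >= target) j <- j - 1L
    j
}

#' Empirical distribution of resolution length
#'
#' Evaluates \code{\link{resolutionLength}} on a seeded random sample of
#' library positions, summarizing how sharply a prefix of the permuted M-mer
#' pins down a locus at the given neighborhood size. Feeding the resulting
#' distribution into \code{\link{prSuccess}} is how J is planned for a target
#' recovery rate.
#'
#' @param index a \linkS4class{PermutedIndex}.
#' @param sampleSize number of library positions to sample (capped at the
#'   library size; sampling without replacement).
#' @param k neighborhood size K (>= 1).
#' @param seed integer seed for the sample.
#' @return List with elements \code{values} (per-sampled-position L),
#'   \code{positions}, \code{histogram} (table of L), and \code{quantiles}
#'   (0, 25, 50, 75, 100 percent).
#' @export
resolutionProfile <- function(index, sampleSize, k, seed = NULL) {
    stopifnot(is(index, "PermutedIndex"))
    if (sampleSize < 1L) stop("sampleSize must be >= 1")
    pos <- index@library@positions
    sampleSize <- min(sampleSize, length(pos))
    take <- with_seed(seed, sample.int(length(pos), sampleSize))
    vals <- vapply(pos[take], function(i) resolutionLength(index, i, k),
                   integer(1))
    list(values = vals, positions = pos[take],
         histogram = table(L = vals),
         quantiles = quantile(vals, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Success-probability planning table
#'
#' Convenience wrapper printing \code{prSuccess} over a grid of mismatch
#' counts and iteration counts at fixed (L, M), as used by the command-line
#' \code{plan} subcommand.
#'
#' @param pMax largest mismatch count tabulated.
#' @param l resolution length.
#' @param m read length.
#' @param jMax largest J tabulated.
#' @return A data.frame with one row per p and one column per J.
#' @export
planTable <- function(pMax, l, m, jMax = 16L) {
    js <- seq_len(jMax)
    out <- data.frame(p = 0:pMax)
    for (j in js)
        out[[paste0("J", j)]] <- round(prSuccess(0:pMax, l, m, j), 4)
    out
}
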