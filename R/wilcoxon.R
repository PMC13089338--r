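#' Two-sided Wilcoxon rank-sum (Mann-Whitney) group comparison
#'
#' Compares two samples of measurements (e.g. mesoglea thickness under two
#' treatments). For small samples (\code{length(a) + length(b) <= exactMax})
#' the null distribution of the Mann-Whitney U statistic is obtained by full
#' enumeration of all \code{choose(n, n_a)} group assignments of the pooled
#' observed values, which handles ties exactly; the two-sided p-value is the
#' doubled smaller tail (including the observed value), capped at 1. For
#' larger samples a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param exactMax largest pooled size for the exact enumeration path.
#' @return List with \code{statistic} (U for sample \code{a}),
#'   \code{p.value}, \code{method} ("exact" or "normal approximation"),
#'   and the sample sizes.
#' @examples
#' compareGroups(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1, exact
#' @importFrom stats pnorm
#' @importFrom utils combn
#' @export
compareGroups <- function(a, b, exactMax = 12L) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 2L || length(b) < 2L)
        stop("each sample needs at least 2 values")
    if (!all(is.finite(c(a, b)))) stop("samples must be finite")
    na <- length(a); nb <- length(b); n <- na + nb
    pooled <- c(a, b)
    r <- rank(pooled)
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    if (n <= exactMax) {
        ustats <- .enumerateU(r, na)
        pLo <- mean(ustats <= U + 1e-9)
        pHi <- mean(ustats >= U - 1e-9)
        p <- min(1, 2 * min(pLo, pHi))
        list(statistic = U, p.value = p, method = "exact",
             n = c(a = na, b = nb))
    } else {
        mu <- na * nb / 2
        ties <- table(r)
        tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
        sigma <- sqrt(na * nb / 12 * (n + 1 - tieCorr))
        if (sigma == 0) stop("all pooled values identical: U is degenerate")
        z <- (U - mu - sign(U - mu) * 0.5) / sigma
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        list(statistic = U, p.value = p, method = "normal approximation",
             n = c(a = na, b = nb))
    }
}

# U statistics of all choose(n, na) assignments of the pooled ranks
.enumerateU <- function(r, na) {
    idx <- utils::combn(length(r), na)
    colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
}
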