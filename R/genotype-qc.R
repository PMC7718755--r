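#' Per-marker quality statistics
#'
#' For each marker: the missing-call rate, the heterozygosity (fraction of
#' code-1 calls among non-missing), and the minor allele frequency
#' computed from non-missing calls as `min(p, 1 - p)` with
#' `p = (2 n2 + n1) / (2 (n0 + n1 + n2))`.
#'
#' @param G a [GenotypeData-class] or a codes matrix.
#' @return a `MarkerStats` data.frame: `marker`, `missing`, `het`, `maf`.
#' @export
markerStats <- function(G) {
    codes <- if (is(G, "GenotypeData")) genoCodes(G) else G
    nTot <- nrow(codes)
    nMiss <- colSums(is.na(codes))
    nObs <- nTot - nMiss
    het <- ifelse(nObs > 0, colSums(codes == 1, na.rm = TRUE) / nObs, NA)
    p <- ifelse(nObs > 0, colSums(codes, na.rm = TRUE) / (2 * nObs), NA)
    data.frame(marker = colnames(codes) %||% as.character(seq_len(ncol(codes))),
               missing = nMiss / nTot, het = het, maf = pmin(p, 1 - p),
               row.names = NULL)
}

#' Filter markers on missing rate, heterozygosity and MAF
#'
#' Keeps markers with missing rate strictly below `missMax`,
#' heterozygosity strictly below `hetMax`, and MAF at or above `mafMin`
#' (boundary semantics exactly as stated by the filters: strict, strict,
#' inclusive).
#'
#' @param G a [GenotypeData-class].
#' @param stats optional precomputed [markerStats()].
#' @param missMax,hetMax,mafMin thresholds (defaults 0.2, 0.1, 0.05).
#' @return the filtered `GenotypeData`; the number of removed markers is
#'   attached as attribute `"removed"` on the map.
#' @export
filterMarkers <- function(G, stats = NULL, missMax = 0.2, hetMax = 0.1,
                          mafMin = 0.05) {
    stopifnot(is(G, "GenotypeData"))
    st <- stats %||% markerStats(G)
    keep <- !is.na(st$maf) & st$missing < missMax & st$het < hetMax &
        st$maf >= mafMin
    out <- G[, keep]
    attr(out@map, "removed") <- sum(!keep)
    out
}

#' Mean-impute missing genotype calls
#'
#' Missing entries are replaced by the marker's mean code, preserving the
#' allele frequency; non-missing entries are untouched. The result is the
#' complete numeric design matrix the association models require.
#'
#' @param G a [GenotypeData-class] or codes matrix.
#' @return a complete numeric matrix (lines x markers).
#' @export
imputeMean <- function(G) {
    codes <- if (is(G, "GenotypeData")) genoCodes(G) else G
    mu <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    if (nrow(idx)) codes[idx] <- mu[idx[, 2]]
    codes
}
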