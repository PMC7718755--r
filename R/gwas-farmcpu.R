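#' Iterative fixed/random-effect association scan
#'
#' The multi-locus association procedure: a fixed-effect model (FEM) tests
#' markers one by one with the current pseudo-QTN set as covariates; the
#' Bonferroni rule (`p < alpha/m`) plus per-linkage-group de-clustering
#' proposes candidates; a random-effect model (REM) whose kinship is
#' derived from the candidate pseudo-QTNs picks, by restricted likelihood,
#' how many of them to keep. FEM and REM alternate until the pseudo-QTN
#' set repeats (or `maxIter`). The final report is the last FEM scan, with
#' pseudo-QTNs re-tested with themselves excluded from the covariates,
#' Benjamini-Hochberg adjustment at level `fdrQ`, and the genomic
#' inflation factor of the final scan. The procedure is deterministic
#' given its inputs.
#'
#' @param y phenotype vector, one value per line of `G` (complete).
#' @param G a [GenotypeData-class]; missing calls are mean-imputed.
#' @param nPcs number of principal-component covariates (0-5 typical), or
#'   `"auto"` to pick by [selectNPcs()].
#' @param alpha family-wise level of the Bonferroni rule (default 0.1).
#' @param fdrQ FDR level of the post hoc step-up rule (default 0.1).
#' @param minSepCM pseudo-QTN de-clustering window (default 1 cM).
#' @param maxIter maximum FEM/REM iterations (default 10).
#' @param cap maximum pseudo-QTN prefix evaluated in the REM (default 20).
#' @param bonferroniM Bonferroni divisor; defaults to the number of
#'   markers scanned.
#' @return an [AssociationResult-class].
#' @export
runFarmcpu <- function(y, G, nPcs = 0, alpha = 0.1, fdrQ = 0.1,
                       minSepCM = 1, maxIter = 10, cap = 20,
                       bonferroniM = NULL) {
    stopifnot(is(G, "GenotypeData"))
    codes <- imputeMean(G)
    map <- markerMap(G)
    stopifnot(length(y) == nrow(codes))
    if (identical(nPcs, "auto"))
        nPcs <- selectNPcs(y, G)$nPcs
    covars <- if (nPcs > 0) pcaCovariates(codes, nPcs) else NULL
    m <- bonferroniM %||% ncol(codes)
    qtns <- character(0)
    history <- list(character(0))
    converged <- FALSE
    iter <- 0L
    repeat {
        iter <- iter + 1L
        scan <- femScan(y, codes, covars, qtns)
        cand <- selectPseudoQtns(scan, map, alpha = alpha, m = m,
                                 minSepCM = minSepCM)
        newQtns <- optimizeQtnSet(cand, y, codes, covars, cap = cap)
        if (any(vapply(history, function(h)
                setequal(h, newQtns), logical(1)))) {
            qtns <- newQtns
            if (!setequal(qtns, history[[length(history)]])) {
                # set revisits an earlier state: rescan once for the report
                scan <- femScan(y, codes, covars, qtns)
            }
            converged <- TRUE
            break
        }
        history[[length(history) + 1L]] <- newQtns
        qtns <- newQtns
        if (iter >= maxIter) break
    }
    fdr <- bhFdr(scan$p, fdrQ)
    res <- data.frame(marker = scan$marker,
                      lg = map$lg[match(scan$marker, map$marker)],
                      pos_cM = map$pos_cM[match(scan$marker, map$marker)],
                      effect = scan$effect, se = scan$se, p = scan$p,
                      p_adj = fdr$adjusted,
                      pseudo_qtn = scan$marker %in% qtns,
                      flag = scan$flag, stringsAsFactors = FALSE)
    new("AssociationResult", results = res, pseudoQtns = qtns,
        nPcs = as.integer(nPcs), alpha = alpha,
        bonferroni = bonferroniThreshold(alpha, m), fdrQ = fdrQ,
        lambda = genomicLambda(scan$p), iterations = iter,
        converged = converged)
}

#' Choose the number of structure PCs by inflation
#'
#' Runs the single-marker scan (the first FEM iteration, no pseudo-QTNs)
#' with each candidate PC count, computes the genomic inflation factor of
#' each scan, and picks the smallest count whose |lambda - 1| lies within
#' twice the sampling standard error of lambda (at the scanned marker
#' count) of the best achieved, so near-ties resolve to the more
#' parsimonious model. This automates the usual visual quantile-quantile
#' comparison; the QQ-plot data tables (expected vs. observed -log10 p per
#' PC count) are returned for inspection.
#'
#' @param y phenotype vector.
#' @param G a [GenotypeData-class].
#' @param candidates PC counts to try (default 0:5).
#' @return list: `nPcs` (chosen count), `lambdas` (named vector), `qq`
#'   (data.frame: `n_pcs`, `expected`, `observed` -log10 p).
#' @export
selectNPcs <- function(y, G, candidates = 0:5) {
    codes <- imputeMean(G)
    maxPcs <- max(candidates)
    pcs <- if (maxPcs > 0) pcaCovariates(codes, maxPcs) else NULL
    lambdas <- numeric(length(candidates))
    qq <- list()
    for (i in seq_along(candidates)) {
        k <- candidates[i]
        covars <- if (k > 0) pcs[, seq_len(k), drop = FALSE] else NULL
        scan <- femScan(y, codes, covars)
        lambdas[i] <- genomicLambda(scan$p)
        ps <- sort(scan$p)
        qq[[i]] <- data.frame(n_pcs = k,
            expected = -log10(stats::ppoints(length(ps))),
            observed = -log10(ps))
    }
    names(lambdas) <- as.character(candidates)
    # parsimony: the fewest PCs whose inflation is within sampling reach of
    # the best |lambda - 1|; the band is twice the large-sample standard
    # error of a median-based lambda estimate at m markers, so differences
    # indistinguishable from noise never buy covariates
    m <- ncol(codes)
    q50 <- stats::qchisq(0.5, 1)
    band <- 2 / (2 * stats::dchisq(q50, 1) * sqrt(m) * q50)
    dev <- abs(lambdas - 1)
    best <- min(candidates[dev <= min(dev) + band])
    list(nPcs = best, lambdas = lambdas, qq = do.call(rbind, qq))
}
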