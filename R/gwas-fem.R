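#' Principal-component covariates for structure correction
#'
#' Top principal components of the column-standardized genotype matrix,
#' used as fixed covariates to absorb population structure (zero to five
#' in practice). Scores carry a deterministic sign convention: for each
#' component, the marker loading with the largest magnitude is made
#' positive.
#'
#' @param G a [GenotypeData-class] or complete codes matrix (impute
#'   first, see [imputeMean()]).
#' @param nPcs number of components (0 returns a 0-column matrix).
#' @return n-by-nPcs matrix of PC scores.
#' @export
pcaCovariates <- function(G, nPcs) {
    codes <- if (is(G, "GenotypeData")) imputeMean(G) else G
    n <- nrow(codes)
    if (nPcs == 0) return(matrix(numeric(0), n, 0))
    if (nPcs >= min(dim(codes)))
        stop("nPcs must be below min(n_lines, n_markers)")
    X <- scale(codes)
    X[, colSums(is.na(X)) > 0 | apply(X, 2, function(c) any(!is.finite(c)))] <- 0
    # eigen of the small n x n cross-product; columns returned orthonormal
    # (the scale of a fixed covariate is irrelevant to the scan)
    e <- eigen(tcrossprod(X) / (ncol(X) - 1), symmetric = TRUE)
    scores <- e$vectors[, seq_len(nPcs), drop = FALSE]
    for (k in seq_len(nPcs)) {
        load <- crossprod(X, e$vectors[, k])
        if (load[which.max(abs(load))] < 0) scores[, k] <- -scores[, k]
    }
    colnames(scores) <- paste0("PC", seq_len(nPcs))
    scores
}

# Build the fixed design [intercept | covariates | pseudo-QTN columns],
# dropping columns that are collinear (rank-deficient) with earlier ones.
buildDesign <- function(n, covariates, qtnCols) {
    W <- cbind(`(Intercept)` = rep(1, n))
    if (!is.null(covariates) && ncol(covariates) > 0) W <- cbind(W, covariates)
    dropped <- character(0)
    if (!is.null(qtnCols) && ncol(qtnCols) > 0) {
        for (j in seq_len(ncol(qtnCols))) {
            cand <- cbind(W, qtnCols[, j])
            if (qr(cand)$rank > qr(W)$rank) {
                W <- cand
                colnames(W)[ncol(W)] <- colnames(qtnCols)[j]
            } else dropped <- c(dropped, colnames(qtnCols)[j])
        }
    }
    list(W = W, dropped = dropped)
}

# OLS of y on [W | s] for every column s of S simultaneously, via
# residualization against W. Returns effect, se, p per column.
scanOls <- function(y, S, W) {
    n <- length(y)
    qrW <- qr(W)
    yr <- stats::residuals(stats::lm.fit(W, y))
    Sr <- S - W %*% qr.coef(qrW, S)
    ssS <- colSums(Sr^2)
    sy <- as.numeric(crossprod(Sr, yr))
    dfree <- n - qrW$rank - 1
    tol <- 1e-10 * n
    ok <- ssS > tol & dfree > 0
    d <- ifelse(ok, sy / ssS, NA)
    rss <- sum(yr^2) - ifelse(ok, d^2 * ssS, 0)
    sigma2 <- pmax(rss, 0) / dfree
    se <- ifelse(ok, sqrt(sigma2 / ssS), NA)
    tstat <- d / se
    p <- 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE)
    p <- pmax(pmin(p, 1), .Machine$double.xmin)
    data.frame(effect = ifelse(ok, d, 0), se = se,
               p = ifelse(ok, p, 1),
               flag = ifelse(ok, "", "collinear"),
               stringsAsFactors = FALSE)
}

#' Fixed-effect model scan (one-by-one marker testing)
#'
#' For every marker j, ordinary least squares of the phenotype on
#' intercept, covariates (PCs), the current pseudo-QTN columns, and the
#' tested marker; the reported p-value is the t-test of the marker effect.
#' A pseudo-QTN is re-tested with itself excluded from the covariate set
#' (otherwise its own test would be degenerate). Markers collinear with
#' the covariates (including constant markers) are flagged and given
#' p = 1. Pseudo-QTN columns that are collinear with earlier design
#' columns are dropped and recorded in attribute `"droppedQtns"`.
#'
#' @param y numeric phenotype vector (complete).
#' @param G a [GenotypeData-class] or complete codes matrix.
#' @param covariates optional covariate matrix (e.g. PCs).
#' @param pseudoQtns character vector of pseudo-QTN marker names (must be
#'   columns of `G`).
#' @return data.frame: `marker`, `effect`, `se`, `p`, `flag`,
#'   `pseudo_qtn`.
#' @export
femScan <- function(y, G, covariates = NULL, pseudoQtns = character(0)) {
    codes <- if (is(G, "GenotypeData")) genoCodes(G) else G
    if (anyNA(codes)) codes <- imputeMean(codes)
    y <- as.numeric(y)
    stopifnot(length(y) == nrow(codes), !anyNA(y))
    markers <- colnames(codes) %||% as.character(seq_len(ncol(codes)))
    qtnCols <- codes[, intersect(pseudoQtns, markers), drop = FALSE]
    des <- buildDesign(length(y), covariates, qtnCols)
    isQtn <- markers %in% pseudoQtns
    res <- scanOls(y, codes[, !isQtn, drop = FALSE], des$W)
    res$marker <- markers[!isQtn]
    # pseudo-QTNs: re-test each with itself excluded from the design
    qres <- NULL
    for (qm in markers[isQtn]) {
        others <- setdiff(intersect(pseudoQtns, markers), qm)
        dq <- buildDesign(length(y), covariates,
                          codes[, others, drop = FALSE])
        r1 <- scanOls(y, codes[, qm, drop = FALSE], dq$W)
        r1$marker <- qm
        qres <- rbind(qres, r1)
    }
    out <- rbind(res, qres)
    out <- out[match(markers, out$marker), ]
    rownames(out) <- NULL
    mu <- colMeans(codes)
    const <- colMeans(codes^2) - mu^2 < 1e-12
    out$flag[const & out$flag == "collinear"] <- "constant"
    out$pseudo_qtn <- isQtn
    attr(out, "droppedQtns") <- des$dropped
    out[, c("marker", "effect", "se", "p", "flag", "pseudo_qtn")]
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise level (the study used 0.1).
#' @param m number of tests (the divisor is configurable because the
#'   effective post-QC marker count may differ from the panel size).
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) {
    stopifnot(alpha > 0, m >= 1)
    alpha / m
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p vector of p-values.
#' @param q FDR level (default 0.1).
#' @return list: `adjusted` (BH-adjusted p-values) and `significant`
#'   (indices with adjusted p at most `q`).
#' @export
bhFdr <- function(p, q = 0.1) {
    adj <- stats::p.adjust(p, method = "BH")
    list(adjusted = adj, significant = which(!is.na(adj) & adj <= q))
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, 1, lower = FALSE)) / qchisq(0.5, 1)`; close
#' to 1 for calibrated p-values.
#'
#' @param p p-values.
#' @return lambda.
#' @export
genomicLambda <- function(p) {
    p <- p[!is.na(p)]
    stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
        stats::qchisq(0.5, df = 1)
}

#' Select pseudo-QTN candidates from a scan
#'
#' Markers passing the Bonferroni rule `p < alpha / m` become candidates,
#' ordered by significance, then de-clustered: within each linkage group,
#' of any two candidates closer than `minSepCM` only the more significant
#' survives. Unmapped (UKN) markers are exempt from distance
#' de-clustering.
#'
#' @param scan a [femScan()] result (needs `marker`, `p`).
#' @param map marker map (`marker`, `lg`, `pos_cM`).
#' @param alpha family-wise level (default 0.1).
#' @param m Bonferroni divisor (default: number of scanned markers).
#' @param minSepCM de-clustering window in cM (default 1).
#' @return character vector of candidate markers, most significant first
#'   (possibly empty).
#' @export
selectPseudoQtns <- function(scan, map, alpha = 0.1, m = nrow(scan),
                             minSepCM = 1) {
    thr <- bonferroniThreshold(alpha, m)
    cand <- scan[!is.na(scan$p) & scan$p < thr, , drop = FALSE]
    if (!nrow(cand)) return(character(0))
    cand <- merge(cand, map, by = "marker", all.x = TRUE, sort = FALSE)
    cand <- cand[order(cand$p), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (is.na(cand$pos_cM[i]) ||
            (!is.na(cand$lg[i]) && cand$lg[i] == "UKN")) {
            keep[i] <- TRUE
            next
        }
        prior <- which(keep & cand$lg == cand$lg[i] & !is.na(cand$pos_cM))
        keep[i] <- !any(abs(cand$pos_cM[prior] - cand$pos_cM[i]) < minSepCM)
    }
    cand$marker[keep]
}
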