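#' Kinship from pseudo-QTN genotypes
#'
#' Line-by-line similarity built only from the pseudo-QTN columns: the
#' columns are mean-centered, `K = Z Z' / c` with `c` chosen so the mean
#' diagonal equals 1. `K` is symmetric PSD by construction; the scaled
#' low-rank factor is attached as attribute `"Z"` (with `2K = Z2 Z2'`,
#' `Z2 = sqrt(2) Z / sqrt(c)`), which the variance-component fit exploits.
#'
#' @param G a [GenotypeData-class] or codes matrix.
#' @param qtns marker names (or column indices) of the pseudo-QTN set
#'   (at least one).
#' @return n-by-n kinship matrix with attribute `"Z"`.
#' @export
kinshipFromQtns <- function(G, qtns) {
    codes <- if (is(G, "GenotypeData")) genoCodes(G) else G
    if (anyNA(codes)) codes <- imputeMean(codes)
    if (length(qtns) < 1) stop("at least one pseudo-QTN required")
    Z <- codes[, qtns, drop = FALSE]
    Z <- scale(Z, center = TRUE, scale = FALSE)
    raw <- tcrossprod(Z)
    c0 <- mean(diag(raw))
    if (c0 <= 0) stop("pseudo-QTN columns are constant; kinship undefined")
    K <- raw / c0
    attr(K, "Z") <- Z / sqrt(c0)
    K
}

#' Clip a symmetric matrix to the PSD cone
#'
#' Eigen-decomposes and zeroes negative eigenvalues; used to sanitize
#' user-supplied kinships.
#'
#' @param K symmetric matrix.
#' @return the nearest-by-eigenvalue-clipping PSD matrix.
#' @export
psdClip <- function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    v <- pmax(e$values, 0)
    e$vectors %*% (v * t(e$vectors))
}

# REML/ML machinery for y = X b + u + e, Var(u) = 2 K sigma_a^2,
# Var(e) = sigma_e^2 I. With the spectral form 2K = U diag(d) U' (rank t),
# M(delta) = I + delta 2K has inverse I - U diag(delta d/(1+delta d)) U'
# and log-determinant sum(log(1 + delta d)); everything needed for the
# profile likelihood is computable from the t-dimensional projections of
# y and X, so a low-rank pseudo-QTN kinship costs O(n t^2) per delta.
remProfile <- function(delta, y, X, U, d) {
    n <- length(y); p <- ncol(X)
    w <- delta * d / (1 + delta * d)
    Uy <- crossprod(U, y); UX <- crossprod(U, X)
    Minv <- function(v, Uv) v - U %*% (w * Uv)
    XtMiX <- crossprod(X, Minv(X, UX))
    XtMiy <- crossprod(X, Minv(y, Uy))
    beta <- solve(XtMiX, XtMiy)
    r <- y - X %*% beta
    Ur <- crossprod(U, r)
    rss <- sum(r * Minv(r, Ur))
    logdetM <- sum(log1p(delta * d))
    nu <- n - p
    sigma2e <- rss / nu
    llr <- -0.5 * (nu * log(2 * pi * sigma2e) + logdetM + nu +
        determinant(XtMiX, logarithm = TRUE)$modulus -
        determinant(crossprod(X), logarithm = TRUE)$modulus)
    list(llr = as.numeric(llr), sigma2e = sigma2e, beta = beta)
}

#' Fit the one-random-effect model by restricted maximum likelihood
#'
#' Variance components of `y = X b + u + e` with `Var(u) = 2 K sigma_a^2`
#' via the spectral decomposition of `2K` and one-dimensional
#' optimization of the variance ratio `delta = sigma_a^2 / sigma_e^2` on a
#' log grid refined by `optimize()`. When the kinship carries a low-rank
#' factor (attribute `"Z"`, as produced by [kinshipFromQtns()]) the fit
#' uses it and costs O(n t^2); otherwise a dense eigendecomposition is
#' used. Non-finite likelihoods or a flat profile fall back to the
#' boundary (`delta = 0`, i.e. no genetic variance).
#'
#' @param y phenotype vector.
#' @param K PSD kinship (or `NULL` with `Z` given).
#' @param covariates optional fixed covariates (intercept always
#'   included).
#' @param Z optional low-rank factor with `2K = (sqrt(2) Z)(sqrt(2) Z)'`.
#' @return list: `sigma2_a`, `sigma2_e`, `logLik` (restricted), `delta`,
#'   `beta`, `boundary` (logical).
#' @export
remFit <- function(y, K = NULL, covariates = NULL, Z = NULL) {
    y <- as.numeric(y)
    n <- length(y)
    X <- cbind(rep(1, n), covariates)
    if (is.null(Z) && !is.null(K)) Z <- attr(K, "Z")
    if (!is.null(Z)) {
        Z2 <- sqrt(2) * Z
        sv <- svd(Z2, nu = min(dim(Z2)), nv = 0)
        pos <- sv$d^2 > 1e-12
        U <- sv$u[, pos, drop = FALSE]
        d <- sv$d[pos]^2
    } else {
        stopifnot(!is.null(K))
        e <- eigen(2 * ((K + t(K)) / 2), symmetric = TRUE)
        if (min(e$values) < -1e-6 * max(abs(e$values)))
            stop("K must be positive semidefinite (see psdClip)")
        pos <- e$values > 1e-12
        U <- e$vectors[, pos, drop = FALSE]
        d <- pmax(e$values[pos], 0)
    }
    if (length(d) == 0) {   # kinship is zero: iid model
        fit <- stats::lm.fit(X, y)
        rss <- sum(fit$residuals^2)
        nu <- n - ncol(X)
        s2 <- rss / nu
        llr <- -0.5 * (nu * log(2 * pi * s2) + nu +
            determinant(crossprod(X), logarithm = TRUE)$modulus -
            determinant(crossprod(X), logarithm = TRUE)$modulus)
        return(list(sigma2_a = 0, sigma2_e = s2, logLik = as.numeric(llr),
                    delta = 0, beta = fit$coefficients, boundary = TRUE))
    }
    obj <- function(ld) remProfile(exp(ld), y, X, U, d)$llr
    grid <- seq(log(1e-6), log(1e6), length.out = 25)
    vals <- vapply(grid, function(g) {
        v <- tryCatch(obj(g), error = function(e) -Inf)
        if (!is.finite(v)) -Inf else v
    }, numeric(1))
    best <- which.max(vals)
    lo <- grid[max(best - 1, 1)]; hi <- grid[min(best + 1, length(grid))]
    opt <- tryCatch(stats::optimize(obj, c(lo, hi), maximum = TRUE),
                    error = function(e) NULL)
    ld <- if (!is.null(opt) && is.finite(opt$objective) &&
              opt$objective >= vals[best]) opt$maximum else grid[best]
    # boundary: compare against delta -> 0 (iid)
    ll0 <- remProfile(1e-12, y, X, U, d)$llr
    prof <- remProfile(exp(ld), y, X, U, d)
    boundary <- FALSE
    if (!is.finite(prof$llr) || ll0 >= prof$llr) {
        prof <- remProfile(1e-12, y, X, U, d)
        ld <- log(1e-12)
        boundary <- TRUE
    }
    delta <- exp(ld)
    if (boundary) delta <- 0
    list(sigma2_a = delta * prof$sigma2e, sigma2_e = prof$sigma2e,
         logLik = prof$llr, delta = delta, beta = prof$beta,
         boundary = boundary || ld >= log(1e6))
}

#' Choose the pseudo-QTN set by REM likelihood
#'
#' Evaluates nested prefixes of the significance-ordered candidate list
#' (empty set, top-1, top-2, ..., up to `cap`): each prefix defines a
#' kinship via [kinshipFromQtns()], and the prefix whose restricted
#' likelihood under [remFit()] is highest wins. The empty set is scored
#' by the iid model, so a pure-noise candidate can be rejected outright.
#'
#' @param candidates significance-ordered marker names (from
#'   [selectPseudoQtns()]).
#' @param y phenotype vector.
#' @param G genotypes ([GenotypeData-class] or complete matrix).
#' @param covariates optional fixed covariates.
#' @param cap maximum prefix length evaluated (default 20).
#' @return character vector: the selected pseudo-QTN set (possibly
#'   empty).
#' @export
optimizeQtnSet <- function(candidates, y, G, covariates = NULL, cap = 20) {
    if (length(candidates) == 0 || cap == 0) return(character(0))
    y <- as.numeric(y)
    codes <- if (is(G, "GenotypeData")) genoCodes(G) else G
    if (anyNA(codes)) codes <- imputeMean(codes)
    n <- length(y)
    X <- cbind(rep(1, n), covariates)
    fit0 <- stats::lm.fit(X, y)
    nu <- n - ncol(X)
    ll0 <- -0.5 * (nu * log(2 * pi * sum(fit0$residuals^2) / nu) + nu)
    kmax <- min(cap, length(candidates))
    lls <- numeric(kmax)
    for (k in seq_len(kmax)) {
        K <- kinshipFromQtns(codes, candidates[seq_len(k)])
        lls[k] <- tryCatch(remFit(y, K, covariates)$logLik,
                           error = function(e) -Inf)
    }
    if (max(lls) <= ll0) return(character(0))
    candidates[seq_len(which.max(lls))]
}
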