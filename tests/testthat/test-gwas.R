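test_that("structure PCs are orthonormal, sign-stable, and separate subpopulations", {
    spec <- panelSpec(nLines = 200, nChecks = 0, nMarkers = 400,
                      divergence = 0.4, subpopFraction = 0.5, seed = 30)
    sim <- simulateGenotypes(spec)
    pcs <- pcaCovariates(sim$geno, 3)
    expect_equal(crossprod(pcs), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    r <- stats::cor(pcs[, 1], as.numeric(sim$subpop == "pop2"))
    expect_gt(abs(r), 0.9)
    expect_identical(pcs, pcaCovariates(sim$geno, 3))

    expect_equal(ncol(pcaCovariates(sim$geno, 0)), 0)
    expect_error(pcaCovariates(genoCodes(sim$geno)[1:5, 1:10], 5), "below")
})

test_that("the fixed-effect scan reproduces textbook least squares", {
    G <- toyGenotypes()
    codes <- genoCodes(G)
    set.seed(8)
    y <- 0.4 * codes[, 3] + rnorm(12)
    scan <- femScan(y, G)
    for (j in seq_len(ncol(codes))) {
        fit <- summary(stats::lm(y ~ codes[, j]))$coefficients
        expect_equal(scan$effect[j], fit[2, 1], tolerance = 1e-8)
        expect_equal(scan$se[j], fit[2, 2], tolerance = 1e-8)
        expect_equal(scan$p[j], fit[2, 4], tolerance = 1e-8)
    }
    # with covariates and a pseudo-QTN the scan equals the joint OLS
    pcs <- matrix(rnorm(12), 12, 1)
    scan2 <- femScan(y, G, covariates = pcs, pseudoQtns = "m03")
    j <- 5
    fit2 <- summary(stats::lm(y ~ pcs + codes[, 3] + codes[, j]))$coefficients
    expect_equal(scan2$effect[j], fit2[4, 1], tolerance = 1e-8)
    expect_equal(scan2$p[j], fit2[4, 4], tolerance = 1e-8)
    # the pseudo-QTN's own row is the fit without itself as covariate
    fitSelf <- summary(stats::lm(y ~ pcs + codes[, 3]))$coefficients
    expect_equal(scan2$effect[3], fitSelf[3, 1], tolerance = 1e-8)
    expect_true(scan2$pseudo_qtn[3])

    # constant marker: flagged, p = 1
    codes2 <- cbind(codes, flat = rep(2, 12))
    scanC <- femScan(y, codes2)
    expect_equal(scanC$p[ncol(codes2)], 1)
    expect_equal(scanC$flag[ncol(codes2)], "constant")
})

test_that("null scans produce uniform p-values", {
    spec <- panelSpec(nLines = 200, nChecks = 0, nMarkers = 2000,
                      divergence = 0, seed = 31)
    sim <- simulateGenotypes(spec)
    set.seed(32)
    y <- rnorm(200)
    scan <- femScan(y, sim$geno)
    expect_gt(stats::ks.test(scan$p, "punif")$p.value, 0.01)
    expect_true(all(scan$p > 0 & scan$p <= 1))
})

test_that("multiple-testing thresholds follow their definitions", {
    expect_equal(bonferroniThreshold(0.05, 10), 0.005)
    expect_equal(bonferroniThreshold(0.1, 22767), 0.1 / 22767)
    expect_lt(bonferroniThreshold(0.1, 3000), bonferroniThreshold(0.1, 2000))

    res <- bhFdr(c(0.001, 0.01, 0.02, 0.9), q = 0.1)
    expect_equal(res$significant, 1:3)
    expect_equal(bhFdr(rep(1, 6), 0.1)$significant, integer(0))

    # step-up equals its enumeration oracle on random vectors
    set.seed(35)
    for (rep in 1:20) {
        m <- sample(1:100, 1)
        p <- round(runif(m), 3)
        q <- sample(c(0.05, 0.1, 0.2), 1)
        expect_equal(bhFdr(p, q)$significant, bhEnumerate(p, q))
    }
})

test_that("genomic inflation is 1 on an exact uniform grid", {
    grid <- (1:10000 - 0.5) / 10000
    expect_equal(genomicLambda(grid), 1, tolerance = 1e-3)
})

test_that("pseudo-QTN candidates are Bonferroni-gated and de-clustered", {
    map <- data.frame(marker = c("a", "b", "c", "u"),
                      lg = c("Mrg01", "Mrg01", "Mrg02", "UKN"),
                      pos_cM = c(10, 10.3, 50, NA))
    scan <- data.frame(marker = c("a", "b", "c", "u"),
                       p = c(1e-8, 1e-6, 0.5, 1e-7))
    got <- selectPseudoQtns(scan, map, alpha = 0.1, m = 4, minSepCM = 1)
    expect_equal(got, c("a", "u"))   # b within 1 cM of the stronger a
    # markers exactly at the window edge both survive
    map$pos_cM[2] <- 11
    expect_equal(selectPseudoQtns(scan, map, alpha = 0.1, m = 4),
                 c("a", "u", "b"))
    none <- selectPseudoQtns(data.frame(marker = "a", p = 0.5), map,
                             alpha = 0.1, m = 100)
    expect_equal(none, character(0))
})

test_that("pseudo-QTN kinship has the expected block structure and is PSD", {
    g <- c(0, 0, 2, 2, 2, 0)
    codes <- cbind(snp = g)
    K <- kinshipFromQtns(codes, "snp")
    expect_true(isSymmetric(K))
    expect_equal(length(unique(as.vector(round(K[g == 0, g == 0], 12)))), 1)
    expect_equal(length(unique(as.vector(round(K[g == 0, g == 2], 12)))), 1)
    expect_equal(mean(diag(K)), 1)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))

    # identical lines: off-diagonal equals the diagonal
    codes2 <- cbind(a = c(0, 0, 2, 2), b = c(2, 2, 0, 0))
    K2 <- kinshipFromQtns(codes2, c("a", "b"))
    expect_equal(K2[1, 2], K2[1, 1])

    Kneg <- diag(2); Kneg[1, 2] <- Kneg[2, 1] <- 2
    expect_true(all(eigen(psdClip(Kneg))$values >= -1e-12))
    expect_error(kinshipFromQtns(codes, character(0)), "at least one")
})

test_that("the variance-component fit matches closed forms and recovers truth", {
    set.seed(40)
    n <- 120
    y <- rnorm(n, 5, 2)
    K <- diag(n) / 2        # 2K = I: the model collapses to iid
    f <- remFit(y, K)
    nu <- n - 1
    rss <- sum((y - mean(y))^2)
    llIid <- -0.5 * (nu * log(2 * pi * rss / nu) + nu)
    expect_equal(f$logLik, llIid, tolerance = 1e-6)
    expect_equal(f$sigma2_a + f$sigma2_e, rss / nu, tolerance = 1e-4)

    # parameter recovery: sigma_a^2 = 2, sigma_e^2 = 1 at n = 500
    set.seed(41)
    n <- 500
    Zbase <- matrix(sample(c(0, 2), n * 50, TRUE), n, 50)
    K <- kinshipFromQtns(Zbase, 1:50)
    Z2 <- sqrt(2) * attr(K, "Z")
    est <- replicate(100, {
        u <- as.numeric(Z2 %*% rnorm(50, 0, sqrt(2)))
        y <- 1 + u + rnorm(n, 0, 1)
        ff <- remFit(y, K)
        c(ff$sigma2_a, ff$sigma2_e)
    })
    expect_lt(abs(stats::median(est[1, ]) - 2) / 2, 0.15)
    expect_lt(abs(stats::median(est[2, ]) - 1) / 1, 0.15)

    # true genetic variance zero: estimate sits at the boundary
    set.seed(42)
    y0 <- rnorm(200)
    K0 <- kinshipFromQtns(matrix(sample(c(0, 2), 200 * 5, TRUE), 200, 5), 1:5)
    f0 <- remFit(y0, K0)
    expect_gte(f0$sigma2_a, 0)
})

test_that("the REM prefix search keeps true QTN and drops noise candidates", {
    wins <- 0L
    for (rep in 1:30) {
        spec <- panelSpec(nLines = 400, nChecks = 0, nMarkers = 200,
                          nBatches = 1, batchSd = 0,
                          qtn = data.frame(marker = 7, effect = 1),
                          h2 = 0.25, seed = 100 + rep)
        sim <- simulateGenotypes(spec)
        lay <- data.frame(line = lineNames(sim$geno), batch = factor(1),
                          is_check = FALSE)
        ph <- simulatePhenotypes(sim, spec, lay)
        truth <- markerNames(sim$geno)[7]
        noise <- markerNames(sim$geno)[150]
        got <- optimizeQtnSet(c(truth, noise), ph$y, sim$geno)
        if (identical(got, truth)) wins <- wins + 1L
    }
    expect_gte(wins / 30, 0.7)

    # degenerate inputs
    expect_equal(optimizeQtnSet(character(0), rnorm(10),
        matrix(0, 10, 0)), character(0))
    set.seed(50)
    codes <- cbind(s1 = sample(c(0, 2), 60, TRUE))
    one <- optimizeQtnSet("s1", rnorm(60), codes)
    expect_true(length(one) <= 1)
    expect_equal(optimizeQtnSet("s1", rnorm(60), codes, cap = 0),
                 character(0))
})

test_that("PC-count selection tracks confounding", {
    # confounded trait: structure inflates the unadjusted scan
    spec <- panelSpec(nLines = 300, nChecks = 0, nMarkers = 800,
                      divergence = 0.35, subpopFraction = 0.5,
                      structureEffect = 1.2, nBatches = 1, batchSd = 0,
                      seed = 60)
    sim <- simulateGenotypes(spec)
    lay <- data.frame(line = lineNames(sim$geno), batch = factor(1),
                      is_check = FALSE)
    ph <- simulatePhenotypes(sim, spec, lay)
    sel <- selectNPcs(ph$y, sim$geno, candidates = 0:2)
    expect_gt(sel$lambdas[["0"]], sel$lambdas[["1"]])
    expect_gt(sel$nPcs, 0)
    expect_true(all(c("n_pcs", "expected", "observed") %in% names(sel$qq)))

    # unstructured traits: the zero-PC model wins in the majority of runs
    chosen <- vapply(1:5, function(i) {
        spec0 <- panelSpec(nLines = 300, nChecks = 0, nMarkers = 800,
                           divergence = 0, nBatches = 1, batchSd = 0,
                           seed = 61 + i)
        sim0 <- simulateGenotypes(spec0)
        ph0 <- simulatePhenotypes(sim0, spec0, lay)
        selectNPcs(ph0$y, sim0$geno, candidates = 0:2)$nPcs
    }, numeric(1))
    expect_gte(sum(chosen == 0), 3)
})

test_that("the iterative scan is deterministic given its inputs", {
    spec <- panelSpec(nLines = 250, nChecks = 0, nMarkers = 600,
                      nBatches = 1, batchSd = 0,
                      qtn = data.frame(marker = c(50, 400), effect = 0.6),
                      h2 = 0.25, seed = 70)
    sim <- simulateGenotypes(spec)
    lay <- data.frame(line = lineNames(sim$geno), batch = factor(1),
                      is_check = FALSE)
    ph <- simulatePhenotypes(sim, spec, lay)
    r1 <- runFarmcpu(ph$y, sim$geno)
    r2 <- runFarmcpu(ph$y, sim$geno)
    expect_identical(assocTable(r1), assocTable(r2))
    expect_identical(pseudoQtns(r1), pseudoQtns(r2))
    expect_s4_class(r1, "AssociationResult")
    expect_true(validObject(r1))
    expect_output(show(r1), "AssociationResult")
})
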