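test_that("batch effects are the centered check marginal means", {
    flat <- makeCheckTable(gEff = c(1, 2, 3), bEff = c(0, 0, 0, 0))
    expect_equal(unname(estimateBatchEffects(flat)), rep(0, 4))

    one <- makeCheckTable(gEff = c(1, 2), bEff = 5)
    expect_equal(unname(estimateBatchEffects(one)), 0)

    # planted shifts {+2, -2} recovered within 2 SE of a check mean
    shifted <- makeCheckTable(gEff = rep(0, 6), bEff = c(2, -2),
                              residSd = 0.5, seed = 1)
    eff <- estimateBatchEffects(shifted)
    se <- 0.5 / sqrt(6)
    expect_lt(abs(eff[["1"]] - 2), 2 * se * sqrt(2))
    expect_lt(abs(eff[["2"]] + 2), 2 * se * sqrt(2))

    noCheck <- flat; noCheck$is_check[noCheck$batch == 2] <- FALSE
    expect_error(estimateBatchEffects(noCheck), "without check")
})

test_that("adjustment removes the batch structure and preserves missing values", {
    tab <- makeCheckTable(gEff = c(0.5, -0.5, 1), bEff = c(3, -1, 2),
                          residSd = 0.2, seed = 2)
    eff <- estimateBatchEffects(tab)
    adj <- adjustTraits(tab, eff)
    bm <- tapply(adj$adjusted[adj$is_check], adj$batch[adj$is_check], mean)
    expect_lt(stats::var(bm), 1e-24)

    zero <- adjustTraits(tab, setNames(rep(0, 3), 1:3))
    expect_equal(zero$adjusted, tab$value)

    tab$value[1] <- NA
    adj2 <- adjustTraits(tab, eff)
    expect_true(is.na(adj2$adjusted[1]))
})

test_that("the check-subset ANOVA matches the classical two-way decomposition", {
    # noise-free genotype differences: residual SS collapses
    pure <- makeCheckTable(gEff = c(1, 4, 9), bEff = c(0, 0, 0))
    aPure <- augmentedAnova(pure)
    expect_lt(aPure$ss[aPure$source == "Residuals"], 1e-20)
    expect_lt(aPure$p[aPure$source == "genotype"], 1e-10)

    # balanced 3 checks x 3 batches against direct SS formulas
    tab <- makeCheckTable(gEff = c(0, 2, 5), bEff = c(-1, 0, 3),
                          residSd = 1, seed = 3)
    a <- augmentedAnova(tab)
    y <- tab$value
    gm <- mean(y)
    ssG <- 3 * sum((tapply(y, tab$line, mean) - gm)^2)
    ssB <- 3 * sum((tapply(y, tab$batch, mean) - gm)^2)
    ssT <- sum((y - gm)^2)
    expect_equal(a$ss[a$source == "genotype"], ssG, tolerance = 1e-10)
    expect_equal(a$ss[a$source == "batch"], ssB, tolerance = 1e-10)
    expect_equal(sum(a$ss), ssT, tolerance = 1e-8)

    # batch relabeling leaves the total SS unchanged
    perm <- tab
    perm$batch <- c(3, 1, 2)[perm$batch]
    aPerm <- augmentedAnova(perm)
    expect_equal(sum(aPerm$ss), sum(a$ss), tolerance = 1e-10)

    expect_error(augmentedAnova(makeCheckTable(gEff = 1, bEff = c(0, 0))),
                 ">= 2 check")
    expect_error(augmentedAnova(makeCheckTable(gEff = c(1, 2), bEff = 0)),
                 ">= 2 batches")
})

test_that("heritability from mean squares recovers the simulation truth", {
    flatAnova <- data.frame(source = c("genotype", "batch", "Residuals"),
                            df = c(5, 7, 35), ss = c(10, 7, 70),
                            ms = c(2, 1, 2), f = NA, p = NA)
    expect_equal(heritability(flatAnova, r = 8)$H2, 0)
    expect_true(is.na(heritability(flatAnova, r = 8, complete = FALSE)$H2))

    # parameter recovery: true H2 = 0.8 with r = 8 batches; 12 replicated
    # genotypes keep the ratio estimator's small-df Jensen bias inside the
    # tolerance
    set.seed(14)
    h2hat <- replicate(200, {
        tab <- makeCheckTable(gEff = rnorm(12, 0, sqrt(0.8)),
                              bEff = rnorm(8, 0, 1),
                              lines = paste0("chk", 1:12))
        tab$value <- tab$value + rnorm(nrow(tab), 0, sqrt(0.2))
        augmentedHeritability(tab)$H2
    })
    expect_lt(abs(mean(h2hat) - 0.8), 0.05)

    # a check missing from one batch forfeits the estimate
    tab <- makeCheckTable(gEff = rnorm(6), bEff = rnorm(3), residSd = 0.1,
                          seed = 6)
    tab$value[tab$line == "chk1" & tab$batch == 2] <- NA
    expect_true(is.na(augmentedHeritability(tab)$H2))
})

test_that("the genotype-by-location LRT is calibrated and detects interaction", {
    set.seed(21)
    # identical observations at both locations (2 replicates per cell,
    # replicate noise shared across locations): zero interaction by
    # construction
    g <- rnorm(80); e <- matrix(rnorm(160), 80, 2)
    d0 <- do.call(rbind, lapply(c("A", "B"), function(loc)
        data.frame(line = rep(sprintf("l%03d", 1:80), 2),
                   location = loc,
                   value = rep(g, 2) + as.vector(e))))
    r0 <- gxeLrt(d0)
    expect_lt(r0$chisq, 1)
    expect_lt(r0$varcomp, 0.05)

    # null simulation (2 observations per line x location cell):
    # rejection rate at alpha = 0.05 stays boundary-conservative
    cellDesign <- function(n) data.frame(
        line = rep(rep(sprintf("l%03d", 1:n), 2), 2),
        location = rep(rep(c("A", "B"), each = n), 2))
    rej <- replicate(60, {
        d <- cellDesign(40)
        g <- rnorm(40)
        d$value <- g[match(d$line, sprintf("l%03d", 1:40))] +
            rnorm(nrow(d), 0, 1)
        gxeLrt(d)$p < 0.05
    })
    margin <- 2 * sqrt(0.05 * 0.95 / 60)
    expect_lte(mean(rej), 0.05 + margin)

    # strong interaction at n = 400 lines: decisively detected
    n <- 400
    d1 <- cellDesign(n)
    g <- rnorm(n); gl <- matrix(rnorm(2 * n, 0, 1), n, 2)
    cellIdx <- cbind(match(d1$line, sprintf("l%03d", 1:n)),
                     ifelse(d1$location == "A", 1, 2))
    d1$value <- g[cellIdx[, 1]] + gl[cellIdx] + rnorm(nrow(d1), 0, 0.5)
    r1 <- gxeLrt(d1)
    expect_lt(r1$p, 1e-4)
    expect_gt(r1$varcomp, 0.5)
    expect_true(all(c("AIC", "BIC", "logLik") %in% names(r1$fits)))
    # halved boundary mixture never exceeds the plain p-value
    expect_lte(gxeLrt(d1, halved = TRUE)$p, r1$p)
})
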