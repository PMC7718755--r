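#' Estimate batch effects from replicated checks
#'
#' In the augmented design the six check varieties are assayed with every
#' batch, so the batch effect is estimable as the marginal mean of the
#' checks in that batch. Effects are centered on the grand mean of the
#' per-batch check means, so the adjustment has zero mean over batches and
#' preserves the trait scale.
#'
#' @param values data.frame with columns `line`, `batch`, `is_check`, and
#'   the trait in `value` (or name it via `trait`).
#' @param trait column name holding the trait (default `"value"`, falls
#'   back to `"y"`).
#' @return named numeric vector of per-batch effects.
#' @export
estimateBatchEffects <- function(values, trait = NULL) {
    trait <- trait %||% if ("value" %in% names(values)) "value" else "y"
    chk <- values[values$is_check & !is.na(values[[trait]]), , drop = FALSE]
    batches <- unique(as.character(values$batch))
    if (!nrow(chk)) stop("no check observations")
    means <- c(tapply(chk[[trait]], as.character(chk$batch), mean))
    if (!all(batches %in% names(means)))
        stop("batch without check observations: ",
             paste(setdiff(batches, names(means)), collapse = ", "))
    eff <- means - mean(means)
    eff[batches]
}

#' Subtract batch effects from trait values
#'
#' `adjusted = raw - effect(batch)`; checks are adjusted identically to
#' test lines, and missing raw values stay missing.
#'
#' @param values data.frame as in [estimateBatchEffects()].
#' @param effects named per-batch effects.
#' @param trait trait column name (default `"value"`/`"y"`).
#' @return the data.frame with an added `adjusted` column.
#' @export
adjustTraits <- function(values, effects, trait = NULL) {
    trait <- trait %||% if ("value" %in% names(values)) "value" else "y"
    values$adjusted <- values[[trait]] - effects[as.character(values$batch)]
    values
}

#' Augmented-design ANOVA on the check subset
#'
#' Two-way fixed-effects ANOVA (genotype + batch) on the replicated check
#' varieties, the part of the augmented design that carries replication.
#' With every check in every batch the design is balanced and the
#' sequential sums of squares equal the classical two-way decomposition;
#' genotype and batch are each tested against the residual.
#'
#' @param values data.frame with `line`, `batch`, `is_check` and the trait
#'   column.
#' @param trait trait column name (default `"value"`/`"y"`).
#' @return an `AnovaTable` data.frame: `source`, `df`, `ss`, `ms`, `f`,
#'   `p`.
#' @export
augmentedAnova <- function(values, trait = NULL) {
    trait <- trait %||% if ("value" %in% names(values)) "value" else "y"
    chk <- values[values$is_check & !is.na(values[[trait]]), , drop = FALSE]
    if (length(unique(chk$line)) < 2) stop("need >= 2 check varieties")
    if (length(unique(as.character(chk$batch))) < 2)
        stop("need checks replicated across >= 2 batches")
    d <- data.frame(y = chk[[trait]], genotype = factor(chk$line),
                    batch = factor(as.character(chk$batch)))
    fit <- stats::aov(y ~ genotype + batch, data = d)
    a <- summary(fit)[[1]]
    out <- data.frame(source = trimws(rownames(a)), df = a$Df,
                      ss = a$`Sum Sq`, ms = a$`Mean Sq`,
                      f = a$`F value`, p = a$`Pr(>F)`)
    out$source <- sub("genotype", "genotype", out$source)
    rownames(out) <- NULL
    out
}

#' Broad-sense heritability from the check ANOVA
#'
#' From the mean squares of the check-subset ANOVA:
#' `sigma2_g = (MS_genotype - MS_residual) / r` (clipped at 0),
#' `sigma2_e = MS_residual`, `H2 = sigma2_g / (sigma2_g + sigma2_e)`.
#' When any check variety is missing from any batch the estimate is not
#' available (`NA`), as the unbalanced check table no longer supports the
#' variance decomposition.
#'
#' @param anova an `AnovaTable` from [augmentedAnova()].
#' @param r replicate count (number of batches the checks appear in).
#' @param complete logical: were all checks observed in all batches?
#' @return a `HeritabilityEstimate` list: `H2`, `sigma2_g`, `sigma2_e`,
#'   `r`.
#' @export
heritability <- function(anova, r, complete = TRUE) {
    if (!complete)
        return(list(H2 = NA_real_, sigma2_g = NA_real_,
                    sigma2_e = NA_real_, r = r))
    msg <- anova$ms[anova$source == "genotype"]
    mse <- anova$ms[anova$source == "Residuals"]
    s2g <- max((msg - mse) / r, 0)
    s2e <- mse
    list(H2 = s2g / (s2g + s2e), sigma2_g = s2g, sigma2_e = s2e, r = r)
}

#' Check-ANOVA heritability straight from trait values
#'
#' Convenience wrapper: runs [augmentedAnova()] on the check subset,
#' determines the replicate count and check completeness, and returns
#' [heritability()].
#'
#' @inheritParams augmentedAnova
#' @return a `HeritabilityEstimate` list.
#' @export
augmentedHeritability <- function(values, trait = NULL) {
    trait <- trait %||% if ("value" %in% names(values)) "value" else "y"
    chk <- values[values$is_check, , drop = FALSE]
    present <- !is.na(chk[[trait]])
    tabCounts <- table(chk$line[present],
                       as.character(chk$batch[present]))
    complete <- all(tabCounts >= 1)
    r <- length(unique(as.character(chk$batch)))
    an <- augmentedAnova(values, trait)
    heritability(an, r, complete = complete)
}

#' Likelihood-ratio test of genotype-by-location interaction
#'
#' Fits, by maximum likelihood, a reduced variance-component model with a
#' random genotype effect and a full model adding a random
#' genotype-by-location effect, and compares them by a 1-df chi-squared
#' likelihood-ratio test (the interaction variance is tested on its
#' boundary; a halved-mixture p-value is available via `halved = TRUE`).
#' AIC, BIC and log-likelihoods of both fits are reported.
#'
#' @param values data.frame with columns `line`, `location`, and the trait
#'   column (`value`/`y`).
#' @param trait trait column name.
#' @param halved use the 0.5*chi2(0) + 0.5*chi2(1) boundary mixture for
#'   the p-value.
#' @return list: `chisq`, `df`, `p`, `fits` (data.frame with AIC, BIC,
#'   logLik per model), `varcomp` (interaction variance), `converged`.
#' @export
gxeLrt <- function(values, trait = NULL, halved = FALSE) {
    trait <- trait %||% if ("value" %in% names(values)) "value" else "y"
    d <- data.frame(y = values[[trait]], line = factor(values$line),
                    location = factor(values$location))
    d <- d[!is.na(d$y), , drop = FALSE]
    if (nlevels(droplevels(d$location)) < 2)
        stop("need observations at two locations")
    # one observation per line:location cell is legitimate here (the
    # interaction variance is then tested purely against the residual)
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.rankZ = "ignore",
                              check.nobs.vs.nRE = "ignore",
                              calc.derivs = FALSE)
    red <- lme4::lmer(y ~ location + (1 | line), data = d, REML = FALSE,
                      control = ctrl)
    full <- suppressMessages(lme4::lmer(
        y ~ location + (1 | line) + (1 | line:location), data = d,
        REML = FALSE, control = ctrl))
    ll <- c(reduced = as.numeric(stats::logLik(red)),
            full = as.numeric(stats::logLik(full)))
    chisq <- max(0, 2 * (ll["full"] - ll["reduced"]))
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    if (halved) p <- p / 2
    vc <- as.data.frame(lme4::VarCorr(full))
    vint <- vc$vcov[vc$grp == "line:location"]
    conv <- length(full@optinfo$conv$lme4$messages %||% character(0)) == 0
    list(chisq = unname(chisq), df = 1, p = unname(p),
         fits = data.frame(model = c("reduced", "full"),
             AIC = c(stats::AIC(red), stats::AIC(full)),
             BIC = c(stats::BIC(red), stats::BIC(full)),
             logLik = unname(ll)),
         varcomp = unname(vint), converged = conv)
}
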