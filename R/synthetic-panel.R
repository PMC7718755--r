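#' Specification of a synthetic oat association panel
#'
#' Parameters of the simulated study population. The defaults reproduce the
#' design of the CORE seed-vigor evaluation: 650 elite inbred lines with a
#' weak two-subpopulation structure (spring vs. southern oats, roughly a
#' fifth of the panel southern), 6 replicated check varieties, 22,767
#' biallelic SNPs on 21 linkage groups with a per-marker MAF floor of 0.05
#' and a small residual heterozygosity, phenotyped in batches of an
#' augmented design (8 batches at the primary site).
#'
#' @param nLines number of test lines (default 650).
#' @param nChecks number of check varieties replicated in every batch
#'   (default 6).
#' @param nMarkers number of SNP markers (default 22767).
#' @param nLinkageGroups number of linkage groups (default 21).
#' @param mapLengthCM linkage-group length in cM (recycled; default 150).
#' @param subpopFraction fraction of lines in the second subpopulation
#'   (default 0.2).
#' @param divergence allele-frequency divergence between subpopulations
#'   (absolute difference added to/subtracted from the base frequency;
#'   default 0.1, a weak structure).
#' @param hetRate residual heterozygosity rate of the inbred lines
#'   (default 0.02; stays safely below the 0.1 marker filter).
#' @param mafMin per-marker minor-allele-frequency floor enforced by
#'   rejection sampling (default 0.05).
#' @param qtn data.frame with columns `marker` (column index) and `effect`
#'   (additive allele-substitution effect), or `NULL` for a null trait.
#' @param h2 target narrow-sense signal fraction of the planted QTN
#'   (residual sd is scaled to meet it); `NA` to use `residualSd` directly.
#' @param nBatches number of batches (default 8).
#' @param batchSd standard deviation of batch effects (default 1).
#' @param structureEffect mean shift of the second subpopulation on the
#'   trait scale (default 0, i.e. no confounding).
#' @param residualSd residual standard deviation (default 1; ignored when
#'   `h2` is set and QTN are planted).
#' @param seed integer seed; fans out to independent per-component streams.
#' @return an object of class `PanelSpec` (a validated list).
#' @export
panelSpec <- function(nLines = 650, nChecks = 6, nMarkers = 22767,
                      nLinkageGroups = 21, mapLengthCM = 150,
                      subpopFraction = 0.2, divergence = 0.1,
                      hetRate = 0.02, mafMin = 0.05,
                      qtn = NULL, h2 = NA, nBatches = 8, batchSd = 1,
                      structureEffect = 0, residualSd = 1, seed = 1L) {
    stopifnot(nLines >= 1, nChecks >= 0, nMarkers >= 1, nLinkageGroups >= 1,
              all(mapLengthCM > 0), subpopFraction >= 0, subpopFraction <= 1,
              divergence >= 0, hetRate >= 0, hetRate < 1,
              mafMin >= 0, mafMin < 0.5, nBatches >= 1,
              is.finite(batchSd), batchSd >= 0, is.finite(residualSd),
              residualSd >= 0, is.finite(structureEffect))
    if (!is.null(qtn)) {
        qtn <- as.data.frame(qtn)
        stopifnot(all(c("marker", "effect") %in% names(qtn)),
                  all(is.finite(qtn$effect)))
        if (any(qtn$marker < 1 | qtn$marker > nMarkers))
            stop("QTN marker index out of range")
        if (nrow(qtn) > nMarkers) stop("more QTN than markers")
    }
    structure(list(nLines = as.integer(nLines), nChecks = as.integer(nChecks),
        nMarkers = as.integer(nMarkers),
        nLinkageGroups = as.integer(nLinkageGroups),
        mapLengthCM = rep_len(mapLengthCM, nLinkageGroups),
        subpopFraction = subpopFraction, divergence = divergence,
        hetRate = hetRate, mafMin = mafMin, qtn = qtn, h2 = h2,
        nBatches = as.integer(nBatches), batchSd = batchSd,
        structureEffect = structureEffect, residualSd = residualSd,
        seed = seed), class = "PanelSpec")
}

#' Simulate a structured inbred SNP panel
#'
#' Draws a biallelic genotype matrix for `nLines + nChecks` inbred lines in
#' two subpopulations. Each marker has a base allele frequency drawn from
#' U(0.15, 0.85); the two subpopulations sit at +/- `divergence`/2 around
#' it. Lines are homozygous except for a small `hetRate` of residual
#' heterozygous calls, matching elite oat germplasm and the het < 0.1 marker
#' filter. Markers whose realized MAF falls below `mafMin` are redrawn
#' (bounded retries), so the MAF floor holds on every run. Map positions are
#' drawn uniformly per linkage group and sorted.
#'
#' @param spec a [panelSpec()].
#' @return a list:
#'   \describe{
#'     \item{geno}{a [GenotypeData-class] for all `nLines + nChecks` lines
#'       (checks last, names `check_*`).}
#'     \item{subpop}{factor of subpopulation labels (`"pop1"`, `"pop2"`),
#'       one per line.}
#'   }
#' @export
simulateGenotypes <- function(spec) {
    stopifnot(inherits(spec, "PanelSpec"))
    n <- spec$nLines + spec$nChecks
    m <- spec$nMarkers
    withSeed(fanOutSeed(spec$seed, "genotypes"), {
        subpop <- factor(ifelse(
            seq_len(n) <= round(spec$nLines * (1 - spec$subpopFraction)) |
                seq_len(n) > spec$nLines,
            "pop1", "pop2"), levels = c("pop1", "pop2"))
        # checks assigned to pop1 by the rule above
        drawColumn <- function(nlin, p1, p2, pop) {
            p <- ifelse(pop == "pop1", p1, p2)
            hom <- 2 * rbinom(nlin, 1, p)
            het <- rbinom(nlin, 1, spec$hetRate) == 1
            hom[het] <- 1
            hom
        }
        G <- matrix(0, n, m)
        base <- runif(m, 0.15, 0.85)
        p1 <- pmin(pmax(base + spec$divergence / 2, 0.02), 0.98)
        p2 <- pmin(pmax(base - spec$divergence / 2, 0.02), 0.98)
        # vectorized first draw
        pmat <- matrix(ifelse(subpop == "pop1", 1, 0), n, m) * rep(p1, each = n) +
                matrix(ifelse(subpop == "pop2", 1, 0), n, m) * rep(p2, each = n)
        G <- 2 * matrix(rbinom(n * m, 1, pmat), n, m)
        hets <- matrix(rbinom(n * m, 1, spec$hetRate), n, m) == 1
        G[hets] <- 1
        maf <- function(col) {
            p <- mean(col) / 2
            min(p, 1 - p)
        }
        bad <- which(apply(G, 2, maf) < spec$mafMin)
        tries <- 0
        while (length(bad) && tries < 50) {
            tries <- tries + 1
            for (j in bad) {
                b <- runif(1, 0.2, 0.8)
                G[, j] <- drawColumn(n,
                    min(max(b + spec$divergence / 2, 0.02), 0.98),
                    min(max(b - spec$divergence / 2, 0.02), 0.98), subpop)
            }
            bad <- bad[vapply(bad, function(j) maf(G[, j]) < spec$mafMin,
                              logical(1))]
        }
        if (length(bad))
            stop("could not satisfy the MAF floor after bounded retries")
        lg <- sprintf("Mrg%02d", sort(rep_len(seq_len(spec$nLinkageGroups), m)))
        pos <- numeric(m)
        for (g in unique(lg)) {
            idx <- which(lg == g)
            gi <- as.integer(sub("Mrg", "", g))
            pos[idx] <- sort(runif(length(idx), 0, spec$mapLengthCM[gi]))
        }
        rownames(G) <- c(sprintf("line_%04d", seq_len(spec$nLines)),
                         if (spec$nChecks > 0)
                             sprintf("check_%d", seq_len(spec$nChecks)))
        map <- data.frame(marker = sprintf("snp_%05d", seq_len(m)),
                          lg = lg, pos_cM = pos)
        colnames(G) <- map$marker
        list(geno = genotypeData(G, map), subpop = subpop)
    })
}

#' Allocate lines to batches of an augmented design
#'
#' Test lines are split across batches without replication, batch sizes
#' differing by at most one; every check variety is assayed in every batch,
#' which is what makes the batch effects estimable.
#'
#' @param lines character vector of test-line names (or a count).
#' @param nBatches number of batches.
#' @param checks character vector of check-variety names (must be
#'   non-empty: without replicated checks the batch adjustment is
#'   impossible).
#' @return a `BatchLayout` data.frame with columns `line`, `batch`
#'   (factor), `is_check`.
#' @export
augmentedLayout <- function(lines, nBatches, checks) {
    if (length(checks) < 1) stop("at least one check variety is required")
    if (nBatches < 1) stop("nBatches must be >= 1")
    if (is.numeric(lines) && length(lines) == 1)
        lines <- sprintf("line_%04d", seq_len(lines))
    n <- length(lines)
    sizes <- rep(n %/% nBatches, nBatches)
    if (n %% nBatches > 0) sizes[seq_len(n %% nBatches)] <- sizes[1] + 1
    batch <- rep(seq_len(nBatches), sizes)
    layout <- rbind(
        data.frame(line = lines, batch = batch, is_check = FALSE),
        do.call(rbind, lapply(seq_len(nBatches), function(b)
            data.frame(line = checks, batch = b, is_check = TRUE))))
    layout$batch <- factor(layout$batch, levels = seq_len(nBatches))
    rownames(layout) <- NULL
    layout
}

#' Simulate phenotypes with planted QTN, batch and structure effects
#'
#' Generates one trait observation per layout entry (test lines once,
#' checks once per batch) under the additive model
#' `y = sum_q a_q g_q + structure + batch + e`, `e ~ N(0, sigma_e^2)`.
#' When the spec sets a target signal fraction `h2` and QTN are planted,
#' the residual sd is scaled so that the realized genetic-variance fraction
#' (relative to genetic + residual variance) matches the target.
#'
#' @param sim result of [simulateGenotypes()] (list with `geno`, `subpop`).
#' @param spec the [panelSpec()].
#' @param layout a [augmentedLayout()] data.frame; line names must exist in
#'   the genotype matrix.
#' @return a data.frame `line, batch, is_check, y` with attribute `truth`
#'   (list: `batchEffects`, `geneticValues`, `residSd`, `qtn`).
#' @export
simulatePhenotypes <- function(sim, spec, layout) {
    stopifnot(inherits(spec, "PanelSpec"))
    G <- genoCodes(sim$geno)
    missing <- setdiff(layout$line, rownames(G))
    if (length(missing))
        stop("layout lines absent from genotypes: ",
             paste(utils::head(missing, 3), collapse = ", "))
    withSeed(fanOutSeed(spec$seed, "phenotypes"), {
        gv <- setNames(numeric(nrow(G)), rownames(G))
        if (!is.null(spec$qtn) && nrow(spec$qtn)) {
            if (any(spec$qtn$marker > ncol(G)))
                stop("QTN marker index out of range")
            Z <- G[, spec$qtn$marker, drop = FALSE]
            Z <- scale(Z, center = TRUE, scale = FALSE)
            gv[] <- as.numeric(Z %*% spec$qtn$effect)
        }
        residSd <- spec$residualSd
        if (!is.na(spec$h2) && stats::var(gv) > 0)
            residSd <- sqrt(stats::var(gv) * (1 - spec$h2) / spec$h2)
        batchEff <- stats::rnorm(nlevels(layout$batch), 0, spec$batchSd)
        names(batchEff) <- levels(layout$batch)
        structEff <- ifelse(sim$subpop == "pop2", spec$structureEffect, 0)
        names(structEff) <- rownames(G)
        y <- gv[layout$line] + structEff[layout$line] +
            batchEff[as.character(layout$batch)] +
            stats::rnorm(nrow(layout), 0, residSd)
        out <- data.frame(line = layout$line, batch = layout$batch,
                          is_check = layout$is_check, y = as.numeric(y))
        attr(out, "truth") <- list(batchEffects = batchEff,
            geneticValues = gv, residSd = residSd, qtn = spec$qtn)
        out
    })
}
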