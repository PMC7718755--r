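#' Run the full seed-vigor pipeline on a synthetic panel
#'
#' End-to-end execution in the order of the study's workflow: pouch
#' images -> measurements -> trait table -> batch adjustment -> marker QC
#' -> association scan -> locus summary, with per-stage logs and a
#' run manifest (seeds, file hashes, package version). Inputs are
#' generated by the synthetic-data module from the panel spec in the
#' config; a subset of pouches is actually rendered and pushed through
#' the image stage so the segmentation contract is exercised on every
#' run, and their measured areas are compared against the renderer's
#' ground truth in the stage log.
#'
#' @param config a [runConfig()] (or a YAML path / named list accepted by
#'   it).
#' @return (invisibly) list with `geno`, `pheno`, `adjusted`, `assoc`
#'   ([AssociationResult-class]), `loci`, `imageCheck`, `manifest`, and
#'   the output directory `outdir`.
#' @export
runPipeline <- function(config = runConfig()) {
    if (is.character(config)) config <- runConfig(config)
    if (!inherits(config, "RunConfig")) config <- runConfig(overrides = config)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    logLines <- character(0)
    say <- function(...) logLines <<- c(logLines, sprintf(...))

    spec <- do.call(panelSpec, utils::modifyList(
        list(seed = config$seed), config$panel))
    say("panel: %d lines + %d checks, %d markers, seed %d",
        spec$nLines, spec$nChecks, spec$nMarkers, spec$seed)

    # stage 1: genotypes + layout + phenotypes
    sim <- simulateGenotypes(spec)
    layout <- augmentedLayout(spec$nLines, spec$nBatches,
        sprintf("check_%d", seq_len(max(spec$nChecks, 1))))
    pheno <- simulatePhenotypes(sim, spec, layout)
    say("phenotypes: %d observations in %d batches", nrow(pheno),
        nlevels(layout$batch))

    # stage 2: image phenotyping on a rendered subset (segmentation check)
    imageCheck <- NULL
    if (config$n_images > 0) {
        cal <- calibrationFor("taipei")
        imageCheck <- do.call(rbind, lapply(seq_len(config$n_images),
            function(i) {
                sp <- randomPouchSpec(seed = fanOutSeed(config$seed,
                                                        paste0("image", i)))
                out <- renderPouchImage(sp)
                meas <- phenotypePouch(out$raster, shootConfig = NULL,
                    cal = cal, metadata = list(line = sprintf("img_%02d", i)))
                data.frame(image = i, truth_px = out$truth$areaPx,
                    measured_px = meas$root_area_mm2 / mm2PerPx(cal))
            }))
        say("image stage: %d/%d pouches segmented to exact truth area",
            sum(abs(imageCheck$truth_px - imageCheck$measured_px) < 1e-9),
            nrow(imageCheck))
    }

    # stage 3: batch adjustment on the augmented design
    eff <- estimateBatchEffects(pheno)
    adjusted <- adjustTraits(pheno, eff)
    h2 <- augmentedHeritability(pheno)
    say("batch effects: sd %.3f; check-ANOVA H2 = %s", stats::sd(eff),
        format(round(h2$H2, 3)))

    # stage 4: marker QC
    geno <- filterMarkers(sim$geno)
    say("marker QC: %d markers kept (%d removed)", ncol(geno),
        attr(markerMap(geno), "removed"))

    # stage 5: association scan on adjusted test-line values
    test <- adjusted[!adjusted$is_check, ]
    y <- setNames(test$adjusted, test$line)
    gTest <- geno[match(names(y), lineNames(geno)), ]
    assoc <- runFarmcpu(as.numeric(y), gTest,
        nPcs = config$gwas$n_pcs, alpha = config$gwas$alpha,
        fdrQ = config$gwas$fdr_q, minSepCM = config$gwas$min_sep_cM,
        maxIter = config$gwas$max_iter)
    say("gwas: %d pseudo-QTN, lambda %.3f, %d FDR hit(s)",
        length(pseudoQtns(assoc)), inflationLambda(assoc),
        length(fdrHits(assoc)))

    # stage 6: locus summary of the significant set
    tab <- assocTable(assoc)
    sig <- tab[tab$marker %in% fdrHits(assoc), , drop = FALSE]
    loci <- if (nrow(sig)) {
        sig$trait <- "synthetic_trait"
        summarizeLoci(sig)
    } else list(loci = NULL, counts = list(n_snps = 0, n_loci = 0))
    say("loci: %d unique SNP(s), %d unique locus/loci",
        loci$counts$n_snps, loci$counts$n_loci)

    # outputs + manifest
    paths <- c(
        writeGenotypes(geno, file.path(config$outdir, "genotypes")),
        pheno = { p <- file.path(config$outdir, "phenotypes.csv")
                  writeMeasurements(adjusted, p); p },
        assoc = { p <- file.path(config$outdir, "associations.csv")
                  writeMeasurements(tab, p); p })
    if (!is.null(loci$loci)) {
        p <- file.path(config$outdir, "loci.csv")
        writeMeasurements(loci$loci, p)
        paths <- c(paths, loci = p)
    }
    manifest <- list(
        package = as.character(utils::packageVersion("oatvigor")),
        seed = config$seed,
        files = as.list(tools::md5sum(unname(paths))),
        log = logLines)
    yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
    writeLines(logLines, file.path(config$outdir, "pipeline.log"))
    invisible(list(geno = geno, pheno = pheno, adjusted = adjusted,
                   assoc = assoc, loci = loci, imageCheck = imageCheck,
                   manifest = manifest, outdir = config$outdir))
}

#' A small randomized pouch spec
#'
#' Convenience generator of a plausible pouch image spec (a few roots, a
#' couple of shoots, sub-300-px specks) with exact ground truth; used by
#' the pipeline's image-stage self-check and handy in tests.
#'
#' @param widthPx,heightPx canvas size.
#' @param nRoots,nShoots,nSpecks structure counts.
#' @param seed integer seed.
#' @return an [imageSpec()].
#' @export
randomPouchSpec <- function(widthPx = 240, heightPx = 200, nRoots = 3,
                            nShoots = 2, nSpecks = 5, seed = 1L) {
    withSeed(seed, {
        roots <- lapply(seq_len(nRoots), function(i) {
            x0 <- runif(1, 20, widthPx - 20)
            pts <- rbind(c(x0, 30),
                         c(x0 + runif(1, -15, 15), heightPx / 2),
                         c(x0 + runif(1, -25, 25), heightPx - 12))
            pts[, 1] <- pmin(pmax(pts[, 1], 8), widthPx - 9)
            list(points = pts, width = sample(3:5, 1), gray = 220)
        })
        shoots <- lapply(seq_len(nShoots), function(i) {
            list(base = c(runif(1, 30, widthPx - 30), 28),
                 length = sample(22:28, 1), width = sample(16:20, 1),
                 gray = 200)
        })
        specks <- lapply(seq_len(nSpecks), function(i)
            list(area = sample(5:40, 1), gray = 210))
        imageSpec(widthPx, heightPx, backgroundGray = 100, roots = roots,
                  shoots = shoots, specks = specks, seed = seed)
    })
}
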